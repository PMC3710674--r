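test_that("protocol initialisation sets phase, target and side map", {
  cfg <- cage_config()
  hab <- init_protocol(cfg, session_plan("HABITUATION", 6), c("a", "b"))
  expect_true(all(vapply(hab, `[[`, "", "phase") == "HABITUATION"))
  alt <- init_protocol(cfg, session_plan("ALTERNATION", 30), "a")
  expect_identical(alt$a$phase, "ALTERNATION")
  expect_true(is.na(alt$a$target_corner))  # either active corner is correct
  expect_identical(alt$a$side_map, cfg$rewarded_side_map)
  rev <- init_protocol(cfg, session_plan("REVERSAL", 6), "a")
  expect_identical(unname(rev$a$side_map[cfg$active_pair]),
                   unname(ifelse(cfg$rewarded_side_map[cfg$active_pair] ==
                                   "left", "right", "left")))
  expect_error(init_protocol(cfg, session_plan("ALTERNATION", 1),
                             character()), "empty roster")
  expect_error(init_protocol(cfg, session_plan("ALTERNATION", 1),
                             c("a", "a")), "duplicate")
})

test_that("a correct visit rewards the first rewarded-side poke and switches the target", {
  cfg <- cage_config()  # C1 rewards left, C2 rewards right
  st <- init_protocol(cfg, session_plan("ALTERNATION", 30), "m")[["m"]]
  st$target_corner <- "C1"
  # first poke already on the rewarded side
  res <- process_visit(st, list(corner = "C1", t_entry = 0, t_exit = 20),
                       list(side = "left", t = 5), cfg)
  expect_identical(res$annotation, "correct")
  expect_identical(res$initial_poke, "correct")
  expect_identical(res$reward$side, "left")
  expect_identical(res$reward$door_open_s, 8)
  expect_identical(res$state$target_corner, "C2")
  # wrong side first: no penalty, reward on the later correct-side poke
  st$target_corner <- "C1"
  res <- process_visit(st, list(corner = "C1", t_entry = 0, t_exit = 20),
                       list(side = c("right", "left"), t = c(5, 7)), cfg)
  expect_identical(res$annotation, "correct")
  expect_identical(res$initial_poke, "incorrect")
  expect_identical(res$reward$t_open, 7)
  expect_identical(res$state$target_corner, "C2")
  # poking without the rewarded side never opens the door
  st$target_corner <- "C1"
  res <- process_visit(st, list(corner = "C1", t_entry = 0, t_exit = 20),
                       list(side = "right", t = 5), cfg)
  expect_null(res$reward)
  expect_identical(res$annotation, "correct")
  expect_identical(res$state$target_corner, "C2")
})

test_that("non-target and exploratory visits leave the target unchanged", {
  cfg <- cage_config()
  st <- init_protocol(cfg, session_plan("ALTERNATION", 30), "m")[["m"]]
  st$target_corner <- "C1"
  res <- process_visit(st, list(corner = "C2", t_entry = 0, t_exit = 10),
                       list(side = "right", t = 2), cfg)
  expect_identical(res$annotation, "incorrect")
  expect_null(res$reward)
  expect_identical(res$state$target_corner, "C1")
  res <- process_visit(st, list(corner = "C3", t_entry = 0, t_exit = 10),
                       list(side = character(), t = numeric()), cfg)
  expect_identical(res$annotation, "exploratory")
  expect_identical(res$state$target_corner, "C1")
  expect_error(process_visit(st, list(corner = "C9", t_entry = 0,
                                      t_exit = 1),
                             list(side = character(), t = numeric()), cfg),
               "corner")
})

test_that("habituation opens doors on every entry without task bookkeeping", {
  cfg <- cage_config()
  st <- init_protocol(cfg, session_plan("HABITUATION", 6), "m")[["m"]]
  for (cn in cfg$corner_ids) {
    res <- process_visit(st, list(corner = cn, t_entry = 0, t_exit = 30),
                         list(side = "left", t = 1), cfg)
    expect_identical(res$annotation, "habituation")
    expect_null(res$reward)
    expect_true(is.na(res$state$target_corner))
  }
})

test_that("side swap is an involution on task states and illegal in habituation", {
  cfg <- cage_config()
  st <- init_protocol(cfg, session_plan("ALTERNATION", 30), "m")[["m"]]
  swapped <- apply_side_swap(st)
  expect_identical(unname(swapped$side_map), c("right", "left"))
  expect_identical(apply_side_swap(swapped)$side_map, st$side_map)
  hab <- init_protocol(cfg, session_plan("HABITUATION", 6), "m")[["m"]]
  expect_error(apply_side_swap(hab), "HABITUATION")
})

test_that("non-licker demotion targets exactly the silent task animals", {
  cfg <- cage_config()
  states <- init_protocol(cfg, session_plan("ALTERNATION", 48),
                          c("quiet", "one_lick", "steady"))
  licks <- data.frame(
    animal_id = c("one_lick", rep("steady", 5)),
    t = c(10 * 3600, (1:5) * 3600), stringsAsFactors = FALSE)
  res <- demote_nonlickers(states, licks, window_h = 24, now_s = 24 * 3600)
  expect_identical(res$demoted, "quiet")
  expect_identical(res$states$quiet$phase, "HABITUATION")
  expect_identical(res$states$one_lick$phase, "ALTERNATION")
  res2 <- demote_nonlickers(res$states["steady"], licks, 24, 24 * 3600)
  expect_length(res2$demoted, 0)
  expect_error(demote_nonlickers(states, licks, window_h = 0), "positive")
})

test_that("session replay walks the weekly plan segments and is deterministic", {
  plan <- session_plan(c("HABITUATION", "ALTERNATION", "REVERSAL"),
                       c(6, 30, 6))
  sim <- quiet_sim(preset_cohort("WT_like", 4), plan = plan, seed = 5)
  sess1 <- run_session(sim$stream, plan)
  sess2 <- run_session(sim$stream, plan)
  expect_identical(sess1$visits, sess2$visits)
  expect_identical(sess1$rewards, sess2$rewards)
  segs <- sess1$trace[sess1$trace$event == "segment_start", ]
  expect_identical(segs$detail, c("ALTERNATION", "REVERSAL"))
  expect_setequal(unique(sess1$visits$phase),
                  c("HABITUATION", "ALTERNATION", "REVERSAL"))
  # an empty stream still replays the full control timeline
  empty <- event_stream(make_visits(character(), numeric(), numeric(),
                                    animal_id = character()),
                        roster = "m1", duration_s = 42 * 3600,
                        validate = FALSE)
  sess0 <- run_session(empty, plan)
  expect_identical(nrow(sess0$visits), 0L)
  expect_identical(sum(sess0$trace$event == "segment_start"), 2L)
  # events beyond the plan are refused
  long <- event_stream(make_visits("C1", 43 * 3600), validate = FALSE)
  expect_error(run_session(long, plan), "beyond")
})

test_that("rewards are conserved and the target strictly alternates", {
  plan <- session_plan("ALTERNATION", 24)
  sim <- quiet_sim(preset_cohort("WT_like", 6), plan = plan, seed = 21)
  sess <- run_session(sim$stream, plan)
  v <- sess$visits
  # every reward sits in a correct visit that contains a rewarded-side poke
  expect_identical(nrow(sess$rewards), sum(v$rewarded))
  expect_true(all(v$annotation[v$rewarded] == "correct"))
  expect_lte(nrow(sess$rewards), sum(v$annotation == "correct"))
  for (a in unique(v$animal_id)) {
    va <- v[v$animal_id == a & v$annotation == "correct", ]
    if (nrow(va) < 2) next
    # after each correct visit the target is the other active corner
    expect_true(all(va$target_after != va$corner))
    expect_true(all(va$corner[-1] != va$corner[-nrow(va)]))
  }
})

test_that("a side_swap alternation segment rewards the mirrored sides", {
  cfg <- cage_config()  # base map: C1 left, C2 right
  plan <- session_plan("ALTERNATION", 30, side_swap = TRUE)
  v <- make_visits(c("C1", "C2"), c(0, 100), c(20, 120))
  np <- data.frame(animal_id = "m1", corner = c("C1", "C1", "C2"),
                   side = c("left", "right", "left"), t = c(2, 4, 102),
                   stringsAsFactors = FALSE)
  sess <- run_session(event_stream(v, np, config = cfg), plan)
  # swapped map: C1 right, C2 left; first poke (left) is now wrong
  expect_identical(sess$visits$initial_poke, c("incorrect", "correct"))
  expect_identical(sess$rewards$side, c("right", "left"))
})

test_that("injected non-lickers are demoted at the next daily check", {
  plan <- session_plan("ALTERNATION", 36)
  sim <- quiet_sim(preset_cohort("WT_like", 5), plan = plan, seed = 3)
  victims <- sim$stream$roster[1:2]
  stream <- inject_nonlickers(sim$stream, victims, onset_s = 0)
  sess <- run_session(stream, plan)
  demoted <- names(Filter(function(s) s$demoted, sess$states))
  expect_setequal(demoted, victims)
  # their visits after the 24-h check are habituation-annotated
  late <- sess$visits[sess$visits$animal_id %in% victims &
                        sess$visits$t_entry >= 24 * 3600, ]
  expect_true(all(late$annotation == "habituation"))
  # an untouched stream demotes nobody
  sess2 <- run_session(sim$stream, plan)
  expect_length(names(Filter(function(s) s$demoted, sess2$states)), 0)
  expect_error(inject_nonlickers(sim$stream, "nobody"), "unknown")
  expect_identical(inject_nonlickers(sim$stream, character()), sim$stream)
  expect_identical(
    inject_nonlickers(sim$stream, victims, onset_s = 40 * 3600)$licks,
    sim$stream$licks)
})

test_that("engine agrees with the brute-force rules on short sequences", {
  cfg <- cage_config()
  sym <- contingency_symbols(cfg$active_pair, cfg$exploratory_pair)
  for (len in 1:3) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(sym))), len)))
    tm <- gap_pattern(len, "short")
    for (r in seq_len(nrow(grid))) {
      corners <- sym$corner[grid[r, ]]
      rel <- sym$poke_rel[grid[r, ]]
      got <- engine_annotate(corners, rel, tm$t_entry, tm$t_exit, cfg)
      want <- oracle_annotate(corners, rel, cfg$active_pair)
      expect_identical(got, want)
    }
  }
})
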