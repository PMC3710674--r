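sch7 <- light_schedule(lights_on_clock = 7)

test_that("corner-entry rates normalise by true per-phase exposure", {
  # 24 visits, one per hour, session starting at lights-on
  v <- regular_visits(24, spacing_s = 3600, t0 = 1800)
  ce <- score_corner_entries(v, sch7, 7, 24 * 3600)
  expect_equal(unname(ce), c(1, 1))
  # all entries in the dark half
  vd <- regular_visits(12, spacing_s = 3600, t0 = 12 * 3600 + 1800)
  ce <- score_corner_entries(vd, sch7, 7, 24 * 3600)
  expect_equal(unname(ce), c(0, 1))
  # 30-h session: 18 h light exposure, 12 h dark; hand-computed rates
  v30 <- regular_visits(30, spacing_s = 3600, t0 = 1800)
  ph <- assign_light_phase(v30$t_entry, 7, sch7)
  expect_equal(unname(score_corner_entries(v30, sch7, 7, 30 * 3600)),
               c(sum(ph == "light") / 18, sum(ph == "dark") / 12))
  # zero-exposure phase is undefined, not zero
  ce6 <- score_corner_entries(regular_visits(6), sch7, 7, 6 * 3600)
  expect_true(is.na(ce6["dark"]))
})

test_that("lick rates sum counts within the phase of each lick", {
  no_licks <- data.frame(animal_id = character(), corner = character(),
                         t = numeric(), lick_count = integer())
  expect_equal(unname(score_licks(no_licks, sch7, 7, 24 * 3600)), c(0, 0))
  licks <- data.frame(animal_id = "m1", corner = "C1",
                      t = seq(12.5, 23.5, by = 1) * 3600,
                      lick_count = 50L)
  expect_equal(unname(score_licks(licks, sch7, 7, 24 * 3600)), c(0, 50))
  # brute-force recount across an arbitrary scatter of lick times
  set.seed(42)
  licks <- data.frame(animal_id = "m1", corner = "C1",
                      t = sort(runif(200, 0, 30 * 3600)),
                      lick_count = rpois(200, 20) + 1L)
  got <- score_licks(licks, sch7, 7, 30 * 3600)
  ph <- assign_light_phase(licks$t, 7, sch7)
  expect_equal(unname(got),
               c(sum(licks$lick_count[ph == "light"]) / 18,
                 sum(licks$lick_count[ph == "dark"]) / 12))
})

test_that("repeat percentage counts unchanged-corner transitions", {
  t4 <- c(0, 60, 120, 180)
  expect_equal(score_repeats(make_visits(c("C1", "C2", "C3", "C4"), t4)), 0)
  expect_equal(score_repeats(make_visits(c("C1", "C1", "C1"), t4[1:3])),
               100)
  expect_equal(score_repeats(
    make_visits(c("C1", "C1", "C2", "C2", "C3"), c(t4, 240))), 50)
  expect_true(is.na(score_repeats(make_visits("C1", 0))))
  # transitions never cross animals
  v <- rbind(make_visits(c("C1", "C2"), c(0, 60), animal_id = "a"),
             make_visits(c("C2", "C2"), c(30, 90), animal_id = "b"))
  expect_equal(score_repeats(v), 100 * 1 / 2)
})

test_that("percent alternation follows the windowed transition rules", {
  ap <- c("C1", "C2")
  perfect <- make_visits(c("C1", "C2", "C1", "C2"), (0:3) * 60,
                         (0:3) * 60 + 10)
  expect_equal(score_alternation(perfect, ap), 100)
  stuck <- make_visits(c("C1", "C1", "C1"), (0:2) * 60, (0:2) * 60 + 10)
  expect_equal(score_alternation(stuck, ap), 0)
  # the mixed case: one excluded long gap, exploratory visit irrelevant
  mixed <- make_visits(c("C1", "C3", "C2", "C2", "C1"),
                       c(0, 15, 30, 50, 200), c(10, 18, 40, 60, 210))
  expect_equal(score_alternation(mixed, ap), 50)
  expect_equal(score_alternation(mixed, ap, window_s = Inf), 200 / 3)
  # agreement with the literal brute-force restatement of the rules
  expect_equal(score_alternation(mixed, ap),
               oracle_alternation(mixed$corner, mixed$t_entry, mixed$t_exit,
                                  ap))
  expect_equal(score_alternation(mixed, ap, window_s = Inf),
               oracle_alternation(mixed$corner, mixed$t_entry, mixed$t_exit,
                                  ap, Inf))
  # the "all transitions" denominator keeps the excluded pair in the count
  expect_equal(score_alternation(mixed, ap, denominator = "all"), 100 / 3)
  expect_true(is.na(score_alternation(make_visits("C1", 0), ap)))
  # exploratory insertions with short gaps never change the score
  base <- make_visits(c("C1", "C2", "C1"), c(0, 50, 100), c(10, 60, 110))
  padded <- make_visits(c("C1", "C3", "C2", "C4", "C1"),
                        c(0, 20, 50, 70, 100), c(10, 25, 60, 75, 110))
  expect_equal(score_alternation(padded, ap), score_alternation(base, ap))
})

test_that("collected rewards count poked active-corner entries only", {
  ap <- c("C1", "C2")
  v <- make_visits(c("C1", "C2", "C1", "C2", "C3"), (0:4) * 100,
                   (0:4) * 100 + 20)
  poke_at <- function(ts, corners)
    data.frame(animal_id = "m1", corner = corners, side = "left", t = ts,
               stringsAsFactors = FALSE)
  expect_equal(score_collected_rewards(
    v, poke_at((0:3) * 100 + 5, c("C1", "C2", "C1", "C2")), ap), 100)
  expect_equal(score_collected_rewards(
    v, poke_at((0:2) * 100 + 5, c("C1", "C2", "C1")), ap), 75)
  # a poke during the exploratory visit changes nothing
  expect_equal(score_collected_rewards(
    v, poke_at(c((0:2) * 100 + 5, 405), c("C1", "C2", "C1", "C3")), ap),
    75)
  expect_true(is.na(score_collected_rewards(
    make_visits("C3", 0), poke_at(numeric(), character()), ap)))
})

test_that("the score table has one row per animal and phase with masked phases", {
  plan <- session_plan(c("HABITUATION", "ALTERNATION"), c(6, 18))
  sim <- quiet_sim(preset_cohort("WT_like", 4), plan = plan, seed = 8)
  sess <- run_session(sim$stream, plan)
  st <- build_score_table(sess, "wk1")
  expect_identical(nrow(st), 8L)
  expect_identical(unique(st$session_label), "wk1")
  expect_setequal(st$light_phase, c("light", "dark"))
  expect_true(all(st$corner_entries >= 0))
  ok <- !is.na(st$alternation_pct)
  expect_true(all(st$alternation_pct[ok] >= 0 & st$alternation_pct[ok] <= 100))
  # per-phase slices recount to the same entry rates
  a1 <- st$animal_id[1]
  va <- sess$visits[sess$visits$animal_id == a1, ]
  ph <- assign_light_phase(va$t_entry, sim$stream$session_start_clock,
                           sim$stream$schedule)
  expo <- phase_exposure_hours(sim$stream$session_start_clock,
                               sim$stream$schedule, plan_total_s(plan))
  expect_equal(st$corner_entries[st$animal_id == a1],
               unname(c(sum(ph == "light"), sum(ph == "dark")) / expo))
  # alternation is computed from task-phase visits only
  task <- va[va$phase == "ALTERNATION", ]
  expect_equal(
    st$alternation_pct[st$animal_id == a1],
    unname(score_alternation(task, sim$stream$config$active_pair,
                             schedule = sim$stream$schedule,
                             session_start_clock =
                               sim$stream$session_start_clock)))
})

test_that("undefined measures propagate as missing, never as 0 or 100", {
  # an animal that never visits during the dark phase and never meets an
  # active corner in the task phase
  v <- make_visits(c("C3", "C4"), c(100, 200), c(110, 210))
  stream <- event_stream(v, config = cage_config(),
                         schedule = sch7, duration_s = 24 * 3600)
  sess <- run_session(stream, session_plan("ALTERNATION", 24))
  st <- build_score_table(sess)
  expect_true(all(is.na(st$alternation_pct)))
  expect_true(all(is.na(st$collected_rewards_pct)))
  expect_true(is.na(st$repeat_pct[st$light_phase == "dark"]))
  expect_equal(st$corner_entries[st$light_phase == "dark"], 0)
})
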