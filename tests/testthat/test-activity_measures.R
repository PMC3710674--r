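par30 <- activity_params(frame_rate_hz = 30)

test_that("track linking follows detections and splits at gaps", {
  # one detection per frame -> a single tracklet
  fr <- const_speed_frames(2, 50)
  tr <- link_tracks(fr, par30)
  expect_identical(length(unique(tr$track_id)), 1L)
  # two well-separated constant-velocity mice keep their assignment
  a <- const_speed_frames(3, 40, y0 = 5)
  b <- const_speed_frames(3, 40, x0 = 45, y0 = 30)
  b$x_cm <- 45 - 3 * (b$t - b$t[1])  # moving the other way
  tr <- link_tracks(rbind(a, b), par30)
  expect_identical(length(unique(tr$track_id)), 2L)
  ids <- unique(tr$track_id[tr$y_cm == 5])
  expect_length(ids, 1)
  expect_false(ids %in% tr$track_id[tr$y_cm == 30])
  # a frame gap beyond min_track_gap_frames starts a new tracklet
  fr2 <- const_speed_frames(2, 20)
  fr2$t[11:20] <- fr2$t[11:20] + 1  # 1-s hole
  tr2 <- link_tracks(fr2, par30)
  expect_identical(length(unique(tr2$track_id)), 2L)
})

test_that("locomotion is distance normalised by mice detected per frame", {
  sch <- light_schedule(lights_on_clock = 7)
  # one mouse covering 100 cm
  one <- const_speed_frames(10, 301)  # 10 cm/s for 10 s
  loco <- compute_locomotion(one, sch, 7, par30)
  expect_equal(unname(loco["light"]), 100, tolerance = 1e-9)
  expect_equal(unname(loco["dark"]), 0)
  # two mice, 100 cm each -> still 100 cm per mouse
  two <- rbind(one, transform(one, y_cm = 30))
  expect_equal(unname(compute_locomotion(two, sch, 7, par30)["light"]),
               100, tolerance = 1e-9)
  # adding a perfectly stationary mouse halves the per-mouse figure
  with_idle <- rbind(one, transform(one, x_cm = 50, y_cm = 30))
  with_idle$x_cm[302:602] <- 50
  expect_equal(unname(compute_locomotion(with_idle, sch, 7,
                                         par30)["light"]),
               50, tolerance = 1e-9)
  # a stationary scene travels nowhere
  still <- const_speed_frames(0, 100)
  expect_equal(unname(compute_locomotion(still, sch, 7, par30)["light"]), 0)
})

test_that("immobility applies the strict 0.7 cm/s cutoff per animal-frame", {
  sch <- light_schedule(lights_on_clock = 7)
  imm <- function(fr) {
    unname(compute_immobility(link_tracks(fr, par30), par30, sch,
                              7)["light"])
  }
  expect_equal(imm(const_speed_frames(0, 60)), 100)
  expect_equal(imm(const_speed_frames(1.0, 60)), 0)
  expect_equal(imm(const_speed_frames(0.7, 60)), 0)  # boundary: not immobile
  expect_equal(imm(const_speed_frames(0.699, 60)), 100)
  # half the animal-frames slow, half fast -> exactly 50%
  slow <- const_speed_frames(0.5, 61)
  fast <- const_speed_frames(2.0, 61, y0 = 30, t0 = 10)
  expect_equal(imm(rbind(slow, fast)), 50)
})

test_that("immobility cannot increase when all speeds scale up", {
  set.seed(7)
  steps <- cumsum(runif(100, 0, 0.06))
  base <- data.frame(t = (0:99) / 30, x_cm = 5 + steps, y_cm = 10,
                     box_w_cm = 4, box_h_cm = 3)
  sch <- light_schedule(lights_on_clock = 7)
  vals <- vapply(c(0.5, 1, 2, 4), function(k) {
    fr <- base
    fr$x_cm <- 5 + k * steps
    unname(compute_immobility(link_tracks(fr, par30), par30, sch,
                              7)["light"])
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("rearing/climbing unions zone occupancy with wall-hugging tall boxes", {
  cfg <- cage_config(climb_zones = list(c(20, 14, 35, 24)))
  sch <- light_schedule(lights_on_clock = 7)
  inside <- data.frame(t = (0:9) / 30, x_cm = 27, y_cm = 20,
                       box_w_cm = 4, box_h_cm = 3)
  expect_equal(unname(compute_rearing_climbing(inside, cfg, par30, sch,
                                               7)["light"]), 100)
  center <- data.frame(t = (0:9) / 30, x_cm = 10, y_cm = 20,
                       box_w_cm = 4, box_h_cm = 3)
  expect_equal(unname(compute_rearing_climbing(center, cfg, par30, sch,
                                               7)["light"]), 0)
  # wall-adjacent and tall -> rearing; wall-adjacent and flat -> not
  rear <- data.frame(t = (0:9) / 30, x_cm = 1, y_cm = 20,
                     box_w_cm = 2, box_h_cm = 4)
  flat <- transform(rear, box_h_cm = 2.5)
  expect_equal(unname(compute_rearing_climbing(rear, cfg, par30, sch,
                                               7)["light"]), 100)
  expect_equal(unname(compute_rearing_climbing(flat, cfg, par30, sch,
                                               7)["light"]), 0)
  # known mixture: 3 of 10 detections in a zone
  mix <- rbind(inside[1:3, ], center[1:7, ])
  mix$t <- (0:9) / 30
  expect_equal(unname(compute_rearing_climbing(mix, cfg, par30, sch,
                                               7)["light"]), 30)
  nozone <- cage_config(climb_zones = list())
  expect_warning(compute_rearing_climbing(center, nozone, par30, sch, 7),
                 "climb zones")
})

test_that("the activity table combines the three endpoints per phase", {
  cfg <- cage_config()
  sch <- light_schedule(lights_on_clock = 7)
  fr <- const_speed_frames(2, 200)
  at <- build_activity_table(fr, cfg, par30, sch, 7, "wk1")
  expect_identical(nrow(at), 2L)
  expect_identical(at$light_phase, c("light", "dark"))
  light <- at[at$light_phase == "light", ]
  expect_equal(light$locomotion_cm_per_mouse, 2 * 199 / 30,
               tolerance = 1e-9)
  expect_equal(light$pct_time_immobile, 0)
  expect_true(is.na(at$pct_time_immobile[at$light_phase == "dark"]))
})

test_that("simulated scenes reproduce the generator's immobility ground truth", {
  pars <- preset_cohort("WT_like", 2)
  pars <- lapply(pars, function(p) {
    p$immobile_fraction <- 0.4
    p$climb_rate_per_h <- 0
    p
  })
  sim <- quiet_sim(pars, plan = session_plan("ALTERNATION", 2), seed = 12,
                   frames = TRUE, frames_window_s = c(0, 1800),
                   frame_rate_hz = 5)
  par5 <- activity_params(frame_rate_hz = 5)
  got <- compute_immobility(link_tracks(sim$stream$frames, par5), par5,
                            sim$stream$schedule,
                            sim$stream$session_start_clock)
  truth <- 100 * mean(sim$frames_truth$immobile)
  expect_equal(unname(got["light"]), truth, tolerance = 0.12)
})
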