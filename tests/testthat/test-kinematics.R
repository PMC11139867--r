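test_that("step lengths are per-transition Euclidean distances", {
  expect_equal(step_lengths(make_traj(c(0, 3), c(0, 4))), 5)  # 3-4-5
  expect_equal(step_lengths(make_traj(rep(2, 10), rep(3, 10))), rep(0, 9))
  expect_error(step_lengths(make_traj(1, 1)),
               class = "fluctkin_run_too_short")
  expect_error(step_lengths(make_traj(c(1, 2), c(1, 2),
                                      visible = c(TRUE, FALSE))),
               class = "fluctkin_run_not_visible")
  # against an independently coded distance loop
  withr::local_seed(1)
  r <- random_traj(n = 40, p_visible = 1)
  manual <- sapply(1:39, function(i)
    sqrt((r$x[i + 1] - r$x[i])^2 + (r$y[i + 1] - r$y[i])^2))
  expect_equal(step_lengths(r), manual)
})

test_that("total travel distance matches the brute-force oracle and skips gaps", {
  expect_equal(total_travel_distance(make_traj(1, 1, visible = FALSE)), 0)
  # square path of side 10
  sq <- make_traj(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(total_travel_distance(sq), 40)
  withr::local_seed(2)
  for (i in 1:10) {
    t <- random_traj(n = sample(2:100, 1), p_visible = runif(1))
    expect_equal(total_travel_distance(t), oracle_travel_distance(t))
  }
})

test_that("distance indices are translation invariant and scale linearly", {
  withr::local_seed(3)
  t <- random_traj(n = 80, p_visible = 0.8)
  shifted <- make_traj(t$x + 50, t$y + 50, t$visible)
  expect_equal(total_travel_distance(shifted), total_travel_distance(t))
  scaled <- tip_trajectory(t$x * 2.5, t$y * 2.5, t$visible,
                           frame_width = 25000, frame_height = 25000)
  expect_equal(total_travel_distance(scaled), 2.5 * total_travel_distance(t))
})

test_that("speed/acceleration/jerk follow the scalar finite-difference chain", {
  # straight line at 4 px/frame, 30 fps
  line <- make_traj(x = 4 * (0:9), y = rep(0, 10))
  expect_equal(speed_series(line), rep(120, 9))
  expect_equal(acceleration_series(line), rep(0, 8))
  expect_equal(jerk_series(line), rep(0, 7))
  # speed ramp 0,1,2,... px/frame: acceleration 30*30, jerk 0
  ramp <- make_traj(x = cumsum(0:8), y = rep(0, 9))
  expect_equal(acceleration_series(ramp), rep(900, 7))
  expect_equal(jerk_series(ramp), rep(0, 6))
  # jerk of any quadratic 1-D path is ~0
  quad <- make_traj(x = 0.05 * (0:20)^2, y = rep(0, 21))
  expect_equal(jerk_series(quad), rep(0, 18), tolerance = 1e-10)
  # random run vs independently coded finite differences
  withr::local_seed(4)
  r <- random_traj(n = 30, p_visible = 1)
  d <- sapply(1:29, function(i)
    sqrt((r$x[i + 1] - r$x[i])^2 + (r$y[i + 1] - r$y[i])^2))
  v <- d * 30
  expect_equal(speed_series(r), v)
  expect_equal(acceleration_series(r), (v[-1] - v[-29]) * 30)
  a <- (v[-1] - v[-29]) * 30
  expect_equal(jerk_series(r), (a[-1] - a[-28]) * 30)
  expect_error(jerk_series(make_traj(1:3, 1:3)),
               class = "fluctkin_run_too_short")
})

test_that("occurrence rate is visible frames over total frames", {
  expect_equal(occurrence_rate(make_traj(1:5, 1:5)), 1)
  expect_equal(occurrence_rate(make_traj(1, 1, visible = FALSE)), 0)
  vis <- rep(c(TRUE, FALSE), c(618, 382))
  expect_equal(occurrence_rate(make_traj(seq_len(1000), seq_len(1000),
                                         visible = vis)), 0.618)
})

test_that("distance per second uses complete one-second bins within runs", {
  # 31 frames at 4 px/frame: one bin of 30 transitions = 120 px
  t31 <- make_traj(x = 4 * (0:30), y = rep(0, 31))
  expect_equal(distance_per_second(t31), 120)
  # 45 frames: 44 transitions -> one bin, trailing 14 dropped
  t45 <- make_traj(x = 4 * (0:44), y = rep(0, 45))
  expect_equal(distance_per_second(t45), 120)
  # sum of bins never exceeds the total distance
  withr::local_seed(5)
  for (i in 1:10) {
    t <- random_traj(n = sample(10:200, 1), p_visible = runif(1, 0.5, 1))
    expect_lte(sum(distance_per_second(t)), total_travel_distance(t) + 1e-9)
  }
  # bins restart at each run: a gap splits 60 transitions into two short runs
  vis <- rep(c(TRUE, FALSE, TRUE), c(25, 1, 25))
  tg <- make_traj(x = 4 * (0:50), y = rep(0, 51), visible = vis)
  expect_length(distance_per_second(tg), 0)
})

test_that("hovering ratio counts the below and working bands", {
  h <- hovering_ratio(c(rep(50, 5), rep(200, 10)))
  expect_equal(h$ratio, 0.5)
  expect_equal(h$time_below, 5)
  expect_equal(h$time_band, 10)
  # band bounds are closed
  expect_equal(hovering_ratio(c(100, 120, 400))$time_band, 2)
  expect_error(hovering_ratio(rep(500, 4)),
               class = "fluctkin_undefined_ratio")
  expect_error(hovering_ratio(numeric(0)), class = "fluctkin_empty_series")
  # brute-force count on random values
  withr::local_seed(6)
  dps <- runif(200, 0, 600)
  h2 <- hovering_ratio(dps)
  expect_equal(h2$ratio,
               sum(dps < 120) / sum(dps >= 120 & dps <= 400))
})

test_that("kde curve is a normalized, unimodality-respecting density", {
  withr::local_seed(8)
  x <- rnorm(1000)
  kc <- kde_curve(x)
  expect_true(all(kc$density >= 0))
  integral <- sum(diff(kc$grid) *
                    (head(kc$density, -1) + tail(kc$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-2)
  # two samples of very different size both integrate to 1
  y <- rnorm(60, mean = 3)
  ky <- kde_curve(y)
  int_y <- sum(diff(ky$grid) * (head(ky$density, -1) + tail(ky$density, -1)) / 2)
  expect_equal(int_y, 1, tolerance = 1e-2)
  # density at the mean of a unimodal sample beats the far tail
  at <- function(g) kde_curve(x, grid = g)$density
  expect_gt(at(mean(x)), at(mean(x) + 5 * sd(x)))
  expect_error(kde_curve(rep(3, 10)), class = "fluctkin_degenerate_sample")
  expect_error(kde_curve(2), class = "fluctkin_degenerate_sample")
})

test_that("frame counts convert to reported durations", {
  expect_equal(round(frames_to_duration(50519, 30)$minutes, 1), 28.1)
  expect_equal(frames_to_duration(0)$minutes, 0)
  expect_equal(round(frames_to_duration(1254010, 30)$hours, 1), 11.6)
  expect_error(frames_to_duration(10, fps = 0), class = "fluctkin_bad_fps")
})

test_that("the per-video summary is consistent with its components", {
  # all-invisible: zero distance, occurrence 0, undefined means
  blank <- make_traj(rep(NA, 5), rep(NA, 5), visible = rep(FALSE, 5))
  s0 <- summarize_kinematics(blank)
  expect_equal(s0$total_travel_distance, 0)
  expect_equal(s0$occurrence_rate, 0)
  expect_true(is.na(s0$mean_speed) && is.na(s0$hover_ratio))

  cfg <- trajectory_config(duration_s = 20, gap_fraction = 0, seed = 31)
  t <- synth_trajectory(cfg)
  s <- summarize_kinematics(t)
  run <- visible_runs(t)[[1]]
  expect_equal(s$total_frames, length(t))
  expect_equal(s$visible_frames, sum(t$visible))
  expect_equal(s$total_travel_distance, total_travel_distance(t))
  expect_equal(s$mean_speed, mean(speed_series(run)))
  expect_equal(s$mean_acceleration, mean(abs(acceleration_series(run))))
  expect_equal(s$mean_jerk, mean(abs(jerk_series(run))))
  expect_equal(s$duration_minutes, length(t) / 1800)
})

test_that("a fixed-seed simulated video gives a stable summary", {
  t <- synth_trajectory(trajectory_config(duration_s = 60, seed = 123))
  s1 <- summarize_kinematics(t)
  s2 <- summarize_kinematics(
    synth_trajectory(trajectory_config(duration_s = 60, seed = 123)))
  expect_identical(s1, s2)
  expect_gt(s1$mean_speed, 0)
})
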