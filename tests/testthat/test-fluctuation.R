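test_that("windowing cuts runs into complete 3-s blocks and never spans gaps", {
  w <- segment_windows(seq_len(270), fps = 30, window_s = 3)
  expect_length(w, 3)
  expect_equal(w[[1]], 1:90)
  expect_equal(w[[3]], 181:270)
  expect_error(segment_windows(seq_len(89)), class = "fluctkin_no_windows")
  # list input: windows are taken per run, remainders dropped per run
  withr::local_seed(10)
  for (i in 1:10) {
    runs <- lapply(sample(30:400, 4), function(n) runif(n))
    w <- segment_windows(runs, fps = 30, window_s = 3)
    expect_equal(length(w), sum(sapply(runs, length) %/% 90))
    # every window is a contiguous slice of a single run
    flat <- lapply(runs, function(r) r)
    for (win in w) {
      found <- any(sapply(flat, function(r)
        length(r) >= 90 && any(sapply(seq_len(length(r) - 89), function(s)
          identical(r[s:(s + 89)], win)))))
      expect_true(found)
    }
  }
})

test_that("periodogram concentrates a sinusoid and satisfies Parseval", {
  fps <- 30; N <- 90
  tt <- (0:(N - 1)) / fps
  x <- sin(2 * pi * 5 * tt)  # 5 Hz: exactly bin 15
  sp <- periodogram(x, fps)
  expect_equal(sp$frequencies, (1:45) / 3)
  expect_equal(which.max(sp$power), which(sp$frequencies == 5))
  expect_gt(sp$power[15] / sum(sp$power[-15]), 1e20)
  # Parseval under the stated one-sided convention (N even)
  withr::local_seed(11)
  y <- rnorm(N)
  spy <- periodogram(y, fps)
  expect_equal(2 * sum(spy$power) - spy$power[45],
               sum((y - mean(y))^2))
  # constant window: flagged, all-zero power
  expect_warning(spz <- periodogram(rep(4, 90), fps),
                 class = "fluctkin_zero_variance_window")
  expect_true(all(spz$power == 0))
})

test_that("spectrum averaging is the arithmetic mean and tracks window count", {
  withr::local_seed(12)
  s1 <- periodogram(rnorm(90), 30)
  s2 <- periodogram(rnorm(90), 30)
  avg <- average_spectrum(list(s1, s2))
  expect_equal(avg$power, (s1$power + s2$power) / 2)
  expect_equal(avg$n_windows, 2)
  expect_equal(average_spectrum(list(s1))$power, s1$power)
  expect_error(average_spectrum(list()), class = "fluctkin_no_windows")
  # averaging white-noise spectra reduces spread around the flat level
  many <- average_spectrum(lapply(1:100, function(i) periodogram(rnorm(90), 30)))
  expect_lt(sd(many$power) / mean(many$power),
            sd(s1$power) / mean(s1$power))
})

test_that("beta estimation recovers exact power laws and the white-noise anchor", {
  f <- (1:45) / 3
  spec_of <- function(p) structure(
    list(frequencies = f, power = p, n_windows = 1L),
    class = "spectrum_estimate")
  est <- estimate_beta(spec_of(f^-1.4))
  expect_equal(est$beta, 1.4)
  expect_equal(est$r_squared, 1)
  # closed-form two-point slope agrees on an exact power law
  two_point <- -(log10(f[45]^-1.4) - log10(f[1]^-1.4)) /
    (log10(f[45]) - log10(f[1]))
  expect_equal(est$beta, two_point)
  # flat spectrum: beta = 0
  expect_equal(estimate_beta(spec_of(rep(2, 45)))$beta, 0)
  # non-positive bins are dropped and counted
  p <- f^-1; p[c(3, 7)] <- 0
  est2 <- estimate_beta(spec_of(p))
  expect_equal(est2$n_bins_dropped, 2)
  expect_equal(est2$beta, 1, tolerance = 1e-10)
  expect_error(estimate_beta(spec_of(rep(0, 45))),
               class = "fluctkin_insufficient_spectrum")
})

test_that("scaling step lengths moves the intercept, not beta", {
  st <- abs(12 + 3 * colored_noise(1.2, 900, seed = 13))
  est <- function(s)
    estimate_beta(average_spectrum(lapply(segment_windows(s), periodogram)))
  e1 <- est(st); e2 <- est(st * 7)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$intercept, e1$intercept + 2 * log10(7), tolerance = 1e-8)
})

test_that("the trajectory-level estimator composes the pipeline deterministically", {
  cfg <- trajectory_config(beta_target = 1.45, duration_s = 120,
                           hover_fraction = 0, seed = 14)
  t <- synth_trajectory(cfg)
  r1 <- beta_for_trajectory(t)
  r2 <- beta_for_trajectory(t)
  expect_identical(r1, r2)  # no RNG in the estimator
  expect_equal(r1$n_windows,
               length(segment_windows(lapply(visible_runs(t), step_lengths))))
  expect_true(r1$r_squared >= 0 && r1$r_squared <= 1)
  # white-noise step series: beta ~ 0
  wn_steps <- abs(12 + 3 * colored_noise(0, 9000, seed = 15))
  wn <- tip_trajectory(x = c(0, cumsum(wn_steps)), y = rep(0, 9001),
                       fps = 30, frame_width = 200000, frame_height = 100)
  expect_lt(abs(beta_for_trajectory(wn)$beta), 0.1)
  # too-short trajectory propagates the windowing error
  expect_error(beta_for_trajectory(make_traj(1:50, 1:50)),
               class = "fluctkin_no_windows")
})

test_that("synthesized noise round-trips through the estimator", {
  # beta recovery within 0.15 and strictly monotone across targets
  targets <- c(0, 0.5, 1, 1.45, 2)
  means <- sapply(targets, function(b) {
    est <- sapply(1:8, function(i) {
      st <- abs(12 + 3 * colored_noise(b, 9000, seed = 500 * b + i))
      estimate_beta(average_spectrum(
        lapply(segment_windows(st), periodogram)))$beta
    })
    mean(est)
  })
  expect_true(all(abs(means - targets) <= 0.15))
  expect_true(all(diff(means) > 0))
})
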