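#' Segment step-length series into fixed-duration spectral windows
#'
#' Cuts each visible run's step-length series into consecutive
#' non-overlapping windows of `fps * window_s` samples, starting at the
#' run start; trailing remainders are discarded. Windows never span an
#' invisibility gap.
#'
#' @param steps A numeric step-length series, or a list of such series
#'   (one per visible run, as from several runs of one video).
#' @param fps Frames per second.
#' @param window_s Window duration in seconds (default 3: the scale at
#'   which the fluctuation index summarizes recent movement).
#' @return A list of numeric windows, each of length `fps * window_s`.
#' @export
segment_windows <- function(steps, fps = 30, window_s = 3) {
  n <- fps * window_s
  if (!is_count(n, 4))
    fk_stop("fluctkin_bad_window",
            "fps * window_s must be an integer >= 4 (got %g)", n)
  if (!is.list(steps)) steps <- list(steps)
  out <- list()
  for (s in steps) {
    k <- length(s) %/% n
    if (k < 1L) next
    out <- c(out, lapply(seq_len(k), function(i) s[((i - 1) * n + 1):(i * n)]))
  }
  if (length(out) == 0L)
    fk_stop("fluctkin_no_windows",
            "no run long enough for a complete %g-s window (%d samples)",
            window_s, n)
  out
}

new_spectrum <- function(frequencies, power, n_windows) {
  structure(list(frequencies = frequencies, power = power,
                 n_windows = n_windows),
            class = "spectrum_estimate")
}

#' Raw periodogram of a single window
#'
#' Mean-removed, untapered FFT periodogram. For a window of `N` samples
#' at `fps` frames/s, power is reported at frequencies `k * fps / N` Hz
#' for `k = 1 .. floor(N/2)` (the DC bin is excluded), with
#' `power_k = |FFT_k|^2 / N`. Under this convention the one-sided sum
#' satisfies Parseval: `2 * sum(power) - power_Nyquist` equals the sum of
#' squared deviations of the window (Nyquist term only when `N` is even).
#'
#' @param window Numeric vector of step lengths, one spectral window.
#' @param fps Frames per second.
#' @return A `spectrum_estimate`: list with `frequencies` (Hz), `power`
#'   and `n_windows = 1`. A zero-variance window yields all-zero power
#'   and signals a `fluctkin_zero_variance_window` warning.
#' @export
periodogram <- function(window, fps = 30) {
  N <- length(window)
  if (N < 4L)
    fk_stop("fluctkin_bad_window", "window too short (%d samples)", N)
  x <- window - mean(window)
  if (all(x == 0))
    fk_warn("fluctkin_zero_variance_window",
            "constant window: all spectral power is zero")
  p <- Mod(fft(x))^2 / N
  k <- seq_len(N %/% 2)
  new_spectrum(frequencies = k * fps / N, power = p[k + 1L], n_windows = 1L)
}

#' Average periodograms across windows
#'
#' Welch-style arithmetic mean of per-window power at each frequency.
#' Averaging before the log-log fit reduces the variance of the slope
#' estimate relative to fitting each window separately.
#'
#' @param spectra A list of `spectrum_estimate`s on the same frequency
#'   grid (e.g. [periodogram()] applied to [segment_windows()] output).
#' @return A `spectrum_estimate` with `n_windows` the total count.
#' @export
average_spectrum <- function(spectra) {
  if (inherits(spectra, "spectrum_estimate")) spectra <- list(spectra)
  if (length(spectra) == 0L)
    fk_stop("fluctkin_no_windows", "no spectra to average")
  f <- spectra[[1]]$frequencies
  ok <- vapply(spectra, function(s)
    inherits(s, "spectrum_estimate") && isTRUE(all.equal(s$frequencies, f)),
    logical(1))
  if (!all(ok))
    fk_stop("fluctkin_bad_window",
            "spectra must share one frequency grid to be averaged")
  pw <- rowMeans(vapply(spectra, `[[`, numeric(length(f)), "power"))
  new_spectrum(f, pw, sum(vapply(spectra, `[[`, integer(1), "n_windows")))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d bins, %.3g-%.3g Hz, %d window(s)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$n_windows))
  invisible(x)
}

#' Estimate the fluctuation exponent beta from a power spectrum
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` over
#' all positive-power bins; `beta` is minus the slope. `beta = 0` is
#' white noise (disorderly movement), `beta = 1` the classical 1/f
#' fluctuation, and values approaching 2 indicate regular movement. No
#' frequency band is truncated and bins are unweighted; zero-power bins
#' (possible in degenerate windows) are dropped and counted.
#'
#' @param spec A `spectrum_estimate`.
#' @return A list of class `fluctuation_result`: `beta`, `intercept`
#'   (log10 power at log10 f = 0), `r_squared`, `n_windows`,
#'   `n_bins_used`, `n_bins_dropped`.
#' @export
#' @examples
#' f <- (1:45) / 3
#' est <- estimate_beta(structure(
#'   list(frequencies = f, power = f^-1.4, n_windows = 1L),
#'   class = "spectrum_estimate"))
#' est$beta  # 1.4 exactly: spectrum is an exact power law
estimate_beta <- function(spec) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  use <- spec$power > 0 & is.finite(spec$power)
  if (sum(use) < 3L)
    fk_stop("fluctkin_insufficient_spectrum",
            "need >= 3 positive-power bins for the log-log fit, have %d",
            sum(use))
  lf <- log10(spec$frequencies[use])
  lp <- log10(spec$power[use])
  fit <- lm(lp ~ lf)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(
    list(beta = -unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_windows = spec$n_windows,
         n_bins_used = sum(use),
         n_bins_dropped = sum(!use)),
    class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_result> beta = %.3f (R^2 = %.3f, %d windows, %d bins)\n",
    x$beta, x$r_squared, x$n_windows, x$n_bins_used))
  invisible(x)
}

#' Fluctuation exponent of a whole trajectory
#'
#' The per-video fluctuation index: the trajectory is split into visible
#' runs, each run's step-length series is cut into `window_s`-second
#' windows, per-window FFT periodograms are averaged, and beta is the
#' negative log-log least-squares slope of the averaged spectrum. The
#' estimator contains no randomness: identical input gives identical
#' beta.
#'
#' @param traj A [tip_trajectory].
#' @param window_s Spectral window duration in seconds (default 3).
#' @return A `fluctuation_result` (see [estimate_beta()]).
#' @export
beta_for_trajectory <- function(traj, window_s = 3) {
  steps <- run_step_series(traj)
  wins <- segment_windows(steps, fps = traj$fps, window_s = window_s)
  spec <- average_spectrum(lapply(wins, periodogram, fps = traj$fps))
  estimate_beta(spec)
}
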