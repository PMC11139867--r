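#' Configuration of the synthetic trajectory generator
#'
#' Bundles every knob of the simulator. The defaults emulate the data
#' regime of HD laparoscopic video analyzed at 30 fps: a mean tip speed
#' of `mean_step * fps` = 360 px/s, tip off screen in bursts covering
#' about 45% of frames (occurrence rate ~55%), and about 10% of seconds
#' spent hovering (distance per second below `hover_target` pixels).
#' `mean_step >= 4 * sd_step` keeps clipping of the nonnegative
#' step-length series rare (Gaussian 4-sigma tail, < 1e-4).
#'
#' @param beta_target Spectral exponent of the step-length series, in
#'   `[0, 2]`.
#' @param duration_s Video duration in seconds; the trajectory has
#'   `duration_s * fps` frame transitions (`+1` frames).
#' @param fps Frames per second.
#' @param mean_step,sd_step Mean and SD of the per-frame step length in
#'   pixels.
#' @param hover_fraction Fraction of whole seconds rescaled into hover
#'   episodes (sum below `hover_target` px).
#' @param hover_target Hover threshold in pixels per second (default 120).
#' @param gap_fraction Fraction of frames marked invisible.
#' @param gap_mean_s Mean duration of one invisibility burst, seconds.
#'   Visible episodes get the complementary mean so the long-run
#'   invisible fraction is `gap_fraction`.
#' @param turn_sd SD of the per-frame heading increment, radians; small
#'   values give smoothly curving paths.
#' @param frame_width,frame_height Frame size in pixels.
#' @param seed Integer RNG seed; all randomness in the generator flows
#'   from it.
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(beta_target = 1.4, duration_s = 300, fps = 30,
                              mean_step = 12, sd_step = 3,
                              hover_fraction = 0.1, hover_target = 120,
                              gap_fraction = 0.45, gap_mean_s = 10,
                              turn_sd = 0.3,
                              frame_width = 1280, frame_height = 720,
                              seed = 1) {
  stopifnot(is_number(beta_target), beta_target >= 0, beta_target <= 2,
            is_number(duration_s), duration_s > 0,
            is_number(fps), fps > 0,
            is_number(mean_step), mean_step >= 0,
            is_number(sd_step), sd_step >= 0,
            is_number(hover_fraction), hover_fraction >= 0,
            hover_fraction <= 1,
            is_number(hover_target), hover_target > 0,
            is_number(gap_fraction), gap_fraction >= 0, gap_fraction < 1,
            is_number(gap_mean_s), gap_mean_s > 0,
            is_number(turn_sd), turn_sd >= 0,
            is_count(frame_width, 1), is_count(frame_height, 1),
            is_count(seed, 0))
  structure(as.list(environment()), class = "trajectory_config")
}

#' Gaussian 1/f^beta colored noise
#'
#' Spectral synthesis: Fourier amplitudes proportional to
#' `f^(-beta/2)` with independent uniform random phases and a
#' conjugate-symmetric spectrum, inverse FFT, then standardization to
#' zero mean and unit variance. The expected periodogram of the result
#' follows a `1/f^beta` power law exactly, making the series a
#' controlled input for validating the fluctuation estimator:
#' `beta = 0` gives white noise, larger beta progressively smoother
#' series.
#'
#' @param beta Target spectral exponent (finite; 0 = white noise).
#' @param n Series length (>= 2).
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return Numeric vector of length `n`, mean 0, SD 1.
#' @export
#' @examples
#' x <- colored_noise(1, 900, seed = 42)
#' c(mean(x), sd(x))  # 0, 1
colored_noise <- function(beta, n, seed = NULL) {
  if (!is_count(n, 2))
    fk_stop("fluctkin_malformed_field", "n must be an integer >= 2")
  if (!is_number(beta))
    fk_stop("fluctkin_malformed_field", "beta must be a finite number")
  with_seed(seed, {
    m <- n %/% 2
    f <- seq_len(m) / n
    amp <- f^(-beta / 2)
    ph <- runif(m, 0, 2 * pi)
    # Nyquist bin of an even-length spectrum must be real
    if (n %% 2 == 0) ph[m] <- if (runif(1) < 0.5) 0 else pi
    bins <- complex(modulus = amp, argument = ph)
    spec <- if (n %% 2 == 0) c(0, bins, Conj(rev(bins[seq_len(m - 1)])))
            else c(0, bins, Conj(rev(bins)))
    x <- Re(fft(spec, inverse = TRUE)) / n
    (x - mean(x)) / sd(x)
  })
}

# Step series under the caller's RNG stream (no seeding here).
synth_step_series_impl <- function(config) {
  n <- round(config$duration_s * config$fps)
  noise <- colored_noise(config$beta_target, n, seed = NULL)
  steps <- pmax(0, config$mean_step + config$sd_step * noise)
  fps <- config$fps
  n_sec <- n %/% fps
  n_hover <- round(config$hover_fraction * n_sec)
  if (n_hover > 0) {
    blocks <- sort(sample.int(n_sec, n_hover))
    # rescale each designated second to a sum well below the threshold
    targets <- runif(n_hover, 0.5, 0.9) * config$hover_target
    for (j in seq_len(n_hover)) {
      idx <- ((blocks[j] - 1) * fps + 1):(blocks[j] * fps)
      tot <- sum(steps[idx])
      if (tot > 0) steps[idx] <- steps[idx] * targets[j] / tot
    }
  }
  steps
}

#' Synthetic step-length series
#'
#' `mean_step + sd_step * colored_noise(beta_target)`, clipped at zero,
#' with `hover_fraction` of the whole seconds rescaled so each sums to
#' below `hover_target` pixels (drawn uniformly in 50-90% of the
#' threshold). The clip and the hover rescaling perturb the spectral
#' exponent only mildly; see the package vignette for when to disable
#' hovering in estimator-validation work.
#'
#' @param config A [trajectory_config()].
#' @return Nonnegative numeric vector of length
#'   `round(duration_s * fps)`.
#' @export
synth_step_series <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, synth_step_series_impl(config))
}

# Alternating visible/invisible episode lengths covering n frames.
# Geometric (shifted, mean m) episode durations; start state visible with
# probability 1 - gap_fraction.
gap_mask <- function(n, gap_fraction, mean_gap) {
  if (gap_fraction <= 0) return(rep(TRUE, n))
  mean_vis <- mean_gap * (1 - gap_fraction) / gap_fraction
  vis <- logical(0)
  state <- runif(1) < (1 - gap_fraction)
  while (length(vis) < n) {
    m <- if (state) mean_vis else mean_gap
    len <- rgeom(1, prob = 1 / max(m, 1)) + 1
    vis <- c(vis, rep(state, len))
    state <- !state
  }
  vis[seq_len(n)]
}

#' Synthesize a full tip trajectory
#'
#' Integrates a [synth_step_series()] along smoothly varying random
#' headings (a random walk on the heading angle), reflecting the heading
#' at the frame boundary so that every position stays inside the frame
#' while consecutive-position distances reproduce the step series
#' exactly. `gap_fraction` of the frames are then marked invisible in
#' contiguous geometric-length bursts, mimicking off-screen episodes and
#' exercising the run-splitting logic of the analysis.
#'
#' @param config A [trajectory_config()].
#' @return A [tip_trajectory] of `round(duration_s * fps) + 1` frames.
#' @export
#' @examples
#' traj <- synth_trajectory(trajectory_config(duration_s = 10, seed = 7))
#' traj
synth_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, {
    steps <- synth_step_series_impl(config)
    n <- length(steps)
    W <- config$frame_width; H <- config$frame_height
    heading <- runif(1, 0, 2 * pi) + cumsum(rnorm(n, 0, config$turn_sd))
    x <- numeric(n + 1); y <- numeric(n + 1)
    x[1] <- runif(1, 0.25 * W, 0.75 * W)
    y[1] <- runif(1, 0.25 * H, 0.75 * H)
    cosh_ <- cos(heading); sinh_ <- sin(heading)
    for (i in seq_len(n)) {
      d <- steps[i]
      nx <- x[i] + d * cosh_[i]
      if (nx < 0 || nx > W) nx <- x[i] - d * cosh_[i]
      ny <- y[i] + d * sinh_[i]
      if (ny < 0 || ny > H) ny <- y[i] - d * sinh_[i]
      x[i + 1] <- nx
      y[i + 1] <- ny
    }
    vis <- gap_mask(n + 1, config$gap_fraction,
                    config$gap_mean_s * config$fps)
    tip_trajectory(x = x, y = y, visible = vis, fps = config$fps,
                   frame_width = W, frame_height = H)
  })
}

#' Configuration of a two-group synthetic cohort
#'
#' Emulates a study design of expert and novice surgeons whose per-video
#' fluctuation exponents are drawn from group-specific normal
#' distributions truncated to `[0, 2]`. Defaults use group means 1.45
#' (expert) and 1.29 (novice), within-group SD 0.08, and 9 videos per
#' group.
#'
#' @param n_per_group Videos per group.
#' @param expert_beta_mean,expert_beta_sd,novice_beta_mean,novice_beta_sd
#'   Group beta distributions.
#' @param template A [trajectory_config()] used for every video (its
#'   `beta_target` and `seed` are overridden per video).
#' @param seed Master seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 9,
                          expert_beta_mean = 1.45, expert_beta_sd = 0.08,
                          novice_beta_mean = 1.29, novice_beta_sd = 0.08,
                          template = trajectory_config(), seed = 1) {
  stopifnot(is_count(n_per_group, 1),
            is_number(expert_beta_mean), is_number(novice_beta_mean),
            is_number(expert_beta_sd), expert_beta_sd >= 0,
            is_number(novice_beta_sd), novice_beta_sd >= 0,
            inherits(template, "trajectory_config"), is_count(seed, 0))
  structure(as.list(environment()), class = "cohort_config")
}

# Normal(mean, sd) truncated to [lo, hi] by rejection.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 2) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Synthesize a labeled two-group cohort
#'
#' Draws a true beta per video from its group's truncated-normal
#' distribution, generates each video with [synth_trajectory()] under a
#' per-video seed derived from the master seed, and returns the
#' trajectories together with a manifest of ground truth.
#'
#' @param config A [cohort_config()].
#' @return A list with `trajectories` (named list of [tip_trajectory])
#'   and `manifest` (data.frame: `video_id`, `group`, `beta_true`,
#'   `seed`).
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_per_group
    beta_true <- c(
      rtrunc_norm(n, config$expert_beta_mean, config$expert_beta_sd),
      rtrunc_norm(n, config$novice_beta_mean, config$novice_beta_sd))
    group <- rep(c("expert", "novice"), each = n)
    seeds <- sample.int(2147483646L, 2 * n)
    ids <- sprintf("%s_%02d", group, c(seq_len(n), seq_len(n)))
    trajs <- lapply(seq_len(2 * n), function(i) {
      cfg <- config$template
      cfg$beta_target <- beta_true[i]
      cfg$seed <- seeds[i]
      synth_trajectory(cfg)
    })
    names(trajs) <- ids
    list(trajectories = trajs,
         manifest = data.frame(video_id = ids, group = group,
                               beta_true = beta_true, seed = seeds,
                               stringsAsFactors = FALSE))
  })
}

#' Synthetic mask pair with exact cardinalities
#'
#' Random predicted/ground-truth mask pair with exactly `true_size` true
#' pixels, `pred_size` predicted pixels and `overlap` pixels in common —
#' a controlled fixture for the mask accuracy metrics.
#'
#' @param height,width Mask dimensions in pixels.
#' @param true_size Number of `TRUE` pixels in the truth mask.
#' @param overlap Number of shared pixels (`<= min(true_size,
#'   pred_size)`).
#' @param pred_size Number of `TRUE` pixels in the prediction (default
#'   `true_size`).
#' @param seed Integer seed.
#' @return A list with logical matrices `pred` and `truth`.
#' @export
synth_mask_pair <- function(height, width, true_size, overlap,
                            pred_size = true_size, seed = 1) {
  npix <- height * width
  if (!is_count(true_size, 0) || !is_count(pred_size, 0) ||
      !is_count(overlap, 0) ||
      overlap > min(true_size, pred_size) ||
      true_size > npix || pred_size + true_size - overlap > npix)
    fk_stop("fluctkin_infeasible_geometry",
            "requested cardinalities do not fit a %dx%d mask", height, width)
  with_seed(seed, {
    truth_idx <- sample.int(npix, true_size)
    shared <- truth_idx[sample.int(true_size, overlap)]
    outside <- setdiff(seq_len(npix), truth_idx)
    extra <- outside[sample.int(length(outside), pred_size - overlap)]
    truth <- matrix(FALSE, height, width)
    pred <- matrix(FALSE, height, width)
    truth[truth_idx] <- TRUE
    pred[c(shared, extra)] <- TRUE
    list(pred = pred, truth = truth)
  })
}
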