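#' Per-transition step lengths of a visible run
#'
#' Euclidean displacement of the tip between consecutive frames, in
#' pixels. This step-length ("travel distance") series is the input to
#' both the travel-distance summaries and the fluctuation analysis.
#'
#' @param run A fully visible [tip_trajectory] segment with at least 2
#'   samples (see [visible_runs()]).
#' @return Numeric vector of length `n - 1` for a run of `n` samples.
#' @export
#' @examples
#' run <- tip_trajectory(x = c(0, 3), y = c(0, 4))
#' step_lengths(run)  # 5: the 3-4-5 triangle
step_lengths <- function(run) {
  stopifnot(inherits(run, "tip_trajectory"))
  if (!all(run$visible))
    fk_stop("fluctkin_run_not_visible",
            "step_lengths() expects a fully visible run; see visible_runs()")
  if (length(run) < 2L)
    fk_stop("fluctkin_run_too_short",
            "need >= 2 samples for step lengths, got %d", length(run))
  sqrt(diff(run$x)^2 + diff(run$y)^2)
}

# Step-length series for every visible run of length >= 2, in order.
run_step_series <- function(traj) {
  runs <- Filter(function(r) length(r) >= 2L, visible_runs(traj))
  lapply(runs, step_lengths)
}

#' Total travel distance of the tip
#'
#' Sum of per-frame Euclidean step lengths over all visible runs.
#' Transitions that span an invisibility gap contribute nothing: the tip's
#' path while off screen is unknown and is not interpolated.
#'
#' @param traj A [tip_trajectory].
#' @return Total distance in pixels (0 for a trajectory with no two
#'   consecutive visible frames).
#' @export
total_travel_distance <- function(traj) {
  sum(vapply(run_step_series(traj), sum, numeric(1)))
}

#' Velocity, acceleration and jerk series of a visible run
#'
#' Scalar finite-difference chain at the video frame rate: speed is the
#' step length times fps (pixels/s); acceleration is the first difference
#' of speed times fps (pixels/s^2); jerk is the first difference of
#' acceleration times fps (pixels/s^3). For a run of `n` samples the
#' series have lengths `n - 1`, `n - 2`, `n - 3`. Acceleration and jerk
#' are signed; per-video summaries report their mean magnitudes.
#'
#' @param run A fully visible [tip_trajectory] segment (length >= 2, 3, 4
#'   respectively).
#' @return Numeric vector.
#' @export
#' @examples
#' run <- tip_trajectory(x = cumsum(rep(4, 10)), y = rep(0, 10),
#'                       frame_width = 100)
#' speed_series(run)         # constant 120 px/s at 30 fps
#' acceleration_series(run)  # zeros
speed_series <- function(run) {
  step_lengths(run) * run$fps
}

#' @rdname speed_series
#' @export
acceleration_series <- function(run) {
  if (length(run) < 3L)
    fk_stop("fluctkin_run_too_short",
            "need >= 3 samples for acceleration, got %d", length(run))
  diff(speed_series(run)) * run$fps
}

#' @rdname speed_series
#' @export
jerk_series <- function(run) {
  if (length(run) < 4L)
    fk_stop("fluctkin_run_too_short",
            "need >= 4 samples for jerk, got %d", length(run))
  diff(acceleration_series(run)) * run$fps
}

#' Tip occurrence rate
#'
#' Fraction of video frames in which the tip is on screen and detected:
#' visible frames / total frames.
#'
#' @param traj A [tip_trajectory].
#' @return A fraction in `[0, 1]`.
#' @export
occurrence_rate <- function(traj) {
  stopifnot(inherits(traj, "tip_trajectory"))
  mean(traj$visible)
}

#' Distance traveled per second
#'
#' Within each visible run, consecutive non-overlapping bins of exactly
#' `fps` frame transitions (one second each), each bin's value the sum of
#' its step lengths. Trailing partial bins are discarded rather than
#' extrapolated: a partial second would be biased downward exactly into
#' the hover region.
#'
#' @param traj A [tip_trajectory].
#' @return Numeric vector of pixels-per-second values (possibly empty).
#' @seealso [hovering_ratio()]
#' @export
distance_per_second <- function(traj) {
  fps <- traj$fps
  out <- lapply(run_step_series(traj), function(s) {
    nbin <- length(s) %/% fps
    if (nbin < 1L) return(numeric(0))
    colSums(matrix(s[seq_len(nbin * fps)], nrow = fps))
  })
  unlist(out, use.names = FALSE)
}

#' Hovering ratio of the distance-per-second distribution
#'
#' Seconds in which the tip traveled less than `low` pixels, divided by
#' seconds in the working band `[low, high]`. Slow "hovering" seconds
#' proxy indecisive dwell; the band above them is ordinary working speed.
#' Seconds above `high` belong to neither count.
#'
#' @param dps Distance-per-second values from [distance_per_second()].
#' @param low,high Band bounds in pixels/s (defaults 120 and 400, the
#'   conventional bounds at 30 fps HD recordings).
#' @return A list of class `hover_summary` with `time_below` and
#'   `time_band` (seconds) and their `ratio`.
#' @export
#' @examples
#' hovering_ratio(c(50, 80, 130, 200, 300, 390))  # 2 / 4 = 0.5
hovering_ratio <- function(dps, low = 120, high = 400) {
  if (length(dps) < 1L)
    fk_stop("fluctkin_empty_series", "no complete seconds to classify")
  stopifnot(low < high)
  below <- sum(dps < low)
  band <- sum(dps >= low & dps <= high)
  if (band == 0L)
    fk_stop("fluctkin_undefined_ratio",
            "no seconds in the [%g, %g] px/s band; hovering ratio undefined",
            low, high)
  structure(list(time_below = below, time_band = band,
                 ratio = below / band, low = low, high = high),
            class = "hover_summary")
}

#' @export
print.hover_summary <- function(x, ...) {
  cat(sprintf("<hover_summary> %d s below %g px/s, %d s in [%g, %g]: ratio %.3f\n",
              x$time_below, x$low, x$time_band, x$low, x$high, x$ratio))
  invisible(x)
}

#' Gaussian kernel density curve
#'
#' Exact Gaussian kernel density estimate with Scott's-rule bandwidth
#' ([stats::bw.nrd]), evaluated on an explicit grid. Used for the
#' distance-per-second density plot; because the density integrates to 1
#' for each cohort separately, the curves are comparable between groups
#' of different total surgical time.
#'
#' The default grid runs from `min(0, min(values) - 3*bw)` to
#' `max(1.2 * max(values), max(values) + 3*bw)`: for nonnegative speed
#' data this is the `[0, 1.2 * max]` display range, while still covering
#' essentially all kernel mass so the numerical integral is ~1.
#'
#' @param values Numeric sample (>= 2 distinct values).
#' @param grid Optional increasing numeric grid on which to evaluate.
#' @param bw Optional bandwidth override in the units of `values`.
#' @param n_grid Grid resolution when `grid` is not given (default 512).
#' @return A data.frame with columns `grid` and `density`.
#' @export
kde_curve <- function(values, grid = NULL, bw = NULL, n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    fk_stop("fluctkin_degenerate_sample", "need >= 2 finite values for a KDE")
  if (sd(values) == 0)
    fk_stop("fluctkin_degenerate_sample",
            "all values identical; density is degenerate")
  if (is.null(bw)) bw <- stats::bw.nrd(values)
  if (is.null(grid)) {
    lo <- min(0, min(values) - 3 * bw)
    hi <- max(1.2 * max(values), max(values) + 3 * bw)
    grid <- seq(lo, hi, length.out = n_grid)
  }
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = values, sd = bw)),
                 numeric(1))
  data.frame(grid = grid, density = dens)
}

#' Convert a frame count to a duration
#'
#' @param n_frames Number of frames (>= 0).
#' @param fps Frames per second (> 0).
#' @return A list with `seconds`, `minutes` and `hours` (unrounded);
#'   report durations to 1 decimal.
#' @export
#' @examples
#' round(frames_to_duration(50519)$minutes, 1)  # 28.1
frames_to_duration <- function(n_frames, fps = 30) {
  if (!is_count(n_frames))
    fk_stop("fluctkin_malformed_field", "n_frames must be a nonnegative count")
  if (!is_number(fps) || fps <= 0)
    fk_stop("fluctkin_bad_fps", "fps must be positive")
  secs <- n_frames / fps
  list(seconds = secs, minutes = secs / 60, hours = secs / 3600)
}

#' Per-video kinematic summary
#'
#' Aggregates the kinematic indices of one trajectory. Means are pooled
#' over all defined series elements across visible runs (runs weighted by
#' their length). Mean acceleration and jerk are means of magnitudes —
#' the signed series average to ~0 by construction, whereas their
#' magnitude tracks movement smoothness.
#'
#' @param traj A [tip_trajectory].
#' @param hover_low,hover_high Hover band bounds in pixels/s, see
#'   [hovering_ratio()].
#' @return A list of class `kinematic_summary` with fields
#'   `total_frames`, `visible_frames`, `occurrence_rate`,
#'   `total_travel_distance`, `mean_speed`, `mean_acceleration`,
#'   `mean_jerk`, `hover_ratio`, `duration_minutes`. Means are `NA` when
#'   no run is long enough; `hover_ratio` is `NA` when undefined (no
#'   seconds in the working band).
#' @export
summarize_kinematics <- function(traj, hover_low = 120, hover_high = 400) {
  stopifnot(inherits(traj, "tip_trajectory"))
  runs <- visible_runs(traj)
  pooled <- function(f, min_len) {
    v <- unlist(lapply(Filter(function(r) length(r) >= min_len, runs), f),
                use.names = FALSE)
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  dps <- distance_per_second(traj)
  hover <- if (length(dps) && any(dps >= hover_low & dps <= hover_high))
    hovering_ratio(dps, hover_low, hover_high)$ratio
  else NA_real_
  structure(
    list(total_frames = length(traj),
         visible_frames = sum(traj$visible),
         occurrence_rate = occurrence_rate(traj),
         total_travel_distance = total_travel_distance(traj),
         mean_speed = pooled(speed_series, 2L),
         mean_acceleration = pooled(function(r) abs(acceleration_series(r)), 3L),
         mean_jerk = pooled(function(r) abs(jerk_series(r)), 4L),
         hover_ratio = hover,
         duration_minutes = frames_to_duration(length(traj), traj$fps)$minutes),
    class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<kinematic_summary>\n",
    "  frames        %d (%.1f min), occurrence %.1f%%\n",
    "  travel        %.0f px\n",
    "  mean |v|      %.1f px/s   mean |a| %.1f px/s^2   mean |j| %.1f px/s^3\n",
    "  hover ratio   %s\n"),
    x$total_frames, x$duration_minutes, 100 * x$occurrence_rate,
    x$total_travel_distance, x$mean_speed, x$mean_acceleration, x$mean_jerk,
    if (is.na(x$hover_ratio)) "undefined" else sprintf("%.3f", x$hover_ratio)))
  invisible(x)
}
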