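#' Simulate a cohort to disk
#'
#' Generates a [synth_cohort()] and writes one trajectory CSV per video
#' plus a `manifest.csv` (video id, group label, true beta, per-video
#' seed) into `out_dir`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly; its `file` column holds
#'   the written trajectory paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- synth_cohort(config)
  manifest <- cohort$manifest
  manifest$file <- file.path(out_dir, paste0(manifest$video_id, ".csv"))
  for (i in seq_len(nrow(manifest)))
    write_trajectory(cohort$trajectories[[i]], manifest$file[i])
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

analyze_one <- function(traj, video_id, window_s, hover_low, hover_high) {
  ks <- summarize_kinematics(traj, hover_low = hover_low,
                             hover_high = hover_high)
  fl <- tryCatch(beta_for_trajectory(traj, window_s = window_s),
                 fluctkin_error = function(e) NULL)
  data.frame(
    video_id = video_id,
    total_frames = ks$total_frames,
    duration_min = ks$duration_minutes,
    occurrence_rate = ks$occurrence_rate,
    total_travel_distance = ks$total_travel_distance,
    mean_speed = ks$mean_speed,
    mean_acceleration = ks$mean_acceleration,
    mean_jerk = ks$mean_jerk,
    hover_ratio = ks$hover_ratio,
    beta = if (is.null(fl)) NA_real_ else fl$beta,
    r_squared = if (is.null(fl)) NA_real_ else fl$r_squared,
    n_windows = if (is.null(fl)) 0L else fl$n_windows,
    stringsAsFactors = FALSE)
}

#' Analyze trajectory files into a per-video metrics table
#'
#' Runs the kinematic and fluctuation pipeline on each trajectory file
#' and returns one row per video. Files that fail to parse are reported
#' as warnings, skipped, and listed in the `failures` attribute of the
#' result; the run continues. Videos too short for a complete spectral
#' window get `beta = NA` and a warning.
#'
#' @param paths Character vector of trajectory CSV paths (see
#'   [read_trajectory()]); alternatively a named list of
#'   [tip_trajectory] objects.
#' @param fps,frame_width,frame_height File-level metadata for reading.
#' @param window_s Spectral window duration, seconds.
#' @param hover_low,hover_high Hover band in pixels/s.
#' @param out Optional path; when given, the table is also written as
#'   CSV.
#' @return A data.frame, one row per successfully analyzed video, with
#'   attribute `failures` (named character vector of error messages,
#'   empty when all files parsed).
#' @export
run_analyze <- function(paths, fps = 30, frame_width = 1280,
                        frame_height = 720, window_s = 3,
                        hover_low = 120, hover_high = 400, out = NULL) {
  if (length(paths) == 0L)
    fk_warn("fluctkin_empty_input", "no trajectory files given")
  rows <- list()
  failures <- character(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    id <- if (!is.null(names(paths)) && nzchar(names(paths)[i]))
      names(paths)[i]
    else if (is.character(p)) tools::file_path_sans_ext(basename(p))
    else sprintf("video_%03d", i)
    traj <- if (inherits(p, "tip_trajectory")) p
    else tryCatch(
      read_trajectory(p, fps = fps, frame_width = frame_width,
                      frame_height = frame_height),
      fluctkin_error = function(e) {
        fk_warn("fluctkin_file_failed", "skipping %s: %s", id,
                conditionMessage(e))
        NULL
      })
    if (is.null(traj)) {
      failures[id] <- sprintf("failed to read %s", as.character(p))
      next
    }
    rows[[id]] <- analyze_one(traj, id, window_s, hover_low, hover_high)
    if (rows[[id]]$n_windows == 0L)
      fk_warn("fluctkin_no_windows",
              "%s: no complete %g-s window; beta is NA", id, window_s)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(video_id = character(0), total_frames = integer(0),
                  duration_min = numeric(0), occurrence_rate = numeric(0),
                  total_travel_distance = numeric(0),
                  mean_speed = numeric(0), mean_acceleration = numeric(0),
                  mean_jerk = numeric(0), hover_ratio = numeric(0),
                  beta = numeric(0), r_squared = numeric(0),
                  n_windows = integer(0), stringsAsFactors = FALSE)
  attr(res, "failures") <- failures
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}

mw_or_null <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) return(NULL)
  if (var(c(a, b)) == 0) return(NULL)  # constant index: no test
  x <- mann_whitney_u(a, b)
  list(u_statistic = x$u_statistic, p_value = x$p_value,
       median_expert = median(a), median_novice = median(b))
}

#' Cohort comparison report
#'
#' Compares expert vs novice videos on every per-video index: group
#' medians and a two-sided Mann-Whitney U test per index, ROC with
#' Youden cutoff on beta, Spearman correlation of operating time (total
#' frames) against beta, and optionally a Monte-Carlo power block.
#'
#' @param metrics A per-video metrics table from [run_analyze()].
#' @param labels Either a data.frame with columns `video_id` and `group`
#'   (a manifest), or a character vector of `"expert"`/`"novice"` labels
#'   aligned to `metrics` rows. Every video must be labeled and both
#'   groups present.
#' @param power `NULL`, or a list with elements `effect_size_d` and
#'   optionally `n_per_group`, `alpha`, `reps`, `seed`, forwarded to
#'   [power_simulation()].
#' @param out Optional path: the report is also written as pretty JSON.
#' @return A list of class `cohort_report`: `groups` (per-group n),
#'   `tests` (per-index Mann-Whitney results), `roc` (on beta),
#'   `correlation` (total frames vs beta), `power` (or NULL), `config`
#'   echo.
#' @export
run_compare <- function(metrics, labels, power = NULL, out = NULL) {
  if (is.data.frame(labels)) {
    if (!all(c("video_id", "group") %in% names(labels)))
      fk_stop("fluctkin_missing_labels",
              "manifest must have video_id and group columns")
    idx <- match(metrics$video_id, labels$video_id)
    if (anyNA(idx))
      fk_stop("fluctkin_missing_labels", "unlabeled videos: %s",
              paste(metrics$video_id[is.na(idx)], collapse = ", "))
    labels <- labels$group[idx]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(metrics))
    fk_stop("fluctkin_missing_labels",
            "need one label per metrics row")
  if (length(unique(labels)) < 2L)
    fk_stop("fluctkin_empty_group",
            "both groups must be present; got only '%s'", unique(labels))
  ex <- labels == "expert"
  indices <- c("total_frames", "total_travel_distance", "occurrence_rate",
               "mean_speed", "mean_acceleration", "mean_jerk",
               "hover_ratio", "beta")
  tests <- lapply(indices, function(ix)
    mw_or_null(metrics[[ix]][ex], metrics[[ix]][!ex]))
  names(tests) <- indices
  ok <- is.finite(metrics$beta)
  roc <- roc_analysis(metrics$beta[ok], labels[ok])
  # degenerate when e.g. all videos share one duration
  corr <- tryCatch(spearman_rho(metrics$total_frames[ok], metrics$beta[ok]),
                   fluctkin_degenerate_sample = function(e) NULL)
  pw <- if (!is.null(power))
    do.call(power_simulation, power)
  report <- structure(
    list(groups = as.list(table(labels)),
         tests = tests,
         roc = list(auc = roc$auc, cutoff = roc$cutoff,
                    sensitivity = roc$sensitivity,
                    specificity = roc$specificity,
                    points = roc$points),
         correlation = if (is.null(corr)) NULL else unclass(corr),
         power = if (is.null(pw)) NULL else unclass(pw),
         config = list(indices = indices, n_videos = nrow(metrics))),
    class = "cohort_report")
  if (!is.null(out))
    jsonlite::write_json(unclass_deep(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  report
}

# Strip S3 classes recursively so jsonlite serializes plain structures.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %s\n",
              paste(sprintf("%s n=%d", names(x$groups),
                            unlist(x$groups)), collapse = ", ")))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (is.null(t)) next
    cat(sprintf("  %-22s expert %10.3f  novice %10.3f   p = %.4g\n",
                nm, t$median_expert, t$median_novice, t$p_value))
  }
  cat(sprintf("  ROC on beta: AUC %.3f, cutoff %.3f (sens %.1f%%, spec %.1f%%)\n",
              x$roc$auc, x$roc$cutoff, 100 * x$roc$sensitivity,
              100 * x$roc$specificity))
  if (!is.null(x$correlation))
    cat(sprintf("  Spearman frames~beta: rho %.3f (p = %.4g)\n",
                x$correlation$rho, x$correlation$p_value))
  if (!is.null(x$power))
    cat(sprintf("  Power: %.3f (d = %g, n = %d, alpha = %g)\n",
                x$power$power, x$power$effect_size_d, x$power$n_per_group,
                x$power$alpha))
  invisible(x)
}
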