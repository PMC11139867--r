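#' Instrument-tip trajectory
#'
#' A `tip_trajectory` holds one sample per video frame: the tip's pixel
#' coordinates and a visibility flag. Coordinates use the standard image
#' convention: origin at the top-left corner of the frame, x to the right,
#' y downward, both in pixels. Frames where the tip is off screen (or the
#' detector missed it) are marked `visible = FALSE` and carry no
#' coordinates; keeping them as rows makes the occurrence rate and the gap
#' structure of a video explicit.
#'
#' @param x,y Numeric vectors of tip coordinates in pixels. May be `NA`
#'   where `visible` is `FALSE`; must be present and inside
#'   `[0, frame_width] x [0, frame_height]` where `visible` is `TRUE`.
#' @param visible Logical vector, `TRUE` when the tip was detected in the
#'   frame. Defaults to all-visible.
#' @param fps Frame rate in frames per second (default 30, standard HD
#'   surgical video).
#' @param frame_width,frame_height Frame dimensions in pixels. Default
#'   1280 x 720; recordings at 1920 x 1080 should set these explicitly,
#'   since downstream pixel thresholds (e.g. the 120 px/s hover bound)
#'   are resolution dependent.
#' @param start_frame 1-based index of the first frame (files always start
#'   at 1; segments produced by [visible_runs()] keep their original
#'   frame numbers).
#'
#' @return An object of class `tip_trajectory`: a list with elements
#'   `frame`, `x`, `y`, `visible`, `fps`, `frame_width`, `frame_height`.
#' @seealso [read_trajectory()], [write_trajectory()], [visible_runs()]
#' @export
#' @examples
#' t <- tip_trajectory(x = c(10, 13, NA, 20), y = c(10, 14, NA, 20),
#'                     visible = c(TRUE, TRUE, FALSE, TRUE))
#' t
tip_trajectory <- function(x, y, visible = rep(TRUE, length(x)), fps = 30,
                           frame_width = 1280, frame_height = 720,
                           start_frame = 1L) {
  n <- length(visible)
  if (n < 1L)
    fk_stop("fluctkin_empty_trajectory", "a trajectory needs >= 1 sample")
  if (length(x) != n || length(y) != n)
    fk_stop("fluctkin_length_mismatch",
            "x, y, visible must have equal length (got %d, %d, %d)",
            length(x), length(y), n)
  if (!is_number(fps) || fps <= 0)
    fk_stop("fluctkin_bad_fps", "fps must be a positive number")
  if (!is_count(frame_width, 1) || !is_count(frame_height, 1))
    fk_stop("fluctkin_bad_frame_size",
            "frame_width/frame_height must be positive integers")
  visible <- as.logical(visible)
  if (anyNA(visible))
    fk_stop("fluctkin_malformed_field", "visible flag contains NA")
  x <- as.numeric(x); y <- as.numeric(y)
  bad <- visible & (!is.finite(x) | !is.finite(y))
  if (any(bad))
    fk_stop("fluctkin_malformed_field",
            "%d visible sample(s) lack coordinates (first at frame %d)",
            sum(bad), which(bad)[1] + start_frame - 1L)
  oob <- visible & (x < 0 | x > frame_width | y < 0 | y > frame_height)
  if (any(oob))
    fk_stop("fluctkin_out_of_bounds",
            "%d sample(s) outside the %dx%d frame (first at frame %d)",
            sum(oob), frame_width, frame_height,
            which(oob)[1] + start_frame - 1L)
  x[!visible] <- NA_real_
  y[!visible] <- NA_real_
  structure(
    list(frame = seq.int(start_frame, length.out = n),
         x = x, y = y, visible = visible, fps = fps,
         frame_width = as.integer(frame_width),
         frame_height = as.integer(frame_height)),
    class = "tip_trajectory")
}

#' @export
print.tip_trajectory <- function(x, ...) {
  n <- length(x$visible)
  cat(sprintf(
    "<tip_trajectory> %d frames @ %g fps (%.1f min), %dx%d px, %.1f%% visible\n",
    n, x$fps, n / (x$fps * 60), x$frame_width, x$frame_height,
    100 * mean(x$visible)))
  invisible(x)
}

#' @export
length.tip_trajectory <- function(x) length(x$visible)

#' @export
as.data.frame.tip_trajectory <- function(x, ...) {
  data.frame(frame = x$frame, x = x$x, y = x$y,
             visible = as.integer(x$visible))
}

#' Read a tip-coordinate trajectory file
#'
#' The file format is comma-separated text with header `frame,x,y,visible`
#' and one row per video frame. `frame` is the 1-based frame number and
#' must be contiguous (step 1, starting at 1); `visible` is 0 or 1; `x`
#' and `y` are pixel coordinates, blank when `visible = 0`. UTF-8 with
#' Unix or Windows line endings is accepted.
#'
#' Frame rate and frame geometry are file-level metadata supplied by the
#' caller, not columns.
#'
#' @param path Path to a trajectory CSV file.
#' @inheritParams tip_trajectory
#' @return A [tip_trajectory].
#' @export
read_trajectory <- function(path, fps = 30, frame_width = 1280,
                            frame_height = 720) {
  if (!file.exists(path))
    fk_stop("fluctkin_missing_file", "trajectory file not found: %s", path)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("frame", "x", "y", "visible")))
    fk_stop("fluctkin_bad_header",
            "expected header 'frame,x,y,visible', got '%s'",
            paste(names(raw), collapse = ","))
  if (nrow(raw) < 1L)
    fk_stop("fluctkin_empty_trajectory", "no data rows in %s", path)
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & nzchar(v)
    if (any(bad))
      fk_stop("fluctkin_malformed_field",
              "malformed %s value '%s' (row %d) in %s",
              what, v[which(bad)[1]], which(bad)[1], path)
    out
  }
  frame <- num(raw$frame, "frame")
  if (anyNA(frame) || any(frame != round(frame)))
    fk_stop("fluctkin_malformed_field", "non-integer frame index in %s", path)
  if (frame[1] != 1L || (length(frame) > 1L && any(diff(frame) != 1)))
    fk_stop("fluctkin_noncontiguous_frames",
            "frame indices must run 1,2,...,n without gaps in %s", path)
  vis <- num(raw$visible, "visible")
  if (anyNA(vis) || !all(vis %in% c(0, 1)))
    fk_stop("fluctkin_malformed_field",
            "visible must be 0 or 1 for every row in %s", path)
  tip_trajectory(x = num(raw$x, "x"), y = num(raw$y, "y"),
                 visible = vis == 1, fps = fps,
                 frame_width = frame_width, frame_height = frame_height)
}

#' Write a trajectory file
#'
#' Emits the tabular format documented in [read_trajectory()]. Output is
#' deterministic (byte-stable) for a given trajectory, and
#' `read_trajectory(write_trajectory(t, f))` reproduces `t` exactly:
#' coordinates are printed with 17 significant digits, enough to
#' round-trip doubles.
#'
#' @param traj A [tip_trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tip_trajectory"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("frame,x,y,visible",
             sprintf("%d,%s,%s,%d", traj$frame, fmt(traj$x), fmt(traj$y),
                     as.integer(traj$visible)))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    fk_stop("fluctkin_unwritable_path",
                            "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Maximal visible runs of a trajectory
#'
#' Splits a trajectory at invisibility gaps into its maximal contiguous
#' stretches of visible frames, in temporal order. All per-run analyses
#' (step lengths, spectral windows) operate on these segments; gaps are
#' never bridged or interpolated, so an off-screen episode can never
#' inject a spurious large displacement.
#'
#' @param traj A [tip_trajectory].
#' @return A list of `tip_trajectory` segments (possibly empty), each
#'   fully visible and keeping its original frame numbers.
#' @export
#' @examples
#' t <- tip_trajectory(x = c(1, 2, NA, 4, 5), y = c(1, 2, NA, 4, 5),
#'                     visible = c(TRUE, TRUE, FALSE, TRUE, TRUE))
#' lengths(visible_runs(t))
visible_runs <- function(traj) {
  stopifnot(inherits(traj, "tip_trajectory"))
  r <- rle(traj$visible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    tip_trajectory(x = traj$x[i], y = traj$y[i],
                   visible = rep(TRUE, length(i)), fps = traj$fps,
                   frame_width = traj$frame_width,
                   frame_height = traj$frame_height,
                   start_frame = traj$frame[i[1]])
  })
}
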