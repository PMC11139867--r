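#' Binary instrument masks
#'
#' Masks are logical matrices (`height x width`, image-row-major: row 1 is
#' the top of the frame), `TRUE` marking instrument-part pixels. On disk
#' they are single-channel PNG images where any value > 0 is foreground;
#' multi-channel images are collapsed with a per-pixel maximum.
#'
#' @param path PNG file path.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    fk_stop("fluctkin_missing_file", "mask file not found: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  img > 0
}

#' @param mask A logical matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

check_same_dim <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    fk_stop("fluctkin_dim_mismatch",
            "mask dimensions differ: %s vs %s",
            paste(dim(pred), collapse = "x"),
            paste(dim(truth), collapse = "x"))
}

#' Pixel-level confusion counts between two masks
#'
#' @param pred,truth Logical matrices of identical dimensions (predicted
#'   and ground-truth masks).
#' @return Named numeric vector `c(TP, FP, FN, TN)`; the four counts sum
#'   to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  check_same_dim(pred, truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  c(TP = tp, FP = fp, FN = fn, TN = length(truth) - tp - fp - fn)
}

#' Mask accuracy scores: Dice, TPR, FPR
#'
#' `dice = 2*TP / (2*TP + FP + FN)` (the overlap of predicted and true
#' pixel sets), `tpr = TP / (TP + FN)` (recall over true pixels),
#' `fpr = FP / (FP + TN)` (fraction of background claimed). Undefined
#' denominators (empty truth for TPR, empty background for FPR, empty
#' union for Dice) raise a `fluctkin_undefined_ratio` error rather than
#' returning NaN.
#'
#' @inheritParams confusion_counts
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
#' dice(a, b)  # |A| = |B| = 4, overlap 2 -> 0.5
dice <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  denom <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
  if (denom == 0)
    fk_stop("fluctkin_undefined_ratio",
            "both masks empty: Dice undefined")
  unname(2 * cc["TP"] / denom)
}

#' @rdname dice
#' @export
tpr <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  if (cc["TP"] + cc["FN"] == 0)
    fk_stop("fluctkin_undefined_ratio", "truth mask empty: TPR undefined")
  unname(cc["TP"] / (cc["TP"] + cc["FN"]))
}

#' @rdname dice
#' @export
fpr <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  if (cc["FP"] + cc["TN"] == 0)
    fk_stop("fluctkin_undefined_ratio",
            "truth mask covers the frame: FPR undefined")
  unname(cc["FP"] / (cc["FP"] + cc["TN"]))
}

#' Tip-hit rule
#'
#' A predicted tip location counts as a hit when it falls on a `TRUE`
#' pixel of the ground-truth tip region — plain pixel membership with no
#' distance tolerance. Sub-pixel predictions are rounded to the nearest
#' pixel center.
#'
#' @param point Numeric `c(x, y)` in pixels, image convention (x right,
#'   y down, 1-based pixel indices after rounding).
#' @param truth_tip_region Logical matrix (`height x width`).
#' @return `TRUE` or `FALSE`.
#' @export
tip_hit <- function(point, truth_tip_region) {
  stopifnot(is.numeric(point), length(point) == 2L,
            is.logical(truth_tip_region), is.matrix(truth_tip_region))
  col <- round(point[1])
  row <- round(point[2])
  h <- nrow(truth_tip_region); w <- ncol(truth_tip_region)
  if (col < 1 || col > w || row < 1 || row > h)
    fk_stop("fluctkin_out_of_bounds",
            "tip point (%g, %g) outside the %dx%d image", point[1], point[2],
            w, h)
  truth_tip_region[row, col]
}

#' Evaluation-frame sampling
#'
#' Divides a video of `n_frames` frames into `parts` equal parts and
#' takes the first frame after each internal boundary:
#' `floor(k * n_frames / parts) + 1` for `k = 1 .. parts - 1`, 1-based.
#' With the default 11 parts this yields 10 evaluation frames spread over
#' the video while skipping its very start.
#'
#' @param n_frames Total frame count (>= `parts`).
#' @param parts Number of equal parts (default 11).
#' @return Strictly increasing integer vector of length `parts - 1`.
#' @export
#' @examples
#' sample_eval_frames(11000)  # 1001, 2001, ..., 10001
sample_eval_frames <- function(n_frames, parts = 11) {
  if (!is_count(parts, 2))
    fk_stop("fluctkin_malformed_field", "parts must be an integer >= 2")
  if (!is_count(n_frames, parts))
    fk_stop("fluctkin_malformed_field",
            "n_frames must be a count >= parts (= %d)", parts)
  k <- seq_len(parts - 1)
  as.integer(floor(k * n_frames / parts) + 1)
}
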