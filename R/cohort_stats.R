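#' Two-sided Mann-Whitney U test
#'
#' Wrapper fixing the conventions used throughout the cohort analysis:
#' two-sided, exact null distribution whenever `n1 * n2 <= 400` and the
#' data are tie-free, otherwise the normal approximation with tie
#' correction and continuity correction (via [stats::wilcox.test]). The
#' reported `u_statistic` counts pairs `(a_i, b_j)` with `a_i > b_j`
#' (plus half-ties), so swapping the groups maps U to `n1*n2 - U` and
#' leaves p unchanged.
#'
#' @param a,b Numeric samples for the two groups.
#' @return A list of class `group_comparison`: `u_statistic`, `p_value`,
#'   `n1`, `n2`, `exact` (logical: exact path used).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    fk_stop("fluctkin_empty_group", "both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(u_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n1 = length(a), n2 = length(b), exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g (n = %d/%d), two-sided p = %.4g%s\n",
              x$u_statistic, x$n1, x$n2, x$p_value,
              if (x$exact) " (exact)" else " (normal approx.)"))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the p-value from the
#' t-distribution approximation (via [stats::cor.test] with
#' `exact = FALSE`). Used e.g. to relate operating time (total frames)
#' to the fluctuation exponent.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    fk_stop("fluctkin_length_mismatch", "x and y must have equal length")
  if (length(x) < 3L)
    fk_stop("fluctkin_empty_group", "need >= 3 pairs")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0)
    fk_stop("fluctkin_degenerate_sample", "zero rank variance")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f (n = %d), p = %.4g\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}

#' ROC analysis with Youden-index cutoff
#'
#' Threshold sweep over the observed index values (no midpoints), with
#' the orientation fixed so that higher values indicate the expert
#' class; a video is classified expert when its value is `>= cutoff`.
#' The reported cutoff maximizes the Youden index
#' `J = sensitivity + specificity - 1`; ties are broken toward the
#' smallest qualifying observed value. AUC is the trapezoidal area under
#' the (FPR, TPR) curve.
#'
#' @param values Numeric index per video (e.g. estimated beta).
#' @param labels Character/factor/logical per video; `TRUE` or
#'   `"expert"` marks the positive (expert) class.
#' @return A list of class `roc_result`: `points` (data.frame `fpr`,
#'   `tpr`, `threshold`, decreasing thresholds), `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
#' @examples
#' roc_analysis(c(1.5, 1.6, 1.7, 1.0, 1.1, 1.2),
#'              rep(c("expert", "novice"), each = 3))
roc_analysis <- function(values, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "expert", "novice")
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  pos <- values[labels == "expert"]
  neg <- values[labels != "expert"]
  if (length(pos) == 0L || length(neg) == 0L)
    fk_stop("fluctkin_empty_group",
            "ROC needs observations from both classes")
  thr <- sort(unique(values))
  sens <- vapply(thr, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(thr, function(c) mean(neg < c), numeric(1))
  fpr_pts <- c(1, 1 - spec)          # add the all-positive endpoint
  tpr_pts <- c(1, sens)
  ord <- order(fpr_pts, tpr_pts)     # increasing fpr for the trapezoid
  fpr_o <- c(fpr_pts[ord], 0)        # (0, 0) endpoint
  tpr_o <- c(tpr_pts[ord], 0)
  o2 <- order(fpr_o, tpr_o)
  auc <- sum(diff(fpr_o[o2]) * (head(tpr_o[o2], -1) + tail(tpr_o[o2], -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]      # thr sorted ascending: smallest wins
  structure(
    list(points = data.frame(threshold = rev(thr), fpr = rev(1 - spec),
                             tpr = rev(sens)),
         auc = auc, cutoff = thr[best], sensitivity = sens[best],
         specificity = spec[best], youden = j[best]),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f; cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
    x$auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Monte-Carlo power of the two-sided Mann-Whitney test
#'
#' Post-hoc power for a two-group design with a standardized mean
#' difference (Cohen's d): each replicate draws `n_per_group`
#' observations from `Normal(0, 1)` and `Normal(d, 1)`, applies the
#' two-sided [mann_whitney_u()] test, and power is the fraction of
#' replicates with `p < alpha`. Normal parents follow the d-based
#' convention of standard power software.
#'
#' @param effect_size_d Cohen's d (>= 0).
#' @param n_per_group Observations per group.
#' @param alpha Significance level in (0, 1).
#' @param reps Monte-Carlo replicates (>= 1000 recommended for
#'   reporting).
#' @param seed Integer seed.
#' @return A list of class `power_result`: `power`, `alpha`,
#'   `effect_size_d`, `n_per_group`, `reps`, `seed`.
#' @export
#' @examples
#' \donttest{
#' power_simulation(1.46, n_per_group = 9, reps = 2000, seed = 1)
#' }
power_simulation <- function(effect_size_d, n_per_group = 9, alpha = 0.05,
                             reps = 10000, seed = 1) {
  stopifnot(is_number(effect_size_d), effect_size_d >= 0,
            is_count(n_per_group, 2), is_count(reps, 1))
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    fk_stop("fluctkin_malformed_field", "alpha must lie in (0, 1)")
  n <- n_per_group
  rejected <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      a <- rnorm(n)
      b <- rnorm(n, mean = effect_size_d)
      mann_whitney_u(a, b)$p_value < alpha
    }, logical(1))
  })
  structure(list(power = mean(rejected), alpha = alpha,
                 effect_size_d = effect_size_d, n_per_group = n_per_group,
                 reps = reps, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> power = %.3f (d = %g, n = %d/group, alpha = %g, %d reps)\n",
    x$power, x$effect_size_d, x$n_per_group, x$alpha, x$reps))
  invisible(x)
}
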