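# Validation-side statistics: 2x2 chi-square association of expression
# group with clinicopathological features, ROC/AUC for tumor-vs-adjacent
# discrimination, 2^-ddCq relative quantification, and paired comparison.

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square WITHOUT Yates continuity correction by default —
#' the form that reproduces published clinicopathological association
#' statistics computed on small case series; the correction is available
#' via `correct = TRUE`. Rows are the clinical category, columns the
#' expression group (high/low).
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `df` (= 1), `p`.
#' @examples
#' chi_square_2x2(c(9, 3, 2, 6))  # 4.848
#' @export
chi_square_2x2 <- function(x, correct = FALSE) {
  if (!is.matrix(x)) {
    if (length(x) != 4L) stop("need a 2x2 matrix or 4 counts")
    x <- matrix(x, 2L, 2L, byrow = TRUE)
  }
  if (!all(dim(x) == 2L)) stop("table must be 2x2")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("empty table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("zero row or column margin: expected counts undefined")
  fit <- suppressWarnings(stats::chisq.test(x, correct = correct))
  list(statistic = unname(fit$statistic), df = 1L, p = fit$p.value)
}

#' Empirical ROC area under the curve
#'
#' `AUC = P(case score > control score) + 0.5 * P(tie)` — the
#' Mann-Whitney probability, computed from ranks. Equivalent to
#' integrating the empirical ROC curve.
#'
#' @param cases,controls Numeric score vectors (cases are expected
#'   higher).
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(cases, controls) {
  if (!length(cases) || !length(controls)) stop("both groups must be non-empty")
  n1 <- length(cases)
  n2 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC curve points
#'
#' Sensitivity/specificity at every distinct threshold, for export and
#' plotting.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls, Inf)))
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(cases >= t), 1),
    specificity = vapply(thr, function(t) mean(controls < t), 1))
}

#' Relative expression by the 2^-ddCq method
#'
#' `dCq = Cq(target) - Cq(reference)` within each condition;
#' `ddCq = dCq(sample) - dCq(calibrator)`; relative expression is
#' `2^-ddCq` (so one extra doubling of the target in the sample gives 2).
#' GAPDH-style housekeeping genes supply the reference Cq.
#'
#' @param target_sample,reference_sample Target and housekeeping Cq in the
#'   sample condition.
#' @param target_calibrator,reference_calibrator Same in the calibrator
#'   condition.
#' @return Relative expression `2^-ddCq` (vectorized).
#' @export
ddcq <- function(target_sample, reference_sample,
                 target_calibrator, reference_calibrator) {
  cq <- c(target_sample, reference_sample, target_calibrator,
          reference_calibrator)
  if (any(!is.finite(cq))) stop("all four Cq values must be finite")
  d_sample <- target_sample - reference_sample
  d_calib <- target_calibrator - reference_calibrator
  2^-(d_sample - d_calib)
}

#' Paired comparison of tumor and adjacent-tissue values
#'
#' Paired Student's t-test on the differences, two-sided. Zero-variance
#' differences follow the package's documented convention: all-zero
#' differences give `t = 0, p = 1`; a constant non-zero shift gives
#' `t = +/-Inf, p = 0`.
#'
#' @param tumor,adjacent Equal-length paired numeric vectors (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_compare <- function(tumor, adjacent) {
  if (length(tumor) != length(adjacent)) stop("paired vectors differ in length")
  if (length(tumor) < 2L) stop("need >= 2 pairs")
  d <- tumor - adjacent
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_difference = mean(d)))
  }
  fit <- stats::t.test(tumor, adjacent, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value,
       mean_difference = unname(fit$estimate))
}
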