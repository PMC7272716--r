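# Two-group microarray differential expression: signed linear fold changes
# on log2 intensities, Student's t (Welch optional), BH FDR, and the
# |FC| >= 2 & p < 0.05 calling rule.

#' Signed linear fold change from log2 intensities
#'
#' `log2FC = mean(case) - mean(control)`. The linear fold change is
#' reported with the signed convention used in microarray tables:
#' `2^log2FC` when the case group is higher, `-2^(-log2FC)` when lower, so
#' `|FC| >= 1` always and down-regulated genes carry negative values
#' (e.g. a log2FC of -2 is reported as FC = -4).
#'
#' @param case,control Numeric vectors of log2 intensities (>= 1 value
#'   each; >= 2 for testing).
#' @return A list with elements `fc` (signed linear) and `log2fc`.
#' @examples
#' fold_change(c(7, 7, 7), c(4, 4, 4))  # log2fc 3, fc +8
#' @export
fold_change <- function(case, control) {
  if (!length(case) || !length(control))
    stop("empty group in fold_change()")
  log2fc <- mean(case) - mean(control)
  fc <- if (log2fc >= 0) 2^log2fc else -2^(-log2fc)
  list(fc = fc, log2fc = log2fc)
}

#' Two-sample t-test with zero-variance conventions
#'
#' Equal-variance (Student's) two-sample t by default, with
#' `df = n1 + n2 - 2`; Welch's unequal-variance form via `welch = TRUE`.
#' Degenerate inputs follow a documented convention: when both groups are
#' constant, identical means give `t = 0, p = 1` and different means give
#' `t = +/-Inf, p = 0`.
#'
#' @param case,control Numeric vectors, >= 2 values each.
#' @param welch Use Welch's t instead of the pooled-variance form.
#' @return A list with elements `t`, `df`, `p` (two-sided).
#' @export
de_t_test <- function(case, control, welch = FALSE) {
  if (length(case) < 2L || length(control) < 2L)
    stop("need >= 2 replicates per group")
  if (stats::var(case) == 0 && stats::var(control) == 0) {
    delta <- mean(case) - mean(control)
    if (delta == 0) return(list(t = 0, df = length(case) + length(control) - 2L,
                                p = 1))
    return(list(t = sign(delta) * Inf,
                df = length(case) + length(control) - 2L, p = 0))
  }
  fit <- stats::t.test(case, control, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; order-preserving and never
#' below the raw p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two groups
#'
#' Applies the screen's rule gene by gene: signed linear fold change from
#' the group means of the log2 intensities, a two-sample t-test, BH FDR,
#' and direction `UP` if `FC >= fc_threshold` with `p < p_threshold`,
#' `DOWN` if `FC <= -fc_threshold` with `p < p_threshold`, else `NS`. The
#' FDR is reported but (matching the original screen) not used as the
#' filter; pass `use_fdr = TRUE` to filter on it instead of the raw p.
#'
#' @param em An [expression_matrix()]; the second design level is the case
#'   (resistant) group.
#' @param fc_threshold Linear fold-change cutoff (default 2).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param welch Use Welch's t-test.
#' @param use_fdr Filter on BH FDR instead of raw p.
#' @return A data frame of class `de_table` with one row per gene: `gene`,
#'   `biotype`, `fc`, `log2fc`, `t`, `p`, `fdr`, `direction`.
#' @export
call_de <- function(em, fc_threshold = 2, p_threshold = 0.05,
                    welch = FALSE, use_fdr = FALSE) {
  stopifnot(inherits(em, "expression_matrix"), fc_threshold >= 1)
  control <- em$values[, em$design == levels(em$design)[1L], drop = FALSE]
  case <- em$values[, em$design == levels(em$design)[2L], drop = FALSE]
  res <- lapply(seq_len(nrow(em$values)), function(i) {
    fc <- fold_change(case[i, ], control[i, ])
    tt <- de_t_test(case[i, ], control[i, ], welch = welch)
    c(fc = fc$fc, log2fc = fc$log2fc, t = tt$t, p = tt$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = rownames(em$values),
                    biotype = unname(em$biotype[rownames(em$values)]),
                    fc = res[, "fc"], log2fc = res[, "log2fc"],
                    t = res[, "t"], p = res[, "p"],
                    fdr = bh_fdr(res[, "p"]),
                    stringsAsFactors = FALSE)
  crit_p <- if (use_fdr) out$fdr else out$p
  out$direction <- ifelse(out$fc >= fc_threshold & crit_p < p_threshold, "UP",
                   ifelse(out$fc <= -fc_threshold & crit_p < p_threshold,
                          "DOWN", "NS"))
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Tally of differential-expression calls by biotype
#'
#' @param de A `de_table` from [call_de()].
#' @return A contingency table of biotype by direction.
#' @export
de_summary <- function(de) {
  table(biotype = de$biotype,
        direction = factor(de$direction, levels = c("UP", "DOWN", "NS")))
}

#' Write a differential-expression table as TSV
#'
#' @param de A `de_table`.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
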