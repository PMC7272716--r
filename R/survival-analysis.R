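# Kaplan-Meier / log-rank survival stratification by expression level, with
# the cohort-cleaning filters (drop expression == 0 and follow-up < 30
# days) and covariate-restricted subgroup analyses.

#' Apply the cohort-cleaning filters
#'
#' Drops records whose expression value equals 0 and records whose
#' follow-up time is below 30 days — the automatic filters of the survival
#' analysis this mirrors. A record failing both rules is dropped once but
#' counted under both; the counts are attached as the `"dropped"`
#' attribute and reported via `message()`.
#'
#' @param cohort Data frame with columns `time`, `event`, `expression`.
#' @param min_days Follow-up cutoff in days (default 30).
#' @return The filtered cohort, with attribute `dropped` =
#'   `c(zero_expression, short_followup)`.
#' @export
clean_cohort <- function(cohort, min_days = 30) {
  need_cols(cohort, c("time", "event", "expression"), "cohort")
  zero <- cohort$expression == 0
  short <- cohort$time < min_days
  out <- cohort[!(zero | short), , drop = FALSE]
  attr(out, "dropped") <- c(zero_expression = sum(zero),
                            short_followup = sum(short))
  message("clean_cohort: dropped ", sum(zero), " zero-expression and ",
          sum(short), " short-follow-up record(s); ", nrow(out), " retained")
  if (!nrow(out)) warning("no records survive the cleaning filters")
  out
}

#' Split a cohort into high/low expression groups
#'
#' `high` is expression strictly above the `prob` quantile (median by
#' default) computed on the cohort as given — clean first. With an odd
#' number of distinct values the median record falls in the low group.
#'
#' @param cohort Data frame with an `expression` column.
#' @param prob Quantile for the cut (default 0.5 = median split).
#' @return Factor of `"low"`/`"high"` labels (levels in that order).
#' @export
split_by_expression <- function(cohort, prob = 0.5) {
  x <- cohort$expression
  cut <- stats::quantile(x, prob, names = FALSE)
  grp <- ifelse(x > cut, "high", "low")
  if (length(unique(grp)) < 2L)
    stop("cannot split: expression does not separate at the ",
         prob, " quantile")
  factor(grp, levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of S(t); censored records leave the risk set
#' without producing a step.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event flags (1 = death, 0 = censored).
#' @return Data frame with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test and O/E hazard ratio for two groups
#'
#' Mantel-Haenszel log-rank chi-square (1 df, ties handled by the
#' hypergeometric variance) with two-sided p, and the hazard ratio
#' estimated from observed/expected event ratios:
#' `HR = (O2/E2) / (O1/E1)` for the *second* factor level relative to the
#' first (so with [split_by_expression()] labels the HR is high vs low).
#' With no events at all the test is undefined: `chisq = 0, p = 1,
#' hr = NA`.
#'
#' @param time,event Follow-up times and event flags.
#' @param group Two-level factor (reference level first).
#' @return List with `n`, `events` (per group), `chisq`, `p`, `hr`.
#' @export
logrank_hr <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly two non-empty groups")
  if (sum(event) == 0)
    return(list(n = table(group), events = c(0, 0), chisq = 0, p = 1,
                hr = NA_real_))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- fit$obs
  expd <- fit$exp
  hr <- if (obs[1L] > 0 && expd[1L] > 0 && expd[2L] > 0)
    (obs[2L] / expd[2L]) / (obs[1L] / expd[1L]) else NA_real_
  list(n = fit$n, events = obs, chisq = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
       hr = unname(hr))
}

#' Full survival stratification of a cohort by expression
#'
#' The complete analysis chain: cleaning filters, median (or quantile)
#' high/low split, per-group Kaplan-Meier curves, log-rank test and O/E
#' hazard ratio (high vs low).
#'
#' @param cohort Data frame with `time`, `event`, `expression` (plus any
#'   covariates).
#' @param split_prob Quantile for the high/low cut (default median).
#' @param min_n Minimum cohort size after cleaning; smaller cohorts are
#'   refused (default 10).
#' @param quiet Suppress the cleaning message.
#' @return An object of class `km_fit`: list with `n`, `n_group`,
#'   `events`, `chisq`, `p`, `hr`, `curves` (list of [km_curve()] frames
#'   for `low` and `high`), `dropped`.
#' @export
analyze_survival <- function(cohort, split_prob = 0.5, min_n = 10,
                             quiet = FALSE) {
  cohort <- if (quiet) suppressMessages(clean_cohort(cohort))
            else clean_cohort(cohort)
  if (nrow(cohort) < min_n)
    stop("cohort too small after cleaning (", nrow(cohort), " < ", min_n, ")")
  grp <- split_by_expression(cohort, prob = split_prob)
  lr <- logrank_hr(cohort$time, cohort$event, grp)
  curves <- lapply(stats::setNames(levels(grp), levels(grp)), function(g)
    km_curve(cohort$time[grp == g], cohort$event[grp == g]))
  structure(list(n = nrow(cohort), n_group = table(grp),
                 events = lr$events, chisq = lr$chisq, p = lr$p, hr = lr$hr,
                 curves = curves, dropped = attr(cohort, "dropped")),
            class = "km_fit")
}

#' Covariate-restricted subgroup survival analysis
#'
#' Restricts the cohort to records matching every `name = value` filter
#' (e.g. `list(ER = 1)` for the ER-positive subgroup), then runs the full
#' [analyze_survival()] chain. Subgroups smaller than `min_n` after
#' filtering and cleaning are refused with an informative error.
#'
#' @param cohort Data frame with covariate columns.
#' @param filters Named list of required covariate values.
#' @param ... Passed to [analyze_survival()].
#' @param min_n Minimum subgroup size (default 10).
#' @return A `km_fit`.
#' @export
subgroup_analysis <- function(cohort, filters, ..., min_n = 10) {
  keep <- rep(TRUE, nrow(cohort))
  for (nm in names(filters)) {
    if (!nm %in% colnames(cohort)) stop("no such covariate: ", nm)
    keep <- keep & cohort[[nm]] == filters[[nm]]
  }
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) < min_n)
    stop("subgroup too small (", nrow(sub), " record(s) match ",
         paste(names(filters), unlist(filters), sep = "=", collapse = ", "),
         "; need >= ", min_n, ")")
  analyze_survival(sub, ..., min_n = min_n)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier stratification (high vs low expression)\n")
  cat("  n = ", x$n, " (low ", x$n_group[["low"]], ", high ",
      x$n_group[["high"]], "); events = ", sum(x$events), "\n", sep = "")
  cat(sprintf("  log-rank chisq = %.3f (1 df), p = %.4g\n", x$chisq, x$p))
  cat(sprintf("  HR (high vs low, O/E) = %.3f\n", x$hr))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, col = c("blue", "red"), xlab = "Time (days)",
                        ylab = "Survival probability", ...) {
  graphics::plot(NA, xlim = c(0, max(vapply(x$curves, function(cv)
    max(cv$time, 0), 1))), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[i])
  }
  graphics::legend("bottomleft", legend = names(x$curves), col = col,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write survival results and step functions as TSV
#'
#' @param fit A `km_fit`.
#' @param path Results TSV (one row: n per group, events, chisq, p, HR).
#' @param curves_path Optional step-function TSV for plotting.
#' @export
write_survival <- function(fit, path, curves_path = NULL) {
  utils::write.table(
    data.frame(n_low = fit$n_group[["low"]], n_high = fit$n_group[["high"]],
               events = sum(fit$events), chisq = fit$chisq, p = fit$p,
               hr = fit$hr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curves_path)) {
    steps <- do.call(rbind, lapply(names(fit$curves), function(g)
      cbind(group = g, fit$curves[[g]])))
    utils::write.table(steps, curves_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
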