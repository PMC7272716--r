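test_that("cohort cleaning drops zero-expression and short-follow-up records", {
  co <- data.frame(sample = paste0("P", 1:5),
                   time = c(100, 20, 400, 300, 250),
                   event = c(1, 1, 0, 1, 0),
                   expression = c(2, 3, 0, 1, 5))
  expect_message(out <- clean_cohort(co), "dropped 1 zero-expression and 1")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "dropped"),
               c(zero_expression = 1L, short_followup = 1L))

  # clean input passes through unchanged
  ok <- co[c(1, 4, 5), ]
  expect_equal(suppressMessages(clean_cohort(ok))$sample, ok$sample)

  # a record failing both rules is dropped once but counted twice
  both <- data.frame(sample = "P1", time = 20, event = 1, expression = 0)
  res <- suppressMessages(suppressWarnings(clean_cohort(rbind(ok, both))))
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "dropped"),
               c(zero_expression = 1L, short_followup = 1L))
})

test_that("median split puts the median record in the low group", {
  co <- data.frame(expression = 1:10)
  grp <- split_by_expression(co)
  expect_equal(as.vector(table(grp)), c(5, 5))
  co_odd <- data.frame(expression = c(1, 2, 3, 4, 5))
  grp_odd <- split_by_expression(co_odd)
  expect_equal(as.character(grp_odd[3L]), "low")
  expect_error(split_by_expression(data.frame(expression = rep(2, 6))),
               "cannot split")
})

test_that("Kaplan-Meier estimator matches hand evaluation and the ECDF route", {
  cv <- km_curve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(cv$surv, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km_curve(c(5, 8), c(0, 0))$surv, c(1, 1))
  cv1 <- km_curve(c(2, 4, 6, 9), c(0, 1, 0, 0))
  expect_equal(cv1$surv[cv1$time == 4], 2 / 3)  # risk set 3 at t = 4

  # without censoring, S(t) = 1 - ECDF(t), and equals the by-hand product
  set.seed(7)
  for (i in 1:5) {
    t <- sample(1:50, 12, replace = TRUE)
    cv <- km_curve(t, rep(1, 12))
    expect_equal(cv$surv, 1 - ecdf(t)(cv$time))
    expect_equal(cv$surv,
                 vapply(cv$time, function(a) km_by_hand(t, rep(1, 12), a), 1))
  }
})

test_that("log-rank statistic, p and O/E hazard ratio behave as derived", {
  # identical groups: no evidence, HR 1
  t <- c(3, 6, 9, 3, 6, 9); ev <- rep(1, 6)
  g <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  lr <- logrank_hr(t, ev, g)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$hr, 1)

  # hand-evaluated O/E and hypergeometric variance at each event time
  lr2 <- logrank_hr(c(1, 2, 3, 4), c(1, 1, 1, 1),
                    factor(c("B", "B", "A", "A"), levels = c("A", "B")))
  expect_equal(lr2$chisq, 2.882, tolerance = 1e-3)
  expect_equal(lr2$hr, 3.8, tolerance = 1e-3)

  # label exchange: HR -> 1/HR, chisq unchanged
  lr2r <- logrank_hr(c(1, 2, 3, 4), c(1, 1, 1, 1),
                     factor(c("B", "B", "A", "A"), levels = c("B", "A")))
  expect_equal(lr2r$chisq, lr2$chisq)
  expect_equal(lr2r$hr, 1 / lr2$hr)

  # no events at all: undefined HR, p = 1
  lr3 <- logrank_hr(c(5, 6, 7, 8), rep(0, 4),
                    factor(c("low", "low", "high", "high")))
  expect_equal(lr3$p, 1)
  expect_true(is.na(lr3$hr))
  expect_error(logrank_hr(1:3, c(1, 1, 1), factor(rep("A", 3))), "two")
})

test_that("full stratification chain reports groups, HR and curves", {
  co <- simulate_survival(survival_sim_config(n_patients = 200, true_hr = 3,
                                              censor_rate = 0.2, seed = 2))
  fit <- analyze_survival(co, quiet = TRUE)
  expect_s3_class(fit, "km_fit")
  # cleaning may drop naturally short follow-up records; groups partition
  # whatever remains
  expect_equal(fit$n, sum(co$expression != 0 & co$time >= 30))
  expect_equal(fit$n, sum(fit$n_group))
  expect_named(fit$curves, c("low", "high"))
  expect_lt(fit$p, 0.01)
  expect_gt(fit$hr, 1)     # high expression is the riskier group
  expect_output(print(fit), "log-rank")
  # curves start at S <= 1 and never increase
  for (cv in fit$curves) expect_true(all(diff(cv$surv) <= 0))
})

test_that("subgroup analysis restricts, refuses tiny subgroups, and localizes effects", {
  co <- simulate_survival(survival_sim_config(n_patients = 400, true_hr = 1,
                                              censor_rate = 0.2, seed = 3))
  expect_error(subgroup_analysis(co, list(ER = 7)), "subgroup too small")
  expect_error(subgroup_analysis(co, list(nope = 1)), "no such covariate")

  # filter matching everyone reproduces the unstratified analysis
  co$all <- 1L
  full <- analyze_survival(co, quiet = TRUE)
  sub <- subgroup_analysis(co, list(all = 1), quiet = TRUE)
  expect_equal(sub$chisq, full$chisq)
  expect_equal(sub$hr, full$hr)

  # planted ER-restricted hazard: the ER+ subgroup detects it, the
  # complement stays near HR 1 (majority over three seeds)
  res <- vapply(1:3, function(s) {
    co <- simulate_survival(survival_sim_config(
      n_patients = 600, true_hr = 3, censor_rate = 0.1,
      hr_covariate = "ER", seed = s))
    pos <- subgroup_analysis(co, list(ER = 1), quiet = TRUE)
    neg <- subgroup_analysis(co, list(ER = 0), quiet = TRUE)
    c(detected = pos$p < 0.01, null_like = neg$p > 0.05)
  }, c(detected = TRUE, null_like = TRUE))
  expect_equal(sum(res["detected", ]), 3)
  expect_gte(sum(res["null_like", ]), 2)
})

test_that("survival results round-trip through the TSV writers", {
  dir <- withr::local_tempdir()
  co <- simulate_survival(survival_sim_config(n_patients = 80, seed = 4))
  fit <- analyze_survival(co, quiet = TRUE)
  write_survival(fit, file.path(dir, "res.tsv"), file.path(dir, "steps.tsv"))
  res <- read.delim(file.path(dir, "res.tsv"))
  expect_equal(res$chisq, fit$chisq)
  steps <- read.delim(file.path(dir, "steps.tsv"))
  expect_setequal(unique(steps$group), c("low", "high"))
})
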