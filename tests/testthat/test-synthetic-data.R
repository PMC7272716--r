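test_that("expression simulator is deterministic and honours planted effects", {
  cfg <- sim_config(n_genes = 100, noise_sd = 0.2, seed = 42,
                    planted_de = list(c(5, 4), c(5, -4)))
  sim1 <- simulate_expression(cfg)
  sim2 <- simulate_expression(cfg)
  expect_identical(sim1$matrix$values, sim2$matrix$values)
  expect_identical(sim1$truth, sim2$truth)

  # planted fold changes recorded with the signed convention
  expect_setequal(unique(abs(sim1$truth$de$true_fc)), 4)
  expect_equal(nrow(sim1$truth$de), 10)

  # null config plants nothing
  null_sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
  expect_equal(nrow(null_sim$truth$de), 0)
  expect_equal(nrow(null_sim$truth$hubs), 0)
})

test_that("planted-signal fidelity: realized log2 difference matches the planted FC", {
  diffs <- vapply(1:30, function(s) {
    sim <- simulate_expression(sim_config(n_genes = 20, noise_sd = 0.3,
                                          seed = s,
                                          planted_de = list(c(1, 4))))
    g <- sim$truth$de$gene[1L]
    v <- sim$matrix$values[g, ]
    mean(v[4:6]) - mean(v[1:3])
  }, 1)
  # MC error: sd = 0.3 * sqrt(2/3) / sqrt(30) ~ 0.045
  expect_equal(mean(diffs), 2, tolerance = 0.1)
})

test_that("hub modules reach the target correlation", {
  # exact in the rho = 1 limit, regardless of residual noise
  sim <- simulate_expression(sim_config(
    n_genes = 40, noise_sd = 0, seed = 3,
    planted_hubs = list(list(size = 14, rho = 1, fc = 4))))
  hub <- sim$truth$hubs$hub[1L]
  for (p in sim$truth$hubs$partner)
    expect_equal(pearson_r(sim$matrix$values[hub, ],
                           sim$matrix$values[p, ]), 1)

  # and converges to rho as the partner noise shrinks: average sample r
  # across seeds approaches the target
  rbar <- mean(vapply(1:20, function(s) {
    sim <- simulate_expression(sim_config(
      n_genes = 30, noise_sd = 0.1, seed = s,
      planted_hubs = list(list(size = 6, rho = 0.995, fc = 4))))
    hub <- sim$truth$hubs$hub[1L]
    mean(vapply(sim$truth$hubs$partner, function(p)
      pearson_r(sim$matrix$values[hub, ], sim$matrix$values[p, ]), 1))
  }, 1))
  expect_equal(rbar, 0.995, tolerance = 0.01)
})

test_that("hub sizing beyond the mRNA pool is an error", {
  cfg <- sim_config(n_genes = 10, frac_lncRNA = 0.5,
                    planted_hubs = list(list(size = 6, rho = 0.99, fc = 2)))
  expect_error(simulate_expression(cfg), "exceed available mRNA")
  expect_error(sim_config(planted_hubs = list(list(size = 3, rho = 1.2))),
               "\\(0, 1\\]")
})

test_that("survival simulator injects exact record counts and recovers the hazard ratio", {
  co <- simulate_survival(survival_sim_config(
    n_patients = 100, frac_zero_expression = 0.1, frac_short_followup = 0.05,
    seed = 5))
  expect_equal(sum(co$expression == 0), 10)
  expect_gte(sum(co$time < 30), 5)
  expect_identical(co, simulate_survival(survival_sim_config(
    n_patients = 100, frac_zero_expression = 0.1, frac_short_followup = 0.05,
    seed = 5)))

  # O/E estimate tracks the generating hazard ratio (true HR 3, no
  # censoring); the Pike O/E ratio attenuates somewhat for effects this
  # large under complete follow-up, so the band is the wide one
  hrs <- vapply(1:20, function(s) {
    co <- simulate_survival(survival_sim_config(n_patients = 500, true_hr = 3,
                                                censor_rate = 0, seed = s))
    grp <- factor(ifelse(co$expression > median(co$expression),
                         "high", "low"), levels = c("low", "high"))
    logrank_hr(co$time, co$event, grp)$hr
  }, 1)
  expect_equal(mean(hrs), 3, tolerance = 0.2)
})

test_that("log-rank holds its nominal size on null survival cohorts", {
  p <- vapply(1:300, function(s) {
    co <- simulate_survival(survival_sim_config(n_patients = 60, true_hr = 1,
                                                censor_rate = 0.2, seed = s))
    analyze_survival(co, quiet = TRUE)$p
  }, 1)
  expect_gt(mean(p < 0.05), 0.015)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("gene-set simulator plants detectable terms and degenerates cleanly", {
  universe <- sprintf("G%03d", 1:200)
  study <- sample(universe, 25)
  gs <- simulate_gene_sets(30, c(10, 40), universe,
                           planted = list(PLANTED = study), seed = 9)
  expect_identical(gs$sets,
                   simulate_gene_sets(30, c(10, 40), universe,
                                      planted = list(PLANTED = study),
                                      seed = 9)$sets)
  res <- enrich(study, gs, universe)
  expect_equal(res$term[1L], "PLANTED")

  empty <- simulate_gene_sets(0, universe = universe, seed = 1)
  expect_equal(length(empty), 0)
  expect_equal(nrow(enrich(study, empty, universe)), 0)

  expect_error(simulate_gene_sets(1, c(5, 10), universe,
                                  planted = list(BAD = "NOT_A_GENE")),
               "absent from universe")
})

test_that("interaction simulator plants rows that pass or fail the ceRNA filters", {
  lnc <- "LNC1"; mir <- paste0("miR-", 1:5); mr <- paste0("M", 1:6)
  all_pass <- simulate_interactions(lnc, mir, mr, lnc_mirna_pass = 1,
                                    mirna_mrna_pass = 1, seed = 2)
  expect_equal(nrow(filter_lnc_mirna(all_pass$lnc_mirna)),
               nrow(all_pass$lnc_mirna))
  expect_equal(nrow(filter_mirna_mrna(all_pass$mirna_mrna)),
               nrow(all_pass$mirna_mrna))

  all_fail <- simulate_interactions(lnc, mir, mr, lnc_mirna_pass = 0,
                                    mirna_mrna_pass = 0, seed = 2)
  net <- assemble_cerna(lnc, all_fail$lnc_mirna, all_fail$mirna_mrna,
                        hub_partners = mr)
  expect_equal(nrow(net$triplets), 0)

  # five planted passing miRNAs -> five miRNA nodes downstream
  net <- assemble_cerna(lnc, all_pass$lnc_mirna, all_pass$mirna_mrna,
                        hub_partners = mr)
  expect_equal(length(net$mirnas), 5)

  expect_error(simulate_interactions(c("A", "B"), c("B"), c("C")),
               "overlap")
})
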