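test_that("pearson_r matches direct evaluation and is affine-invariant", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, rev(x)), -1)
  r <- pearson_r(x, c(1, 2, 3, 5))
  expect_equal(r, 0.9827, tolerance = 1e-4)
  expect_error(pearson_r(1:2, 1:2), ">= 3")
  expect_error(pearson_r(1:4, 2:5 * 0 + 1), "zero variance")

  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2.5 * a + 7, b), pearson_r(a, b))
  }
})

test_that("network construction thresholds |r| and keeps the sign", {
  # exact duplicates (one negated) are the only pairs at threshold 1
  base <- c(1, 2, 3, 7, 8, 9)
  em <- tiny_em(list(LNC1 = base, LNC2 = c(2, 5, 3, 6, 9, 1),
                     MRNA1 = 2 * base + 1, MRNA2 = -base,
                     MRNA3 = c(4, 1, 5, 2, 8, 3)),
                biotype = c("lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA"))
  net <- build_coexpression_network(em, r_threshold = 1)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$mRNA, c("MRNA1", "MRNA2"))
  expect_equal(net$edges$sign[net$edges$mRNA == "MRNA2"], "negative")

  # the r = 0.9827 pair from the pearson example is NOT retained at 0.99
  em2 <- tiny_em(list(LNCA = c(1, 2, 3, 5, 2, 4), MRNAA = c(1, 2, 3, 4, 2, 4)),
                 biotype = c("lncRNA", "mRNA"))
  r <- pearson_r(em2$values["LNCA", ], em2$values["MRNAA", ])
  expect_lt(abs(r), 0.99)
  expect_equal(nrow(build_coexpression_network(em2)$edges), 0)

  # zero-variance genes are skipped with a warning, not an error
  em3 <- tiny_em(list(LNC1 = base, FLAT = rep(2, 6), MRNA1 = base + 1),
                 biotype = c("lncRNA", "lncRNA", "mRNA"))
  expect_warning(net3 <- build_coexpression_network(em3), "FLAT")
  expect_false("FLAT" %in% net3$nodes$id)
})

test_that("a noiseless planted hub acquires exactly its module edges", {
  sim <- simulate_expression(sim_config(
    n_genes = 40, noise_sd = 0.3, seed = 17,
    planted_hubs = list(list(size = 14, rho = 1, fc = 8))))
  net <- build_coexpression_network(sim$matrix)
  hub <- sim$truth$hubs$hub[1L]
  expect_equal(unname(net$degree[hub]), 14)
  expect_setequal(net$edges$mRNA[net$edges$lncRNA == hub],
                  sim$truth$hubs$partner)
})

test_that("degree centrality and bipartite conservation hold", {
  edges <- candidate_lncrna_edges()
  deg <- degree_centrality(edges[, c("lncRNA", "mRNA")])
  expect_equal(unname(deg["ENST00000456355"]), 14L)
  expect_equal(unname(deg["ENST00000422749"]), 18L)

  net <- coexpression_network(edges)
  lnc_deg <- net$nodes$degree[net$nodes$biotype == "lncRNA"]
  mrna_deg <- net$nodes$degree[net$nodes$biotype == "mRNA"]
  expect_equal(sum(lnc_deg), nrow(net$edges))
  expect_equal(sum(mrna_deg), nrow(net$edges))

  empty <- coexpression_network(data.frame(lncRNA = character(),
                                           mRNA = character(), r = numeric()))
  expect_length(degree_centrality(empty), 0)
})

test_that("raising the correlation threshold never adds edges", {
  sim <- simulate_expression(sim_config(
    n_genes = 80, noise_sd = 0.2, seed = 23,
    planted_hubs = list(list(size = 8, rho = 0.995, fc = 6))))
  key <- function(net) paste(net$edges$lncRNA, net$edges$mRNA)
  loose <- build_coexpression_network(sim$matrix, r_threshold = 0.98)
  tight <- build_coexpression_network(sim$matrix, r_threshold = 0.995)
  expect_true(all(key(tight) %in% key(loose)))
  # inclusive vs strict boundary
  em <- tiny_em(list(L = c(1, 2, 3, 7, 8, 9), M = c(1, 2, 3, 7, 8, 9)),
                biotype = c("lncRNA", "mRNA"))
  expect_equal(nrow(build_coexpression_network(em, r_threshold = 1)$edges), 1)
  expect_equal(
    nrow(build_coexpression_network(em, r_threshold = 1,
                                    inclusive = FALSE)$edges), 0)
})

test_that("hub selection sorts by degree then id and respects the cutoff", {
  net <- coexpression_network(candidate_lncrna_edges())
  hubs <- select_hubs(net)
  expect_equal(hubs, c("ENST00000422749", "NONHSAT057283", "ENST00000456355",
                       "ENST00000455354", "NONHSAT097797", "ENST00000594783"))
  expect_length(select_hubs(net, min_degree = 19), 0)
  expect_equal(select_hubs(net, min_degree = 15),
               c("ENST00000422749", "NONHSAT057283"))
})

test_that("planted hubs are recovered from simulated expression", {
  hits <- vapply(1:25, function(s) {
    sim <- simulate_expression(sim_config(
      n_genes = 60, frac_lncRNA = 0.4, noise_sd = 0.05, seed = s,
      planted_hubs = list(list(size = 8, rho = 0.999, fc = 8),
                          list(size = 7, rho = 0.999, fc = -6))))
    net <- build_coexpression_network(sim$matrix)
    identical(sort(select_hubs(net)), sort(unique(sim$truth$hubs$hub)))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("hub summary mirrors the published table layout", {
  edges <- candidate_lncrna_edges()
  net <- coexpression_network(edges)
  tab <- hub_summary(net)
  expect_equal(nrow(tab), 71)
  expect_equal(tab$degree[tab$lncRNA == "ENST00000456355"][1L], 14L)
  expect_setequal(colnames(tab), c("lncRNA", "degree", "mRNA", "r"))
})
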