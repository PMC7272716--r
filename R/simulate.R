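# Seeded generators for every input the pipeline consumes. Defaults mirror
# the study design they emulate: a 3-vs-3 two-colour lncRNA microarray
# comparison of doxorubicin-resistant vs sensitive cells, a TCGA-like
# survival cohort, GO/KEGG-style gene sets and scored interaction tables.

#' Configuration for the two-group expression simulator
#'
#' @param n_genes Total number of genes on the simulated array.
#' @param frac_lncRNA Proportion of genes annotated as lncRNA.
#' @param n_per_group Replicates per condition (the emulated design has 3).
#' @param baseline_mean,baseline_sd Location/scale of per-gene baseline
#'   log2 intensity.
#' @param planted_de List of `c(size, fc)` pairs: `size` genes planted with
#'   signed linear fold change `fc` (case vs control; negative = down).
#' @param planted_hubs List of hub-module specs, each a list with elements
#'   `size` (number of mRNA partners), `rho` (target Pearson correlation
#'   between hub and partners, in (0, 1]) and `fc` (signed linear fold
#'   change applied to the whole module). An optional `hub` element names
#'   the hub lncRNA; by default hubs take the first lncRNA ids.
#' @param noise_sd Residual per-observation log2 noise SD.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_lncRNA = 0.4, n_per_group = 3,
                       baseline_mean = 8, baseline_sd = 1.5,
                       planted_de = list(), planted_hubs = list(),
                       noise_sd = 0.25, seed = 1L) {
  stopifnot(n_genes >= 2, frac_lncRNA >= 0, frac_lncRNA <= 1,
            n_per_group >= 2, baseline_sd >= 0, noise_sd >= 0)
  planted_hubs <- lapply(planted_hubs, function(h) {
    h <- as.list(h)
    if (is.null(h$size) || h$size < 1) stop("hub module size must be >= 1")
    if (is.null(h$rho) || h$rho <= 0 || h$rho > 1)
      stop("hub target correlation must lie in (0, 1]")
    if (is.null(h$fc)) h$fc <- 1
    h
  })
  for (d in planted_de)
    if (length(d) != 2L || d[[1L]] < 1 || abs(d[[2L]]) < 1)
      stop("planted_de entries are c(size, fc) with size >= 1 and |fc| >= 1")
  structure(list(n_genes = as.integer(n_genes), frac_lncRNA = frac_lncRNA,
                 n_per_group = as.integer(n_per_group),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 planted_de = planted_de, planted_hubs = planted_hubs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

signed_fc_to_log2 <- function(fc) ifelse(fc >= 0, log2(fc), -log2(-fc))

#' Simulate a two-group expression matrix with known ground truth
#'
#' Generates log2 intensities for `2 * n_per_group` samples: per-gene
#' Gaussian baselines, a group effect of `log2(|fc|)` for planted
#' differentially expressed genes, and Gaussian residual noise. Hub modules
#' are generated as affine transforms of the realized hub profile plus noise
#' calibrated from the realized hub standard deviation so that the expected
#' hub-partner Pearson correlation equals the target `rho` (exactly 1 when
#' `rho = 1`). Hub partners are mRNAs; hubs are lncRNAs; the module fold
#' change applies to hub and partners alike.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{an [expression_matrix()] (groups `sensitive`,
#'       `resistant`)}
#'     \item{truth}{a list with `de` (data frame of planted genes, signed
#'       true fold change) and `hubs` (data frame of hub-partner edges)}
#'   }
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_lnc <- round(config$n_genes * config$frac_lncRNA)
  n_mrna <- config$n_genes - n_lnc
  lnc_ids <- sprintf("LNC%05d", seq_len(n_lnc))
  mrna_ids <- sprintf("MRNA%05d", seq_len(n_mrna))
  gid <- c(lnc_ids, mrna_ids)
  n <- config$n_per_group
  sid <- c(sprintf("SENS_%d", seq_len(n)), sprintf("RES_%d", seq_len(n)))
  case <- rep(c(0, 1), each = n)

  hub_sizes <- vapply(config$planted_hubs, function(h) as.integer(h$size), 1L)
  if (sum(hub_sizes) > n_mrna)
    stop("hub module sizes (", sum(hub_sizes),
         " partners) exceed available mRNA count (", n_mrna, ")")
  if (length(config$planted_hubs) > n_lnc)
    stop("more hubs than lncRNAs")

  # assign hub lncRNAs and disjoint partner mRNA blocks
  free_mrna <- mrna_ids
  auto_hub <- setdiff(lnc_ids,
                      unlist(lapply(config$planted_hubs, `[[`, "hub")))
  hubs <- list()
  for (h in config$planted_hubs) {
    hub_id <- h$hub
    if (is.null(hub_id)) { hub_id <- auto_hub[1L]; auto_hub <- auto_hub[-1L] }
    if (!hub_id %in% lnc_ids) stop("hub id not a lncRNA: ", hub_id)
    partners <- free_mrna[seq_len(h$size)]
    free_mrna <- free_mrna[-seq_len(h$size)]
    hubs[[length(hubs) + 1L]] <-
      list(hub = hub_id, partners = partners, rho = h$rho, fc = h$fc)
  }
  module_genes <- unlist(lapply(hubs, function(h) c(h$hub, h$partners)))

  # planted DE genes among the remaining (non-module) genes
  effect <- stats::setNames(numeric(length(gid)), gid)
  free <- setdiff(gid, module_genes)
  for (d in config$planted_de) {
    size <- d[[1L]]
    if (size > length(free)) stop("not enough free genes for planted_de")
    pick <- sample(free, size)
    free <- setdiff(free, pick)
    effect[pick] <- signed_fc_to_log2(d[[2L]])
  }

  baseline <- stats::rnorm(length(gid), config$baseline_mean,
                           config$baseline_sd)
  values <- baseline +
    outer(effect[gid], case) +
    matrix(stats::rnorm(length(gid) * 2 * n, 0, config$noise_sd),
           length(gid), 2 * n)
  dimnames(values) <- list(gid, sid)

  # hub modules: partner = baseline + hub-centred profile + calibrated noise
  for (h in hubs) {
    fx <- signed_fc_to_log2(h$fc)
    hub_profile <- stats::rnorm(1, config$baseline_mean, config$baseline_sd) +
      fx * case + stats::rnorm(2 * n, 0, config$noise_sd)
    values[h$hub, ] <- hub_profile
    centred <- hub_profile - mean(hub_profile)
    sd_h <- stats::sd(hub_profile)
    eps_sd <- if (h$rho == 1) 0 else sd_h * sqrt(1 / h$rho^2 - 1)
    for (p in h$partners) {
      values[p, ] <- stats::rnorm(1, config$baseline_mean, config$baseline_sd) +
        centred + stats::rnorm(2 * n, 0, eps_sd)
    }
    effect[c(h$hub, h$partners)] <- fx
  }

  em <- expression_matrix(
    values,
    design = factor(rep(c("sensitive", "resistant"), each = n),
                    levels = c("sensitive", "resistant")),
    biotype = stats::setNames(rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)), gid))

  planted <- names(effect)[effect != 0]
  truth <- list(
    de = data.frame(gene = planted,
                    true_log2fc = unname(effect[planted]),
                    true_fc = ifelse(effect[planted] >= 0,
                                     2^effect[planted], -2^(-effect[planted])),
                    stringsAsFactors = FALSE),
    hubs = if (length(hubs)) {
      do.call(rbind, lapply(hubs, function(h)
        data.frame(hub = h$hub, partner = h$partners,
                   rho = h$rho, stringsAsFactors = FALSE)))
    } else data.frame(hub = character(), partner = character(),
                      rho = numeric()))
  list(matrix = em, truth = truth)
}

#' Configuration for the survival-cohort simulator
#'
#' @param n_patients Cohort size.
#' @param true_hr Hazard ratio of the high-expression group relative to the
#'   low-expression group (must be > 0).
#' @param baseline_hazard Events per day in the low-expression group.
#' @param censor_rate Proportion of records censored (exact count).
#' @param frac_zero_expression Proportion of records overwritten with
#'   expression exactly 0 (exact count), for filter testing.
#' @param frac_short_followup Proportion of records overwritten with a
#'   follow-up time below 30 days (exact count).
#' @param hr_covariate Optional name of a binary covariate (`"ER"`,
#'   `"HER2"`, `"chemoresistance"`): when set, `true_hr` applies only to
#'   patients positive for that covariate, with hazard ratio 1 elsewhere.
#' @param seed RNG seed.
#' @return A validated list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(n_patients = 300, true_hr = 1,
                                baseline_hazard = 1 / 1500,
                                censor_rate = 0.3,
                                frac_zero_expression = 0,
                                frac_short_followup = 0,
                                hr_covariate = NULL, seed = 1L) {
  stopifnot(n_patients >= 1, true_hr > 0, baseline_hazard > 0)
  for (p in c(censor_rate, frac_zero_expression, frac_short_followup))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (!is.null(hr_covariate) &&
      !hr_covariate %in% c("ER", "HER2", "chemoresistance"))
    stop("unknown hr_covariate: ", hr_covariate)
  structure(list(n_patients = as.integer(n_patients), true_hr = true_hr,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 frac_zero_expression = frac_zero_expression,
                 frac_short_followup = frac_short_followup,
                 hr_covariate = hr_covariate, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a survival cohort with a planted expression effect
#'
#' Draws log-normal expression values, assigns `high = expression > median`,
#' and samples exponential event times whose hazard is multiplied by
#' `true_hr` in the high-expression group (restricted to
#' `hr_covariate`-positive patients when that is set). Censoring is
#' independent exponential, with its rate set so the expected censored
#' proportion equals `censor_rate` under the baseline hazard; the
#' configured fractions of zero-expression and sub-30-day records are then
#' injected by overwriting sampled records, so those counts are exact for
#' filter testing.
#'
#' @param config A [survival_sim_config()].
#' @return A data frame with columns `sample`, `time`, `event`,
#'   `expression`, `ER`, `HER2`, `chemoresistance`.
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  expr <- stats::rlnorm(n, meanlog = 1, sdlog = 0.6)
  covars <- data.frame(ER = stats::rbinom(n, 1, 0.5),
                       HER2 = stats::rbinom(n, 1, 0.3),
                       chemoresistance = stats::rbinom(n, 1, 0.4))
  high <- expr > stats::median(expr)
  affected <- if (is.null(config$hr_covariate)) rep(TRUE, n)
              else covars[[config$hr_covariate]] == 1L
  rate <- config$baseline_hazard *
    ifelse(high & affected, config$true_hr, 1)
  event_time <- stats::rexp(n, rate)
  if (config$censor_rate >= 1) {
    cens_time <- rep(0, n)
  } else if (config$censor_rate > 0) {
    # competing exponential censoring clock: P(censored) = censor_rate at
    # the baseline hazard
    cens_rate <- config$baseline_hazard * config$censor_rate /
      (1 - config$censor_rate)
    cens_time <- stats::rexp(n, cens_rate)
  } else cens_time <- rep(Inf, n)
  event <- as.integer(event_time <= cens_time)
  time <- pmin(event_time, cens_time)
  if (config$frac_zero_expression > 0) {
    idx <- sample.int(n, round(config$frac_zero_expression * n))
    expr[idx] <- 0
  }
  if (config$frac_short_followup > 0) {
    idx <- sample.int(n, round(config$frac_short_followup * n))
    time[idx] <- stats::runif(length(idx), 0, 29.9)
  }
  data.frame(sample = sprintf("P%04d", seq_len(n)), time = time,
             event = event, expression = expr, covars,
             stringsAsFactors = FALSE)
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' @param n_terms Number of random terms to draw.
#' @param term_size_range Integer range of random term sizes.
#' @param universe Character vector of gene ids to draw members from.
#' @param planted Named list of gene vectors inserted verbatim as terms
#'   (so enrichment of those gene lists is detectable by construction);
#'   all planted genes must belong to the universe.
#' @param category Category for all terms (`BP`, `CC`, `MF` or `KEGG`).
#' @param seed RNG seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(n_terms, term_size_range = c(10, 50),
                               universe, planted = list(),
                               category = "BP", seed = 1L) {
  set.seed(seed)
  if (max(term_size_range) > length(universe))
    stop("term sizes exceed universe size")
  for (nm in names(planted)) {
    bad <- setdiff(planted[[nm]], universe)
    if (length(bad))
      stop("planted genes absent from universe in '", nm, "': ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  sets <- planted
  if (n_terms > 0) {
    sizes <- sample(seq(term_size_range[1L], term_size_range[2L]), n_terms,
                    replace = TRUE)
    rand <- lapply(sizes, function(s) sample(universe, s))
    names(rand) <- sprintf("%s%04d", category, seq_len(n_terms))
    sets <- c(sets, rand)
  }
  gene_set_collection(sets, category = category)
}

#' Simulate scored lncRNA-miRNA and miRNA-mRNA interaction tables
#'
#' Generates full cross tables: every lncRNA x miRNA pair with
#' `correlation` and `binding` scores, every miRNA x mRNA pair with a
#' cumulative weighted `context` (context++) score. A planted subset of
#' rows receives scores passing the ceRNA filters (correlation > 0.9,
#' binding > 0.04, context <= -0.2); all other rows receive failing scores.
#'
#' @param lnc_ids,mirna_ids,mrna_ids Disjoint id sets.
#' @param lnc_mirna_pass Either a fraction in \[0, 1\] (random subset of
#'   rows passes) or a two-column data frame (`lncRNA`, `miRNA`) of pairs
#'   forced to pass.
#' @param mirna_mrna_pass Same, with columns `miRNA`, `mRNA`.
#' @param seed RNG seed.
#' @return List with data frames `lnc_mirna` (`lncRNA`, `miRNA`,
#'   `correlation`, `binding`) and `mirna_mrna` (`miRNA`, `mRNA`,
#'   `context`).
#' @export
simulate_interactions <- function(lnc_ids, mirna_ids, mrna_ids,
                                  lnc_mirna_pass = 0.5,
                                  mirna_mrna_pass = 0.5, seed = 1L) {
  ids <- c(lnc_ids, mirna_ids, mrna_ids)
  if (anyDuplicated(ids))
    stop("id namespaces overlap: ", ids[duplicated(ids)][1L])
  set.seed(seed)

  lm <- expand.grid(lncRNA = lnc_ids, miRNA = mirna_ids,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pass1 <- planted_rows(lm, lnc_mirna_pass)
  n1 <- nrow(lm)
  lm$correlation <- ifelse(pass1, stats::runif(n1, 0.905, 0.999),
                           stats::runif(n1, 0.2, 0.89))
  lm$binding <- ifelse(pass1, stats::runif(n1, 0.045, 0.2),
                       stats::runif(n1, 0.001, 0.039))

  mm <- expand.grid(miRNA = mirna_ids, mRNA = mrna_ids,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pass2 <- planted_rows(mm, mirna_mrna_pass)
  n2 <- nrow(mm)
  mm$context <- ifelse(pass2, stats::runif(n2, -0.8, -0.21),
                       stats::runif(n2, -0.19, -0.01))

  list(lnc_mirna = lm, mirna_mrna = mm)
}

# Which rows of a cross table are planted to pass: fraction or pair frame.
planted_rows <- function(grid, spec) {
  if (is.data.frame(spec)) {
    key <- paste(grid[[1L]], grid[[2L]], sep = "\r")
    want <- paste(spec[[1L]], spec[[2L]], sep = "\r")
    missing <- setdiff(want, key)
    if (length(missing)) stop("planted pair not in id cross product")
    key %in% want
  } else {
    stopifnot(spec >= 0, spec <= 1)
    seq_len(nrow(grid)) %in% sample.int(nrow(grid), round(spec * nrow(grid)))
  }
}
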