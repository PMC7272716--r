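# Bundled worked-example data (plain-text TSVs under inst/extdata).

#' Candidate lncRNA-mRNA edge list from the doxorubicin-resistance screen
#'
#' The published correlation table of the six candidate lncRNAs from the
#' MCF-7/ADR vs MCF-7 microarray screen: each row is one lncRNA-mRNA
#' coexpression edge with the lncRNA's signed linear fold change, p-value
#' and regulation level, and the edge's Pearson r (71 edges over 6
#' lncRNAs).
#'
#' @return Data frame with columns `lncRNA`, `alias`, `fold_change`,
#'   `p_value`, `level`, `mRNA`, `r`.
#' @export
candidate_lncrna_edges <- function() {
  utils::read.delim(system.file("extdata", "candidate_lncrna_mrna_edges.tsv",
                                package = "lncnet"))
}

#' Clinicopathological 2x2 counts for the validation cohort
#'
#' High/low lnc-TRDMT1-5 expression counts by clinical category for the
#' 20-patient breast-cancer validation series: age, lymph-node metastasis,
#' ER, PR, HER2, TNM stage and Ki-67 group (two rows per feature).
#'
#' @return Data frame with columns `feature`, `category`, `high`, `low`.
#' @export
clinicopath_counts <- function() {
  utils::read.delim(system.file("extdata", "clinicopath_2x2.tsv",
                                package = "lncnet"))
}

#' Example scored interaction tables for the ceRNA worked example
#'
#' Synthetic score tables (the external database scores are not published;
#' see the files' `_synthetic` suffix) encoding the five reported
#' candidate miRNAs of lnc-TRDMT1-5 and their six reported mRNA targets
#' with passing scores, plus deliberately failing rows: a miRNA below the
#' correlation cutoff, a target above the context++ cutoff, and a passing
#' target outside the hub's coexpression partners.
#'
#' @return List with data frames `lnc_mirna` and `mirna_mrna`.
#' @export
example_cerna_tables <- function() {
  list(
    lnc_mirna = utils::read.delim(
      system.file("extdata", "cerna_lnc_mirna_synthetic.tsv",
                  package = "lncnet")),
    mirna_mrna = utils::read.delim(
      system.file("extdata", "cerna_mirna_mrna_synthetic.tsv",
                  package = "lncnet")))
}
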