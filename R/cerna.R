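# Competing endogenous RNA (ceRNA) network: filter scored lncRNA-miRNA and
# miRNA-mRNA interaction tables on the screen's thresholds and assemble
# lncRNA-miRNA-mRNA triplets restricted to the hub's coexpressed mRNAs.

#' Filter lncRNA-miRNA interactions on correlation and binding scores
#'
#' Retains rows with `correlation > corr_min` AND `binding > binding_min`
#' — both strictly, exactly as the published thresholds ("> 0.9",
#' "> 0.04") are stated, so a row at the boundary is rejected.
#'
#' @param table Data frame with columns `correlation` and `binding` (plus
#'   id columns).
#' @param corr_min Correlation-score cutoff (default 0.9, exclusive).
#' @param binding_min Binding-score cutoff (default 0.04, exclusive).
#' @return The retained rows.
#' @export
filter_lnc_mirna <- function(table, corr_min = 0.9, binding_min = 0.04) {
  need_cols(table, c("correlation", "binding"), "lncRNA-miRNA table")
  out <- table[table$correlation > corr_min & table$binding > binding_min, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter miRNA-mRNA interactions on the context++ score
#'
#' Retains rows with cumulative weighted context++ score `<= context_max`
#' (inclusive, per the published "<= -0.2"; more negative means stronger
#' predicted targeting).
#'
#' @param table Data frame with a `context` column.
#' @param context_max Score cutoff (default -0.2, inclusive).
#' @return The retained rows.
#' @export
filter_mirna_mrna <- function(table, context_max = -0.2) {
  need_cols(table, "context", "miRNA-mRNA table")
  out <- table[table$context <= context_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the lncRNA-miRNA-mRNA (ceRNA) network
#'
#' Forms a triplet for every chain `hub -> miRNA -> mRNA` in which the
#' lncRNA-miRNA pair survives [filter_lnc_mirna()], the miRNA-mRNA pair
#' survives [filter_mirna_mrna()], and (by default) the mRNA belongs to
#' the hub's coexpression partners — the cytoplasmic sponge model only
#' makes sense for targets the hub is actually coexpressed with. Output is
#' sorted by (miRNA, mRNA) so it is invariant to input row order.
#'
#' @param hub The hub lncRNA id.
#' @param lnc_mirna Data frame with columns `lncRNA`, `miRNA`,
#'   `correlation`, `binding` (raw table; filtering is applied here).
#' @param mirna_mrna Data frame with columns `miRNA`, `mRNA`, `context`.
#' @param hub_partners Character vector of the hub's coexpressed mRNAs.
#' @param restrict_to_partners Keep only triplets whose mRNA lies in
#'   `hub_partners` (default TRUE when partners are given).
#' @param corr_min,binding_min,context_max Score thresholds, passed to the
#'   filters.
#' @return An object of class `cerna_network`: list with `triplets` (data
#'   frame `lncRNA`, `miRNA`, `mRNA`, `correlation`, `binding`,
#'   `context`), `mirnas`, `mrnas` (sorted distinct node ids).
#' @export
assemble_cerna <- function(hub, lnc_mirna, mirna_mrna, hub_partners = NULL,
                           restrict_to_partners = !is.null(hub_partners),
                           corr_min = 0.9, binding_min = 0.04,
                           context_max = -0.2) {
  need_cols(lnc_mirna, c("lncRNA", "miRNA"), "lncRNA-miRNA table")
  need_cols(mirna_mrna, c("miRNA", "mRNA"), "miRNA-mRNA table")
  if (restrict_to_partners && is.null(hub_partners))
    stop("restrict_to_partners = TRUE needs hub_partners")
  lm <- filter_lnc_mirna(lnc_mirna, corr_min, binding_min)
  lm <- lm[lm$lncRNA == hub, , drop = FALSE]
  mm <- filter_mirna_mrna(mirna_mrna, context_max)
  if (restrict_to_partners)
    mm <- mm[mm$mRNA %in% hub_partners, , drop = FALSE]
  tri <- merge(lm[, c("lncRNA", "miRNA", "correlation", "binding")],
               mm[, c("miRNA", "mRNA", "context")], by = "miRNA")
  tri <- tri[, c("lncRNA", "miRNA", "mRNA", "correlation", "binding",
                 "context")]
  tri <- tri[order(tri$miRNA, tri$mRNA), , drop = FALSE]
  rownames(tri) <- NULL
  structure(list(triplets = tri,
                 mirnas = sort(unique(tri$miRNA)),
                 mrnas = sort(unique(tri$mRNA))),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network: ", nrow(x$triplets), " triplet(s); ",
      length(x$mirnas), " miRNA node(s), ", length(x$mrnas),
      " mRNA node(s)\n", sep = "")
  invisible(x)
}

#' Write ceRNA triplets as TSV
#'
#' @param network A [assemble_cerna()] result.
#' @param path Output path.
#' @export
write_cerna <- function(network, path) {
  utils::write.table(network$triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
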