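# lncRNA-mRNA coexpression network: Pearson correlation across all pooled
# samples, |r| thresholded at 0.99, degree centrality, and degree >= 6 hub
# selection.

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with the pipeline's preconditions
#' made explicit: equal length >= 3 and non-zero variance in both vectors
#' (a correlation over fewer points, or with a constant vector, is
#' undefined here rather than NA).
#'
#' @param x,y Numeric vectors.
#' @return The correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Construct a coexpression network from an edge list
#'
#' Low-level constructor: takes lncRNA-mRNA edges with their correlation
#' values and assembles the classed network object (edge sign, per-node
#' degree, node table). Used by [build_coexpression_network()] and directly
#' when loading a published edge list.
#'
#' @param edges Data frame with columns `lncRNA`, `mRNA`, `r`.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (with `sign` added), `degree` (named integer vector over all nodes)
#'   and `nodes` (data frame: `id`, `biotype`, `degree`).
#' @export
coexpression_network <- function(edges) {
  need_cols(edges, c("lncRNA", "mRNA", "r"), "edges")
  edges <- data.frame(lncRNA = as.character(edges$lncRNA),
                      mRNA = as.character(edges$mRNA),
                      r = as.numeric(edges$r), stringsAsFactors = FALSE)
  if (any(abs(edges$r) > 1)) stop("|r| > 1 in edge list")
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  ids <- c(unique(edges$lncRNA), unique(edges$mRNA))
  degree <- stats::setNames(integer(length(ids)), ids)
  tab <- table(c(edges$lncRNA, edges$mRNA))
  degree[names(tab)] <- as.integer(tab)
  nodes <- data.frame(
    id = ids,
    biotype = rep(c("lncRNA", "mRNA"),
                  c(length(unique(edges$lncRNA)),
                    length(unique(edges$mRNA)))),
    degree = unname(degree[ids]), stringsAsFactors = FALSE)
  structure(list(edges = edges, degree = degree, nodes = nodes),
            class = "coexpression_network")
}

#' Build the lncRNA-mRNA coexpression network from expression data
#'
#' Computes the Pearson correlation of every lncRNA against every mRNA
#' across *all* samples of both groups pooled, and retains the pair as an
#' edge when `|r|` meets the threshold (inclusive `>=` by default,
#' matching the screen's "equal to or greater than 0.99"; the correlation
#' sign is kept as an edge attribute, since strongly anti-correlated pairs
#' are part of the network). The default network is strictly bipartite;
#' genes with zero variance are skipped with a warning.
#'
#' @param em An [expression_matrix()].
#' @param lnc_ids,mrna_ids Gene ids for the two sides; default to all
#'   genes of the respective biotype. Restrict `mrna_ids` to the
#'   enrichment-selected mRNAs to mirror the published screen.
#' @param r_threshold Correlation cutoff on `|r|` (default 0.99).
#' @param inclusive Retain edges at exactly the threshold (default TRUE).
#' @return A [coexpression_network()].
#' @export
build_coexpression_network <- function(em, lnc_ids = NULL, mrna_ids = NULL,
                                       r_threshold = 0.99,
                                       inclusive = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 3L) stop("need >= 3 samples for correlations")
  if (is.null(lnc_ids)) lnc_ids <- biotype_ids(em, "lncRNA")
  if (is.null(mrna_ids)) mrna_ids <- biotype_ids(em, "mRNA")
  missing <- setdiff(c(lnc_ids, mrna_ids), rownames(em$values))
  if (length(missing))
    stop("ids absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))

  keep_var <- function(ids) {
    sds <- apply(em$values[ids, , drop = FALSE], 1L, stats::sd)
    if (any(sds == 0))
      warning("skipping zero-variance gene(s): ",
              paste(utils::head(ids[sds == 0], 3), collapse = ", "))
    ids[sds > 0]
  }
  lnc_ids <- keep_var(lnc_ids)
  mrna_ids <- keep_var(mrna_ids)

  rmat <- stats::cor(t(em$values[lnc_ids, , drop = FALSE]),
                     t(em$values[mrna_ids, , drop = FALSE]))
  # round away float fuzz so exact duplicates reach |r| = 1 and boundary
  # comparisons at the threshold are well defined
  rmat <- round(rmat, 12L)
  hit <- if (inclusive) abs(rmat) >= r_threshold else abs(rmat) > r_threshold
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(lncRNA = lnc_ids[idx[, 1L]],
                      mRNA = mrna_ids[idx[, 2L]],
                      r = rmat[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$lncRNA, edges$mRNA), , drop = FALSE]
  rownames(edges) <- NULL
  coexpression_network(edges)
}

#' Degree centrality of network nodes
#'
#' The number of edges incident to each node — the centrality measure used
#' to rank candidate regulators in the network.
#'
#' @param network A [coexpression_network()], or a data frame whose first
#'   two columns are the edge endpoints.
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(network) UseMethod("degree_centrality")

#' @export
degree_centrality.coexpression_network <- function(network) network$degree

#' @export
degree_centrality.data.frame <- function(network) {
  ends <- c(as.character(network[[1L]]), as.character(network[[2L]]))
  tab <- table(ends)
  stats::setNames(as.integer(tab), names(tab))
}

#' Select hub lncRNAs by degree
#'
#' Hubs are the lncRNAs with at least `min_degree` incident edges (the
#' screen used degree >= 6), returned sorted by decreasing degree with
#' lexicographic id tie-break for reproducibility.
#'
#' @param network A [coexpression_network()].
#' @param min_degree Minimum degree (default 6).
#' @param biotype Which side to select from (default `"lncRNA"`).
#' @return Character vector of hub ids.
#' @export
select_hubs <- function(network, min_degree = 6, biotype = "lncRNA") {
  stopifnot(inherits(network, "coexpression_network"))
  nodes <- network$nodes[network$nodes$biotype == biotype, , drop = FALSE]
  nodes <- nodes[nodes$degree >= min_degree, , drop = FALSE]
  nodes <- nodes[order(-nodes$degree, nodes$id), , drop = FALSE]
  nodes$id
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network: ", nrow(x$edges), " edges between ",
      sum(x$nodes$biotype == "lncRNA"), " lncRNAs and ",
      sum(x$nodes$biotype == "mRNA"), " mRNAs\n", sep = "")
  if (nrow(x$edges))
    cat("sign: ", sum(x$edges$sign == "positive"), " positive, ",
        sum(x$edges$sign == "negative"), " negative; max degree ",
        max(x$degree), "\n", sep = "")
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, min_degree = 6, ...) {
  hubs <- select_hubs(object, min_degree = min_degree)
  cat("edges:", nrow(object$edges), "\n")
  cat("hub lncRNAs (degree >= ", min_degree, "): ",
      paste(hubs, collapse = ", "), "\n", sep = "")
  invisible(list(edges = nrow(object$edges), hubs = hubs))
}

#' Per-hub summary table
#'
#' One row per hub-partner edge, mirroring the layout of published
#' candidate tables: hub id, its fold change/p/direction when a
#' differential-expression table is supplied, degree, partner mRNA and the
#' correlation.
#'
#' @param network A [coexpression_network()].
#' @param hubs Hub ids (default: [select_hubs()] at degree >= 6).
#' @param de Optional `de_table` from [call_de()] for the fold-change
#'   columns.
#' @return A data frame.
#' @export
hub_summary <- function(network, hubs = select_hubs(network), de = NULL) {
  edges <- network$edges[network$edges$lncRNA %in% hubs, , drop = FALSE]
  out <- data.frame(lncRNA = edges$lncRNA,
                    degree = unname(network$degree[edges$lncRNA]),
                    mRNA = edges$mRNA, r = edges$r,
                    stringsAsFactors = FALSE)
  if (!is.null(de)) {
    idx <- match(out$lncRNA, de$gene)
    out <- cbind(out[1L], fc = de$fc[idx], p = de$p[idx],
                 direction = de$direction[idx], out[-1L])
  }
  out <- out[order(match(out$lncRNA, hubs)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
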