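# Over-representation analysis against GO/KEGG-style gene-set collections
# via the upper-tail hypergeometric test, and the dual GO+KEGG overlap rule
# used to select mRNAs for the coexpression stage.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of seeing at
#' least `k` of the `K` term members in a study set of size `n` drawn from
#' a universe of `N` genes. With `ease = TRUE`, the EASE-style conservative
#' variant is computed by discounting one overlapping gene (the upper-tail
#' p at `k - 1` successes).
#'
#' @param k Overlap count.
#' @param K Term size in the universe.
#' @param n Study-set size.
#' @param N Universe size.
#' @param ease Use the EASE (k - 1) variant.
#' @return The p-value; 1 when `k = 0`.
#' @examples
#' hypergeom_p(4, 4, 5, 10)  # 6/252
#' @export
hypergeom_p <- function(k, K, n, N, ease = FALSE) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n) <= N)")
  if (ease) k <- max(k - 1L, 0L)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a study set
#'
#' Tests every term of the collection for enrichment in the study set by
#' the upper-tail hypergeometric test, keeping terms with at least one
#' overlapping gene. Significance is called on the raw p-value by default
#' (the convention of the screen this mirrors); the BH FDR is reported
#' alongside.
#'
#' @param study Character vector of study gene ids (must lie in `universe`).
#' @param collection A [gene_set_collection()].
#' @param universe Character vector: the background, conventionally all
#'   genes on the array annotation.
#' @param alpha Significance cutoff applied to the raw p (default 0.05).
#' @param ease Use the EASE (k - 1) hypergeometric variant.
#' @return A data frame sorted by p: `term`, `name`, `category`, `k`, `K`,
#'   `n`, `N`, `p`, `fdr`, `significant`, and a list column `genes` with
#'   the overlapping ids.
#' @export
enrich <- function(study, collection, universe, alpha = 0.05, ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  bad <- setdiff(study, universe)
  if (length(bad))
    stop("study genes outside the universe: ",
         paste(utils::head(bad, 3), collapse = ", "))
  study <- unique(study)
  n <- length(study)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    hit <- intersect(study, members)
    if (!length(hit)) return(NULL)
    data.frame(term = id, name = collection$name[[id]],
               category = collection$category[[id]],
               k = length(hit), K = length(members), n = n, N = N,
               p = hypergeom_p(length(hit), length(members), n, N,
                               ease = ease),
               genes = I(list(sort(hit))), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term = character(), name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), significant = logical(),
                      genes = I(list())))
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Select mRNAs overlapping significant GO and KEGG terms
#'
#' Returns the differentially expressed mRNAs that belong to at least one
#' significant GO term *and* at least one significant KEGG pathway — the
#' dual-membership rule used to pick the mRNA side of the coexpression
#' network. Interpretation is at the gene level; the result is sorted and
#' duplicate-free, so the selection is idempotent and order-independent.
#'
#' @param de_mrnas Character vector of differentially expressed mRNA ids.
#' @param go_results,kegg_results Data frames from [enrich()].
#' @param alpha Significance cutoff on the raw p (default 0.05).
#' @return Sorted character vector of selected mRNA ids.
#' @export
overlap_go_kegg <- function(de_mrnas, go_results, kegg_results,
                            alpha = 0.05) {
  sig_genes <- function(res) {
    keep <- res$p < alpha
    unique(unlist(res$genes[keep]))
  }
  hit <- intersect(sig_genes(go_results), sig_genes(kegg_results))
  sort(intersect(unique(de_mrnas), hit))
}

#' Write enrichment results as TSV
#'
#' @param res An [enrich()] result.
#' @param path Output path; the overlap gene list is comma-joined.
#' @export
write_enrichment <- function(res, path) {
  flat <- res
  flat$genes <- vapply(res$genes, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
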