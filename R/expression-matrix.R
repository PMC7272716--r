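#' Expression matrix with two-group design and biotype annotation
#'
#' Container for a genes x samples matrix of log2 intensities together with
#' the sample-to-group assignment and the gene biotype (lncRNA or mRNA).
#' All downstream stages (differential expression, coexpression networks)
#' operate on this object.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Log2 scale, finite values only.
#' @param design Factor or character vector, one group label per sample,
#'   named by sample id (or in column order). Exactly two levels; the
#'   *second* level is treated as the case (resistant) group by
#'   [call_de()].
#' @param biotype Character vector of `"lncRNA"`/`"mRNA"`, named by gene id
#'   (or in row order).
#' @param symbol Optional gene symbols, named by gene id; defaults to the
#'   gene ids themselves.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `design`, `biotype`, `symbol`.
#' @examples
#' m <- matrix(rnorm(12, 8), 2, 6,
#'             dimnames = list(c("LNC1", "MRNA1"), paste0("S", 1:6)))
#' em <- expression_matrix(m, rep(c("sensitive", "resistant"), each = 3),
#'                         c("lncRNA", "mRNA"))
#' em
#' @export
expression_matrix <- function(values, design, biotype, symbol = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  if (!all(is.finite(values)))
    stop("non-finite expression values present")

  design <- resolve_names(design, sid, "design")
  if (!is.factor(design))  # first-seen group becomes the control level
    design <- factor(as.character(design),
                     levels = unique(as.character(design)))
  design <- droplevels(design)
  names(design) <- sid
  if (nlevels(design) != 2L)
    stop("design must have exactly two groups, got: ",
         paste(levels(design), collapse = ", "))

  biotype <- resolve_names(biotype, gid, "biotype")
  if (!all(biotype %in% c("lncRNA", "mRNA")))
    stop("biotype must be 'lncRNA' or 'mRNA'")
  names(biotype) <- gid

  if (is.null(symbol)) symbol <- stats::setNames(gid, gid)
  else symbol <- resolve_names(symbol, gid, "symbol")
  names(symbol) <- gid

  structure(list(values = values, design = design, biotype = biotype,
                 symbol = symbol),
            class = "expression_matrix")
}

# Align a per-gene/per-sample attribute vector to the required ids, either
# by name or by position.
resolve_names <- function(x, ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop("missing ", what, " for: ", paste(utils::head(missing, 3), collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop("'", what, "' must have one entry per id (", length(ids), ")")
  }
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes (",
      sum(x$biotype == "lncRNA"), " lncRNA, ", sum(x$biotype == "mRNA"),
      " mRNA) x ", ncol(x$values), " samples\n", sep = "")
  cat("groups: ", paste(sprintf("%s (n=%d)", levels(x$design),
                                tabulate(x$design)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene ids of a given biotype
#'
#' @param em An [expression_matrix()].
#' @param biotype `"lncRNA"` or `"mRNA"`.
#' @return Character vector of gene ids.
#' @export
biotype_ids <- function(em, biotype = c("lncRNA", "mRNA")) {
  biotype <- match.arg(biotype)
  names(em$biotype)[em$biotype == biotype]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
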