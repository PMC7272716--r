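# File formats. Everything is tab-separated UTF-8 with a mandatory header
# row and "." as decimal point; GMT and SIF follow their usual line-oriented
# conventions.

#' Read an expression matrix with design and annotation
#'
#' Reads a genes x samples TSV (first column gene id, remaining columns one
#' per sample), a design TSV (`sample_id`, `group`) and an annotation TSV
#' (`gene_id`, `symbol`, `biotype`), and assembles a validated
#' [expression_matrix()].
#'
#' @param path Expression TSV.
#' @param design_path Design TSV mapping every sample to one of two groups.
#'   Group order in the file determines level order (first-seen group is
#'   the control).
#' @param annotation_path Annotation TSV with columns `gene_id`, `symbol`,
#'   `biotype` (`lncRNA`/`mRNA`).
#' @return An [expression_matrix()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, design_path, annotation_path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus samples")
  gid <- raw[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene id in ", path, ": ", gid[duplicated(gid)][1L])
  vals <- as.matrix(raw[-1L])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                     dimnames = list(gid, colnames(vals))))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene '", gid[bad[1L]], "', sample '",
         colnames(storage)[bad[2L]], "'")
  }

  des <- utils::read.delim(design_path, colClasses = "character")
  need_cols(des, c("sample_id", "group"), design_path)
  missing <- setdiff(colnames(storage), des$sample_id)
  if (length(missing))
    stop("samples without group label: ", paste(missing, collapse = ", "))
  design <- factor(des$group, levels = unique(des$group))
  names(design) <- des$sample_id

  ann <- read_annotation(annotation_path)
  missing <- setdiff(gid, ann$gene_id)
  if (length(missing))
    stop("genes missing from annotation: ",
         paste(utils::head(missing, 3), collapse = ", "))
  idx <- match(gid, ann$gene_id)

  expression_matrix(storage,
                    design = design[colnames(storage)],
                    biotype = stats::setNames(ann$biotype[idx], gid),
                    symbol = stats::setNames(ann$symbol[idx], gid))
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `symbol`, `biotype`.
#' @return A data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character")
  need_cols(ann, c("gene_id", "symbol", "biotype"), path)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1L])
  ann
}

#' Write an expression matrix (plus design and annotation files)
#'
#' @param em An [expression_matrix()].
#' @param path Expression TSV to write.
#' @param design_path,annotation_path Companion files; omit (`NULL`) to skip.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, design_path = NULL,
                             annotation_path = NULL) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(
      data.frame(sample_id = names(em$design), group = as.character(em$design)),
      design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(
      data.frame(gene_id = names(em$biotype), symbol = unname(em$symbol),
                 biotype = unname(em$biotype)),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set collection
#'
#' A named collection of gene sets, each with a display name and a category
#' (`BP`, `CC`, `MF` for GO; `KEGG` for pathways).
#'
#' @param sets Named list of character vectors (member gene ids); every set
#'   must be non-empty and term ids unique.
#' @param category Character vector of categories, one per set (recycled if
#'   length 1).
#' @param name Display names, one per set; defaults to the term ids.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = "BP", name = NULL) {
  if (length(sets) && is.null(names(sets))) stop("sets must be named by term id")
  if (anyDuplicated(names(sets)))
    stop("duplicate term id: ", names(sets)[duplicated(names(sets))][1L])
  if (any(!lengths(sets)))
    stop("empty member list for term: ",
         names(sets)[which(!lengths(sets))[1L]])
  category <- rep_len(as.character(category), length(sets))
  ok <- category %in% c("BP", "CC", "MF", "KEGG")
  if (length(sets) && !all(ok))
    stop("unknown category: ", category[!ok][1L])
  if (is.null(name)) name <- names(sets)
  structure(list(sets = lapply(sets, as.character),
                 category = stats::setNames(category, names(sets)),
                 name = stats::setNames(rep_len(as.character(name),
                                                length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "terms")
  if (length(x$sets))
    cat(" (", paste(sprintf("%s: %d", names(table(x$category)),
                            table(x$category)), collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read / write gene sets in GMT format
#'
#' GMT is one term per line: term id, description, then member genes, all
#' tab-separated. The description field carries `category|display name` so
#' collections round-trip losslessly.
#'
#' @param path GMT file.
#' @return `read_gmt()`: a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], " in ", path,
         " (need term, description, >=1 gene)")
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  cat_name <- strsplit(desc, "|", fixed = TRUE)
  category <- vapply(cat_name, `[[`, "", 1L)
  name <- vapply(cat_name, function(p) if (length(p) > 1L) p[[2L]] else p[[1L]],
                 "")
  gene_set_collection(sets, category = category, name = name)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, paste0(collection$category[[id]], "|", collection$name[[id]]),
            collection$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical follow-up table
#'
#' @param path TSV with at least `sample`, `time` (days), `event` (0/1) and
#'   `expression`; any further columns are kept as covariates.
#' @return A data frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path)
  need_cols(cl, c("sample", "time", "event", "expression"), path)
  if (any(cl$time < 0)) stop("negative survival time in ", path)
  if (!all(cl$event %in% c(0L, 1L))) stop("event flag must be 0/1 in ", path)
  cl
}

#' Read a scored interaction table
#'
#' @param path TSV whose first two columns are source and target ids and
#'   whose remaining columns are numeric scores.
#' @param required_scores Score column names that must be present.
#' @return A data frame.
#' @export
read_interactions <- function(path, required_scores = character()) {
  tab <- utils::read.delim(path)
  need_cols(tab, required_scores, path)
  for (sc in setdiff(colnames(tab), colnames(tab)[1:2]))
    if (!is.numeric(tab[[sc]]))
      stop("score column '", sc, "' is not numeric in ", path)
  tab
}

#' Export a network as SIF plus attribute tables
#'
#' Writes `<prefix>.sif` (source, interaction type, target), a node
#' attribute TSV `<prefix>_nodes.tsv` and an edge attribute TSV
#' `<prefix>_edges.tsv`, loadable by standard network viewers.
#'
#' For coexpression networks the interaction type encodes the correlation
#' sign (`pos`/`neg`); for ceRNA networks it is `sponges` (lncRNA-miRNA) or
#' `targets` (miRNA-mRNA).
#'
#' @param network A [coexpression_network()], [assemble_cerna()] result, or
#'   a data frame with columns `source`, `interaction`, `target` (plus
#'   optional extra edge-attribute columns).
#' @param path_prefix Path prefix for the three output files.
#' @param node_attrs Optional data frame of node attributes (first column
#'   node id) merged into the node table.
#' @return `path_prefix`, invisibly.
#' @export
write_network_sif <- function(network, path_prefix, node_attrs = NULL) {
  UseMethod("write_network_sif")
}

#' @export
write_network_sif.data.frame <- function(network, path_prefix,
                                         node_attrs = NULL) {
  need_cols(network, c("source", "interaction", "target"), "network")
  sif <- paste(network$source, network$interaction, network$target, sep = "\t")
  writeLines(sif, paste0(path_prefix, ".sif"))
  nodes <- data.frame(id = unique(c(network$source, network$target)))
  if (!is.null(node_attrs))
    nodes <- merge(nodes, node_attrs, by.x = "id",
                   by.y = colnames(node_attrs)[1L], all.x = TRUE, sort = FALSE)
  utils::write.table(nodes, paste0(path_prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network, paste0(path_prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path_prefix)
}

#' @export
write_network_sif.coexpression_network <- function(network, path_prefix,
                                                   node_attrs = NULL) {
  edges <- data.frame(source = network$edges$lncRNA,
                      interaction = ifelse(network$edges$r >= 0, "pos", "neg"),
                      target = network$edges$mRNA,
                      r = network$edges$r)
  if (is.null(node_attrs)) {
    node_attrs <- network$nodes
  }
  write_network_sif.data.frame(edges, path_prefix, node_attrs)
}

#' @export
write_network_sif.cerna_network <- function(network, path_prefix,
                                            node_attrs = NULL) {
  tr <- network$triplets
  edges <- unique(rbind(
    data.frame(source = tr$lncRNA, interaction = "sponges", target = tr$miRNA),
    data.frame(source = tr$miRNA, interaction = "targets", target = tr$mRNA)))
  write_network_sif.data.frame(edges, path_prefix, node_attrs)
}

need_cols <- function(df, cols, where) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop("missing column(s) in ", where, ": ", paste(missing, collapse = ", "))
  invisible(df)
}
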