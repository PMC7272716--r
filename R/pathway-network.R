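# Tripartite lncRNA-mRNA-pathway network: hub partners linked to every
# pathway containing them (membership links), plus hypergeometric scoring
# of pathway association for a hub's partner set.

#' Assemble the lncRNA-mRNA-pathway network
#'
#' For each hub lncRNA, links every coexpressed partner mRNA to every
#' pathway (gene set) that contains it. Links carry the coexpression r of
#' the lncRNA-mRNA edge as provenance; partner mRNAs belonging to no
#' pathway contribute nothing.
#'
#' @param network A [coexpression_network()].
#' @param hubs Character vector of hub lncRNA ids (must be network nodes).
#' @param collection A [gene_set_collection()] of pathways.
#' @return Data frame with columns `lncRNA`, `mRNA`, `pathway`, `r`.
#' @export
build_pathway_network <- function(network, hubs, collection) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(collection, "gene_set_collection"))
  absent <- setdiff(hubs, network$edges$lncRNA)
  if (length(absent))
    stop("hub absent from network: ", paste(absent, collapse = ", "))
  # pathway memberships per gene
  membership <- stack_sets(collection)
  edges <- network$edges[network$edges$lncRNA %in% hubs, , drop = FALSE]
  hit <- merge(edges, membership, by.x = "mRNA", by.y = "gene")
  out <- data.frame(lncRNA = hit$lncRNA, mRNA = hit$mRNA,
                    pathway = hit$term, r = hit$r,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncRNA, out$mRNA, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

stack_sets <- function(collection) {
  data.frame(term = rep(names(collection$sets), lengths(collection$sets)),
             gene = unlist(collection$sets, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Pathway association significance for one hub's partner mRNAs
#'
#' Hypergeometric over-representation of each pathway in the hub's set of
#' coexpressed partner mRNAs, BH-adjusted; a pathway is called
#' significantly associated with the hub at `fdr < fdr_alpha` (default
#' 0.05).
#'
#' @param hub A hub lncRNA id with at least one network partner.
#' @param network A [coexpression_network()].
#' @param collection A [gene_set_collection()] of pathways.
#' @param universe Background gene ids (conventionally the whole array).
#' @param fdr_alpha FDR cutoff for the `significant` column.
#' @return An [enrich()]-style data frame with `significant` defined on
#'   the FDR.
#' @export
hub_pathway_significance <- function(hub, network, collection, universe,
                                     fdr_alpha = 0.05) {
  partners <- network$edges$mRNA[network$edges$lncRNA == hub]
  if (!length(partners)) stop("hub has no partners in the network: ", hub)
  res <- enrich(intersect(unique(partners), universe), collection, universe)
  res$significant <- res$fdr < fdr_alpha
  res
}

#' Export the tripartite pathway network as SIF
#'
#' Node classes (`lncRNA`, `mRNA`, `pathway`) go to the node-attribute
#' table; coexpression edges are typed by correlation sign and
#' mRNA-pathway links as `member_of`.
#'
#' @param links A [build_pathway_network()] result.
#' @param path_prefix Output path prefix.
#' @export
write_pathway_sif <- function(links, path_prefix) {
  lnc_mrna <- unique(data.frame(
    source = links$lncRNA,
    interaction = ifelse(links$r >= 0, "pos", "neg"),
    target = links$mRNA, stringsAsFactors = FALSE))
  mrna_path <- unique(data.frame(
    source = links$mRNA, interaction = "member_of",
    target = links$pathway, stringsAsFactors = FALSE))
  nodes <- rbind(
    data.frame(id = unique(links$lncRNA), class = "lncRNA"),
    data.frame(id = unique(links$mRNA), class = "mRNA"),
    data.frame(id = unique(links$pathway), class = "pathway"))
  write_network_sif(rbind(lnc_mrna, mrna_path), path_prefix,
                    node_attrs = nodes)
}
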