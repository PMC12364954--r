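#' Build a typed ceRNA network from triads
#'
#' Nodes are every RNA appearing in any triad (with its class); edges are
#' typed `mirna_target` (miRNA-ceRNA and miRNA-mRNA, carrying the Spearman
#' coefficient) or `cerna_pair` (ceRNA-mRNA, carrying the Pearson
#' coefficient and hypergeometric p-value). Edges are deduplicated by
#' unordered node pair + type, so an edge appearing in several triads
#' counts once for degree -- connectivity as a viewer of the drawn network
#' would read it. Degree is computed with igraph.
#'
#' @param triads data.frame from [assemble_triads()].
#' @return object of class `cerna_network`: list with data.frames `nodes`
#'   (`id`, `class`, `degree`) and `edges` (`source`, `interaction_type`,
#'   `target`, `scc`, `pcc`, `hypergeom_p`).
#' @export
build_network <- function(triads) {
  if (nrow(triads) == 0L) return(empty_network())
  e1 <- data.frame(source = triads$mirna_id, interaction_type = "mirna_target",
                   target = triads$cerna_id, scc = triads$scc_cerna_mirna,
                   pcc = NA_real_, hypergeom_p = NA_real_)
  e2 <- data.frame(source = triads$mirna_id, interaction_type = "mirna_target",
                   target = triads$mrna_id, scc = triads$scc_mirna_mrna,
                   pcc = NA_real_, hypergeom_p = NA_real_)
  e3 <- data.frame(source = triads$cerna_id, interaction_type = "cerna_pair",
                   target = triads$mrna_id, scc = NA_real_,
                   pcc = triads$pcc_pair, hypergeom_p = triads$pair_p_value)
  edges <- rbind(e1, e2, e3)
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target),
               edges$interaction_type, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  class_of <- c(stats::setNames(triads$cerna_class, triads$cerna_id),
                stats::setNames(rep("miRNA", nrow(triads)), triads$mirna_id),
                stats::setNames(rep("mRNA", nrow(triads)), triads$mrna_id))
  class_of <- class_of[!duplicated(names(class_of))]
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     directed = FALSE,
                                     vertices = names(class_of))
  nodes <- data.frame(id = names(class_of), class = unname(class_of),
                      degree = as.integer(igraph::degree(g)[names(class_of)]))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

empty_network <- function() {
  structure(list(
    nodes = data.frame(id = character(), class = character(),
                       degree = integer()),
    edges = data.frame(source = character(), interaction_type = character(),
                       target = character(), scc = numeric(), pcc = numeric(),
                       hypergeom_p = numeric())),
    class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) {
    cat("node classes:\n")
    print(table(x$nodes$class))
  }
  invisible(x)
}

#' Rank network nodes by connectivity
#'
#' Sorts nodes by degree, descending, ties broken lexicographically by id,
#' and returns the `top_k` hubs. When `top_k` exceeds the node count, all
#' nodes are returned with a note.
#'
#' @param network a `cerna_network`.
#' @param top_k number of hubs to return (default 10).
#' @return data.frame `id`, `class`, `degree`, ordered.
#' @export
rank_connectivity <- function(network, top_k = 10) {
  n <- network$nodes
  n <- n[order(-n$degree, n$id), , drop = FALSE]
  if (top_k > nrow(n)) {
    message("top_k (", top_k, ") exceeds node count (", nrow(n),
            "); returning all nodes")
    top_k <- nrow(n)
  }
  out <- utils::head(n, top_k)
  rownames(out) <- NULL
  out
}

#' Extract the ceRNA subnetwork around a gene set
#'
#' Returns the subnetwork induced by the listed mRNAs plus every node
#' adjacent to them (their miRNAs and ceRNA partners), with all edges among
#' those nodes; degrees are recomputed within the subnetwork. Gene ids not
#' present in the network are reported and skipped.
#'
#' @param network a `cerna_network`.
#' @param gene_set nonempty character vector of mRNA ids.
#' @return a `cerna_network`.
#' @export
extract_subnetwork <- function(network, gene_set) {
  stopifnot(length(gene_set) > 0L)
  absent <- setdiff(gene_set, network$nodes$id)
  if (length(absent))
    message("gene id(s) absent from network, skipped: ",
            paste(absent, collapse = ", "))
  seed <- intersect(gene_set, network$nodes$id)
  if (length(seed) == 0L) return(empty_network())
  e <- network$edges
  adj <- unique(c(e$target[e$source %in% seed], e$source[e$target %in% seed]))
  keep_nodes <- union(seed, adj)
  keep <- e$source %in% keep_nodes & e$target %in% keep_nodes
  sub_edges <- e[keep, , drop = FALSE]
  rownames(sub_edges) <- NULL
  nodes <- network$nodes[network$nodes$id %in% keep_nodes, , drop = FALSE]
  deg <- table(c(sub_edges$source, sub_edges$target))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = sub_edges), class = "cerna_network")
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes the edge list either as edge-TSV (columns `source`,
#' `interaction_type`, `target`, `scc`, `pcc`, `hypergeom_p`; empty cells
#' where a statistic does not apply) or as SIF (`source interaction_type
#' target`), plus a node-attribute TSV (`id`, `class`, `degree`) alongside
#' (same path with extension `.nodes.tsv`). Both dialects import directly
#' into Cytoscape.
#'
#' @param network a `cerna_network`.
#' @param path output path for the edge file.
#' @param dialect `"edge-tsv"` or `"sif"`.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, path, dialect = c("edge-tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (dialect == "edge-tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    lines <- paste(network$edges$source, network$edges$interaction_type,
                   network$edges$target, sep = "\t")
    writeLines(lines, path)
  }
  node_path <- paste0(sub("\\.(tsv|sif)$", "", path), ".nodes.tsv")
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, node_path))
}

#' Read an edge-TSV written by [write_network()]
#'
#' @param path edge-TSV path.
#' @return data.frame with the edge columns of a `cerna_network`.
#' @export
read_network_edges <- function(path) {
  d <- read_tsv_strict(path)
  for (col in c("scc", "pcc", "hypergeom_p"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  d
}
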