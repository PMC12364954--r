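#' Hypergeometric over-representation analysis
#'
#' Generic one-sided enrichment of a query gene list against user-supplied
#' gene-set annotations (GO terms, pathways, ...): for each term the
#' upper-tail hypergeometric probability of observing at least the seen
#' number of query hits, with `N` = background size, `K` = term size within
#' the background, `M` = query size, `s` = query hits. The same math core
#' as the shared-miRNA ceRNA-pair test ([hypergeom_upper_tail()]).
#' Benjamini-Hochberg FDRs are reported across terms; terms with raw
#' `p < alpha` are flagged enriched.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector of gene ids (e.g. all expressed
#'   features of the query's RNA class).
#' @param annotation data.frame with columns `term_id`, `term_name`,
#'   `gene_id` (one row per term membership; see [read_gene_sets()]).
#'   Members outside the background are ignored.
#' @param alpha enrichment threshold on the raw p-value (strict `<`).
#' @return data.frame with columns `term_id`, `term_name`, `k` (query
#'   hits), `K` (term size), `n` (query size), `N` (background size),
#'   `p_value`, `fdr`, `enriched`.
#' @export
over_representation <- function(query, background, annotation, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0L || length(background) == 0L)
    stop("query and background must be nonempty", call. = FALSE)
  if (!all(query %in% background))
    stop("query must be a subset of the background", call. = FALSE)
  need <- c("term_id", "term_name", "gene_id")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns term_id, term_name, gene_id",
         call. = FALSE)
  terms <- split(annotation, annotation$term_id)
  N <- length(background)
  n <- length(query)
  rows <- lapply(terms, function(d) {
    members <- intersect(unique(d$gene_id), background)
    K <- length(members)
    k <- length(intersect(members, query))
    data.frame(term_id = d$term_id[1L], term_name = d$term_name[1L],
               k = k, K = K, n = n, N = N,
               p_value = if (K == 0L) 1 else hypergeom_upper_tail(N, K, n, k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p_value)
  out$enriched <- out$p_value < alpha
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Read a gene-set annotation table
#'
#' TSV with columns `term_id`, `term_name`, `gene_id`, one row per term
#' membership.
#'
#' @param path annotation TSV path.
#' @return data.frame with those three columns.
#' @export
read_gene_sets <- function(path) {
  d <- read_tsv_strict(path)
  need <- c("term_id", "term_name", "gene_id")
  if (!all(need %in% names(d)))
    stop("annotation file '", path,
         "' must have columns term_id, term_name, gene_id", call. = FALSE)
  if (nrow(d) == 0L)
    stop("annotation file '", path, "' has no memberships", call. = FALSE)
  d[need]
}
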