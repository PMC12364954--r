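#' Upper-tail hypergeometric probability of a shared-miRNA overlap
#'
#' The significance test of the ceRNA hypothesis: with `N` miRNAs in the
#' universe, `K` of them targeting the ceRNA and `M` targeting the mRNA,
#' the probability of observing `s` or more shared miRNAs by chance is
#' `P(X >= s)` with `X ~ Hypergeometric(N, K, M)`. Computed in log space
#' (`lchoose` + log-sum-exp) for numerical stability; symmetric in
#' `(K, M)`.
#'
#' @param N universe size (>= 1).
#' @param K successes in the universe (miRNAs targeting the ceRNA).
#' @param M number drawn (miRNAs targeting the mRNA).
#' @param s observed overlap, `0 <= s <= min(K, M)`.
#' @return `P(X >= s)`, in (0, 1].
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_upper_tail <- function(N, K, M, s) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(M) == 1L,
            length(s) == 1L)
  if (N < 1 || K < 0 || M < 0 || s < 0 || K > N || M > N || s > min(K, M))
    stop("require N >= 1, 0 <= K,M <= N and 0 <= s <= min(K, M)",
         call. = FALSE)
  if (s == 0) return(1)
  i <- s:min(K, M)
  lw <- lchoose(K, i) + lchoose(N - K, M - i) - lchoose(N, M)
  m <- max(lw)
  exp(m + log(sum(exp(lw - m))))
}

#' Shared-miRNA hypergeometric test on candidate ceRNA pairs
#'
#' For each candidate pair the targeting relation is taken from the
#' retained (anticorrelation-passing) miRNA-target edges: `K` = miRNAs
#' targeting the ceRNA, `M` = miRNAs targeting the mRNA, `s` = their
#' overlap, all intersected with the supplied universe, whose size is `N`.
#' Pairs with upper-tail p below `alpha` (strict) pass. No multiple-testing
#' correction is applied to the pair p-values by default; the analysis
#' thresholds raw p at 0.05.
#'
#' The p-values depend on the universe, which must be passed explicitly --
#' typically all miRNAs present in the expression matrix (the pipeline
#' default), or only DE miRNAs, or only miRNAs with a retained edge (see
#' [mirna_universe()]). The choice is recorded in attribute `universe_size`.
#'
#' @param candidates data.frame from [candidate_cerna_pairs()]; only rows
#'   with `passes == TRUE` are tested.
#' @param edges evaluated edge table from [filter_mirna_targets()]; rows
#'   with `passes == TRUE` define the targeting relation.
#' @param universe character vector of miRNA ids defining the test
#'   universe.
#' @param alpha significance threshold on the raw p-value (strict `<`).
#' @return data.frame with columns `cerna_id`, `cerna_class`, `mrna_id`,
#'   `pcc`, `N`, `K`, `M`, `s`, `p_value`, `passes`.
#' @export
test_cerna_pairs <- function(candidates, edges, universe, alpha = 0.05) {
  if (length(universe) == 0L)
    stop("empty miRNA universe", call. = FALSE)
  universe <- unique(universe)
  re <- edges[edges$passes, , drop = FALSE]
  targeting <- lapply(split(re$mirna_id, re$target_id),
                      function(m) intersect(unique(m), universe))
  cand <- candidates[candidates$passes, , drop = FALSE]
  unknown <- setdiff(unique(c(cand$cerna_id, cand$mrna_id)), names(targeting))
  if (length(unknown))
    stop("candidate pair references id(s) with no retained edge: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  N <- length(universe)
  out <- cand[c("cerna_id", "cerna_class", "mrna_id", "pcc")]
  out$N <- N
  ksm <- vapply(seq_len(nrow(cand)), function(i) {
    mk <- targeting[[cand$cerna_id[i]]]
    mm <- targeting[[cand$mrna_id[i]]]
    c(length(mk), length(mm), length(intersect(mk, mm)))
  }, numeric(3))
  if (nrow(cand)) {
    out$K <- ksm[1L, ]
    out$M <- ksm[2L, ]
    out$s <- ksm[3L, ]
    out$p_value <- vapply(seq_len(nrow(out)), function(i)
      hypergeom_upper_tail(N, out$K[i], out$M[i], out$s[i]), numeric(1))
  } else {
    out$K <- out$M <- out$s <- out$p_value <- numeric(0)
  }
  out$passes <- out$p_value < alpha
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  out
}

#' miRNA universes for the shared-miRNA test
#'
#' Returns the miRNA id set implied by a universe policy: `"expressed"` --
#' all miRNA features in the expression matrix (default policy of the
#' pipeline, so that a pair sharing its sole miRNA can reach significance
#' in a sparse network); `"de"` -- all differentially expressed miRNAs;
#' `"retained"` -- miRNAs with at least one retained target edge (the most
#' conservative option).
#'
#' @param policy one of `"expressed"`, `"de"`, `"retained"`.
#' @param se expression matrix (needed for `"expressed"`).
#' @param de DE table (needed for `"de"`).
#' @param edges evaluated edge table (needed for `"retained"`).
#' @return character vector of miRNA ids.
#' @export
mirna_universe <- function(policy = c("expressed", "de", "retained"),
                           se = NULL, de = NULL, edges = NULL) {
  policy <- match.arg(policy)
  switch(policy,
    expressed = {
      stopifnot(!is.null(se))
      rownames(se)[feature_classes(se) == "miRNA"]
    },
    de = {
      stopifnot(!is.null(de))
      de$feature_id[de$is_de & de$feature_class == "miRNA"]
    },
    retained = {
      stopifnot(!is.null(edges))
      unique(edges$mirna_id[edges$passes])
    })
}

#' Expand significant ceRNA pairs into (ceRNA, miRNA, mRNA) triads
#'
#' One triad per (passing pair, shared miRNA) combination, carrying the two
#' Spearman edge coefficients, the pair's Pearson coefficient and its
#' hypergeometric p-value.
#'
#' @param tests output of [test_cerna_pairs()]; only passing rows are
#'   expanded.
#' @param edges evaluated edge table from [filter_mirna_targets()].
#' @return data.frame with columns `cerna_id`, `cerna_class`, `mirna_id`,
#'   `mrna_id`, `scc_cerna_mirna`, `scc_mirna_mrna`, `pcc_pair`,
#'   `pair_p_value`.
#' @export
assemble_triads <- function(tests, edges) {
  re <- edges[edges$passes, , drop = FALSE]
  key <- paste(re$mirna_id, re$target_id, sep = "\r")
  scc_of <- stats::setNames(re$scc, key)
  mir_of <- split(re$mirna_id, re$target_id)
  keep <- tests[tests$passes, , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    shared <- intersect(mir_of[[keep$cerna_id[i]]], mir_of[[keep$mrna_id[i]]])
    if (length(shared) == 0L) return(NULL)
    data.frame(cerna_id = keep$cerna_id[i], cerna_class = keep$cerna_class[i],
               mirna_id = shared, mrna_id = keep$mrna_id[i],
               scc_cerna_mirna = unname(scc_of[paste(shared, keep$cerna_id[i],
                                                     sep = "\r")]),
               scc_mirna_mrna = unname(scc_of[paste(shared, keep$mrna_id[i],
                                                    sep = "\r")]),
               pcc_pair = keep$pcc[i], pair_p_value = keep$p_value[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cerna_id = character(), cerna_class = character(),
                      mirna_id = character(), mrna_id = character(),
                      scc_cerna_mirna = numeric(), scc_mirna_mrna = numeric(),
                      pcc_pair = numeric(), pair_p_value = numeric())
  rownames(out) <- NULL
  out
}

#' Write a triad table
#' @param triads data.frame from [assemble_triads()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_triad_table <- function(triads, path) {
  utils::write.table(triads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
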