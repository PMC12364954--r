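#' Spearman and Pearson correlation with degenerate-input handling
#'
#' Thin wrappers around [stats::cor] that enforce the preconditions the
#' edge filters rely on: equal length, at least 3 paired observations, and
#' non-constant vectors. Spearman is computed as the Pearson correlation of
#' mid-ranks (average ranks on ties), which is exact in the presence of
#' ties. A constant vector makes the correlation undefined; both functions
#' then signal an error of class `"cernet_degenerate_correlation"` so
#' callers can drop the pair and log it.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite values.
#' @return correlation coefficient in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_cor
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("correlation needs at least 3 paired samples", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("correlation inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop(errorCondition("correlation undefined for a constant vector",
                        class = c("cernet_degenerate_correlation", "error")))
  invisible(TRUE)
}

#' Filter predicted miRNA-target pairs by expression anticorrelation
#'
#' For every predicted (miRNA, target) pair whose members are both flagged
#' differentially expressed (the network is built from DE RNAs; set
#' `de_only = FALSE` to use all features), the Spearman rank correlation of
#' raw abundances is computed across all samples (both groups pooled). A
#' pair passes when `scc < scc_cutoff` (strict; default -0.7). Pairs whose
#' correlation is undefined (constant vector) are dropped and counted, as
#' are pairs referencing ids absent from the matrix.
#'
#' @param se a validated expression `SummarizedExperiment`.
#' @param targets miRNA-target data.frame (see [read_target_table()]).
#' @param de differential-expression table from [call_de()]; required unless
#'   `de_only = FALSE`.
#' @param scc_cutoff retention threshold on the Spearman coefficient
#'   (strict `<`).
#' @param de_only restrict to pairs where both members are DE (default).
#' @return data.frame of evaluated edges with columns `mirna_id`,
#'   `target_id`, `target_class`, `scc`, `passes`; attributes
#'   `n_unresolved`, `n_not_de`, `n_degenerate` count skipped pairs.
#' @export
filter_mirna_targets <- function(se, targets, de = NULL, scc_cutoff = -0.7,
                                 de_only = TRUE) {
  v <- SummarizedExperiment::assay(se, "abundance")
  resolvable <- targets$mirna_id %in% rownames(v) &
    targets$target_id %in% rownames(v)
  n_unresolved <- sum(!resolvable)
  if (n_unresolved > 0L)
    message("skipping ", n_unresolved,
            " predicted pair(s) with unresolvable ids")
  tt <- targets[resolvable, , drop = FALSE]
  if (de_only) {
    if (is.null(de))
      stop("`de` table required when de_only = TRUE", call. = FALSE)
    de_ids <- de$feature_id[de$is_de]
    keep <- tt$mirna_id %in% de_ids & tt$target_id %in% de_ids
    n_not_de <- sum(!keep)
    tt <- tt[keep, , drop = FALSE]
  } else n_not_de <- 0L
  scc <- rep(NA_real_, nrow(tt))
  for (i in seq_len(nrow(tt))) {
    scc[i] <- tryCatch(spearman_cor(v[tt$mirna_id[i], ], v[tt$target_id[i], ]),
                       cernet_degenerate_correlation = function(e) NA_real_)
  }
  n_degenerate <- sum(is.na(scc))
  if (n_degenerate > 0L)
    message("dropped ", n_degenerate,
            " pair(s) with undefined correlation (constant vector)")
  out <- data.frame(mirna_id = tt$mirna_id, target_id = tt$target_id,
                    target_class = tt$target_class, scc = scc,
                    row.names = NULL)[!is.na(scc), , drop = FALSE]
  out$passes <- out$scc < scc_cutoff
  attr(out, "n_unresolved") <- n_unresolved
  attr(out, "n_not_de") <- n_not_de
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Candidate ceRNA pairs by shared miRNAs and Pearson co-expression
#'
#' Enumerates every (lncRNA-or-circRNA, mRNA) pair that shares at least one
#' retained miRNA edge, computes the Pearson correlation of log2
#' pseudocounted abundances across all samples, and flags pairs with
#' `pcc > pcc_cutoff` (strict; default 0.9) as candidates.
#'
#' @inheritParams filter_mirna_targets
#' @param edges evaluated edge table from [filter_mirna_targets()]; only
#'   rows with `passes == TRUE` define the sharing relation.
#' @param pcc_cutoff retention threshold on the Pearson coefficient
#'   (strict `>`).
#' @param pseudocount offset for the log2 transform.
#' @return data.frame with columns `cerna_id`, `cerna_class`, `mrna_id`,
#'   `pcc`, `passes`.
#' @export
candidate_cerna_pairs <- function(se, edges, pcc_cutoff = 0.9,
                                  pseudocount = 0.01) {
  re <- edges[edges$passes, , drop = FALSE]
  lv <- log2_abundance(se, pseudocount)
  pairs <- unique(do.call(rbind, lapply(split(re, re$mirna_id), function(d) {
    ce <- d[d$target_class != "mRNA", c("target_id", "target_class")]
    mr <- d$target_id[d$target_class == "mRNA"]
    if (nrow(ce) == 0L || length(mr) == 0L) return(NULL)
    expand <- expand.grid(i = seq_len(nrow(ce)), mrna_id = mr,
                          stringsAsFactors = FALSE)
    data.frame(cerna_id = ce$target_id[expand$i],
               cerna_class = ce$target_class[expand$i],
               mrna_id = expand$mrna_id)
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(cerna_id = character(), cerna_class = character(),
                      mrna_id = character(), pcc = numeric(),
                      passes = logical()))
  rownames(pairs) <- NULL
  pairs$pcc <- vapply(seq_len(nrow(pairs)), function(i)
    tryCatch(pearson_cor(lv[pairs$cerna_id[i], ], lv[pairs$mrna_id[i], ]),
             cernet_degenerate_correlation = function(e) NA_real_),
    numeric(1))
  pairs <- pairs[!is.na(pairs$pcc), , drop = FALSE]
  pairs$passes <- pairs$pcc > pcc_cutoff
  pairs
}

#' Cis target assignment: protein-coding genes near a lncRNA locus
#'
#' A protein-coding gene is a cis target of a lncRNA when the gap between
#' the two gene bodies (closest interval edges, strand-agnostic; 0 for
#' overlapping or adjacent intervals) on the same chromosome is at most
#' `window_bp` (non-strict, default 10 kb).
#'
#' @param lnc_intervals `GRanges` of lncRNA loci (see [read_intervals()]).
#' @param gene_intervals `GRanges` of genes; only `biotype ==
#'   "protein_coding"` records are considered.
#' @param window_bp maximum gap in base pairs (inclusive).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `distance_bp`.
#' @export
cis_targets <- function(lnc_intervals, gene_intervals, window_bp = 10000) {
  genes <- gene_intervals[gene_intervals$biotype == "protein_coding"]
  if (length(lnc_intervals) == 0L || length(genes) == 0L)
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance_bp = integer()))
  grid <- expand.grid(i = seq_along(lnc_intervals), j = seq_along(genes))
  d <- suppressWarnings(GenomicRanges::distance(
    lnc_intervals[grid$i], genes[grid$j], ignore.strand = TRUE))
  keep <- !is.na(d) & d <= window_bp
  out <- data.frame(lncrna_id = lnc_intervals$feature_id[grid$i[keep]],
                    gene_id = genes$feature_id[grid$j[keep]],
                    distance_bp = as.integer(d[keep]))
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Trans target assignment: genome-wide co-expression partners
#'
#' All (lncRNA, gene) pairs whose Pearson correlation of log2 pseudocounted
#' abundances satisfies `|r| >= threshold` (non-strict, default 0.95).
#'
#' @inheritParams candidate_cerna_pairs
#' @param lnc_ids,gene_ids feature ids resolvable in `se`.
#' @param threshold minimum absolute Pearson correlation (inclusive).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `pearson_r`.
#' @export
trans_targets <- function(se, lnc_ids, gene_ids, threshold = 0.95,
                          pseudocount = 0.01) {
  missing <- setdiff(c(lnc_ids, gene_ids), rownames(se))
  if (length(missing)) {
    message("skipping unresolvable id(s): ",
            paste(utils::head(missing, 5L), collapse = ", "))
    lnc_ids <- intersect(lnc_ids, rownames(se))
    gene_ids <- intersect(gene_ids, rownames(se))
  }
  lv <- log2_abundance(se, pseudocount)
  grid <- expand.grid(lncrna_id = lnc_ids, gene_id = gene_ids,
                      stringsAsFactors = FALSE)
  grid$pearson_r <- vapply(seq_len(nrow(grid)), function(i)
    tryCatch(pearson_cor(lv[grid$lncrna_id[i], ], lv[grid$gene_id[i], ]),
             cernet_degenerate_correlation = function(e) NA_real_),
    numeric(1))
  grid <- grid[!is.na(grid$pearson_r) & abs(grid$pearson_r) >= threshold, ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid
}
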