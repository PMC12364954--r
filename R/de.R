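#' Log2 fold change between the two sample groups
#'
#' Fold change is computed on pseudocounted group means,
#' `log2((mean_B + c) / (mean_A + c))`, with group B the second factor level
#' of the design. The pseudocount bounds fold changes of features touching
#' zero abundance.
#'
#' @param se a validated expression `SummarizedExperiment`.
#' @param feature feature id(s); default all features.
#' @param pseudocount positive offset added to both group means
#'   (default 0.01, on the FPKM/TPM scale).
#' @return named numeric vector of log2 fold changes (B over A).
#' @export
log2_fold_change <- function(se, feature = rownames(se), pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  missing <- setdiff(feature, rownames(se))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- SummarizedExperiment::assay(se, "abundance")[feature, , drop = FALSE]
  grp <- sample_groups(se)
  a <- rowMeans(v[, grp == levels(grp)[1L], drop = FALSE])
  b <- rowMeans(v[, grp == levels(grp)[2L], drop = FALSE])
  log2((b + pseudocount) / (a + pseudocount))
}

#' Welch two-sample test on log2 abundances
#'
#' The surrogate differential-expression test used throughout the pipeline:
#' Welch's unequal-variance t-test on `log2(x + pseudocount)`, two-sided.
#' When both groups have (numerically) zero variance the test statistic is
#' undefined; the p-value is then 1 if the group means are equal and 0
#' otherwise.
#'
#' @inheritParams log2_fold_change
#' @param feature a single feature id.
#' @return two-sided p-value in \[0, 1\].
#' @export
two_group_test <- function(se, feature, pseudocount = 0.01) {
  if (!feature %in% rownames(se))
    stop("unknown feature: ", feature, call. = FALSE)
  grp <- sample_groups(se)
  if (any(table(grp) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  x <- SummarizedExperiment::assay(se, "abundance")[feature, ]
  welch_log2_p(x[grp == levels(grp)[1L]], x[grp == levels(grp)[2L]],
               pseudocount)
}

welch_log2_p <- function(a, b, pseudocount = 0.01) {
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  if (stats::var(la) + stats::var(lb) < 1e-20)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  stats::t.test(la, lb, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment (via [stats::p.adjust]), returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed features
#'
#' Computes per-feature log2 fold change and the Welch surrogate p-value,
#' then applies the class-specific decision rules: BH adjustment is done
#' within each RNA class separately; long RNAs (mRNA/lncRNA/circRNA) are
#' differentially expressed when `|log2FC| >= log2(fc_min)` and
#' `FDR < fdr_alpha`, miRNAs when `|log2FC| >= log2(fc_min)` and raw
#' `p < mirna_p_alpha`. Defaults are fold change >= 2, FDR < 0.05 (long
#' RNAs) and p < 0.05 (miRNAs). A summary of up/down counts per class is
#' attached as attribute `"summary"`.
#'
#' @inheritParams log2_fold_change
#' @param fc_min minimum fold change (linear scale, default 2).
#' @param fdr_alpha FDR threshold for long RNAs (strict `<`).
#' @param mirna_p_alpha raw p-value threshold for miRNAs (strict `<`).
#' @return data.frame with one row per feature: `feature_id`,
#'   `feature_class`, `mean_groupA`, `mean_groupB`, `log2fc`, `p_value`,
#'   `fdr`, `direction` (`up`/`down`/`none`), `is_de`.
#' @export
call_de <- function(se, fc_min = 2, fdr_alpha = 0.05, mirna_p_alpha = 0.05,
                    pseudocount = 0.01) {
  validate_expression_matrix(se)
  grp <- sample_groups(se)
  v <- SummarizedExperiment::assay(se, "abundance")
  ia <- grp == levels(grp)[1L]
  ib <- grp == levels(grp)[2L]
  stats_df <- data.frame(
    feature_id = rownames(se),
    feature_class = feature_classes(se),
    mean_groupA = rowMeans(v[, ia, drop = FALSE]),
    mean_groupB = rowMeans(v[, ib, drop = FALSE]),
    log2fc = unname(log2_fold_change(se, pseudocount = pseudocount)),
    p_value = vapply(seq_len(nrow(v)), function(i)
      welch_log2_p(v[i, ia], v[i, ib], pseudocount), numeric(1)),
    row.names = NULL)
  out <- apply_de_rules(stats_df, fc_min = fc_min, fdr_alpha = fdr_alpha,
                        mirna_p_alpha = mirna_p_alpha)
  smry <- de_summary(out)
  message(paste(utils::capture.output(print(smry)), collapse = "\n"))
  attr(out, "summary") <- smry
  attr(out, "test") <- "welch_log2_surrogate"
  out
}

#' Apply the class-specific differential-expression decision rules
#'
#' Exposed separately from [call_de()] so the thresholding logic (which
#' statistic gates which RNA class, and the strictness of each inequality)
#' can be exercised on arbitrary statistics.
#'
#' @param stats_df data.frame with columns `feature_id`, `feature_class`,
#'   `log2fc`, `p_value` (and optionally the group means).
#' @inheritParams call_de
#' @return `stats_df` with added columns `fdr`, `direction`, `is_de`.
#' @export
apply_de_rules <- function(stats_df, fc_min = 2, fdr_alpha = 0.05,
                           mirna_p_alpha = 0.05) {
  stopifnot(fc_min >= 1)
  lfc_min <- log2(fc_min)
  fdr <- rep(NA_real_, nrow(stats_df))
  for (cl in unique(stats_df$feature_class)) {
    i <- stats_df$feature_class == cl
    fdr[i] <- bh_adjust(stats_df$p_value[i])
  }
  stats_df$fdr <- fdr
  pass_fc <- abs(stats_df$log2fc) >= lfc_min
  is_mir <- stats_df$feature_class == "miRNA"
  stats_df$is_de <- pass_fc &
    ifelse(is_mir, stats_df$p_value < mirna_p_alpha, stats_df$fdr < fdr_alpha)
  stats_df$direction <- ifelse(!stats_df$is_de, "none",
                               ifelse(stats_df$log2fc > 0, "up", "down"))
  stats_df
}

de_summary <- function(de) {
  cls <- intersect(RNA_CLASSES, unique(de$feature_class))
  do.call(rbind, lapply(cls, function(cl) {
    d <- de[de$feature_class == cl, ]
    data.frame(feature_class = cl,
               up = sum(d$direction == "up"),
               down = sum(d$direction == "down"),
               total_de = sum(d$is_de),
               n = nrow(d))
  }))
}

#' Write a differential-expression table
#' @param de data.frame from [call_de()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
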