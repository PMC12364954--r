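#' Assemble a validated multi-class expression matrix
#'
#' Builds the container every downstream computation operates on: a
#' [SummarizedExperiment::SummarizedExperiment] holding one non-negative
#' abundance assay (`"abundance"`), a per-feature RNA class
#' (`mRNA`/`lncRNA`/`circRNA`/`miRNA`) with its abundance unit (TPM for
#' miRNA, FPKM otherwise), and a per-sample two-level group factor
#' (e.g. small vs large yellow follicles).
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must be named with unique identifiers. All values must be
#'   finite and >= 0.
#' @param feature_class character vector of RNA classes, one per row of
#'   `values` (optionally named by feature id).
#' @param group character/factor vector of group labels, one per column of
#'   `values`; exactly two groups, each with at least two samples. The first
#'   factor level is the reference ("group A"); fold changes are B over A.
#' @return a `SummarizedExperiment` with rowData columns `feature_class`,
#'   `unit` and colData column `group`.
#' @examples
#' m <- matrix(rpois(24, 50), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
#' se <- expression_matrix(m, rep(c("mRNA", "miRNA"), each = 2),
#'                         rep(c("SYF", "LYF"), each = 3))
#' @export
expression_matrix <- function(values, feature_class, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) names",
         call. = FALSE)
  feature_class <- as.character(feature_class)
  if (length(feature_class) != nrow(values))
    stop("`feature_class` must have one entry per feature", call. = FALSE)
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  group <- droplevels(group)
  if (length(group) != ncol(values))
    stop("`group` must have one entry per sample", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    rowData = S4Vectors::DataFrame(
      feature_class = feature_class,
      unit = ifelse(feature_class == "miRNA", "TPM", "FPKM"),
      row.names = rownames(values)),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(values)))
  validate_expression_matrix(se)
  se
}

RNA_CLASSES <- c("mRNA", "lncRNA", "circRNA", "miRNA")

#' Validate the invariants of an expression matrix
#'
#' Checks that values are finite and non-negative, feature and sample ids are
#' unique, every feature class is one of mRNA/lncRNA/circRNA/miRNA, units
#' match classes, and that there are exactly two groups with >= 2 samples
#' each. Stops with an informative error on the first violation.
#'
#' @param se a `SummarizedExperiment` as built by [expression_matrix()].
#' @return `se`, invisibly.
#' @export
validate_expression_matrix <- function(se) {
  v <- SummarizedExperiment::assay(se, "abundance")
  if (anyNA(v) || any(!is.finite(v)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(v)[bad[1L]], colnames(v)[bad[2L]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(se)))
    stop("duplicated feature id(s): ",
         paste(unique(rownames(se)[duplicated(rownames(se))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(se)))
    stop("duplicated sample id(s): ",
         paste(unique(colnames(se)[duplicated(colnames(se))]), collapse = ", "),
         call. = FALSE)
  cls <- feature_classes(se)
  if (!all(cls %in% RNA_CLASSES))
    stop("unknown feature class(es): ",
         paste(unique(setdiff(cls, RNA_CLASSES)), collapse = ", "),
         call. = FALSE)
  unit <- SummarizedExperiment::rowData(se)$unit
  if (!all(unit == ifelse(cls == "miRNA", "TPM", "FPKM")))
    stop("unit must be TPM for miRNA features and FPKM otherwise",
         call. = FALSE)
  grp <- sample_groups(se)
  if (nlevels(grp) != 2L)
    stop("design must have exactly two sample groups, got ",
         nlevels(grp), call. = FALSE)
  if (any(table(grp) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  invisible(se)
}

#' @rdname expression_matrix
#' @param se a validated expression `SummarizedExperiment`.
#' @export
feature_classes <- function(se)
  as.character(SummarizedExperiment::rowData(se)$feature_class)

#' @rdname expression_matrix
#' @export
sample_groups <- function(se) SummarizedExperiment::colData(se)$group

# log2-transformed abundances; pseudocount keeps zero-expression features
# bounded
log2_abundance <- function(se, pseudocount = 0.01)
  log2(SummarizedExperiment::assay(se, "abundance") + pseudocount)
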