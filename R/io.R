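#' Read an expression matrix and its design file
#'
#' The expression TSV has a header row of sample ids and a first column of
#' feature ids. The design TSV assigns roles to those ids with three columns
#' `id`, `kind`, `value`: rows with `kind = "sample"` map sample id to group
#' label, rows with `kind = "feature"` map feature id to RNA class. Lines
#' starting with `#` are ignored in both files. Load errors name the file
#' and the offending id or cell.
#'
#' @param path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return a validated `SummarizedExperiment` (see [expression_matrix()]);
#'   row order of the TSV is preserved.
#' @export
read_expression <- function(path, design_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2L)
    stop("expression file '", path, "' needs a feature id column plus ",
         "at least one sample column", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    tok <- if (length(bad)) tab[bad[1L, 1L], bad[1L, 2L] + 1L] else "?"
    stop("non-numeric expression value in '", path, "' (feature '",
         ids[bad[1L, 1L]], "', token '", tok, "')", call. = FALSE)
  }
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value in '", path, "' at feature '",
         ids[bad[1L]], "', sample '", colnames(vals)[bad[2L]], "'",
         call. = FALSE)
  }
  rownames(vals) <- ids
  design <- read_design(design_path)
  cls <- design$feature_class[ids]
  if (anyNA(cls))
    stop("design file '", design_path, "' lacks a class for feature(s): ",
         paste(utils::head(ids[is.na(cls)], 5L), collapse = ", "),
         call. = FALSE)
  grp <- design$group[colnames(vals)]
  if (anyNA(grp))
    stop("design file '", design_path, "' lacks a group for sample(s): ",
         paste(colnames(vals)[is.na(grp)], collapse = ", "), call. = FALSE)
  expression_matrix(vals, unname(cls), unname(grp))
}

read_design <- function(path) {
  d <- read_tsv_strict(path)
  need <- c("id", "kind", "value")
  if (!all(need %in% names(d)))
    stop("design file '", path, "' must have columns id, kind, value",
         call. = FALSE)
  if (!all(d$kind %in% c("sample", "feature")))
    stop("design file '", path, "' has unknown kind(s): ",
         paste(unique(setdiff(d$kind, c("sample", "feature"))),
               collapse = ", "), call. = FALSE)
  smp <- d[d$kind == "sample", ]
  ftr <- d[d$kind == "feature", ]
  list(group = stats::setNames(smp$value, smp$id),
       feature_class = stats::setNames(ftr$value, ftr$id))
}

#' Write an expression matrix and design file
#'
#' Inverse of [read_expression()]; values are written at full precision
#' (17 significant digits) so write/read round-trips are exact.
#'
#' @param se a validated expression `SummarizedExperiment`.
#' @param path expression TSV output path.
#' @param design_path design TSV output path.
#' @return invisibly, `c(path, design_path)`.
#' @export
write_expression <- function(se, path, design_path) {
  v <- SummarizedExperiment::assay(se, "abundance")
  tab <- data.frame(feature_id = rownames(v),
                    format(v, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- rbind(
    data.frame(id = colnames(se), kind = "sample",
               value = as.character(sample_groups(se))),
    data.frame(id = rownames(se), kind = "feature",
               value = feature_classes(se)))
  utils::write.table(des, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, design_path))
}

#' Read a predicted miRNA-target table
#'
#' Expects columns `mirna_id`, `target_id`, `target_class` and optionally
#' `sites` (positive integer count of predicted binding sites). Duplicate
#' (miRNA, target) pairs -- which upstream predictors legitimately emit, one
#' row per site -- are collapsed into a single record with summed site
#' counts; the number of collapsed rows is reported as a message and stored
#' in attribute `n_collapsed`.
#'
#' @param path path to the target TSV.
#' @return data.frame with columns `mirna_id`, `target_id`, `target_class`,
#'   `site_count` (NA when the input has no `sites` column).
#' @export
read_target_table <- function(path) {
  d <- read_tsv_strict(path)
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(d)))
    stop("target table '", path,
         "' must have columns mirna_id, target_id, target_class",
         call. = FALSE)
  if (nrow(d) == 0L) {
    warning("target table '", path, "' is empty", call. = FALSE)
    out <- data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), site_count = integer())
    attr(out, "n_collapsed") <- 0L
    return(out)
  }
  if (any(d$target_class == "miRNA"))
    stop("target table '", path, "' contains target_class 'miRNA' ",
         "(miRNA-miRNA edges are unsupported), e.g. target '",
         d$target_id[d$target_class == "miRNA"][1L], "'", call. = FALSE)
  bad <- setdiff(unique(d$target_class), setdiff(RNA_CLASSES, "miRNA"))
  if (length(bad))
    stop("target table '", path, "' has unknown target_class: ",
         paste(bad, collapse = ", "), call. = FALSE)
  has_sites <- "sites" %in% names(d)
  sites <- if (has_sites) as.numeric(d$sites) else rep(1, nrow(d))
  key <- paste(d$mirna_id, d$target_id, sep = "\r")
  agg <- rowsum(sites, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(mirna_id = d$mirna_id[first],
                    target_id = d$target_id[first],
                    target_class = d$target_class[first],
                    site_count = if (has_sites) as.integer(agg[, 1L])
                                 else NA_integer_)
  n_collapsed <- nrow(d) - nrow(out)
  if (n_collapsed > 0L)
    message("collapsed ", n_collapsed, " duplicate miRNA-target row(s)")
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' Write a miRNA-target table
#' @param targets data.frame as returned by [read_target_table()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_target_table <- function(targets, path) {
  out <- targets[c("mirna_id", "target_id", "target_class")]
  if (!all(is.na(targets$site_count))) out$sites <- targets$site_count
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# strict TSV reader shared by all text inputs: tab-separated, UTF-8,
# '#' comment lines skipped, ragged rows rejected
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fill = FALSE, blank.lines.skip = TRUE),
    error = function(e)
      stop("failed to parse '", path, "': ", conditionMessage(e),
           call. = FALSE))
}
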