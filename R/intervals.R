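#' Read gene intervals from GTF or BED
#'
#' Returns a [GenomicRanges::GRanges] (1-based closed coordinates, the R
#' ecosystem convention) with metadata columns `feature_id` and `biotype`
#' (`protein_coding`, `lncRNA` or `other`). GTF input is parsed with
#' rtracklayer (1-based inclusive, gene records keyed by the `gene_id`
#' attribute, biotype from `gene_biotype` when present); BED input (0-based
#' half-open) is converted by rtracklayer on import, so the usual GTF/BED
#' off-by-one relation holds between the two dialects.
#'
#' @param path path to a GTF or BED file.
#' @param dialect `"gtf"` or `"bed"`.
#' @return a `GRanges` with unique `feature_id`s.
#' @export
read_intervals <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (dialect == "gtf") {
    check_gtf_coords(path)
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene", na.rm = TRUE))
      gr <- gr[gr$type == "gene"]
    if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
      stop("GTF '", path, "' has no gene_id attribute", call. = FALSE)
    fid <- gr$gene_id
    bt <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr)))
      gr$gene_biotype else rep("other", length(gr))
    bt[is.na(bt) | !(bt %in% c("protein_coding", "lncRNA"))] <- "other"
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    fid <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    bt <- rep("other", length(gr))
  }
  if (anyDuplicated(fid))
    stop("duplicated feature id(s) in '", path, "': ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$feature_id <- fid
  S4Vectors::mcols(out)$biotype <- bt
  names(out) <- fid
  out
}

# reject start > end with a line number before handing the file to
# rtracklayer, whose GRanges constructor reports widths, not lines
check_gtf_coords <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 9L)
      stop("GTF '", path, "' line ", lineno[i], ": expected 9 fields, got ",
           length(f), call. = FALSE)
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e) || s > e)
      stop("GTF '", path, "' line ", lineno[i],
           ": invalid coordinates (start=", f[4L], ", end=", f[5L], ")",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write gene intervals as GTF or BED
#'
#' GTF output carries one `gene` record per interval with `gene_id` and
#' `gene_biotype` attributes; BED output is written by rtracklayer (and so
#' is 0-based half-open on disk).
#'
#' @param gr a `GRanges` as returned by [read_intervals()].
#' @param path output path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return invisibly, `path`.
#' @export
write_intervals <- function(gr, path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    lines <- sprintf(
      '%s\tcernet\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
      as.character(GenomicRanges::seqnames(gr)),
      GenomicRanges::start(gr), GenomicRanges::end(gr), strand,
      gr$feature_id, gr$biotype)
    writeLines(lines, path)
  } else {
    out <- gr
    names(out) <- NULL
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = gr$feature_id)
    rtracklayer::export(out, path, format = "bed")
  }
  invisible(path)
}
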