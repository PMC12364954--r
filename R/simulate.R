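#' Configuration for the planted-structure simulator
#'
#' Defines a two-group, replicated expression study with known ground
#' truth: planted ceRNA triads (a lncRNA or circRNA and an mRNA coupled
#' positively to a shared latent signal, their shared miRNA coupled
#' negatively), planted differentially expressed features, and independent
#' log-normal background features. Defaults describe the canonical design
#' this pipeline targets: two conditions with three biological replicates
#' each and FPKM/TPM-scale abundances.
#'
#' @param n_background named integer vector: background feature counts per
#'   class (`mRNA`, `lncRNA`, `circRNA`, `miRNA`).
#' @param n_planted_triads number of planted (ceRNA, miRNA, mRNA) triads;
#'   ceRNA classes alternate lncRNA/circRNA.
#' @param n_planted_de named integer vector: planted DE features per class
#'   (directions alternate up/down).
#' @param n_samples_per_group replicates per group (default 3).
#' @param planted_log2fc group-mean log2 shift of planted DE features and
#'   latent-coupling slope of triads (default 1.5).
#' @param latent_sd sd of the within-sample latent signal of a triad on top
#'   of its group shift (default 0.1); this is what makes planted
#'   correlations imperfect under noise rather than copies of one vector.
#'   Kept a modest fraction of the group effect so that the coupling noise
#'   it induces does not overwhelm the n = 3 per group design.
#' @param noise_sd sd of additive log2-scale (i.e. multiplicative raw-scale)
#'   measurement noise, >= 0 (default 0.1).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-feature
#'   baseline log2 abundance (defaults 4 and 1.5, a realistic FPKM spread).
#' @param decoy_target_fraction controls how many decoy prediction rows
#'   (miRNA -> background feature) pad the target table: decoy rows =
#'   `round(f * (2 * n_planted_triads + n_background_miRNA))`.
#' @param seed integer seed; all randomness flows from one generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_background = c(mRNA = 24L, lncRNA = 8L,
                                        circRNA = 4L, miRNA = 24L),
                       n_planted_triads = 5L,
                       n_planted_de = c(mRNA = 3L, lncRNA = 3L,
                                        circRNA = 3L, miRNA = 3L),
                       n_samples_per_group = 3L,
                       planted_log2fc = 1.5,
                       latent_sd = 0.1,
                       noise_sd = 0.1,
                       baseline_log2_mean = 4,
                       baseline_log2_sd = 1.5,
                       decoy_target_fraction = 0.6,
                       seed = 1L) {
  cfg <- list(n_background = n_background[RNA_CLASSES],
              n_planted_triads = as.integer(n_planted_triads),
              n_planted_de = n_planted_de[RNA_CLASSES],
              n_samples_per_group = as.integer(n_samples_per_group),
              planted_log2fc = planted_log2fc, latent_sd = latent_sd,
              noise_sd = noise_sd, baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              decoy_target_fraction = decoy_target_fraction,
              seed = as.integer(seed))
  names(cfg$n_background) <- names(cfg$n_planted_de) <- RNA_CLASSES
  cfg$n_background[is.na(cfg$n_background)] <- 0L
  cfg$n_planted_de[is.na(cfg$n_planted_de)] <- 0L
  if (any(cfg$n_background < 0) || cfg$n_planted_triads < 0 ||
      any(cfg$n_planted_de < 0) || cfg$n_samples_per_group < 2)
    stop("counts must be >= 0 and n_samples_per_group >= 2", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$latent_sd < 0)
    stop("noise_sd and latent_sd must be >= 0", call. = FALSE)
  if (cfg$decoy_target_fraction < 0 || cfg$decoy_target_fraction > 1)
    stop("decoy_target_fraction must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' The canonical test fixture configuration
#'
#' 6 samples (3 per group), 60 background features (24 mRNA, 8 lncRNA,
#' 4 circRNA, 24 miRNA), 5 planted triads, 12 planted DE features,
#' log2-scale noise sd 0.05 and decoy target rows. The miRNA-rich class
#' split keeps the shared-miRNA test's universe large enough (29 miRNAs)
#' for a single shared miRNA to reach significance, echoing the miRNA-rich
#' universes of real whole-transcriptome studies.
#'
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
canonical_fixture_config <- function(seed = 20250806L)
  sim_config(noise_sd = 0.05, seed = seed)

#' Simulate an expression study with planted ceRNA structure
#'
#' Generative model, all on the log2 scale with expression `2^log2value`
#' (hence strictly positive): each planted triad draws a latent per-sample
#' signal `z = 1[group B] + Normal(0, latent_sd)`; its miRNA decreases in
#' `z` (`a - planted_log2fc * z + eps`), its ceRNA and mRNA increase in `z`
#' (`c + planted_log2fc * z + eps`), `eps ~ Normal(0, noise_sd^2)`; both
#' the ceRNA and the mRNA appear in the target table under the shared
#' miRNA. Planted DE features shift their group-B mean by
#' `+/- planted_log2fc`; background features are mutually independent
#' log-normal draws. Decoy target rows point miRNAs at background
#' features. Synthetic gene intervals are laid on one chromosome, with two
#' background lncRNA/mRNA pairs placed at gaps of exactly 10,000 and
#' 10,001 bp to exercise the cis-window boundary.
#'
#' @param config a [sim_config()].
#' @return list of class `cerna_simulation`: `expr` (a
#'   `SummarizedExperiment`), `targets` (data.frame), `intervals`
#'   (`GRanges`), `truth` (list with `triads`, `de`, `cis_boundary`,
#'   `config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  n <- config$n_samples_per_group
  n_tot <- 2L * n
  sample_ids <- c(paste0("groupA_", seq_len(n)), paste0("groupB_", seq_len(n)))
  group <- rep(c("groupA", "groupB"), each = n)
  is_b <- group == "groupB"
  fc <- config$planted_log2fc

  rows <- list(); classes <- character(); ids <- character()
  add_row <- function(id, cls, log2v) {
    rows[[length(rows) + 1L]] <<- log2v
    ids[length(ids) + 1L] <<- id
    classes[length(classes) + 1L] <<- cls
  }
  baseline <- function()
    stats::rnorm(1L, config$baseline_log2_mean, config$baseline_log2_sd)
  eps <- function() stats::rnorm(n_tot, 0, config$noise_sd)

  # planted triads
  T <- config$n_planted_triads
  triads <- NULL
  if (T > 0L) {
    triads <- data.frame(
      cerna_id = ifelse(seq_len(T) %% 2L == 1L,
                        sprintf("tri%d_lnc", seq_len(T)),
                        sprintf("tri%d_circ", seq_len(T))),
      cerna_class = ifelse(seq_len(T) %% 2L == 1L, "lncRNA", "circRNA"),
      mirna_id = sprintf("tri%d_mir", seq_len(T)),
      mrna_id = sprintf("tri%d_mrna", seq_len(T)))
    for (i in seq_len(T)) {
      z <- as.numeric(is_b) + stats::rnorm(n_tot, 0, config$latent_sd)
      add_row(triads$mirna_id[i], "miRNA", baseline() - fc * z + eps())
      add_row(triads$cerna_id[i], triads$cerna_class[i],
              baseline() + fc * z + eps())
      add_row(triads$mrna_id[i], "mRNA", baseline() + fc * z + eps())
    }
  }

  # planted DE features (no latent coupling; pure group shift)
  de_rows <- list()
  for (cl in RNA_CLASSES) {
    k <- config$n_planted_de[[cl]]
    if (k == 0L) next
    for (i in seq_len(k)) {
      dir_up <- i %% 2L == 1L
      id <- sprintf("de_%s_%d", cl, i)
      shift <- (if (dir_up) fc else -fc) * as.numeric(is_b)
      add_row(id, cl, baseline() + shift + eps())
      de_rows[[length(de_rows) + 1L]] <-
        data.frame(feature_id = id, feature_class = cl,
                   direction = if (dir_up) "up" else "down",
                   origin = "planted_de")
    }
  }

  # background features: independent log-normal draws
  for (cl in RNA_CLASSES) {
    k <- config$n_background[[cl]]
    if (k == 0L) next
    for (i in seq_len(k))
      add_row(sprintf("bg_%s_%02d", cl, i), cl, baseline() + eps())
  }

  values <- 2^do.call(rbind, rows)
  dimnames(values) <- list(ids, sample_ids)
  se <- expression_matrix(values, classes, group)

  # target table: planted edges + decoys onto background features
  planted_rows <- if (T > 0L)
    data.frame(mirna_id = rep(triads$mirna_id, 2L),
               target_id = c(triads$cerna_id, triads$mrna_id),
               target_class = c(triads$cerna_class, rep("mRNA", T)))
  else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character())
  mirna_ids <- ids[classes == "miRNA"]
  bg_targets <- ids[startsWith(ids, "bg_") & classes != "miRNA"]
  n_decoy <- round(config$decoy_target_fraction *
                     (2L * T + sum(classes == "miRNA" & startsWith(ids, "bg_"))))
  decoys <- NULL
  if (n_decoy > 0L && length(mirna_ids) && length(bg_targets)) {
    cand <- expand.grid(mirna_id = mirna_ids, target_id = bg_targets,
                        stringsAsFactors = FALSE)
    pick <- sample.int(nrow(cand), min(n_decoy, nrow(cand)))
    decoys <- cand[pick, , drop = FALSE]
    decoys$target_class <- classes[match(decoys$target_id, ids)]
  }
  targets <- rbind(planted_rows, decoys)
  targets <- targets[!duplicated(paste(targets$mirna_id, targets$target_id)), ]
  rownames(targets) <- NULL
  targets$site_count <- 1L

  intervals <- simulate_intervals(ids, classes)

  truth_de <- rbind(
    if (T > 0L) data.frame(
      feature_id = c(triads$cerna_id, triads$mrna_id, triads$mirna_id),
      feature_class = c(triads$cerna_class, rep("mRNA", T),
                        rep("miRNA", T)),
      direction = c(rep("up", 2L * T), rep("down", T)),
      origin = "triad"),
    do.call(rbind, de_rows))
  if (is.null(truth_de))
    truth_de <- data.frame(feature_id = character(),
                           feature_class = character(),
                           direction = character(), origin = character())
  structure(list(
    expr = se, targets = targets, intervals = intervals$gr,
    truth = list(triads = if (is.null(triads)) data.frame(
                   cerna_id = character(), cerna_class = character(),
                   mirna_id = character(), mrna_id = character())
                 else triads,
                 de = truth_de,
                 cis_boundary = intervals$boundary,
                 config = config)),
    class = "cerna_simulation")
}

# one synthetic chromosome; width-1000 loci every 50 kb, with two background
# lncRNAs repositioned at gaps of exactly 10,000 and 10,001 bp from two
# background mRNAs to probe the cis-window boundary
simulate_intervals <- function(ids, classes) {
  width <- 1000L
  start <- 1L + (seq_along(ids) - 1L) * 50000L
  end <- start + width - 1L
  boundary <- NULL
  bg_mrna <- which(startsWith(ids, "bg_mRNA"))
  bg_lnc <- which(startsWith(ids, "bg_lncRNA"))
  if (length(bg_mrna) >= 2L && length(bg_lnc) >= 2L) {
    start[bg_lnc[1L]] <- end[bg_mrna[1L]] + 10000L + 1L   # gap 10,000
    end[bg_lnc[1L]] <- start[bg_lnc[1L]] + width - 1L
    start[bg_lnc[2L]] <- end[bg_mrna[2L]] + 10001L + 1L   # gap 10,001
    end[bg_lnc[2L]] <- start[bg_lnc[2L]] + width - 1L
    boundary <- data.frame(
      lncrna_id = ids[bg_lnc[1:2]], gene_id = ids[bg_mrna[1:2]],
      gap_bp = c(10000L, 10001L))
  }
  biotype <- c(mRNA = "protein_coding", lncRNA = "lncRNA",
               circRNA = "other", miRNA = "other")[classes]
  gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(start, end),
                               strand = "+")
  S4Vectors::mcols(gr)$feature_id <- ids
  S4Vectors::mcols(gr)$biotype <- unname(biotype)
  names(gr) <- ids
  list(gr = gr, boundary = boundary)
}

#' Write the canonical fixture suite to a directory
#'
#' Emits the four data files the pipeline consumes -- `expression.tsv`,
#' `design.tsv`, `targets.tsv`, `genes.gtf` -- plus `truth.tsv` describing
#' the planted structure (columns `record` (`triad`/`de`), `id1`, `id2`,
#' `id3`, `info`: for triads id1/id2/id3 = ceRNA/miRNA/mRNA and info = the
#' ceRNA class; for DE records id1 = feature, id2 = class, id3 = direction,
#' info = origin). Deterministic: re-running with the same config
#' reproduces every file byte for byte.
#'
#' @param outdir writable output directory (created if needed).
#' @param config a [sim_config()]; default [canonical_fixture_config()].
#' @return invisibly, the simulation object.
#' @export
emit_fixture_suite <- function(outdir, config = canonical_fixture_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  write_expression(sim$expr, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "design.tsv"))
  write_target_table(sim$targets, file.path(outdir, "targets.tsv"))
  write_intervals(sim$intervals, file.path(outdir, "genes.gtf"), "gtf")
  tri <- sim$truth$triads
  truth <- rbind(
    if (nrow(tri)) data.frame(record = "triad", id1 = tri$cerna_id,
                              id2 = tri$mirna_id, id3 = tri$mrna_id,
                              info = tri$cerna_class),
    data.frame(record = "de", id1 = sim$truth$de$feature_id,
               id2 = sim$truth$de$feature_class,
               id3 = sim$truth$de$direction, info = sim$truth$de$origin))
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sim)
}
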