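#' Run the full ceRNA inference on in-memory objects
#'
#' Chains the analysis stages on a validated expression matrix and target
#' table: DE calling, Spearman anticorrelation filtering of predicted
#' miRNA-target pairs, Pearson screening of candidate ceRNA pairs sharing a
#' retained miRNA, the shared-miRNA hypergeometric test, triad assembly and
#' network construction. All thresholds default to the values the analysis
#' design prescribes (fold change >= 2; FDR < 0.05 for long RNAs and
#' p < 0.05 for miRNAs; SCC < -0.7; PCC > 0.9; pair p < 0.05).
#'
#' @param se a validated expression `SummarizedExperiment`.
#' @param targets miRNA-target data.frame.
#' @param fc_min,de_fdr,mirna_de_p differential-expression thresholds.
#' @param scc_cutoff,pcc_cutoff,pair_alpha correlation and pair-test
#'   thresholds.
#' @param universe_policy miRNA universe for the pair test (see
#'   [mirna_universe()]).
#' @param de_only restrict edges to DE features (default TRUE).
#' @param pseudocount log2 pseudocount.
#' @return list with components `de`, `edges`, `candidates`, `tests`,
#'   `triads`, `network`, `hubs`.
#' @export
infer_cerna_network <- function(se, targets, fc_min = 2, de_fdr = 0.05,
                                mirna_de_p = 0.05, scc_cutoff = -0.7,
                                pcc_cutoff = 0.9, pair_alpha = 0.05,
                                universe_policy = "expressed",
                                de_only = TRUE, pseudocount = 0.01) {
  de <- suppressMessages(call_de(se, fc_min = fc_min, fdr_alpha = de_fdr,
                                 mirna_p_alpha = mirna_de_p,
                                 pseudocount = pseudocount))
  edges <- suppressMessages(filter_mirna_targets(
    se, targets, de, scc_cutoff = scc_cutoff, de_only = de_only))
  candidates <- candidate_cerna_pairs(se, edges, pcc_cutoff = pcc_cutoff,
                                      pseudocount = pseudocount)
  universe <- mirna_universe(universe_policy, se = se, de = de, edges = edges)
  tests <- if (nrow(candidates[candidates$passes, , drop = FALSE]) > 0L &&
               length(universe) > 0L)
    test_cerna_pairs(candidates, edges, universe, alpha = pair_alpha)
  else {
    t0 <- data.frame(cerna_id = character(), cerna_class = character(),
                     mrna_id = character(), pcc = numeric(), N = integer(),
                     K = integer(), M = integer(), s = integer(),
                     p_value = numeric(), passes = logical())
    attr(t0, "universe_size") <- length(unique(universe))
    t0
  }
  triads <- assemble_triads(tests, edges)
  network <- build_network(triads)
  hubs <- suppressMessages(rank_connectivity(network, top_k = 10))
  list(de = de, edges = edges, candidates = candidates, tests = tests,
       triads = triads, network = network, hubs = hubs)
}

#' Pipeline configuration
#'
#' Collects every input path, output directory and threshold of the staged
#' pipeline. Threshold defaults are exactly the analysis design's printed
#' values, so a bare run applies the standard procedure to any input.
#'
#' @param outdir output directory for all artifacts.
#' @param expression,design,targets,gtf,annotation,gene_set input paths
#'   (those not needed by the stages you run may stay `NULL`). When
#'   `expression` is `NULL` the `simulate` stage writes the inputs into
#'   `outdir` first.
#' @inheritParams infer_cerna_network
#' @param cis_window cis-target window in bp (inclusive).
#' @param trans_r minimum |Pearson r| for trans targets (inclusive).
#' @param enrich_alpha enrichment threshold.
#' @param seed integer seed for the simulate stage.
#' @param sim a [sim_config()] used by the simulate stage (its seed is
#'   overridden by `seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, expression = NULL, design = NULL,
                            targets = NULL, gtf = NULL, annotation = NULL,
                            gene_set = NULL, fc_min = 2, de_fdr = 0.05,
                            mirna_de_p = 0.05, scc_cutoff = -0.7,
                            pcc_cutoff = 0.9, pair_alpha = 0.05,
                            cis_window = 10000, trans_r = 0.95,
                            enrich_alpha = 0.05,
                            universe_policy = "expressed", de_only = TRUE,
                            pseudocount = 0.01, seed = 1L,
                            sim = sim_config()) {
  cfg <- list(outdir = outdir, expression = expression, design = design,
              targets = targets, gtf = gtf, annotation = annotation,
              gene_set = gene_set, fc_min = fc_min, de_fdr = de_fdr,
              mirna_de_p = mirna_de_p, scc_cutoff = scc_cutoff,
              pcc_cutoff = pcc_cutoff, pair_alpha = pair_alpha,
              cis_window = cis_window, trans_r = trans_r,
              enrich_alpha = enrich_alpha,
              universe_policy = match.arg(universe_policy,
                                          c("expressed", "de", "retained")),
              de_only = isTRUE(de_only), pseudocount = pseudocount,
              seed = as.integer(seed), sim = sim)
  stopifnot(cfg$fc_min >= 1, cfg$de_fdr > 0, cfg$de_fdr <= 1,
            cfg$mirna_de_p > 0, cfg$mirna_de_p <= 1,
            cfg$scc_cutoff >= -1, cfg$scc_cutoff <= 1,
            cfg$pcc_cutoff >= -1, cfg$pcc_cutoff <= 1,
            cfg$pair_alpha > 0, cfg$pair_alpha <= 1,
            cfg$cis_window >= 0, cfg$trans_r >= 0, cfg$trans_r <= 1,
            cfg$pseudocount > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat-key YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; simulator fields use a
#' `sim_` prefix (e.g. `sim_noise_sd`). Entries in `overrides` (e.g. parsed
#' command-line flags) replace file values.
#'
#' @param path YAML file path (or `NULL` to use defaults + overrides).
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  sim_keys <- grep("^sim_", names(vals), value = TRUE)
  sim_args <- stats::setNames(vals[sim_keys], sub("^sim_", "", sim_keys))
  vals <- vals[setdiff(names(vals), sim_keys)]
  known <- setdiff(names(formals(pipeline_config)), "sim")
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals$sim <- do.call(sim_config, sim_args)
  if (!is.null(vals$seed)) vals$sim$seed <- as.integer(vals$seed)
  do.call(pipeline_config, vals)
}

pipeline_paths <- function(cfg) {
  o <- cfg$outdir
  list(expression = cfg$expression %||% file.path(o, "expression.tsv"),
       design = cfg$design %||% file.path(o, "design.tsv"),
       targets = cfg$targets %||% file.path(o, "targets.tsv"),
       gtf = cfg$gtf %||% file.path(o, "genes.gtf"),
       de = file.path(o, "de.tsv"),
       edges = file.path(o, "edges.tsv"),
       candidates = file.path(o, "candidate_pairs.tsv"),
       tests = file.path(o, "cerna_pairs.tsv"),
       triads = file.path(o, "triads.tsv"),
       network = file.path(o, "network.edges.tsv"),
       sif = file.path(o, "network.sif"),
       hubs = file.path(o, "hubs.tsv"),
       cis = file.path(o, "cis_targets.tsv"),
       trans = file.path(o, "trans_targets.tsv"),
       enrichment = file.path(o, "enrichment.tsv"),
       manifest = file.path(o, "manifest.json"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages
#'
#' Executes the named stages in order, reading each stage's inputs from
#' disk and writing its TSV artifacts plus a JSON run manifest (package
#' version, configuration echo, input checksums -- no timestamps, so
#' identical config and seed reproduce byte-identical artifacts).
#' `"run-all"` expands to simulate, de, filter, cerna, network and, when an
#' annotation is configured, enrich; running stages one at a time produces
#' the same artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param stages character vector of stage names among `simulate`, `de`,
#'   `filter`, `cerna`, `network`, `enrich`, or `"run-all"`.
#' @return invisibly, the list of artifact paths.
#' @export
run_pipeline <- function(cfg, stages = "run-all") {
  stopifnot(inherits(cfg, "pipeline_config"))
  if ("run-all" %in% stages) {
    stages <- c("simulate", "de", "filter", "cerna", "network",
                if (!is.null(cfg$annotation)) "enrich")
    if (!is.null(cfg$expression)) stages <- setdiff(stages, "simulate")
  }
  bad <- setdiff(stages, c("simulate", "de", "filter", "cerna", "network",
                           "enrich"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(cfg)
  for (st in stages) {
    message("stage: ", st)
    switch(st,
           simulate = stage_simulate(cfg, p),
           de = stage_de(cfg, p),
           filter = stage_filter(cfg, p),
           cerna = stage_cerna(cfg, p),
           network = stage_network(cfg, p),
           enrich = stage_enrich(cfg, p))
  }
  write_manifest(cfg, p)
  invisible(p)
}

stage_simulate <- function(cfg, p) {
  sim <- cfg$sim
  sim$seed <- cfg$seed
  emit_fixture_suite(cfg$outdir, sim)
}

load_inputs <- function(cfg, p) {
  for (f in c("expression", "design", "targets"))
    if (!file.exists(p[[f]]))
      stop("required input not found: ", p[[f]],
           " (run the simulate stage or point the config at your data)",
           call. = FALSE)
  list(se = read_expression(p$expression, p$design),
       targets = suppressMessages(read_target_table(p$targets)))
}

stage_de <- function(cfg, p) {
  inp <- load_inputs(cfg, p)
  de <- suppressMessages(call_de(inp$se, fc_min = cfg$fc_min,
                                 fdr_alpha = cfg$de_fdr,
                                 mirna_p_alpha = cfg$mirna_de_p,
                                 pseudocount = cfg$pseudocount))
  write_de_table(de, p$de)
}

stage_filter <- function(cfg, p) {
  inp <- load_inputs(cfg, p)
  if (!file.exists(p$de))
    stop("required input not found: ", p$de, " (run the de stage first)",
         call. = FALSE)
  de <- read_tsv_strict(p$de)
  de$is_de <- as.logical(de$is_de)
  edges <- suppressMessages(filter_mirna_targets(
    inp$se, inp$targets, de, scc_cutoff = cfg$scc_cutoff,
    de_only = cfg$de_only))
  utils::write.table(edges, p$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cand <- candidate_cerna_pairs(inp$se, edges, pcc_cutoff = cfg$pcc_cutoff,
                                pseudocount = cfg$pseudocount)
  utils::write.table(cand, p$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (file.exists(p$gtf)) {
    gr <- read_intervals(p$gtf, "gtf")
    lnc <- gr[gr$biotype == "lncRNA"]
    cis <- cis_targets(lnc, gr, window_bp = cfg$cis_window)
    utils::write.table(cis, p$cis, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lnc_de <- intersect(lnc$feature_id, de$feature_id[de$is_de])
    genes <- intersect(gr$feature_id[gr$biotype == "protein_coding"],
                       rownames(inp$se))
    trans <- suppressMessages(trans_targets(
      inp$se, lnc_de, genes, threshold = cfg$trans_r,
      pseudocount = cfg$pseudocount))
    utils::write.table(trans, p$trans, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
}

stage_cerna <- function(cfg, p) {
  inp <- load_inputs(cfg, p)
  for (f in c("edges", "candidates"))
    if (!file.exists(p[[f]]))
      stop("required input not found: ", p[[f]],
           " (run the filter stage first)", call. = FALSE)
  edges <- read_tsv_strict(p$edges)
  edges$passes <- as.logical(edges$passes)
  cand <- read_tsv_strict(p$candidates)
  cand$passes <- as.logical(cand$passes)
  de <- if (file.exists(p$de)) {
    d <- read_tsv_strict(p$de); d$is_de <- as.logical(d$is_de); d
  } else NULL
  universe <- mirna_universe(cfg$universe_policy, se = inp$se, de = de,
                             edges = edges)
  tests <- if (any(cand$passes) && length(universe))
    test_cerna_pairs(cand, edges, universe, alpha = cfg$pair_alpha)
  else data.frame(cerna_id = character(), cerna_class = character(),
                  mrna_id = character(), pcc = numeric(), N = integer(),
                  K = integer(), M = integer(), s = integer(),
                  p_value = numeric(), passes = logical())
  utils::write.table(tests, p$tests, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  triads <- assemble_triads(tests, edges)
  write_triad_table(triads, p$triads)
}

stage_network <- function(cfg, p) {
  if (!file.exists(p$triads))
    stop("required input not found: ", p$triads,
         " (run the cerna stage first)", call. = FALSE)
  triads <- read_tsv_strict(p$triads)
  net <- build_network(triads)
  write_network(net, p$network, "edge-tsv")
  write_network(net, p$sif, "sif")
  hubs <- suppressMessages(rank_connectivity(net, top_k = 10))
  utils::write.table(hubs, p$hubs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cfg$gene_set)) {
    genes <- readLines(cfg$gene_set)
    genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
    sub <- suppressMessages(extract_subnetwork(net, genes))
    write_network(sub, file.path(cfg$outdir, "subnetwork.edges.tsv"),
                  "edge-tsv")
  }
}

stage_enrich <- function(cfg, p) {
  if (is.null(cfg$annotation))
    stop("enrich stage needs an annotation file in the config",
         call. = FALSE)
  if (!file.exists(p$triads))
    stop("required input not found: ", p$triads,
         " (run the cerna stage first)", call. = FALSE)
  inp <- load_inputs(cfg, p)
  triads <- read_tsv_strict(p$triads)
  ann <- read_gene_sets(cfg$annotation)
  background <- rownames(inp$se)[feature_classes(inp$se) == "mRNA"]
  query <- intersect(unique(triads$mrna_id), background)
  if (length(query) == 0L) {
    utils::write.table(
      data.frame(term_id = character(), term_name = character(),
                 k = integer(), K = integer(), n = integer(), N = integer(),
                 p_value = numeric(), fdr = numeric(), enriched = logical()),
      p$enrichment, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(NULL))
  }
  res <- over_representation(query, background, ann,
                             alpha = cfg$enrich_alpha)
  utils::write.table(res, p$enrichment, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_manifest <- function(cfg, p) {
  inputs <- Filter(file.exists, unlist(p[c("expression", "design", "targets",
                                           "gtf")]))
  cfg_plain <- unclass(cfg)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  manifest <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    seed = cfg$seed,
    config = cfg_plain,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(p$manifest)
}
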