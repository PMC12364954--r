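make_edge_se <- function() {
  # mir anticorrelates perfectly with lnc and mrna; decoy is independent
  rows <- list(mir = c(6, 5, 4, 3, 2, 1),
               lnc = c(1, 2, 3, 4, 5, 6),
               mrna = c(2, 4, 6, 8, 10, 12),
               decoy = c(3, 1, 4, 1, 5, 9))
  se_from_rows(rows, c("miRNA", "lncRNA", "mRNA", "mRNA"))
}

fake_de <- function(se, de_ids) {
  data.frame(feature_id = rownames(se),
             feature_class = feature_classes(se),
             is_de = rownames(se) %in% de_ids)
}

test_that("anticorrelated predicted pairs are retained, others not", {
  se <- make_edge_se()
  targets <- data.frame(mirna_id = "mir",
                        target_id = c("lnc", "mrna", "decoy"),
                        target_class = c("lncRNA", "mRNA", "mRNA"))
  de <- fake_de(se, rownames(se))
  edges <- suppressMessages(filter_mirna_targets(se, targets, de))
  expect_equal(edges$scc[edges$target_id == "lnc"], -1)
  expect_equal(edges$scc[edges$target_id == "mrna"], -1)
  expect_true(all(edges$passes[edges$target_id %in% c("lnc", "mrna")]))
  expect_false(edges$passes[edges$target_id == "decoy"])
})

test_that("the SCC retention threshold is strictly 'less than'", {
  se <- make_edge_se()
  targets <- data.frame(mirna_id = "mir", target_id = "lnc",
                        target_class = "lncRNA")
  de <- fake_de(se, rownames(se))
  # scc is exactly -1: a cutoff equal to the computed value must reject
  at_cut <- suppressMessages(filter_mirna_targets(se, targets, de,
                                                  scc_cutoff = -1))
  expect_false(at_cut$passes)
  below <- suppressMessages(filter_mirna_targets(se, targets, de,
                                                 scc_cutoff = -0.999))
  expect_true(below$passes)
})

test_that("non-DE members and unresolvable ids are excluded", {
  se <- make_edge_se()
  targets <- data.frame(mirna_id = c("mir", "mir", "ghost"),
                        target_id = c("lnc", "mrna", "lnc"),
                        target_class = c("lncRNA", "mRNA", "lncRNA"))
  de <- fake_de(se, c("mir", "lnc"))  # mrna not DE
  edges <- suppressMessages(filter_mirna_targets(se, targets, de))
  expect_equal(edges$target_id, "lnc")
  expect_equal(attr(edges, "n_unresolved"), 1L)
  expect_equal(attr(edges, "n_not_de"), 1L)
  # with de_only = FALSE the non-DE pair is evaluated too
  all_edges <- suppressMessages(filter_mirna_targets(se, targets,
                                                     de_only = FALSE))
  expect_setequal(all_edges$target_id, c("lnc", "mrna"))
})

test_that("constant-vector pairs are dropped and counted", {
  rows <- list(mir = c(6, 5, 4, 3, 2, 1), flat = rep(2, 6))
  se <- se_from_rows(rows, c("miRNA", "mRNA"))
  targets <- data.frame(mirna_id = "mir", target_id = "flat",
                        target_class = "mRNA")
  edges <- suppressMessages(filter_mirna_targets(se, targets,
                                                 de_only = FALSE))
  expect_equal(nrow(edges), 0L)
  expect_equal(attr(edges, "n_degenerate"), 1L)
})

test_that("candidate ceRNA pairs require a shared retained miRNA", {
  se <- make_edge_se()
  targets <- data.frame(mirna_id = "mir", target_id = c("lnc", "mrna"),
                        target_class = c("lncRNA", "mRNA"))
  de <- fake_de(se, rownames(se))
  edges <- suppressMessages(filter_mirna_targets(se, targets, de))
  cand <- candidate_cerna_pairs(se, edges)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$cerna_id, "lnc")
  expect_equal(cand$mrna_id, "mrna")
  expect_equal(cand$pcc, 1, tolerance = 1e-5)  # log2 of proportional
  expect_true(cand$passes)                     # vectors is near-affine
  # decoy shares no retained miRNA with lnc -> never a candidate
  expect_false("decoy" %in% cand$mrna_id)
})

test_that("the PCC retention threshold is strictly 'greater than'", {
  se <- make_edge_se()
  targets <- data.frame(mirna_id = "mir", target_id = c("lnc", "mrna"),
                        target_class = c("lncRNA", "mRNA"))
  de <- fake_de(se, rownames(se))
  edges <- suppressMessages(filter_mirna_targets(se, targets, de))
  pcc <- candidate_cerna_pairs(se, edges, pcc_cutoff = 0)$pcc
  at_cut <- candidate_cerna_pairs(se, edges, pcc_cutoff = pcc)
  expect_false(at_cut$passes)   # pcc == cutoff is rejected
  below <- candidate_cerna_pairs(se, edges, pcc_cutoff = pcc - 1e-6)
  expect_true(below$passes)
})

test_that("tightening either cutoff never grows the retained sets", {
  run <- run_fixture_pipeline(31L)
  se <- run$sim$expr; targets <- run$sim$targets; de <- run$res$de
  prev <- Inf
  for (cut in c(-0.5, -0.7, -0.9, -1)) {
    e <- suppressMessages(filter_mirna_targets(se, targets, de,
                                               scc_cutoff = cut))
    expect_lte(sum(e$passes), prev)
    prev <- sum(e$passes)
  }
  edges <- run$res$edges
  prev <- Inf
  for (cut in c(0.5, 0.7, 0.9, 0.99)) {
    cand <- candidate_cerna_pairs(se, edges, pcc_cutoff = cut)
    expect_lte(sum(cand$passes), prev)
    prev <- sum(cand$passes)
  }
})

test_that("decoy retention at n = 6 matches the exact permutation null", {
  perms <- all_permutations(6L)
  null_rho <- apply(perms, 1L, function(y) oracle_spearman(1:6, y))
  p0 <- mean(null_rho < -0.7)   # exact null P(rho < -0.7)
  set.seed(61)
  n_sim <- 4000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    if (spearman_cor(stats::rnorm(6), stats::rnorm(6)) < -0.7)
      hits <- hits + 1L
  }
  se3 <- 3 * sqrt(p0 * (1 - p0) / n_sim)
  expect_lt(abs(hits / n_sim - p0), se3 + 1e-12)
})

test_that("cis assignment respects the 10 kb gap boundary inclusively", {
  # gene body [1, 1000]; lncRNA starting at 11001 leaves a 10,000 bp gap
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(1, 11001, 11002, 500), c(1000, 11500, 11700, 800)))
  S4Vectors::mcols(gr)$feature_id <- c("gene1", "lnc_at", "lnc_past", "lnc_in")
  S4Vectors::mcols(gr)$biotype <- c("protein_coding", "lncRNA", "lncRNA",
                                    "lncRNA")
  names(gr) <- gr$feature_id
  lnc <- gr[gr$biotype == "lncRNA"]
  genes <- gr[gr$biotype == "protein_coding"]
  cis <- cis_targets(lnc, genes, window_bp = 10000)
  expect_true("lnc_at" %in% cis$lncrna_id)     # gap exactly 10,000
  expect_false("lnc_past" %in% cis$lncrna_id)  # gap 10,001
  expect_equal(cis$distance_bp[cis$lncrna_id == "lnc_at"], 10000L)
  expect_equal(cis$distance_bp[cis$lncrna_id == "lnc_in"], 0L)  # overlap
})

test_that("cis gaps are symmetric and chromosome-restricted", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  b <- GenomicRanges::GRanges(c("chr1", "chr2"),
                              IRanges::IRanges(c(5001, 5001), c(6000, 6000)))
  S4Vectors::mcols(a)$feature_id <- "x"
  S4Vectors::mcols(a)$biotype <- "protein_coding"
  S4Vectors::mcols(b)$feature_id <- c("y", "z")
  S4Vectors::mcols(b)$biotype <- "protein_coding"
  d_ab <- suppressWarnings(GenomicRanges::distance(a, b[1],
                                                   ignore.strand = TRUE))
  d_ba <- suppressWarnings(GenomicRanges::distance(b[1], a,
                                                   ignore.strand = TRUE))
  expect_equal(d_ab, d_ba)
  # different chromosome never assigned
  S4Vectors::mcols(a)$biotype <- "lncRNA"
  cis <- cis_targets(a, b)
  expect_equal(cis$gene_id, "y")
})

test_that("trans assignment uses |r| >= threshold inclusively", {
  rows <- list(lnc = c(1, 2, 3, 4, 5, 6),
               same = c(1, 2, 3, 4, 5, 6),
               anti = c(6, 5, 4, 3, 2, 1),
               noise = c(2, 7, 1, 8, 2, 8))
  se <- se_from_rows(rows, c("lncRNA", "mRNA", "mRNA", "mRNA"))
  tr <- trans_targets(se, "lnc", c("same", "anti", "noise"), threshold = 1)
  # identical vectors give r = 1; |r| equal to the threshold is included
  expect_equal(tr$gene_id, "same")
  expect_equal(tr$pearson_r, 1)
  # negative correlations qualify through the absolute value, also
  # inclusively at the exact computed magnitude
  lv <- log2(SummarizedExperiment::assay(se, "abundance") + 0.01)
  r_anti <- pearson_cor(lv["lnc", ], lv["anti", ])
  tr2 <- trans_targets(se, "lnc", "anti", threshold = abs(r_anti))
  expect_equal(tr2$gene_id, "anti")
  expect_equal(tr2$pearson_r, r_anti)
})
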