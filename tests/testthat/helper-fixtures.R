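# Small in-code fixtures shared across test files.

# 4 features x 6 samples, two groups of 3, deterministic values.
make_toy_se <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6,
                6, 5, 4, 3, 2, 1,
                2, 2, 2, 8, 8, 8,
                10, 11, 12, 100, 110, 120),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("mrna1", "mir1", "lnc1", "circ1"),
                              paste0("s", 1:6)))
  cernet::expression_matrix(m, c("mRNA", "miRNA", "lncRNA", "circRNA"),
                            rep(c("groupA", "groupB"), each = 3))
}

# Expression matrix built directly from a named list of row vectors.
se_from_rows <- function(rows, classes, n_per_group = 3) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  cernet::expression_matrix(m, classes,
                            rep(c("groupA", "groupB"),
                                each = ncol(m) / 2))
}

run_fixture_pipeline <- function(seed, n_triads = NULL) {
  cfg <- cernet::canonical_fixture_config(seed)
  if (!is.null(n_triads)) cfg$n_planted_triads <- as.integer(n_triads)
  sim <- cernet::simulate_dataset(cfg)
  res <- cernet::infer_cerna_network(sim$expr, sim$targets)
  list(sim = sim, res = res)
}

triad_key <- function(d) paste(d$cerna_id, d$mirna_id, d$mrna_id)
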