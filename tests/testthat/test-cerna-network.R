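toy_edges <- function() {
  # two miRNAs; mirA targets lncX and mrna1/mrna2, mirB targets lncX, mrna1
  data.frame(
    mirna_id = c("mirA", "mirA", "mirA", "mirB", "mirB"),
    target_id = c("lncX", "mrna1", "mrna2", "lncX", "mrna1"),
    target_class = c("lncRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    scc = c(-0.9, -0.95, -0.8, -0.85, -0.75),
    passes = TRUE)
}

toy_candidates <- function() {
  data.frame(cerna_id = c("lncX", "lncX"), cerna_class = "lncRNA",
             mrna_id = c("mrna1", "mrna2"), pcc = c(0.99, 0.95),
             passes = TRUE)
}

test_that("shared-miRNA counts and p-values follow the retained relation", {
  universe <- c("mirA", "mirB", paste0("bg", 1:58))  # N = 60
  tests <- test_cerna_pairs(toy_candidates(), toy_edges(), universe)
  expect_equal(tests$N, c(60, 60))
  r1 <- tests[tests$mrna_id == "mrna1", ]
  expect_equal(r1[, c("K", "M", "s")], data.frame(K = 2, M = 2, s = 2),
               ignore_attr = TRUE)
  expect_equal(r1$p_value, oracle_hyper_tail(60, 2, 2, 2), tolerance = 1e-12)
  expect_true(r1$passes)
  r2 <- tests[tests$mrna_id == "mrna2", ]
  expect_equal(r2[, c("K", "M", "s")], data.frame(K = 2, M = 1, s = 1),
               ignore_attr = TRUE)
  expect_equal(r2$p_value, oracle_hyper_tail(60, 2, 1, 1), tolerance = 1e-12)
  expect_true(r2$passes)  # p = 2/60 < 0.05
})

test_that("pairs with disjoint miRNA sets get p = 1 and are dropped", {
  edges <- data.frame(mirna_id = c("mirA", "mirB"),
                      target_id = c("lncX", "mrna1"),
                      target_class = c("lncRNA", "mRNA"),
                      scc = -0.9, passes = TRUE)
  cand <- data.frame(cerna_id = "lncX", cerna_class = "lncRNA",
                     mrna_id = "mrna1", pcc = 0.95, passes = TRUE)
  tests <- test_cerna_pairs(cand, edges, c("mirA", "mirB", "mirC"))
  expect_equal(tests$s, 0)
  expect_equal(tests$p_value, 1)
  expect_false(tests$passes)
})

test_that("the pair threshold is strict and the universe matters", {
  # one shared miRNA out of K = M = 1: p = 1/N
  edges <- data.frame(mirna_id = "mirA", target_id = c("lncX", "mrna1"),
                      target_class = c("lncRNA", "mRNA"), scc = -0.9,
                      passes = TRUE)
  cand <- data.frame(cerna_id = "lncX", cerna_class = "lncRNA",
                     mrna_id = "mrna1", pcc = 0.95, passes = TRUE)
  p20 <- test_cerna_pairs(cand, edges,
                          c("mirA", paste0("m", 1:19)))  # p = 1/20
  expect_equal(p20$p_value, 0.05, tolerance = 1e-12)
  expect_false(p20$passes)  # p < alpha is strict
  p40 <- test_cerna_pairs(cand, edges,
                          c("mirA", paste0("m", 1:39)))  # p = 1/40
  expect_true(p40$passes)
  expect_error(test_cerna_pairs(cand, edges, character()), "empty")
})

test_that("triads expand one row per (pair, shared miRNA)", {
  universe <- c("mirA", "mirB", paste0("bg", 1:58))
  tests <- test_cerna_pairs(toy_candidates(), toy_edges(), universe)
  triads <- assemble_triads(tests, toy_edges())
  # (lncX, mrna1) shares mirA+mirB -> 2 triads; (lncX, mrna2) shares mirA
  expect_equal(nrow(triads), 3L)
  t1 <- triads[triads$mrna_id == "mrna1" & triads$mirna_id == "mirA", ]
  expect_equal(t1$scc_cerna_mirna, -0.9)
  expect_equal(t1$scc_mirna_mrna, -0.95)
  expect_equal(t1$pcc_pair, 0.99)
  # no retained pairs -> empty triad set
  none <- tests; none$passes <- FALSE
  expect_equal(nrow(assemble_triads(none, toy_edges())), 0L)
})

test_that("a single triad builds a triangle with all degrees 2", {
  triads <- data.frame(cerna_id = "lncX", cerna_class = "lncRNA",
                       mirna_id = "mirA", mrna_id = "mrna1",
                       scc_cerna_mirna = -1, scc_mirna_mrna = -1,
                       pcc_pair = 1, pair_p_value = 0.01)
  net <- build_network(triads)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$nodes$degree, c(2L, 2L, 2L))
  expect_equal(sum(net$edges$interaction_type == "mirna_target"), 2L)
  expect_equal(sum(net$edges$interaction_type == "cerna_pair"), 1L)
})

test_that("edges are deduplicated across triads and degrees obey the
           handshake lemma", {
  universe <- c("mirA", "mirB", paste0("bg", 1:58))
  tests <- test_cerna_pairs(toy_candidates(), toy_edges(), universe)
  triads <- assemble_triads(tests, toy_edges())
  net <- build_network(triads)
  key <- paste(pmin(net$edges$source, net$edges$target),
               pmax(net$edges$source, net$edges$target),
               net$edges$interaction_type)
  expect_false(any(duplicated(key)))
  expect_false(any(net$edges$source == net$edges$target))
  expect_equal(sum(net$nodes$degree), 2L * nrow(net$edges))
  # two triads sharing a miRNA: the shared miRNA accumulates degree
  expect_equal(net$nodes$degree[net$nodes$id == "mirA"], 3L)
})

test_that("hub ranking sorts by degree then id and caps at the node count", {
  triads <- data.frame(
    cerna_id = "lncX", cerna_class = "lncRNA",
    mirna_id = "mirA", mrna_id = paste0("mrna", 1:5),
    scc_cerna_mirna = -1, scc_mirna_mrna = -1, pcc_pair = 1,
    pair_p_value = 0.01)
  net <- build_network(triads)
  hubs <- suppressMessages(rank_connectivity(net, top_k = 3))
  # mirA touches lncX and all 5 mRNAs; lncX touches mirA and all 5 mRNAs
  expect_equal(hubs$id[1:2], c("lncX", "mirA"))  # degree tie -> lexicographic
  expect_equal(hubs$degree[1:2], c(6L, 6L))
  expect_message(all_ranked <- rank_connectivity(net, top_k = 100),
                 "exceeds")
  expect_equal(nrow(all_ranked), nrow(net$nodes))
})

test_that("subnetwork extraction returns the triad neighborhood", {
  universe <- c("mirA", "mirB", paste0("bg", 1:58))
  tests <- test_cerna_pairs(toy_candidates(), toy_edges(), universe)
  triads <- assemble_triads(tests, toy_edges())
  net <- build_network(triads)
  sub <- extract_subnetwork(net, "mrna2")
  expect_true(all(c("mrna2", "mirA", "lncX") %in% sub$nodes$id))
  expect_equal(sum(sub$nodes$degree), 2L * nrow(sub$edges))
  # a gene set disjoint from the network gives an empty subnetwork
  expect_message(empty <- extract_subnetwork(net, "absent_gene"), "absent")
  expect_equal(nrow(empty$nodes), 0L)
  # union over all mRNAs covers the full network
  mrnas <- net$nodes$id[net$nodes$class == "mRNA"]
  edge_key <- function(n) paste(pmin(n$edges$source, n$edges$target),
                                pmax(n$edges$source, n$edges$target),
                                n$edges$interaction_type)
  covered <- unique(unlist(lapply(mrnas, function(g)
    edge_key(extract_subnetwork(net, g)))))
  expect_setequal(covered, edge_key(net))
})

test_that("network export round-trips edges and writes node attributes", {
  universe <- c("mirA", "mirB", paste0("bg", 1:58))
  tests <- test_cerna_pairs(toy_candidates(), toy_edges(), universe)
  net <- build_network(assemble_triads(tests, toy_edges()))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "net.tsv")
  paths <- write_network(net, p, "edge-tsv")
  edges2 <- read_network_edges(p)
  expect_equal(edges2, net$edges, tolerance = 1e-12)
  nodes2 <- utils::read.delim(paths[2])
  expect_equal(nodes2$id, net$nodes$id)
  expect_equal(nodes2$degree, net$nodes$degree)
  # SIF dialect: one line per edge, relation in the middle
  sp <- file.path(dir, "net.sif")
  write_network(net, sp, "sif")
  sif <- strsplit(readLines(sp), "\t")
  expect_equal(length(sif), nrow(net$edges))
  expect_true(all(vapply(sif, `[`, "", 2) %in%
                    c("mirna_target", "cerna_pair")))
  # empty network -> header-only edge file
  ep <- file.path(dir, "empty.tsv")
  write_network(build_network(assemble_triads(
    transform(tests, passes = FALSE), toy_edges())), ep, "edge-tsv")
  expect_equal(length(readLines(ep)), 1L)
})
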