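test_that("pairwise_pcc matches the definitional formula and handles edges", {
  samples <- sprintf("S%d", 1:4)
  a <- toy_matrix(c(1, 2, 4, 8,
                    3, 3, 3, 3), c("g1", "const"), samples, "lncRNA")
  b <- toy_matrix(c(2, 1, 5, 6,
                    -1, -2, -4, -8), c("h1", "neg"), samples, "mRNA")
  tab <- pairwise_pcc(a, b)
  # definitional oracle: cov / (sd * sd), computed in place
  x <- c(1, 2, 4, 8); y <- c(2, 1, 5, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab$r[tab$id_a == "g1" & tab$id_b == "h1"], r_hand,
               tolerance = 1e-12)
  # antisymmetry: x against -x
  expect_equal(tab$r[tab$id_a == "g1" & tab$id_b == "neg"], -1,
               tolerance = 1e-12)
  # identity: a gene against itself
  self_tab <- pairwise_pcc(a, a, "g1", "g1")
  expect_equal(self_tab$r, 1, tolerance = 1e-12)
  # constant vector flagged undefined, not NaN-propagated
  const_rows <- tab[tab$id_a == "const", ]
  expect_false(any(const_rows$defined))
  expect_true(all(is.na(const_rows$r)))
  expect_true(all(tab$n == 4))
})

test_that("pairwise_pcc validates samples and gene presence", {
  a <- toy_matrix(1:4, "g1", sprintf("S%d", 1:4), "lncRNA")
  b <- toy_matrix(1:4, "h1", sprintf("T%d", 1:4), "mRNA")
  expect_error(pairwise_pcc(a, b), "samples")
  b2 <- toy_matrix(1:4, "h1", sprintf("S%d", 1:4), "mRNA")
  expect_error(pairwise_pcc(a, b2, genes_a = "missing"), "missing")
  a3 <- toy_matrix(1:2, "g1", sprintf("S%d", 1:2), "lncRNA")
  b3 <- toy_matrix(1:2, "h1", sprintf("S%d", 1:2), "mRNA")
  expect_error(pairwise_pcc(a3, b3), ">= 3")
})

test_that("candidate_pairs filters strictly above the threshold", {
  corr <- data.frame(id_a = c("l1", "l2", "l3", "l4"),
                     id_b = c("m1", "m2", "m3", "m4"),
                     r = c(0.5, 0.51, -0.2, NA),
                     n = 4, defined = c(TRUE, TRUE, TRUE, FALSE))
  out <- candidate_pairs(corr, 0.5)
  expect_identical(out$lncrna_id, "l2")   # r == 0.5 excluded, strict
  all_defined <- candidate_pairs(corr, -1)
  expect_identical(nrow(all_defined), 3L) # undefined never retained
})

test_that("mediation_filter enforces sign, DE membership and targeting", {
  cand <- data.frame(lncrna_id = "l1", mrna_id = "m1", r_lm = 0.8,
                     stringsAsFactors = FALSE)
  inter <- interaction_table(c("i1", "i1"), c("m1", "l1"),
                             c("mRNA", "lncRNA"))
  corr <- function(r_im, r_il) list(
    im = data.frame(id_a = "i1", id_b = "m1", r = r_im, n = 10,
                    defined = TRUE),
    il = data.frame(id_a = "i1", id_b = "l1", r = r_il, n = 10,
                    defined = TRUE))
  # positive miRNA-mRNA correlation: no triplet
  cc <- corr(0.2, -0.5)
  expect_identical(nrow(mediation_filter(cand, inter, cc$im, cc$il, "i1")), 0L)
  # miRNA not differentially expressed: no triplet
  cc <- corr(-0.5, -0.5)
  expect_identical(nrow(mediation_filter(cand, inter, cc$im, cc$il,
                                         character(0))), 0L)
  # all conditions met: exactly one triplet carrying all three correlations
  out <- mediation_filter(cand, inter, cc$im, cc$il, "i1")
  expect_identical(nrow(out), 1L)
  expect_equal(out$r_im, -0.5)
  expect_equal(out$r_lm, 0.8)
  # missing correlation entries must be reported, not skipped
  expect_error(mediation_filter(cand, inter, cc$im[0, ], cc$il, "i1"),
               "missing correlation")
})

test_that("a pair with k qualifying miRNAs yields k triplets", {
  cand <- data.frame(lncrna_id = "l1", mrna_id = "m1", r_lm = 0.9)
  inter <- interaction_table(rep(c("i1", "i2", "i3"), each = 2),
                             rep(c("m1", "l1"), 3),
                             rep(c("mRNA", "lncRNA"), 3))
  im <- data.frame(id_a = c("i1", "i2", "i3"), id_b = "m1",
                   r = c(-0.6, -0.4, 0.3), n = 10, defined = TRUE)
  il <- data.frame(id_a = c("i1", "i2", "i3"), id_b = "l1",
                   r = c(-0.7, -0.2, -0.9), n = 10, defined = TRUE)
  out <- mediation_filter(cand, inter, im, il, c("i1", "i2", "i3"))
  expect_identical(out$mirna_id, c("i1", "i2"))  # i3 fails the mRNA sign
})

test_that("pipeline triplets equal the brute-force oracle on random instances", {
  for (s in 1:20) {
    ds <- generate_dataset(synth_config(
      n_per_group = 5, n_mrna = 25, n_lncrna = 25, n_mirna = 10,
      n_de_per_class = 8, n_triplets = 4, coupling = 0.7,
      n_decoy_interactions = 60, noise_sd = 0.6, seed = s))
    got <- pipeline_triplets(ds)
    oracle <- oracle_triplets(ds$lncrna, ds$mrna, ds$mirna,
                              got$de$lncRNA$gene_id, got$de$mRNA$gene_id,
                              got$de$miRNA$gene_id, ds$interactions)
    expect_identical(triplet_key(got$triplets), triplet_key(oracle),
                     label = paste("seed", s))
  }
})

test_that("tightening either threshold never adds triplets", {
  ds <- generate_dataset(synth_config(
    n_per_group = 6, n_mrna = 30, n_lncrna = 30, n_mirna = 10,
    n_de_per_class = 10, n_triplets = 5, coupling = 0.8,
    n_decoy_interactions = 80, seed = 13))
  base <- triplet_key(pipeline_triplets(ds)$triplets)
  tighter_pcc <- triplet_key(pipeline_triplets(ds, pcc_threshold = 0.7)$triplets)
  tighter_neg <- triplet_key(pipeline_triplets(ds, neg_threshold = -0.3)$triplets)
  expect_true(all(tighter_pcc %in% base))
  expect_true(all(tighter_neg %in% base))
})

test_that("build_network integrates triplets into a deduplicated typed graph", {
  empty <- build_network(data.frame(lncrna_id = character(),
                                    mrna_id = character(),
                                    mirna_id = character()))
  s0 <- network_summary(empty)
  expect_identical(s0$n_nodes, 0L)
  expect_identical(s0$n_edges, 0L)

  one <- build_network(data.frame(lncrna_id = "l1", mrna_id = "m1",
                                  mirna_id = "i1"))
  s1 <- network_summary(one)
  expect_identical(s1$n_nodes, 3L)
  expect_identical(s1$n_edges, 3L)
  expect_identical(unname(s1$edge_kinds), c(1L, 1L, 1L))

  # two triplets sharing miRNA and mRNA: nodes {l1,l2,m1,i1} = 4,
  # edges l1-m1, l2-m1, i1-m1, i1-l1, i1-l2 = 5 (hand enumeration)
  two <- build_network(data.frame(lncrna_id = c("l1", "l2"),
                                  mrna_id = "m1", mirna_id = "i1"))
  s2 <- network_summary(two)
  expect_identical(s2$n_nodes, 4L)
  expect_identical(s2$n_edges, 5L)

  # two triplets sharing only the miRNA: 5 nodes, 6 edges
  two_b <- build_network(data.frame(lncrna_id = c("l1", "l2"),
                                    mrna_id = c("m1", "m2"),
                                    mirna_id = "i1"))
  s2b <- network_summary(two_b)
  expect_identical(s2b$n_nodes, 5L)
  expect_identical(s2b$n_edges, 6L)

  # node set is exactly the union of triplet members; counts are consistent
  expect_setequal(two$nodes$id, c("l1", "l2", "m1", "i1"))
  expect_identical(s2$n_nodes, s2$n_mirna + s2$n_mrna + s2$n_lncrna)
  expect_identical(s2$n_edges, sum(s2$edge_kinds))
  expect_identical(node_total(s2$n_mirna, s2$n_mrna, s2$n_lncrna),
                   s2$n_nodes)
})

test_that("network writers produce the documented formats", {
  net <- build_network(data.frame(lncrna_id = "l1", mrna_id = "m1",
                                  mirna_id = "i1"))
  sif <- tempfile(fileext = ".sif")
  write_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_identical(length(lines), 3L)
  expect_true(any(grepl("lnc_m_cerna", lines)))

  el <- tempfile(fileext = ".tsv")
  write_network(net, el, "edge_list")
  back <- read_edge_list(el)
  expect_equal(back[order(back$kind), ],
               net$edges[order(net$edges$kind), ],
               ignore_attr = TRUE)

  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  doc <- xml2::read_xml(gml)
  expect_identical(xml2::xml_name(doc), "graphml")
  txt <- paste(readLines(gml), collapse = "")
  expect_match(txt, "rna_class")
  expect_match(txt, "kind")

  expect_error(write_network(net, tempfile(), "dot"), "should be one of")
})
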