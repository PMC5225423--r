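test_that("co_targets is the exact intersection of target sets", {
  tm <- target_map(list(a = c("g1", "g2", "g3"), b = c("g4", "g5"),
                        c = c("g2", "g3", "g6"), d = c("g1", "g2", "g3")))
  expect_length(co_targets(tm, "a", "b"), 0)
  expect_equal(co_targets(tm, "a", "d"), c("g1", "g2", "g3"))
  expect_equal(co_targets(tm, "a", "c"), c("g2", "g3"))
  expect_error(co_targets(tm, "a", "zzz"), "zzz")
  # randomized sets vs a naive double-loop membership scan
  set.seed(12)
  for (i in 1:20) {
    s1 <- sample(sprintf("g%02d", 1:40), 15)
    s2 <- sample(sprintf("g%02d", 1:40), 15)
    tm2 <- target_map(list(p = s1, q = s2))
    brute <- character(0)
    for (g in s1) for (h in s2) if (g == h) brute <- c(brute, g)
    expect_setequal(co_targets(tm2, "p", "q"), brute)
  }
})

test_that("hypergeom_tail matches closed-form and summation oracles", {
  expect_equal(hypergeom_tail(100, 10, 5, 0), 1)
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-14)
  # large problem vs direct term-by-term log-space summation
  direct <- sum(exp(lchoose(50, 8:40) + lchoose(2000 - 50, 40 - (8:40)) -
                    lchoose(2000, 40)))
  expect_equal(hypergeom_tail(2000, 50, 40, 8), direct, tolerance = 1e-12)
  expect_error(hypergeom_tail(10, 12, 5, 2), "invalid")
  expect_error(hypergeom_tail(10, 5, 4, 5), "invalid")
})

test_that("hypergeom_tail equals full-draw enumeration for small universes", {
  for (N in c(6, 9)) for (M in c(2, 4)) for (n in c(3, 5))
    for (k in 0:min(n, M))
      expect_equal(hypergeom_tail(N, M, n, k),
                   oracle_hypergeom_enum(N, M, n, k), tolerance = 1e-12)
})

test_that("enrichment p is nonincreasing in the observed overlap", {
  p <- vapply(0:10, function(k) hypergeom_tail(500, 40, 10, k), 0)
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p > 0 & p <= 1))
})

test_that("within-pair BH never creates significance absent in raw p", {
  ids <- sprintf("m%d", 1:4)
  ann <- generate_annotation(
    annotation_config(planted_synergy_pairs = list(ids[1:2]),
                      n_pathways = 30, seed = 4), ids)
  edge <- synergy_test_pair(ann$targets, ids[1], ids[2], ann$pathways)
  expect_s3_class(edge, "synergy_edge")
  expect_true(all(edge$pathways$p_adj >= edge$pathways$p_raw - 1e-15))
})

test_that("a single pathway makes BH the identity and creates the edge", {
  tm <- target_map(list(a = c("g1", "g2", paste0("x", 1:8)),
                        b = c("g1", "g2", paste0("y", 1:8))))
  # universe = 18 genes, co-targets {g1,g2}; one 2-gene pathway fully hit
  pw <- list(only = c("g1", "g2"))
  edge <- synergy_test_pair(tm, "a", "b", pw)
  raw <- hypergeom_tail(18, 2, 2, 2)
  expect_equal(edge$pathways$p_raw, raw, tolerance = 1e-12)
  expect_equal(edge$pathways$p_adj, raw, tolerance = 1e-12)
  expect_equal(edge$co_target_count, 2)
})

test_that("pairs with empty co-targets yield no edge", {
  tm <- target_map(list(a = paste0("x", 1:5), b = paste0("y", 1:5)))
  expect_null(synergy_test_pair(tm, "a", "b", list(pw = c("x1", "y1"))))
})

test_that("a planted pair is strongly significant", {
  ids <- c("mirA", "mirB")
  ann <- generate_annotation(
    annotation_config(n_genes = 5000, targets_per_mirna = 50,
                      n_pathways = 10, pathway_size = 20,
                      planted_synergy_pairs = list(ids),
                      co_target_overlap = 10, seed = 6), ids)
  edge <- synergy_test_pair(ann$targets, "mirA", "mirB", ann$pathways)
  expect_s3_class(edge, "synergy_edge")
  expect_lt(edge$pathways$p_raw[1], 1e-6)
  expect_equal(edge$pathways$pathway[1], ann$truth$pathway[1])
})

test_that("the network recovers exactly the planted synergy edges", {
  sim <- generate_expression(sim_config(n_mirnas = 80, n_de = 10,
                                        corr_blocks = list(), seed = 15))
  x <- preprocess_expression(sim$expr)
  res <- filter_demirs(differential_test(x))
  demirs <- res$mirna_id[res$passes]
  planted <- list(demirs[1:2], demirs[3:4], demirs[5:6])
  ann <- generate_annotation(
    annotation_config(planted_synergy_pairs = planted, seed = 15), demirs)
  pr <- pairwise_ce(x, demirs)
  net <- build_network(pr, ann$targets, ann$pathways)
  key <- function(d) paste(d$mirna_a, d$mirna_b)
  expect_setequal(key(net$edges), key(ann$truth))
  expect_equal(igraph::vcount(net$graph), 6)
  expect_equal(net$n_positive + net$n_negative, 3)
  expect_true(all(net$edges$sign_class %in% c("positive", "negative")))
})

test_that("the edge set is invariant to candidate-pair order", {
  ids <- sprintf("m%d", 1:6)
  ann <- generate_annotation(
    annotation_config(planted_synergy_pairs = list(ids[1:2], ids[3:4]),
                      seed = 20), ids)
  cmb <- combn(ids, 2)
  pairs <- data.frame(mirna_a = cmb[1, ], mirna_b = cmb[2, ],
                      ce = seq(-0.7, 0.7, length.out = ncol(cmb)),
                      stringsAsFactors = FALSE)
  n1 <- build_network(pairs, ann$targets, ann$pathways)
  n2 <- build_network(pairs[rev(seq_len(nrow(pairs))), ],
                      ann$targets, ann$pathways)
  expect_identical(n1$edges, n2$edges)
})

test_that("no surviving candidate yields an empty network with a warning", {
  tm <- target_map(list(a = paste0("x", 1:5), b = paste0("y", 1:5)))
  pairs <- data.frame(mirna_a = "a", mirna_b = "b", ce = 0.5,
                      stringsAsFactors = FALSE)
  expect_warning(net <- build_network(pairs, tm, list(pw = c("x1", "x2"))),
                 "no synergy edge")
  expect_equal(nrow(net$edges), 0)
  expect_equal(igraph::vcount(net$graph), 0)
})
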