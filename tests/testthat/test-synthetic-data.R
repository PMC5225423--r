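test_that("generator is seed-deterministic and respects dimensions", {
  cfg <- sim_config(n_case = 10, n_control = 9, n_mirnas = 60, n_de = 6,
                    missing_frac = 0.05, seed = 11)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$expr$values), c(60L, 19L))
  expect_equal(sum(a$expr$groups == "case"), 10L)
  expect_equal(sum(a$expr$groups == "control"), 9L)
  expect_true(all(a$truth$de$mirna_id %in% rownames(a$expr$values)))
  c2 <- generate_expression(sim_config(n_case = 10, n_control = 9,
                                       n_mirnas = 60, n_de = 6,
                                       missing_frac = 0.05, seed = 12))
  expect_false(identical(a$expr$values, c2$expr$values))
})

test_that("planted rows shift group means by the configured effect", {
  cfg <- sim_config(n_case = 200, n_control = 200, n_mirnas = 50,
                    n_de = 10, effect_log2 = 1.2, corr_blocks = list(),
                    missing_frac = 0, seed = 3)
  sim <- generate_expression(cfg)
  v <- sim$expr$values
  grp <- sim$expr$groups
  dm <- rowMeans(v[, grp == "case"]) - rowMeans(v[, grp == "control"])
  planted <- sim$truth$de
  # observed shifts ~ N(effect, noise_sd * sqrt(2/200)) = N(+-1.2, 0.1)
  expect_equal(dm[planted$mirna_id], setNames(planted$effect,
                                              planted$mirna_id),
               tolerance = 0.35)
  null_ids <- setdiff(rownames(v), planted$mirna_id)
  expect_lt(max(abs(dm[null_ids])), 0.5)
})

test_that("correlation blocks reach their nominal CE (loading squared)", {
  # direct simulation at 1000 samples pins the expected-CE algebra
  cfg <- sim_config(n_case = 500, n_control = 500, n_mirnas = 10,
                    n_de = 0, effect_log2 = 0,
                    corr_blocks = list(c(3, 0.95)), missing_frac = 0,
                    noise_sd = 0.3, seed = 5)
  sim <- generate_expression(cfg)
  mem <- sim$truth$blocks[[1]]
  expect_length(mem, 3)
  cm <- cor(t(sim$expr$values[mem, ]))
  offdiag <- cm[upper.tri(cm)]
  expect_true(all(offdiag > 0.8))
  expect_equal(offdiag, rep(0.95^2, 3), tolerance = 0.04)
  expect_equal(sim$truth$block_pairs$nominal_ce, rep(0.95^2, 3))
})

test_that("null configuration gives nominal differential test size", {
  cfg <- sim_config(n_mirnas = 1000, n_de = 0, effect_log2 = 0,
                    corr_blocks = list(), missing_frac = 0, seed = 21)
  sim <- generate_expression(cfg)
  res <- differential_test(preprocess_expression(sim$expr), "welch_t")
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("differential recall is monotone in effect size on average", {
  recall_at <- function(effect) {
    mean(vapply(1:20, function(s) {
      sim <- generate_expression(sim_config(
        n_case = 20, n_control = 20, n_mirnas = 200, n_de = 10,
        effect_log2 = effect, corr_blocks = list(), missing_frac = 0,
        seed = 100 + s))
      res <- filter_demirs(differential_test(
        preprocess_expression(sim$expr), "welch_t"))
      mean(sim$truth$de$mirna_id %in% res$mirna_id[res$passes])
    }, 0))
  }
  r <- vapply(c(0.5, 1.0, 1.8), recall_at, 0)
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], r[1])
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_case = 0), "positive")
  expect_error(sim_config(n_de = 50, n_mirnas = 40), "n_de")
  expect_error(sim_config(corr_blocks = list(c(3, 1.2))), "loading")
  expect_error(sim_config(corr_blocks = list(c(1, 0.5))), "size")
  expect_error(sim_config(n_mirnas = 5, n_de = 0,
                          corr_blocks = list(c(3, 0.5), c(3, 0.5))),
               "block sizes")
  expect_error(sim_config(missing_frac = 1), "missing_frac")
})

test_that("annotation plants exact co-target overlaps inside one pathway", {
  ids <- sprintf("mir-%02d", 1:8)
  cfg <- annotation_config(n_genes = 5000, targets_per_mirna = 50,
                           n_pathways = 20, pathway_size = 20,
                           planted_synergy_pairs = list(ids[1:2], ids[3:4]),
                           co_target_overlap = 10, seed = 2)
  ann <- generate_annotation(cfg, ids)
  for (i in 1:2) {
    pr <- ann$truth[i, ]
    co <- co_targets(ann$targets, pr$mirna_a, pr$mirna_b)
    expect_length(co, 10)
    expect_true(all(co %in% ann$pathways[[pr$pathway]]))
  }
  expect_true(all(lengths(ann$targets) == 50))
  # zero overlap -> empty co-target set
  cfg0 <- annotation_config(planted_synergy_pairs = list(ids[1:2]),
                            co_target_overlap = 0, seed = 2)
  ann0 <- generate_annotation(cfg0, ids)
  expect_length(co_targets(ann0$targets, ids[1], ids[2]), 0)
  # determinism
  expect_identical(unclass(generate_annotation(cfg, ids)$targets),
                   unclass(generate_annotation(cfg, ids)$targets))
})

test_that("invalid annotation configs are rejected", {
  expect_error(annotation_config(co_target_overlap = 30, pathway_size = 20),
               "pathway_size")
  expect_error(annotation_config(co_target_overlap = 60,
                                 targets_per_mirna = 50),
               "targets_per_mirna")
  expect_error(annotation_config(
    planted_synergy_pairs = list(c("a", "b"), c("b", "c"))),
    "disjoint")
  expect_error(generate_annotation(
    annotation_config(planted_synergy_pairs = list(c("a", "b"))),
    mirna_ids = c("a", "x")), "not in mirna_ids")
})

test_that("unplanted pairs pass the synergy screen only at chance level", {
  # no planted structure: BH-adjusted pathway enrichment across random
  # target draws should essentially never create an edge
  n_edges <- vapply(1:5, function(s) {
    ids <- sprintf("m%02d", 1:8)
    ann <- generate_annotation(
      annotation_config(n_genes = 5000, targets_per_mirna = 25,
                        n_pathways = 40, seed = 300 + s), ids)
    cnt <- 0L
    cmb <- combn(ids, 2)
    for (j in seq_len(ncol(cmb)))
      if (!is.null(synergy_test_pair(ann$targets, cmb[1, j], cmb[2, j],
                                     ann$pathways)))
        cnt <- cnt + 1L
    cnt / ncol(cmb)
  }, 0)
  expect_lte(mean(n_edges), 0.05)
})
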