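make_fc_table <- function(type, fc_exp, fc_prop) {
  data.frame(type = type, gene = sprintf("g%03d", seq_along(fc_exp)),
             fc_exp = fc_exp, fc_prop = fc_prop, stringsAsFactors = FALSE)
}

test_that("alteration_score evaluates the score formula", {
  # one unchanged gene contributes log2(1*1 + 1) = 1
  r1 <- alteration_score(make_fc_table("MG", 1, 1))
  expect_equal(r1$score, 1)
  # (2,2) and (1,1): log2(5) + log2(2)
  r2 <- alteration_score(make_fc_table("MG", c(2, 1), c(2, 1)))
  expect_equal(r2$score, log2(5) + log2(2))
  # contributions sum to the score and are nonnegative
  ctr <- attr(r2, "contributions")
  expect_equal(sum(ctr$contribution), r2$score)
  expect_true(all(ctr$contribution >= 0))
})

test_that("alteration_score equals the brute-force oracle", {
  set.seed(11)
  for (rep in 1:20) {
    fe <- exp(rnorm(30, sd = 0.8))
    fp <- exp(rnorm(30, sd = 0.4))
    r <- alteration_score(make_fc_table("t", fe, fp))
    expect_equal(r$score, acscore_oracle(fe, fp), tolerance = 1e-12)
  }
})

test_that("no-change identity: score equals signature size", {
  for (n in c(1, 7, 50)) {
    r <- alteration_score(make_fc_table("t", rep(1, n), rep(1, n)))
    expect_equal(r$score, n)
    expect_equal(r$score_per_gene, 1)
  }
})

test_that("score is strictly monotone in each fold change", {
  set.seed(12)
  fe <- exp(rnorm(10)); fp <- exp(rnorm(10))
  base <- alteration_score(make_fc_table("t", fe, fp))$score
  for (i in c(1, 5, 10)) {
    fe2 <- fe; fe2[i] <- fe[i] * 1.3
    expect_gt(alteration_score(make_fc_table("t", fe2, fp))$score, base)
    fp2 <- fp; fp2[i] <- fp[i] * 1.3
    expect_gt(alteration_score(make_fc_table("t", fe, fp2))$score, base)
  }
})

test_that("symmetric mode scores down-regulation above baseline", {
  lit <- alteration_score(make_fc_table("t", 0.25, 1))
  sym <- alteration_score(make_fc_table("t", 0.25, 1), symmetric = TRUE)
  expect_lt(lit$score, 1)  # literal form: strong down-regulation < 1
  expect_equal(sym$score, log2(4 * 1 + 1))
})

test_that("alteration_score rejects nonpositive fold changes", {
  expect_error(alteration_score(make_fc_table("t", c(1, 0), c(1, 1))),
               "non-positive")
  expect_error(alteration_score(make_fc_table("t", 1, -2)), "non-positive")
})

test_that("compute_fold_changes matches a hand-computed 4-vs-4 toy", {
  # type T: 4 stress cells and 4 control cells, 2 genes
  counts <- rbind(c(4, 0), c(2, 0), c(2, 0), c(4, 0),   # stress
                  c(1, 0), c(1, 0), c(1, 0), c(1, 0))   # control
  meta <- data.frame(cell_id = paste0("c", 1:8), donor = "d1",
                     region = "macula",
                     condition = rep(c("stress", "control"), each = 4),
                     type = "T", stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = c("gA", "gB"), is_mito = FALSE,
                   is_hemoglobin = FALSE)
  s <- expression_study(counts, meta, gm)
  # use the counts themselves as "normalized" values for hand arithmetic
  norm <- Matrix::Matrix(counts, sparse = TRUE,
                         dimnames = list(meta$cell_id, gm$gene_id))
  sigs <- list(T = c("gA", "gB"))
  fc <- compute_fold_changes(norm, s$counts, meta, sigs,
                             eps = 0.01, delta = 0.001)
  # gA: mean stress 3, mean control 1 -> (3.01)/(1.01); props 1/1
  expect_equal(fc$fc_exp[fc$gene == "gA"], 3.01 / 1.01)
  expect_equal(fc$fc_prop[fc$gene == "gA"], 1.001 / 1.001)
  # gB undetected everywhere -> eps/eps and delta/delta = 1 exactly
  expect_equal(fc$fc_exp[fc$gene == "gB"], 1)
  expect_equal(fc$fc_prop[fc$gene == "gB"], 1)
})

test_that("compute_fold_changes drops types missing a condition", {
  counts <- matrix(1, 4, 2)
  meta <- data.frame(cell_id = paste0("c", 1:4), donor = "d1",
                     region = "macula", condition = "control",
                     type = "T", stringsAsFactors = FALSE)
  norm <- Matrix::Matrix(counts, sparse = TRUE,
                         dimnames = list(meta$cell_id, c("gA", "gB")))
  expect_warning(
    fc <- compute_fold_changes(norm, norm, meta, list(T = "gA")),
    "lacks a condition")
  expect_equal(nrow(fc), 0)
})

test_that("select_signature_genes recovers planted markers", {
  g <- generate_study(two_type_config(17, n_per_group = 200))
  norm <- normalize_log1p(g$study)
  sigs <- select_signature_genes(norm, g$study$cell_meta)
  for (tp in c("A", "B")) {
    planted <- g$truth$markers[[tp]]
    expect_gte(mean(planted %in% sigs[[tp]]$gene), 0.9)
  }
})

test_that("signature cap keeps the largest fold changes", {
  g <- generate_study(two_type_config(18, n_per_group = 150))
  norm <- normalize_log1p(g$study)
  full <- select_signature_genes(norm, g$study$cell_meta, cap = 1000)
  capped <- select_signature_genes(norm, g$study$cell_meta, cap = 10)
  expect_equal(nrow(capped$A), 10)
  ord <- order(-full$A$log2fc, full$A$gene)
  expect_identical(capped$A$gene, full$A$gene[ord][1:10])
})

test_that("a type without enriched genes gets an empty signature", {
  # marker_fold kept small: a strong marker program in type A shifts the
  # library-size composition enough to make A-absent genes look enriched
  # in B, which is real compositional behavior but not what this test is
  # about
  cfg <- generator_config(
    n_genes = 200, n_cells_per_group = 60, n_donors = 2,
    cell_types = data.frame(type = c("A", "B"), n_markers = c(10L, 0L),
                            prop_macula = c(0.5, 0.5),
                            prop_periphery = c(0.5, 0.5)),
    marker_fold = 2, stress_programs = no_programs(), seed = 3)
  g <- generate_study(cfg)
  norm <- normalize_log1p(g$study)
  sigs <- select_signature_genes(norm, g$study$cell_meta)
  expect_equal(nrow(sigs$B), 0)
  fc <- compute_fold_changes(norm, g$study$counts, g$study$cell_meta,
                             sigs)
  sc <- alteration_score(fc)
  expect_false("B" %in% sc$type)  # empty signature scores nothing
})

test_that("tiny types are excluded from signature selection", {
  g <- generate_study(two_type_config(19, n_per_group = 30))
  meta <- g$study$cell_meta
  meta$type[meta$type == "B"] <- "A"
  meta$type[1:2] <- "B"
  meta$condition[1:2] <- "control"
  norm <- normalize_log1p(g$study)
  expect_warning(sigs <- select_signature_genes(norm, meta), "<3 control")
  expect_false("B" %in% names(sigs))
})

test_that("acscore_null_band is deterministic and brackets null data", {
  g <- generate_study(generator_config(
    n_genes = 200, n_cells_per_group = 80, n_donors = 2,
    cell_types = data.frame(type = c("A", "B"), n_markers = c(25L, 25L),
                            prop_macula = c(0.5, 0.5),
                            prop_periphery = c(0.5, 0.5)),
    stress_programs = no_programs(), seed = 23))
  norm <- normalize_log1p(g$study)
  sigs <- select_signature_genes(norm, g$study$cell_meta)
  band <- acscore_null_band(g$study, sigs, n_perm = 40, seed = 5)
  band2 <- acscore_null_band(g$study, sigs, n_perm = 40, seed = 5)
  expect_identical(band, band2)
  # null data: observed score inside the 95% band
  expect_true(all(band$observed >= band$q025 & band$observed <= band$q975))
  # identity permutation puts the observed score in the null set
  band3 <- acscore_null_band(g$study, sigs, n_perm = 20, seed = 5,
                             include_identity = TRUE)
  perm <- attr(band3, "perm_scores")
  for (tp in band3$type)
    expect_true(any(abs(perm[, tp] -
                          band3$observed[band3$type == tp]) < 1e-12))
  expect_error(acscore_null_band(g$study, sigs, n_perm = 5), "n_perm")
})
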