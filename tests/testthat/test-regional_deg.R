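test_that("wilcoxon p-values equal the exact enumeration oracle", {
  set.seed(41)
  for (rep in 1:30) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    # mix of continuous values and ties
    x <- if (rep %% 2) rnorm(nA + nB) else sample(0:3, nA + nB, TRUE)
    mat <- matrix(x, ncol = 1)
    p <- wilcoxon_pvalues(mat, seq_len(nA), nA + seq_len(nB))
    expect_equal(p, wilcoxon_oracle(x[seq_len(nA)], x[nA + seq_len(nB)]),
                 tolerance = 1e-12)
  }
})

test_that("large-sample wilcoxon path agrees with stats::wilcox.test", {
  set.seed(42)
  xA <- rnorm(30); xB <- rnorm(25, mean = 0.5)
  p <- wilcoxon_pvalues(matrix(c(xA, xB), ncol = 1), 1:30, 31:55,
                        exact_max = 0)
  ref <- stats::wilcox.test(xA, xB, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-9)
})

test_that("differential_expression gates on min.pct and logfc", {
  set.seed(43)
  # gene 1 detected in 10% of A and 15% of B -> never tested
  n <- 40
  g1 <- c(rbinom(n, 1, 0.10), rbinom(n, 1, 0.15))
  g2 <- c(rnorm(n, 4), rnorm(n, 1))  # strong, well-detected difference
  norm <- Matrix::Matrix(abs(cbind(g1, g2)), sparse = TRUE)
  colnames(norm) <- c("sparse_gene", "strong_gene")
  rownames(norm) <- sprintf("c%02d", 1:(2 * n))
  deg <- differential_expression(norm, 1:n, n + 1:n)
  expect_false("sparse_gene" %in% deg$gene)
  expect_true("strong_gene" %in% deg$gene)
  expect_true(all(deg$p_adj >= deg$p))
  expect_error(differential_expression(norm, integer(0), 1:n), "empty")
})

test_that("identical groups yield no significant genes", {
  g <- generate_study(two_type_config(44, n_per_group = 60))
  norm <- normalize_log1p(g$study)
  half <- nrow(norm) / 2
  # A and B are copies of the same cells
  dup <- rbind(norm[1:half, ], norm[1:half, ])
  rownames(dup) <- sprintf("c%03d", 1:(2 * half))
  deg <- differential_expression(dup, 1:half, half + 1:half,
                                 logfc_threshold = 0)
  if (nrow(deg) > 0) expect_true(all(deg$p_adj >= 0.05))
})

test_that("BH adjustment preserves raw-p order", {
  set.seed(45)
  g <- generate_study(periph_only_config(45, n_per_group = 60,
                                         n_genes = 300))
  norm <- normalize_log1p(g$study)
  m <- g$study$cell_meta
  deg <- differential_expression(norm, which(m$condition == "stress"),
                                 which(m$condition == "control"))
  ord <- order(deg$p)
  expect_true(all(diff(deg$p_adj[ord]) >= -1e-15))
})

test_that("categorize_regional applies the 1.5-fold rule", {
  deg <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    fc = c(1.6, 1.4, 1 / 1.6, 1 / 1.4, 2.0),
                    p_adj = c(0.01, 0.01, 0.01, 0.01, 0.5))
  cat <- categorize_regional(deg)
  expect_equal(cat$category, c("m-HX", "none", "p-HX", "none", "none"))
  # disjointness on random tables
  set.seed(46)
  rnd <- data.frame(gene = sprintf("g%03d", 1:200),
                    fc = exp(rnorm(200)), p_adj = runif(200))
  rc <- categorize_regional(rnd)
  expect_equal(sum(rc$category == "m-HX" & rc$category == "p-HX"), 0)
  # pure function: permutation invariance over genes
  perm <- sample(200)
  rc2 <- categorize_regional(rnd[perm, ])
  expect_identical(rc2$category, rc$category[perm])
})

test_that("flag_light_induced applies the 9% rule in both directions", {
  deg <- data.frame(gene = c("a", "b", "c", "d"),
                    fc = c(1.10, 1.05, 0.90, 0.92),
                    p_adj = c(0.01, 0.01, 0.01, 0.01))
  fl <- flag_light_induced(deg)
  expect_equal(fl$flag, c("up", "none", "down", "none"))
  # not significant -> never flagged
  deg$p_adj <- 0.5
  expect_true(all(flag_light_induced(deg)$flag == "none"))
})

test_that("top_k_by_fold_change saturates and breaks ties as documented", {
  deg <- data.frame(
    gene = c("g01", "g02", "g03", "g04", "g05", "g06", "g07", "g08",
             "g09", "g10"),
    fc = c(3, 3, 2.5, 2, 0.5, 0.4, 0.4, 1.2, 5, 0.9),
    p_adj = c(0.02, 0.01, 0.01, 0.01, 0.01, 0.02, 0.01, 0.5, 0.5, 0.01))
  # hand ranking, A-high significant: g01..g04 (g09 not significant);
  # g01/g02 tie on fc -> smaller p_adj (g02) first
  expect_identical(top_k_by_fold_change(deg, 3, "A-high"),
                   c("g02", "g01", "g03"))
  # saturation: fewer significant than k
  expect_identical(top_k_by_fold_change(deg, 40, "A-high"),
                   c("g02", "g01", "g03", "g04"))
  # B-high side: smallest fc first; g06/g07 tie -> smaller p_adj (g07)
  expect_identical(top_k_by_fold_change(deg, 3, "B-high"),
                   c("g07", "g06", "g05"))
})

test_that("marker_normalized_expression computes group ratios", {
  vals <- log1p(rbind(c(2, 4), c(2, 4), c(3, 0), c(3, 0)))
  norm <- Matrix::Matrix(vals, sparse = TRUE,
                         dimnames = list(paste0("c", 1:4),
                                         c("target", "ref")))
  out <- marker_normalized_expression(norm, "target", "ref",
                                      list(g1 = 1:2))
  expect_equal(out$ratio, 0.5)
  expect_warning(
    out2 <- marker_normalized_expression(norm, "target", "ref",
                                         list(g1 = 1:2, g2 = 3:4)),
    "zero")
  expect_true(is.na(out2$ratio[out2$group == "g2"]))
  expect_error(marker_normalized_expression(norm, "target", "nope",
                                            list(g = 1:2)), "absent")
})

test_that("deg_set_overlap enumerates all Venn regions", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c")
  ov <- deg_set_overlap(sets)
  get <- function(r) ov$count[ov$region == r]
  expect_equal(get("A"), 1)        # {a}
  expect_equal(get("B"), 1)        # {d}
  expect_equal(get("C"), 0)
  expect_equal(get("A&B"), 1)      # {b}
  expect_equal(get("A&C"), 0)
  expect_equal(get("B&C"), 0)
  expect_equal(get("A&B&C"), 1)    # {c}
  # disjoint and identical sets
  ov2 <- deg_set_overlap(list(X = "x", Y = "y"))
  expect_equal(ov2$count[ov2$region == "X&Y"], 0)
  ov3 <- deg_set_overlap(list(X = c("x", "y"), Y = c("x", "y")))
  expect_equal(ov3$count[ov3$region == "X&Y"], 2)
  expect_equal(ov3$count[ov3$region == "X"], 0)
  expect_error(deg_set_overlap(list(A = "a")), "2 sets")
})

test_that("annotate_by_markers labels forced cases and leaves ties", {
  norm <- Matrix::Matrix(rbind(c(5, 5, 0, 0),
                               c(0, 0, 5, 5),
                               c(5, 0, 5, 0)), sparse = TRUE)
  colnames(norm) <- c("a1", "a2", "b1", "b2")
  rownames(norm) <- c("cellA", "cellB", "cellTie")
  markers <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  lab <- annotate_by_markers(norm, markers)
  expect_equal(unname(lab[1:2]), c("A", "B"))
  expect_true(is.na(lab[3]))  # exact tie -> unassigned
  expect_error(annotate_by_markers(norm, list(A = character(0))),
               "non-empty")
})

test_that("annotate_by_markers agrees with generator ground truth", {
  cfg <- generator_config(
    n_genes = 400, n_cells_per_group = 100, n_donors = 2,
    cell_types = data.frame(
      type = c("t1", "t2", "t3", "t4", "t5"),
      n_markers = rep(15L, 5),
      prop_macula = rep(0.2, 5), prop_periphery = rep(0.2, 5)),
    stress_programs = no_programs(), seed = 47)
  g <- generate_study(cfg)
  norm <- normalize_log1p(g$study)
  lab <- annotate_by_markers(norm, g$truth$markers)
  expect_gte(mean(lab == g$study$cell_meta$type, na.rm = TRUE), 0.95)
  expect_gte(mean(!is.na(lab)), 0.9)
})
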