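# shared fixtures: all data built in code, no files

# 5-cell, 4-gene toy with hand-checkable QC metrics; gene 3 mito, gene 4 hb
toy_study <- function() {
  counts <- rbind(c(5, 0, 2, 0),   # 3 features, total 7,  mito 2/7
                  c(0, 0, 0, 0),   # all-zero cell
                  c(1, 1, 1, 1),   # 4 features, total 4,  mito 1/4, hb 1/4
                  c(10, 10, 0, 0), # 2 features, total 20, mito 0
                  c(0, 0, 3, 1))   # 2 features, total 4,  mito 3/4, hb 1/4
  cell_meta <- data.frame(
    cell_id = paste0("c", 1:5),
    donor = c("d1", "d1", "d2", "d2", "d1"),
    region = c("macula", "macula", "periphery", "periphery", "macula"),
    condition = c("control", "stress", "control", "stress", "control"),
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = paste0("g", 1:4),
                          is_mito = c(FALSE, FALSE, TRUE, FALSE),
                          is_hemoglobin = c(FALSE, FALSE, FALSE, TRUE),
                          stringsAsFactors = FALSE)
  expression_study(counts, cell_meta, gene_meta)
}

no_programs <- function() {
  data.frame(type = character(), region = character(),
             n_genes = integer(), fold = numeric())
}

# two tight, well-separated types, no stress response
two_type_config <- function(seed, n_per_group = 150, n_genes = 400) {
  generator_config(
    n_genes = n_genes, n_cells_per_group = n_per_group, n_donors = 2,
    cell_types = data.frame(type = c("A", "B"), n_markers = c(40L, 40L),
                            prop_macula = c(0.5, 0.5),
                            prop_periphery = c(0.5, 0.5)),
    stress_programs = no_programs(),
    marker_fold = 16, nb_dispersion = 0.2,
    library_size_lognormal = c(0, 0.15), seed = seed)
}

# default retina-like world with a stress program only in peripheral MG
periph_mg_config <- function(seed, n_per_group = 500, n_genes = 800,
                             fold = 2) {
  generator_config(
    n_genes = n_genes, n_cells_per_group = n_per_group, n_donors = 4,
    stress_programs = data.frame(type = "MG", region = "periphery",
                                 n_genes = 50L, fold = fold),
    seed = seed)
}

# stress programs only in the periphery (MG and rods)
periph_only_config <- function(seed, n_per_group = 500, n_genes = 800) {
  generator_config(
    n_genes = n_genes, n_cells_per_group = n_per_group, n_donors = 4,
    stress_programs = data.frame(type = c("MG", "rod"),
                                 region = "periphery",
                                 n_genes = c(50L, 50L),
                                 fold = c(2, 1.8)),
    seed = seed)
}

# independent brute-force Alteration Score: plain loop, no vectorization
acscore_oracle <- function(fc_exp, fc_prop) {
  total <- 0
  for (i in seq_along(fc_exp))
    total <- total + log2(fc_exp[i] * fc_prop[i] + 1)
  total
}

# independent exact Wilcoxon rank-sum enumeration via bitmask subsets
wilcoxon_oracle <- function(xA, xB) {
  nA <- length(xA); nB <- length(xB); N <- nA + nB
  r <- rank(c(xA, xB))
  mu <- nA * (N + 1) / 2
  w_obs <- sum(r[seq_len(nA)])
  hits <- 0L; total <- 0L
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(N)]
    if (sum(bits) != nA) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}
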