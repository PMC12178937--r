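#' Configuration for the synthetic study generator
#'
#' Describes the statistical world the generator draws from: gene-level
#' negative-binomial counts with log-normal library sizes, around ten cell
#' types with marker genes and region-specific composition, gene-wise donor
#' factors, flagged mitochondrial/hemoglobin genes, and stress-response gene
#' programs whose fold change can differ by cell type and region. Defaults
#' emulate a paired two-region, two-condition retinal explant design with
#' four donors: the strongest planted responses sit in peripheral Muller
#' glia and rods, with weaker macular programs in rods and amacrine cells.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_group cells per (region x condition) group.
#' @param n_donors number of donors; cells are split evenly across donors
#'   within each group.
#' @param cell_types data.frame with columns `type`, `n_markers`,
#'   `prop_macula`, `prop_periphery`; per-region proportions must each sum
#'   to 1. Defaults to ten retinal cell types with a cone-enriched macula
#'   and rod-dominated periphery.
#' @param nb_dispersion negative-binomial dispersion (1/size); variance is
#'   mu + dispersion * mu^2.
#' @param library_size_lognormal length-2 numeric `(meanlog, sdlog)` of the
#'   per-cell size factor.
#' @param mito_gene_fraction,hb_gene_fraction fractions of genes flagged as
#'   mitochondrial / hemoglobin.
#' @param marker_fold multiplicative mean shift of a marker gene in its own
#'   type.
#' @param donor_sd sdlog of the gene-wise log-normal donor factor.
#' @param stress_programs data.frame with columns `type`, `region`,
#'   `n_genes`, `fold`: in stressed cells of that type and region, the
#'   program's genes have their mean multiplied by `fold`.
#' @param stress_on_markers fraction of each stress program drawn from the
#'   target type's own marker genes (the rest come from unassigned genes).
#'   A stress response remodels the responding type's expression program,
#'   so signature-based scoring can only see it if the program and the
#'   signature overlap.
#' @param doublet_rate fraction of cells replaced by synthetic doublets at
#'   generation time (see [inject_doublets()] to do this separately).
#' @param n_qc_violators number of cells planted with an inflated
#'   mitochondrial fraction so QC has something to remove.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the config.
#' @return a validated `generator_config` object.
#' @export
generator_config <- function(n_genes = 1500,
                             n_cells_per_group = 500,
                             n_donors = 4,
                             cell_types = default_cell_types(),
                             nb_dispersion = 0.5,
                             library_size_lognormal = c(0, 0.3),
                             mito_gene_fraction = 0.05,
                             hb_gene_fraction = 0.01,
                             marker_fold = 8,
                             donor_sd = 0.1,
                             stress_programs = default_stress_programs(),
                             stress_on_markers = 0.5,
                             doublet_rate = 0,
                             n_qc_violators = 0,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_group = as.integer(n_cells_per_group),
              n_donors = as.integer(n_donors),
              cell_types = cell_types,
              nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              mito_gene_fraction = mito_gene_fraction,
              hb_gene_fraction = hb_gene_fraction,
              marker_fold = marker_fold,
              donor_sd = donor_sd,
              stress_programs = stress_programs,
              stress_on_markers = stress_on_markers,
              doublet_rate = doublet_rate,
              n_qc_violators = as.integer(n_qc_violators),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1 || n_cells_per_group < 1 || n_donors < 1)
      stop_regioglia("n_genes, n_cells_per_group and n_donors must be >= 1")
    need <- c("type", "n_markers", "prop_macula", "prop_periphery")
    miss <- setdiff(need, names(cell_types))
    if (length(miss))
      stop_regioglia("cell_types lacks column(s): %s",
                     paste(miss, collapse = ", "))
    if (nrow(cell_types) == 0) stop_regioglia("cell_types is empty")
    if (anyDuplicated(cell_types$type))
      stop_regioglia("duplicate cell type names")
    for (col in c("prop_macula", "prop_periphery")) {
      p <- cell_types[[col]]
      if (any(p < 0 | p > 1)) stop_regioglia("%s outside [0, 1]", col)
      if (abs(sum(p) - 1) > 1e-8)
        stop_regioglia("%s must sum to 1 (got %.6f)", col, sum(p))
    }
    if (nb_dispersion <= 0) stop_regioglia("nb_dispersion must be > 0")
    if (mito_gene_fraction < 0 || mito_gene_fraction > 1 ||
        hb_gene_fraction < 0 || hb_gene_fraction > 1)
      stop_regioglia("gene fractions must lie in [0, 1]")
    if (nrow(stress_programs) > 0) {
      if (any(stress_programs$fold <= 0))
        stop_regioglia("stress program fold multipliers must be > 0")
      bad <- setdiff(stress_programs$type, cell_types$type)
      if (length(bad))
        stop_regioglia("stress program references unknown type(s): %s",
                       paste(bad, collapse = ", "))
      bad <- setdiff(stress_programs$region, c("macula", "periphery"))
      if (length(bad))
        stop_regioglia("stress program references unknown region(s): %s",
                       paste(bad, collapse = ", "))
    }
    if (stress_on_markers < 0 || stress_on_markers > 1)
      stop_regioglia("stress_on_markers must lie in [0, 1]")
    if (doublet_rate < 0 || doublet_rate >= 1)
      stop_regioglia("doublet_rate must lie in [0, 1)")
  })
  invisible(cfg)
}

#' Default ten-type retinal composition
#'
#' Macula is cone- and interneuron-enriched; the periphery is rod-dominated,
#' with Muller glia the second most abundant type in both regions.
#'
#' @return data.frame accepted by the `cell_types` argument of
#'   [generator_config()].
#' @export
default_cell_types <- function() {
  data.frame(
    type = c("rod", "MG", "cone", "bipolar", "amacrine", "horizontal",
             "RGC", "astrocyte", "microglia", "endothelial"),
    n_markers = c(20L, 20L, 15L, 15L, 12L, 10L, 10L, 10L, 10L, 10L),
    prop_macula = c(0.30, 0.20, 0.14, 0.12, 0.08, 0.04, 0.05,
                     0.03, 0.02, 0.02),
    prop_periphery = c(0.45, 0.22, 0.05, 0.10, 0.05, 0.04, 0.03,
                        0.03, 0.02, 0.01),
    stringsAsFactors = FALSE)
}

#' Default planted stress programs
#'
#' Strong peripheral programs in Muller glia and rods, weaker macular
#' programs in rods and amacrine cells, mirroring a periphery-dominant
#' light-stress response.
#'
#' @return data.frame accepted by the `stress_programs` argument of
#'   [generator_config()].
#' @export
default_stress_programs <- function() {
  data.frame(
    type = c("MG", "rod", "rod", "amacrine"),
    region = c("periphery", "periphery", "macula", "macula"),
    n_genes = c(50L, 50L, 30L, 20L),
    fold = c(2.0, 1.8, 1.4, 1.6),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic expression study with ground truth
#'
#' Draws counts gene-wise from a negative binomial whose mean combines a
#' log-normal baseline, a multiplicative marker boost in the gene's own
#' type, a stress-program multiplier in stressed cells of the targeted
#' (type, region), a gene-wise donor factor and a per-cell log-normal
#' library-size factor. The result is bit-identical for a given config.
#'
#' @param config a [generator_config()].
#' @return list with elements `study` (an `expression_study`, cell types in
#'   `cell_meta$type`) and `truth` (list: `markers` per type, `stress_truth`
#'   table of planted fold changes, `doublets`, `cell_types`,
#'   `qc_violators`, `base_means`).
#' @export
generate_study <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  G <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(G))
  base_mean <- stats::rlnorm(G, meanlog = log(0.3), sdlog = 1.2)

  n_flag <- round(c(cfg$mito_gene_fraction, cfg$hb_gene_fraction) * G)
  flagged <- sample.int(G, sum(n_flag))
  mito_idx <- flagged[seq_len(n_flag[1])]
  hb_idx <- setdiff(flagged, mito_idx)
  if (length(mito_idx)) gene_id[mito_idx] <- sprintf("MT-G%04d", mito_idx)
  if (length(hb_idx)) gene_id[hb_idx] <- sprintf("HBG%04d", hb_idx)

  types <- cfg$cell_types$type
  free <- setdiff(seq_len(G), flagged)
  markers <- list()
  for (i in seq_along(types)) {
    k <- min(cfg$cell_types$n_markers[i], length(free))
    pick <- sample(free, k)
    markers[[types[i]]] <- gene_id[pick]
    free <- setdiff(free, pick)
  }

  sp <- cfg$stress_programs
  stress_truth <- NULL
  if (nrow(sp) > 0) {
    rows <- vector("list", nrow(sp))
    for (i in seq_len(nrow(sp))) {
      tp_markers <- match(markers[[sp$type[i]]], gene_id)
      k_m <- min(round(cfg$stress_on_markers * sp$n_genes[i]),
                 length(tp_markers))
      k_f <- min(sp$n_genes[i] - k_m, length(free))
      if (k_m + k_f == 0)
        stop_regioglia("not enough free genes for stress programs")
      pick_m <- if (k_m > 0) sample(tp_markers, k_m) else integer(0)
      pick_f <- if (k_f > 0) sample(free, k_f) else integer(0)
      free <- setdiff(free, pick_f)
      pick <- c(pick_m, pick_f)
      rows[[i]] <- data.frame(type = sp$type[i], region = sp$region[i],
                              gene = gene_id[pick], fold = sp$fold[i],
                              stringsAsFactors = FALSE)
    }
    stress_truth <- do.call(rbind, rows)
  } else {
    stress_truth <- data.frame(type = character(), region = character(),
                               gene = character(), fold = numeric())
  }

  donor_ids <- sprintf("d%d", seq_len(cfg$n_donors))
  donor_factor <- matrix(stats::rlnorm(G * cfg$n_donors, 0, cfg$donor_sd),
                         nrow = G, dimnames = list(gene_id, donor_ids))

  groups <- expand.grid(region = c("macula", "periphery"),
                        condition = c("control", "stress"),
                        stringsAsFactors = FALSE)
  n_per <- cfg$n_cells_per_group
  cells <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    region <- groups$region[gi]
    condition <- groups$condition[gi]
    props <- if (region == "macula") cfg$cell_types$prop_macula else
      cfg$cell_types$prop_periphery
    donor <- donor_ids[rep_len(seq_len(cfg$n_donors), n_per)]
    type <- sample(types, n_per, replace = TRUE, prob = props)
    code <- paste0(if (condition == "stress") "L" else "C",
                   if (region == "macula") "M" else "P")
    cells[[gi]] <- data.frame(
      cell_id = sprintf("%s_%s_%04d", code, donor, seq_len(n_per)),
      donor = donor, region = region, condition = condition, type = type,
      stringsAsFactors = FALSE)
  }
  cell_meta <- do.call(rbind, cells)
  n_cells <- nrow(cell_meta)

  # per-type mean profiles (marker boost applied once per type)
  type_mean <- matrix(base_mean, nrow = G, ncol = length(types),
                      dimnames = list(gene_id, types))
  for (tp in types) {
    idx <- match(markers[[tp]], gene_id)
    type_mean[idx, tp] <- type_mean[idx, tp] * cfg$marker_fold
  }

  size_factor <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1],
                               cfg$library_size_lognormal[2])

  qc_violators <- character(0)
  if (cfg$n_qc_violators > 0) {
    qc_violators <- sample(cell_meta$cell_id, min(cfg$n_qc_violators,
                                                  n_cells))
  }

  counts <- matrix(0, nrow = n_cells, ncol = G,
                   dimnames = list(cell_meta$cell_id, gene_id))
  for (ci in seq_len(n_cells)) {
    mu <- type_mean[, cell_meta$type[ci]] *
      donor_factor[, cell_meta$donor[ci]] * size_factor[ci]
    if (cell_meta$condition[ci] == "stress" && nrow(stress_truth) > 0) {
      hit <- stress_truth$type == cell_meta$type[ci] &
        stress_truth$region == cell_meta$region[ci]
      if (any(hit)) {
        idx <- match(stress_truth$gene[hit], gene_id)
        mu[idx] <- mu[idx] * stress_truth$fold[hit]
      }
    }
    if (cell_meta$cell_id[ci] %in% qc_violators && length(mito_idx))
      mu[mito_idx] <- mu[mito_idx] * 20
    counts[ci, ] <- stats::rnbinom(G, mu = mu, size = 1 / cfg$nb_dispersion)
  }

  gene_meta <- data.frame(gene_id = gene_id,
                          is_mito = seq_len(G) %in% mito_idx,
                          is_hemoglobin = seq_len(G) %in% hb_idx,
                          stringsAsFactors = FALSE)
  study <- expression_study(counts, cell_meta, gene_meta)

  doublet_ids <- character(0)
  if (cfg$doublet_rate > 0) {
    inj <- inject_doublets(study, cfg$doublet_rate,
                           seed = derive_seed(cfg$seed, "doublets"))
    study <- inj$study
    doublet_ids <- inj$doublet_ids
  }

  truth <- list(markers = markers, stress_truth = stress_truth,
                doublets = doublet_ids,
                cell_types = stats::setNames(cell_meta$type,
                                             cell_meta$cell_id),
                qc_violators = qc_violators,
                base_means = stats::setNames(base_mean, gene_id))
  list(study = study, truth = truth)
}

#' Replace a fraction of cells with synthetic doublets
#'
#' `round(rate * n)` cells are replaced by the gene-wise sum of the counts
#' of two distinct parent cells drawn from the untouched remainder, the
#' additive model that artificial-doublet detectors assume. Metadata of the
#' first parent is kept (its type label is what a detector must overcome).
#'
#' @param study an `expression_study`.
#' @param rate doublet fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list: `study` with doublets substituted, `doublet_ids`, and
#'   `parents` (two-column character matrix of parent cell ids).
#' @export
inject_doublets <- function(study, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop_regioglia("rate must lie in [0, 1)")
  n <- nrow(study$counts)
  n_dbl <- round(rate * n)
  if (n_dbl == 0)
    return(list(study = study, doublet_ids = character(0),
                parents = matrix(character(0), ncol = 2)))
  with_seed(seed, {
    dbl_pos <- sample.int(n, n_dbl)
    pool <- setdiff(seq_len(n), dbl_pos)
    if (length(pool) < 2) stop_regioglia("too few cells to form doublets")
    counts <- as.matrix(study$counts)
    parents <- matrix("", nrow = n_dbl, ncol = 2)
    for (i in seq_len(n_dbl)) {
      pr <- sample(pool, 2)
      counts[dbl_pos[i], ] <- counts[pr[1], ] + counts[pr[2], ]
      parents[i, ] <- study$cell_meta$cell_id[pr]
    }
    meta <- study$cell_meta
    ids <- meta$cell_id[dbl_pos]
    out <- expression_study(counts, meta, study$gene_meta)
    list(study = out, doublet_ids = ids, parents = parents)
  })
}
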