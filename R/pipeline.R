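#' Pipeline run configuration
#'
#' Collects every stage's parameters, all defaulting to the published
#' settings: QC bounds 200/6000 features, 15 % mito, 5 % hemoglobin;
#' DoubletFinder-style pN 0.25 / pK 0.09 / 20 PCs; 2000 HVGs; signature
#' cap 50; heat-kernel beta 67 with k = 7 neighbors; likelihood cutoffs
#' 0.4/0.6; DE min.pct 0.2 and log2FC threshold 0.2; regional fold-change
#' cutoff 1.5; light-induced change 9 %; top-40 lists.
#'
#' @param generator `NULL` or a list of [generator_config()] arguments —
#'   when present the pipeline simulates its input.
#' @param input `NULL` or a directory readable by [read_study_10x()].
#' @param qc list: `min_features`, `max_features`, `max_mito_ratio`,
#'   `max_hb_ratio`.
#' @param doublets list: `pN`, `pK`, `n_pcs`, `expected_rate`.
#' @param hvg list: `n`.
#' @param acscore list: `cap`, `min_log2fc`, `min_pct`, `alpha`, `n_perm`
#'   (0 skips the null band), `symmetric`.
#' @param likelihood list: `beta`, `knn`, `n_pcs`, `low`, `high`.
#' @param deg list: `celltype` (focal type for regional DE), `min_pct`,
#'   `logfc_threshold`, `alpha`, `fc_cutoff`, `min_change`, `top_k`.
#' @param seed master seed; each stage derives its own stream from it.
#' @param out output directory.
#' @return a canonicalized `run_config` list.
#' @export
run_config <- function(generator = list(), input = NULL,
                       qc = list(), doublets = list(), hvg = list(),
                       acscore = list(), likelihood = list(), deg = list(),
                       seed = 1L, out = "regioglia_out") {
  # canonicalize all numeric scalars to double so a JSON/YAML round trip
  # (which reads whole numbers back as integer) is the identity
  canon <- function(x) {
    if (is.data.frame(x)) { x[] <- lapply(x, canon); x }
    else if (is.list(x)) lapply(x, canon)
    else if (is.integer(x)) as.numeric(x)
    else x
  }
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop_regioglia("unknown config field(s): %s",
                                    paste(bad, collapse = ", "))
    defaults[names(user)] <- canon(user)
    defaults
  }
  cfg <- list(
    generator = if (is.null(generator)) NULL else canon(generator),
    input = input,
    qc = merge_defaults(qc, list(min_features = 200, max_features = 6000,
                                 max_mito_ratio = 0.15,
                                 max_hb_ratio = 0.05)),
    doublets = merge_defaults(doublets, list(pN = 0.25, pK = 0.09,
                                             n_pcs = 20,
                                             expected_rate = 0.075)),
    hvg = merge_defaults(hvg, list(n = 2000)),
    acscore = merge_defaults(acscore, list(cap = 50, min_log2fc = 0.5,
                                           min_pct = 0.25, alpha = 0.05,
                                           n_perm = 0,
                                           symmetric = FALSE)),
    likelihood = merge_defaults(likelihood, list(beta = 67, knn = 7,
                                                 n_pcs = 20, low = 0.4,
                                                 high = 0.6)),
    deg = merge_defaults(deg, list(celltype = "MG", min_pct = 0.2,
                                   logfc_threshold = 0.2, alpha = 0.05,
                                   fc_cutoff = 1.5, min_change = 0.09,
                                   top_k = 40)),
    seed = as.integer(seed),
    out = out)
  if (is.null(cfg$generator) && is.null(cfg$input))
    stop_regioglia("config needs either a generator block or an input dir")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration
#'
#' JSON (or YAML when the file ends in .yaml/.yml and the yaml package is
#' available). Reading re-canonicalizes through [run_config()], so a
#' write/read round trip is the identity.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_regioglia("yaml package not available")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_regioglia("yaml package not available")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(x$generator) && !is.null(x$generator$stress_programs))
    x$generator$stress_programs <-
      as.data.frame(x$generator$stress_programs)
  if (!is.null(x$generator) && !is.null(x$generator$cell_types))
    x$generator$cell_types <- as.data.frame(x$generator$cell_types)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' simulate/read -> QC (feature/mito/hemoglobin filters, doublet removal)
#' -> normalization and HVG selection -> pseudobulk group correlation ->
#' per-type signatures and Alteration Scores -> graph heat-kernel relative
#' likelihoods with three-way classification -> regional and
#' condition-wise differential expression with m-HX/p-HX and
#' light-induced-change categorization. All tables are written as CSV
#' under `config$out`, with a JSON run report; reruns with the same config
#' are bit-identical for every deterministic stage (all stages are,
#' because each derives its RNG stream from the master seed).
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(
    utils::packageVersion("regioglia")), seed = config$seed, stages = list())
  stage <- function(name, rec) report$stages[[name]] <<- rec

  # ---- input ----
  if (!is.null(config$generator)) {
    gen_args <- config$generator
    gen_args$seed <- gen_args$seed %||% derive_seed(config$seed, "simulate")
    gen <- generate_study(do.call(generator_config, gen_args))
    study <- gen$study
    truth <- gen$truth
    stage("simulate", list(n_cells = nrow(study$counts),
                           n_genes = ncol(study$counts),
                           seed = gen_args$seed))
  } else {
    study <- read_study_10x(config$input)
    truth <- NULL
    stage("read", list(input = config$input,
                       n_cells = nrow(study$counts),
                       n_genes = ncol(study$counts)))
  }
  n_in <- nrow(study$counts)

  # ---- QC ----
  qc_tab <- compute_cell_qc(study)
  thr <- do.call(qc_thresholds, config$qc)
  keep <- filter_cells(qc_tab, thr)
  study <- subset_cells(study, keep)
  utils::write.csv(qc_tab, file.path(out_dir, "qc_table.csv"),
                   row.names = FALSE)
  writeLines(keep, file.path(out_dir, "retained_cells.txt"))

  norm0 <- normalize_log1p(study)
  hvg0 <- select_hvg(norm0, config$hvg$n)
  db <- config$doublets
  flags <- detect_doublets(norm0[, hvg0, drop = FALSE], pN = db$pN,
                           pK = db$pK, n_pcs = db$n_pcs,
                           expected_rate = db$expected_rate,
                           seed = derive_seed(config$seed, "doublets"),
                           counts = study$counts)
  study <- subset_cells(study, which(!flags))
  stage("qc", list(thresholds = unclass(thr), cells_in = n_in,
                   cells_after_filters = length(keep),
                   doublets_removed = sum(flags),
                   cells_out = nrow(study$counts)))

  # ---- normalization / HVG ----
  norm <- normalize_log1p(study)
  hvg <- select_hvg(norm, config$hvg$n)
  stage("normalize", list(scale = attr(norm, "scale"),
                          n_hvg = length(hvg)))

  # ---- pseudobulk correlation ----
  pb <- pseudobulk_correlation(norm, study$cell_meta, hvg)
  utils::write.csv(as.data.frame(pb),
                   file.path(out_dir, "pseudobulk_corr.csv"))
  stage("pseudobulk", list(groups = colnames(pb)))

  if (is.null(study$cell_meta$type))
    stop_regioglia("stage acscore: cell metadata has no 'type' column")

  # ---- alteration scores ----
  ac <- config$acscore
  sigs <- select_signature_genes(norm, study$cell_meta, alpha = ac$alpha,
                                 min_log2fc = ac$min_log2fc,
                                 min_pct = ac$min_pct, cap = ac$cap)
  fc <- compute_fold_changes(norm, study$counts, study$cell_meta, sigs)
  scores <- alteration_score(fc, symmetric = ac$symmetric)
  sig_tab <- do.call(rbind, lapply(names(sigs), function(tp)
    if (nrow(sigs[[tp]])) cbind(type = tp, sigs[[tp]])))
  if (!is.null(sig_tab))
    utils::write.csv(sig_tab, file.path(out_dir, "signatures.csv"),
                     row.names = FALSE)
  utils::write.csv(fc, file.path(out_dir, "fold_changes.csv"),
                   row.names = FALSE)
  score_out <- as.data.frame(scores)
  if (ac$n_perm >= 20) {
    band <- acscore_null_band(study, sigs, n_perm = ac$n_perm,
                              seed = derive_seed(config$seed, "acscore"))
    score_out <- merge(score_out, band[c("type", "q025", "q50", "q975")],
                       by = "type", sort = TRUE)
  }
  utils::write.csv(score_out, file.path(out_dir, "acscores.csv"),
                   row.names = FALSE)
  stage("acscore", list(n_types_scored = nrow(score_out),
                        cap = ac$cap, n_perm = ac$n_perm))

  # ---- relative likelihood ----
  lk <- config$likelihood
  emb <- pca_embedding(norm, hvg, lk$n_pcs)
  graph <- build_knn_graph(emb, k = lk$knn)
  res <- relative_likelihood(graph, study$cell_meta, beta = lk$beta)
  cats <- classify_likelihood(res, lk$low, lk$high)
  lik_tab <- data.frame(cell_id = study$cell_meta$cell_id,
                        res$per_replicate,
                        likelihood = res$likelihood, category = cats,
                        stringsAsFactors = FALSE)
  utils::write.csv(lik_tab, file.path(out_dir, "likelihood.csv"),
                   row.names = FALSE)
  summ <- summarize_by_celltype(res, cats, study$cell_meta)
  utils::write.csv(summ, file.path(out_dir, "type_summary.csv"),
                   row.names = FALSE)
  stage("likelihood", list(beta = lk$beta, knn = lk$knn, n_pcs = lk$n_pcs,
                           n_cells = nrow(lik_tab),
                           n_high = sum(cats == "highly-changed")))

  # ---- regional / condition DE ----
  dg <- config$deg
  meta <- study$cell_meta
  focal <- meta$type == dg$celltype
  deg_written <- character(0)
  venn_sets <- list()
  for (contrast in c("LP_vs_CP", "LM_vs_CM", "CP_vs_CM")) {
    parts <- strsplit(contrast, "_vs_")[[1]]
    grp <- group_code(meta)
    idxA <- which(grp == parts[1])
    idxB <- which(grp == parts[2])
    if (length(idxA) < 3 || length(idxB) < 3) next
    deg <- differential_expression(norm, idxA, idxB, dg$min_pct,
                                   dg$logfc_threshold)
    f <- sprintf("deg_%s.csv", contrast)
    utils::write.csv(deg, file.path(out_dir, f), row.names = FALSE)
    deg_written <- c(deg_written, f)
    venn_sets[[contrast]] <- deg$gene[deg$p_adj < dg$alpha]
  }
  if (length(venn_sets) >= 2) {
    venn <- deg_set_overlap(venn_sets)
    jsonlite::write_json(stats::setNames(as.list(venn$count),
                                         venn$region),
                         file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE)
  }

  regional <- NULL
  if (sum(focal & meta$region == "macula") >= 3 &&
      sum(focal & meta$region == "periphery") >= 3) {
    deg_reg <- differential_expression(
      norm, which(focal & meta$region == "macula"),
      which(focal & meta$region == "periphery"),
      dg$min_pct, dg$logfc_threshold)
    cat_reg <- categorize_regional(deg_reg, dg$fc_cutoff, dg$alpha)
    # light response of the focal type, per region
    flags_by_gene <- list()
    for (rg in c("macula", "periphery")) {
      idxA <- which(focal & meta$region == rg & meta$condition == "stress")
      idxB <- which(focal & meta$region == rg & meta$condition == "control")
      if (length(idxA) < 3 || length(idxB) < 3) next
      deg_lc <- differential_expression(norm, idxA, idxB, dg$min_pct,
                                        dg$logfc_threshold)
      flags_by_gene[[rg]] <- flag_light_induced(deg_lc, dg$alpha,
                                                dg$min_change)
    }
    regional <- merge(deg_reg, cat_reg, by = "gene")
    for (rg in names(flags_by_gene)) {
      fl <- flags_by_gene[[rg]]
      names(fl)[2] <- paste0("light_", rg)
      regional <- merge(regional, fl, by = "gene", all.x = TRUE)
      regional[[paste0("light_", rg)]][
        is.na(regional[[paste0("light_", rg)]])] <- "none"
    }
    utils::write.csv(regional,
                     file.path(out_dir, "regional_categories.csv"),
                     row.names = FALSE)
    top_m <- top_k_by_fold_change(deg_reg, dg$top_k, "A-high", dg$alpha)
    top_p <- top_k_by_fold_change(deg_reg, dg$top_k, "B-high", dg$alpha)
    jsonlite::write_json(list(m_high = top_m, p_high = top_p),
                         file.path(out_dir, "top_regional_genes.json"))
  }
  stage("deg", list(celltype = dg$celltype, contrasts = deg_written,
                    n_regional = if (is.null(regional)) 0L else
                      nrow(regional)))

  report$config <- unclass(config)
  if (!is.null(truth))
    report$truth_summary <- list(
      n_planted_stress_genes = nrow(truth$stress_truth),
      n_doublets = length(truth$doublets))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic study as a 10x-style directory) and
#' `run-all` (full pipeline). Options: `--config cfg.json|cfg.yaml`,
#' `--seed N`, `--out dir`.
#'
#' @param args character vector, default the command line.
#' @return exit status, invisibly (0 on success).
#' @export
regioglia_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: regioglia <simulate|run-all>",
                 "[--config cfg.json] [--seed N] [--out dir]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  opts <- list(seed = 1L, out = "regioglia_out", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  cfg_args <- if (!is.null(opts$config)) {
    unclass(read_run_config(opts$config))
  } else list(generator = list())
  cfg_args$seed <- opts$seed
  cfg_args$out <- opts$out
  cfg <- do.call(run_config, cfg_args[!vapply(cfg_args, is.null,
                                              logical(1))])
  if (verb == "simulate") {
    gen_args <- cfg$generator %||% list()
    gen_args$seed <- gen_args$seed %||% derive_seed(cfg$seed, "simulate")
    gen <- generate_study(do.call(generator_config, gen_args))
    write_study_10x(gen$study, cfg$out)
    jsonlite::write_json(gen$truth[c("stress_truth", "doublets",
                                     "qc_violators")],
                         file.path(cfg$out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    message(sprintf("wrote %d cells x %d genes to %s",
                    nrow(gen$study$counts), ncol(gen$study$counts),
                    cfg$out))
    return(invisible(0L))
  }
  if (verb %in% c("run-all", "run")) {
    run_pipeline(cfg)
    message(sprintf("pipeline complete; outputs in %s", cfg$out))
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
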