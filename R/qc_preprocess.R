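#' Cell-level QC thresholds
#'
#' Boundary semantics follow the filtering wording "over X" / "less than Y"
#' strictly: a cell sitting exactly on a threshold is retained.
#'
#' @param min_features minimum unique feature count (strictly fewer is
#'   removed).
#' @param max_features maximum unique feature count (strictly more is
#'   removed); 10000 is the variant used for high-glucose treatment.
#' @param max_mito_ratio maximum mitochondrial count fraction.
#' @param max_hb_ratio maximum hemoglobin count fraction.
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 6000,
                          max_mito_ratio = 0.15, max_hb_ratio = 0.05) {
  if (min_features >= max_features)
    stop_regioglia("min_features must be < max_features")
  if (max_mito_ratio < 0 || max_mito_ratio > 1 ||
      max_hb_ratio < 0 || max_hb_ratio > 1)
    stop_regioglia("ratio thresholds must lie in [0, 1]")
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_ratio = max_mito_ratio,
                 max_hb_ratio = max_hb_ratio),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param study an `expression_study` whose `gene_meta` carries `is_mito`
#'   and `is_hemoglobin` flags.
#' @return data.frame with per-cell `cell_id`, `n_features` (genes with
#'   count > 0), `total_counts`, `mito_ratio`, `hb_ratio`. Ratios are 0 by
#'   convention for an all-zero cell.
#' @export
compute_cell_qc <- function(study) {
  for (col in c("is_mito", "is_hemoglobin"))
    if (is.null(study$gene_meta[[col]]))
      stop_regioglia("gene_meta lacks column '%s'", col)
  counts <- study$counts
  total <- Matrix::rowSums(counts)
  n_features <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, study$gene_meta$is_mito, drop = FALSE])
  hb <- Matrix::rowSums(counts[, study$gene_meta$is_hemoglobin,
                               drop = FALSE])
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  data.frame(cell_id = study$cell_meta$cell_id,
             n_features = as.integer(n_features),
             total_counts = total,
             mito_ratio = safe_div(mito, total),
             hb_ratio = safe_div(hb, total),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' A cell is retained iff `min_features <= n_features <= max_features`,
#' `mito_ratio <= max_mito_ratio` and `hb_ratio <= max_hb_ratio`; equality
#' always retains (strict "over"/"less than" removal).
#'
#' @param qc data.frame from [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()].
#' @return character vector of retained cell ids.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  keep <- qc$n_features >= thresholds$min_features &
    qc$n_features <= thresholds$max_features &
    qc$mito_ratio <= thresholds$max_mito_ratio &
    qc$hb_ratio <= thresholds$max_hb_ratio
  if (!any(keep)) message("filter_cells: no cells retained")
  qc$cell_id[keep]
}

#' Library-size normalization with log1p transform
#'
#' Each count becomes `log(1 + scale * count / cell_total)`; cells with zero
#' total map to all-zero rows.
#'
#' @param study an `expression_study` (or a bare counts matrix, cells x
#'   genes).
#' @param scale library-size scale factor.
#' @return dgCMatrix of log-normalized expression, cells x genes, with a
#'   `"scale"` attribute.
#' @export
normalize_log1p <- function(study, scale = 1e4) {
  counts <- if (inherits(study, "expression_study")) study$counts else
    as_dgc(study)
  total <- Matrix::rowSums(counts)
  inv <- ifelse(total > 0, scale / total, 0)
  norm <- Matrix::Diagonal(x = inv) %*% counts
  norm@x <- log1p(norm@x)
  norm <- as_dgc(norm)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale") <- scale
  norm
}

#' Highly variable gene selection by binned dispersion
#'
#' Genes are ranked by the z-score of their dispersion (variance/mean of
#' the log-normalized values) within 20 equal-frequency bins of mean
#' expression, the classic binned-dispersion recipe.
#'
#' @param norm normalized matrix (cells x genes) from [normalize_log1p()].
#' @param n number of genes to return; if `n >= ncol(norm)` all genes are
#'   returned (still ordered by the criterion).
#' @param n_bins number of mean-expression bins.
#' @return character vector of gene ids ordered by decreasing standardized
#'   dispersion.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  if (n < 1) stop_regioglia("n must be >= 1")
  mu <- Matrix::colMeans(norm)
  m2 <- Matrix::colMeans(norm^2)
  v <- pmax(m2 - mu^2, 0) * nrow(norm) / max(nrow(norm) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, max(1L, floor(ncol(norm) / 2))))
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- stats::sd(disp[idx])
    ctr <- disp[idx] - mean(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else ctr / s
  }
  # constant genes can never outrank genes with positive variance
  z[v == 0] <- -Inf
  ids <- colnames(norm) %||% as.character(seq_len(ncol(norm)))
  ord <- order(z, decreasing = TRUE)
  ids[utils::head(ord, min(n, ncol(norm)))]
}

#' Doublet detection via artificial doublets
#'
#' Artificial doublets are built from pN * n random real-cell pairs: when
#' `counts` is supplied the pair's raw counts are summed and the sum
#' renormalized — the same arithmetic that produced any real doublet, so
#' artificial and real doublets land on the same manifold (this also gives
#' partial sensitivity to same-type doublets); without `counts` the pair's
#' normalized profiles are averaged. Real and artificial cells are embedded
#' together in the top principal components; each real cell's pANN is the
#' fraction of artificial cells among its
#' k = round(pK * (n_real + n_artificial)) nearest neighbors, and the
#' `round(expected_rate * n_real)` cells with the highest pANN are flagged.
#'
#' @param norm normalized matrix (cells x genes), ideally subset to HVGs.
#' @param pN artificial doublet fraction.
#' @param pK neighborhood size as a fraction of the merged dataset.
#' @param n_pcs number of principal components.
#' @param expected_rate fraction of real cells to flag, in `[0, 1)`.
#' @param seed integer seed.
#' @param counts optional raw count matrix aligned with `norm` (same cells,
#'   any gene superset including `norm`'s genes) used to build artificial
#'   doublets in count space.
#' @return logical vector, `TRUE` for flagged cells, with the pANN vector
#'   as attribute `"pANN"`.
#' @export
detect_doublets <- function(norm, pN = 0.25, pK = 0.09, n_pcs = 20,
                            expected_rate = 0.075, seed = 1L,
                            counts = NULL) {
  if (expected_rate < 0 || expected_rate >= 1)
    stop_regioglia("expected_rate must lie in [0, 1)")
  n_real <- nrow(norm)
  n_art <- round(pN * n_real)
  k <- round(pK * (n_real + n_art))
  if (k < 1) stop_regioglia("dataset too small: pK * n rounds to k < 1")
  n_flag <- round(expected_rate * n_real)
  if (n_flag == 0)
    return(structure(rep(FALSE, n_real), pANN = rep(NA_real_, n_real)))
  with_seed(seed, {
    p1 <- sample.int(n_real, n_art, replace = TRUE)
    p2 <- sample.int(n_real, n_art, replace = TRUE)
    same <- which(p1 == p2)
    while (length(same)) {
      p2[same] <- sample.int(n_real, length(same), replace = TRUE)
      same <- same[p1[same] == p2[same]]
    }
    if (is.null(counts)) {
      art <- (as.matrix(norm[p1, , drop = FALSE]) +
                as.matrix(norm[p2, , drop = FALSE])) / 2
    } else {
      if (nrow(counts) != n_real)
        stop_regioglia("counts rows != norm rows")
      art_counts <- counts[p1, , drop = FALSE] + counts[p2, , drop = FALSE]
      art <- as.matrix(normalize_log1p(art_counts,
                                       scale = attr(norm, "scale") %||%
                                         1e4))
      cols <- colnames(norm)
      if (!is.null(cols) && !is.null(colnames(art)))
        art <- art[, cols, drop = FALSE]
    }
    merged <- rbind(as.matrix(norm), art)
    n_pcs <- min(n_pcs, nrow(merged) - 1L, ncol(merged))
    pcs <- stats::prcomp(merged, center = TRUE, scale. = FALSE,
                         rank. = n_pcs)$x
    is_art <- c(rep(FALSE, n_real), rep(TRUE, n_art))
    d2 <- euclidean_dist2(pcs[seq_len(n_real), , drop = FALSE], pcs)
    pann <- numeric(n_real)
    for (i in seq_len(n_real)) {
      di <- d2[i, ]
      di[i] <- Inf  # a real cell is not its own neighbor
      nb <- order(di)[seq_len(k)]
      pann[i] <- mean(is_art[nb])
    }
    flags <- rep(FALSE, n_real)
    flags[order(pann, decreasing = TRUE)[seq_len(n_flag)]] <- TRUE
    structure(flags, pANN = pann)
  })
}

# squared Euclidean distances between rows of a (n x d) and rows of b (m x d)
euclidean_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Pseudobulk correlation between groups
#'
#' Mean log-normalized expression over the HVGs is computed per group
#' (LM, CM, LP, CP) and group vectors are compared by Pearson correlation.
#'
#' @param norm normalized matrix (cells x genes).
#' @param cell_meta cell metadata with `region` and `condition`.
#' @param hvg gene ids to use; default all genes.
#' @param groups group codes that must be present; any requested group with
#'   zero cells is an error. Default: the groups present in `cell_meta`.
#' @return symmetric correlation matrix with unit diagonal, one row per
#'   group.
#' @export
pseudobulk_correlation <- function(norm, cell_meta, hvg = colnames(norm),
                                   groups = NULL) {
  grp <- group_code(cell_meta)
  if (is.null(groups)) {
    groups <- intersect(c("LM", "CM", "LP", "CP"), unique(grp))
  } else {
    empty <- setdiff(groups, unique(grp))
    if (length(empty))
      stop_regioglia("group(s) with 0 cells: %s",
                     paste(empty, collapse = ", "))
  }
  if (length(groups) < 2) stop_regioglia("need at least 2 groups")
  hvg <- intersect(hvg, colnames(norm))
  if (!length(hvg)) stop_regioglia("no HVGs present in matrix")
  means <- vapply(groups, function(g)
    Matrix::colMeans(norm[grp == g, hvg, drop = FALSE]),
    numeric(length(hvg)))
  cc <- stats::cor(means)
  diag(cc) <- 1
  cc
}
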