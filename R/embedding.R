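#' PCA embedding of log-normalized expression
#'
#' Centered (not variance-scaled) principal components of the cells-by-HVG
#' matrix, the embedding used for the doublet detector and the cell graph.
#'
#' @param norm normalized matrix (cells x genes).
#' @param hvg gene ids to use; default all genes.
#' @param n_pcs number of components (capped at the matrix rank bound).
#' @return cells x n_pcs score matrix.
#' @export
pca_embedding <- function(norm, hvg = colnames(norm), n_pcs = 20) {
  hvg <- intersect(hvg, colnames(norm))
  if (!length(hvg)) stop_regioglia("no HVGs present in matrix")
  m <- as.matrix(norm[, hvg, drop = FALSE])
  n_pcs <- min(n_pcs, nrow(m) - 1L, ncol(m))
  sc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  rownames(sc) <- rownames(norm)
  sc
}
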