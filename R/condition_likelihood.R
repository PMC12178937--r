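#' Build a kNN cell graph with adaptive Gaussian weights
#'
#' Directed k-nearest-neighbor edges by Euclidean distance in the supplied
#' embedding get weights `exp(-d(u,v)^2 / (sigma_u * sigma_v))` with
#' `sigma_u` the distance from u to its k-th neighbor (an adaptive
#' bandwidth, wide in sparse regions); the adjacency is then symmetrized
#' by averaging and self-loops removed. Duplicate points (bandwidth 0) get
#' weight capped at 1.
#'
#' @param embedding numeric matrix, cells x dimensions (e.g. top 20 PCs).
#' @param k number of neighbors (must be < number of cells).
#' @return a `cell_graph`: list with `adjacency` (symmetric dgCMatrix, zero
#'   diagonal), `sigma` (per-cell bandwidth) and `k`.
#' @export
build_knn_graph <- function(embedding, k = 7) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop_regioglia("k must be < number of cells")
  d2 <- euclidean_dist2(embedding, embedding)
  diag(d2) <- Inf
  nn <- apply(d2, 1, function(x) order(x)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  sigma <- sqrt(d2[cbind(seq_len(n), nn[, k])])
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  ss <- sigma[ii] * sigma[jj]
  dd <- d2[cbind(ii, jj)]
  w <- ifelse(ss > 0, exp(-dd / ss), 1)
  w <- pmin(w, 1)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- (A + Matrix::t(A)) / 2
  diag(W) <- 0
  W <- Matrix::drop0(W)
  rownames(W) <- colnames(W) <- rownames(embedding)
  structure(list(adjacency = as_dgc(W), sigma = sigma, k = k),
            class = "cell_graph")
}

#' Heat-kernel smoothing of a density indicator on the cell graph
#'
#' Applies the filter `exp(-beta * L_rw)` to the sum-normalized indicator,
#' where `L_rw = I - D^-1 W` is the random-walk normalized graph Laplacian.
#' The filter is evaluated as the Poisson-weighted power series
#' `sum_k dpois(k, beta) P^k h` with `P = D^-1 W`, truncated when the
#' remaining Poisson tail mass drops below `tol` — numerically stable for
#' large `beta` because every term is a convex combination of the input.
#' Constants are fixed points, `beta = 0` is the identity, and no mass
#' crosses between disconnected components.
#'
#' @param graph a `cell_graph`.
#' @param indicator non-negative per-cell vector, not all zero.
#' @param beta diffusion time of the heat kernel.
#' @param tol truncation tolerance on the Poisson tail.
#' @return smoothed density vector (a convex combination of the normalized
#'   input at every vertex; the row-stochastic filter preserves the range
#'   of the input, not its sum).
#' @export
graph_density <- function(graph, indicator, beta = 67, tol = 1e-6) {
  W <- graph$adjacency
  n <- nrow(W)
  if (length(indicator) != n)
    stop_regioglia("indicator length %d != %d cells", length(indicator), n)
  if (any(indicator < 0)) stop_regioglia("indicator must be non-negative")
  s <- sum(indicator)
  if (s == 0) stop_regioglia("indicator is all zero")
  h <- indicator / s
  if (beta < 0) stop_regioglia("beta must be >= 0")
  deg <- Matrix::rowSums(W)
  iso <- deg == 0
  step <- function(v) {
    out <- as.vector(W %*% v) / ifelse(iso, 1, deg)
    out[iso] <- v[iso]  # isolated vertices keep their mass
    out
  }
  # K chosen so the truncated Poisson tail is below tol
  K <- 0L
  if (beta > 0) {
    K <- max(1L, ceiling(beta))
    while (stats::ppois(K, beta, lower.tail = FALSE) > tol) K <- K + 10L
  }
  acc <- stats::dpois(0, beta) * h
  v <- h
  if (K >= 1) for (k in seq_len(K)) {
    v <- step(v)
    acc <- acc + stats::dpois(k, beta) * v
  }
  acc
}

#' Per-cell condition-associated relative likelihood
#'
#' For each replicate (donor) with cells in both conditions, the stress and
#' control cell indicators are sum-normalized, smoothed with the graph heat
#' kernel, and combined per cell as
#' `l_r = d_stress / (d_stress + d_control)`; the reported likelihood is
#' the unweighted mean of `l_r` over replicates, clipped to `[0, 1]`.
#' A cell reached by neither density (disconnected from both samples) gets
#' 0.5 in that replicate.
#'
#' @param graph a `cell_graph` over all cells.
#' @param cell_meta cell metadata with `donor` and `condition`, rows
#'   aligned with the graph vertices.
#' @param beta diffusion time, passed to [graph_density()].
#' @param stress_label,control_label condition labels.
#' @return a `likelihood_result`: list with `likelihood` (per-cell vector
#'   in `[0, 1]`), `per_replicate` (cells x replicates matrix) and
#'   `params`.
#' @export
relative_likelihood <- function(graph, cell_meta, beta = 67,
                                stress_label = "stress",
                                control_label = "control") {
  n <- nrow(graph$adjacency)
  if (nrow(cell_meta) != n)
    stop_regioglia("cell_meta rows != graph vertices")
  donors <- unique(cell_meta$donor)
  cols <- list()
  for (r in donors) {
    in_r <- cell_meta$donor == r
    s_idx <- in_r & cell_meta$condition == stress_label
    c_idx <- in_r & cell_meta$condition == control_label
    if (!any(s_idx) || !any(c_idx)) {
      warning(sprintf("replicate '%s' lacks a condition; dropped", r),
              call. = FALSE)
      next
    }
    ds <- graph_density(graph, as.numeric(s_idx), beta)
    dc <- graph_density(graph, as.numeric(c_idx), beta)
    tot <- ds + dc
    lr <- ifelse(tot > 0, ds / tot, 0.5)
    cols[[as.character(r)]] <- lr
  }
  if (!length(cols))
    stop_regioglia("no replicate has cells in both conditions")
  per_rep <- do.call(cbind, cols)
  rownames(per_rep) <- cell_meta$cell_id
  l <- pmin(pmax(rowMeans(per_rep), 0), 1)
  structure(list(likelihood = l, per_replicate = per_rep,
                 params = list(beta = beta, k = graph$k)),
            class = "likelihood_result")
}

#' Three-way change classification of relative likelihoods
#'
#' Cells with likelihood below `low` are `non-changed`, within the closed
#' interval `[low, high]` `slightly-changed`, and strictly above `high`
#' `highly-changed`.
#'
#' @param result a `likelihood_result` or a numeric likelihood vector.
#' @param low,high category cutoffs, `0 < low < high < 1`.
#' @return character vector of categories.
#' @export
classify_likelihood <- function(result, low = 0.4, high = 0.6) {
  if (!(low > 0 && low < high && high < 1))
    stop_regioglia("need 0 < low < high < 1")
  l <- if (inherits(result, "likelihood_result")) result$likelihood else
    as.numeric(result)
  ifelse(l < low, "non-changed",
         ifelse(l > high, "highly-changed", "slightly-changed"))
}

#' Per-cell-type likelihood summary
#'
#' @param result a `likelihood_result` or numeric likelihood vector.
#' @param categories categories from [classify_likelihood()].
#' @param cell_meta cell metadata with a `type` column.
#' @return data.frame per type: `type`, `n_cells`, `mean_likelihood`,
#'   `n_high`, `prop_high` (within-type fraction highly-changed) and
#'   `share_of_high` (the type's share of all highly-changed cells; `NA`
#'   for every type when no cell is highly-changed, otherwise summing
#'   to 1).
#' @export
summarize_by_celltype <- function(result, categories, cell_meta) {
  if (is.null(cell_meta$type)) stop_regioglia("cell_meta lacks 'type'")
  l <- if (inherits(result, "likelihood_result")) result$likelihood else
    as.numeric(result)
  high <- categories == "highly-changed"
  total_high <- sum(high)
  types <- sort(unique(cell_meta$type))
  out <- do.call(rbind, lapply(types, function(tp) {
    idx <- cell_meta$type == tp
    n_high <- sum(high & idx)
    data.frame(type = tp, n_cells = sum(idx),
               mean_likelihood = mean(l[idx]),
               n_high = n_high,
               prop_high = n_high / sum(idx),
               share_of_high = if (total_high > 0) n_high / total_high else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
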