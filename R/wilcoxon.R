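#' Two-sided Wilcoxon rank-sum p-values, one per gene
#'
#' For small groups (both sizes at most `exact_max`) the p-value is exact:
#' the rank-sum statistic is enumerated over every assignment of the
#' observed values (midranks, so ties are handled) to group A, and the
#' two-sided p is the probability of a statistic at least as far from its
#' mean as the observed one. For larger groups a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param mat numeric matrix, cells x genes (dense or sparse).
#' @param idxA,idxB row indices of the two groups (disjoint).
#' @param exact_max largest group size for which exact enumeration is used.
#' @return numeric vector of p-values, one per column of `mat`.
#' @export
wilcoxon_pvalues <- function(mat, idxA, idxB, exact_max = 8) {
  nA <- length(idxA); nB <- length(idxB)
  if (nA == 0 || nB == 0) stop_regioglia("empty group in Wilcoxon test")
  if (length(intersect(idxA, idxB)))
    stop_regioglia("groups overlap")
  sub <- as.matrix(mat[c(idxA, idxB), , drop = FALSE])
  a <- seq_len(nA)
  mu <- nA * (nA + nB + 1) / 2
  if (nA <= exact_max && nB <= exact_max) {
    subsets <- utils::combn(nA + nB, nA)   # all C(N, nA) group-A choices
    apply(sub, 2, function(x) {
      r <- rank(x)
      w_obs <- sum(r[a])
      w_perm <- colSums(matrix(r[subsets], nrow = nA))
      mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
    })
  } else {
    N <- nA + nB
    apply(sub, 2, function(x) {
      r <- rank(x)
      w <- sum(r[a])
      ties <- table(x)
      sigma2 <- nA * nB / 12 *
        ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      if (sigma2 <= 0) return(1)
      z <- w - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(-abs(z)))
    })
  }
}

# linear fold change of gene means between groups on the de-logged
# normalized scale, with a pseudocount guarding against zero means
fold_change_linear <- function(norm, idxA, idxB, pseudo = 0.01) {
  mA <- Matrix::colMeans(expm1(norm[idxA, , drop = FALSE]))
  mB <- Matrix::colMeans(expm1(norm[idxB, , drop = FALSE]))
  (mA + pseudo) / (mB + pseudo)
}

detection_fraction <- function(mat, idx) {
  Matrix::colMeans(mat[idx, , drop = FALSE] > 0)
}
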