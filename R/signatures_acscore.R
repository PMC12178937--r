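#' Select per-cell-type signature genes
#'
#' One-vs-rest marker selection computed on control cells only: for each
#' cell type, candidate genes must be detected in at least `min_pct` of the
#' type's control cells and show a log2 fold change vs all other control
#' cells of at least `min_log2fc`; candidates are then tested with a
#' two-sided Wilcoxon rank-sum on the normalized values, BH-adjusted over
#' the candidates, and those with adjusted p below `alpha` are kept, capped
#' at the `cap` largest log2 fold changes (ties broken by gene id).
#'
#' @param norm normalized matrix (cells x genes).
#' @param cell_meta cell metadata with `condition` and `type` columns.
#' @param types cell types to process; default all types present.
#' @param alpha adjusted-p cutoff.
#' @param min_log2fc minimum one-vs-rest log2 fold change.
#' @param min_pct minimum detection fraction within the type.
#' @param cap maximum signature size per type.
#' @return a `signature_set`: named list (one entry per type) of
#'   data.frames `gene`, `log2fc`, `pct`, `p`, `p_adj`, ordered by
#'   decreasing log2fc. Types with fewer than 3 control cells are dropped
#'   with a warning; a type with no passing gene gets a zero-row table.
#' @export
select_signature_genes <- function(norm, cell_meta, types = NULL,
                                   alpha = 0.05, min_log2fc = 0.5,
                                   min_pct = 0.25, cap = 50) {
  if (is.null(cell_meta$type)) stop_regioglia("cell_meta lacks 'type'")
  ctrl <- which(cell_meta$condition == "control")
  if (!length(ctrl)) stop_regioglia("no control cells")
  types <- types %||% sort(unique(cell_meta$type))
  genes <- colnames(norm) %||% as.character(seq_len(ncol(norm)))
  out <- list()
  empty <- data.frame(gene = character(), log2fc = numeric(),
                      pct = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  for (tp in types) {
    idxA <- ctrl[cell_meta$type[ctrl] == tp]
    idxB <- setdiff(ctrl, idxA)
    if (length(idxA) < 3) {
      warning(sprintf("type '%s' has <3 control cells; excluded", tp),
              call. = FALSE)
      next
    }
    pct <- detection_fraction(norm, idxA)
    l2fc <- log2(fold_change_linear(norm, idxA, idxB))
    cand <- which(pct >= min_pct & l2fc >= min_log2fc)
    if (!length(cand)) { out[[tp]] <- empty; next }
    p <- wilcoxon_pvalues(norm[, cand, drop = FALSE], idxA, idxB)
    p_adj <- stats::p.adjust(p, method = "BH")
    keep <- p_adj < alpha
    if (!any(keep)) { out[[tp]] <- empty; next }
    tab <- data.frame(gene = genes[cand[keep]], log2fc = l2fc[cand[keep]],
                      pct = pct[cand[keep]], p = p[keep],
                      p_adj = p_adj[keep], stringsAsFactors = FALSE)
    tab <- tab[order(-tab$log2fc, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    out[[tp]] <- utils::head(tab, cap)
  }
  structure(out, class = "signature_set")
}

#' Expression and detection-proportion fold changes of signature genes
#'
#' Within each cell type, for each of its signature genes:
#' `fc_exp = (mean normalized expression in stress + eps) /
#' (mean in control + eps)` and `fc_prop = (fraction of stress cells with
#' count > 0 + delta) / (fraction of control cells with count > 0 +
#' delta)`. The pseudocounts keep both ratios finite and positive; a gene
#' detected in no cell of either condition gets fc_exp = fc_prop = 1.
#'
#' @param norm normalized matrix (cells x genes).
#' @param counts raw count matrix (cells x genes), used for the detection
#'   proportions.
#' @param cell_meta cell metadata with `condition` and `type`.
#' @param signatures a `signature_set` (or named list type -> gene ids).
#' @param eps expression pseudocount.
#' @param delta proportion pseudocount.
#' @return data.frame `type`, `gene`, `fc_exp`, `fc_prop`; types missing a
#'   condition are excluded with a warning. Pseudocounts are recorded as
#'   attributes `"eps"` and `"delta"`.
#' @export
compute_fold_changes <- function(norm, counts, cell_meta, signatures,
                                 eps = 0.01, delta = 0.001) {
  if (is.null(cell_meta$type)) stop_regioglia("cell_meta lacks 'type'")
  rows <- list()
  for (tp in names(signatures)) {
    sig <- signatures[[tp]]
    gs <- if (is.data.frame(sig)) sig$gene else sig
    if (!length(gs)) next
    idx_s <- which(cell_meta$type == tp & cell_meta$condition == "stress")
    idx_c <- which(cell_meta$type == tp & cell_meta$condition == "control")
    if (!length(idx_s) || !length(idx_c)) {
      warning(sprintf("type '%s' lacks a condition; excluded", tp),
              call. = FALSE)
      next
    }
    gs <- intersect(gs, colnames(norm))
    mean_s <- Matrix::colMeans(norm[idx_s, gs, drop = FALSE])
    mean_c <- Matrix::colMeans(norm[idx_c, gs, drop = FALSE])
    prop_s <- Matrix::colMeans(counts[idx_s, gs, drop = FALSE] > 0)
    prop_c <- Matrix::colMeans(counts[idx_c, gs, drop = FALSE] > 0)
    rows[[tp]] <- data.frame(type = tp, gene = gs,
                             fc_exp = (mean_s + eps) / (mean_c + eps),
                             fc_prop = (prop_s + delta) / (prop_c + delta),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(type = character(), gene = character(),
               fc_exp = numeric(), fc_prop = numeric())
  }
  attr(out, "eps") <- eps
  attr(out, "delta") <- delta
  out
}

#' Alteration Score per cell type
#'
#' For each cell type j with signature genes i, the score is
#' `sum_i log2(fc_exp(i) * fc_prop(i) + 1)`: a gene whose expression and
#' detection proportion are unchanged contributes exactly 1, so under no
#' change the score equals the signature size. With `symmetric = TRUE`
#' each fold change is replaced by `max(fc, 1/fc)` so strong
#' down-regulation also raises the score instead of falling below the
#' no-change baseline.
#'
#' @param fc fold-change table from [compute_fold_changes()].
#' @param symmetric score magnitude of change rather than signed change.
#' @return an `alteration_result`: data.frame `type`, `n_genes`, `score`,
#'   `score_per_gene` with the per-gene contribution table as attribute
#'   `"contributions"` (columns `type`, `gene`, `contribution`).
#' @export
alteration_score <- function(fc, symmetric = FALSE) {
  if (nrow(fc) > 0) {
    bad <- !is.finite(fc$fc_exp) | !is.finite(fc$fc_prop) |
      fc$fc_exp <= 0 | fc$fc_prop <= 0
    if (any(bad))
      stop_regioglia("non-positive or non-finite fold change for %d gene(s)",
                     sum(bad))
  }
  fe <- fc$fc_exp; fp <- fc$fc_prop
  if (symmetric) { fe <- pmax(fe, 1 / fe); fp <- pmax(fp, 1 / fp) }
  contrib <- log2(fe * fp + 1)
  contributions <- data.frame(type = fc$type, gene = fc$gene,
                              contribution = contrib,
                              stringsAsFactors = FALSE)
  types <- unique(fc$type)
  score <- vapply(types, function(tp) sum(contrib[fc$type == tp]),
                  numeric(1))
  n_genes <- vapply(types, function(tp) sum(fc$type == tp), integer(1))
  out <- data.frame(type = types, n_genes = n_genes, score = score,
                    score_per_gene = ifelse(n_genes > 0, score / n_genes,
                                            0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, contributions = contributions,
            symmetric = symmetric, class = c("alteration_result",
                                             "data.frame"))
}

#' Permutation null band for Alteration Scores
#'
#' Condition labels are permuted within (type, donor) strata (within type
#' only, with a warning, when fewer than two donors are present), fold
#' changes and scores recomputed per permutation, and per-type null
#' quantiles returned. With `include_identity = TRUE` the first
#' "permutation" is the identity, so the observed score is a member of the
#' null set (useful for rank-based p-values).
#'
#' @param study an `expression_study` with typed cells.
#' @param signatures a `signature_set`.
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @param eps,delta pseudocounts passed to [compute_fold_changes()].
#' @param symmetric passed to [alteration_score()].
#' @param include_identity make the identity permutation the first draw.
#' @return data.frame `type`, `q025`, `q50`, `q975`, `observed`, with the
#'   full permutation score matrix as attribute `"perm_scores"`.
#' @export
acscore_null_band <- function(study, signatures, n_perm = 200, seed = 1L,
                              eps = 0.01, delta = 0.001,
                              symmetric = FALSE, include_identity = FALSE) {
  if (n_perm < 20) stop_regioglia("n_perm must be >= 20")
  meta <- study$cell_meta
  if (is.null(meta$type)) stop_regioglia("cell_meta lacks 'type'")
  norm <- normalize_log1p(study)
  obs <- alteration_score(compute_fold_changes(norm, study$counts, meta,
                                               signatures, eps, delta),
                          symmetric)
  strata <- if (length(unique(meta$donor)) >= 2) {
    paste(meta$type, meta$donor)
  } else {
    warning("fewer than 2 donors; permuting within type only",
            call. = FALSE)
    meta$type
  }
  with_seed(seed, {
    perm_scores <- matrix(NA_real_, nrow = n_perm, ncol = nrow(obs),
                          dimnames = list(NULL, obs$type))
    for (b in seq_len(n_perm)) {
      pm <- meta
      if (!(b == 1 && include_identity)) {
        for (st in unique(strata)) {
          idx <- which(strata == st)
          pm$condition[idx] <- sample(meta$condition[idx])
        }
      }
      sc <- alteration_score(compute_fold_changes(norm, study$counts, pm,
                                                  signatures, eps, delta),
                             symmetric)
      perm_scores[b, sc$type] <- sc$score
    }
    qs <- apply(perm_scores, 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
    out <- data.frame(type = obs$type,
                      q025 = qs[1, obs$type], q50 = qs[2, obs$type],
                      q975 = qs[3, obs$type], observed = obs$score,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    structure(out, perm_scores = perm_scores)
  })
}
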