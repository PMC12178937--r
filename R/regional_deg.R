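#' Differential expression between two cell groups
#'
#' Genes are tested iff detected (normalized value > 0) in at least
#' `min_pct` of group A or of group B and the absolute log2 fold change is
#' at least `logfc_threshold`; tested genes get a two-sided Wilcoxon
#' rank-sum p on the log-normalized values and a Benjamini-Hochberg (or
#' Bonferroni) adjusted p over the tested set. Fold changes are computed on
#' expm1-averaged normalized values with pseudocount 0.01, reported in
#' log2; only tested genes appear in the output.
#'
#' @param norm normalized matrix (cells x genes) from [normalize_log1p()].
#' @param cellsA,cellsB row indices or cell-id character vectors of the two
#'   groups (A vs B; fold change direction is A/B).
#' @param min_pct minimum detection fraction in either group.
#' @param logfc_threshold minimum |log2 fold change|.
#' @param p_adjust `"BH"` (default) or `"bonferroni"`.
#' @param pseudo pseudocount on group means before the ratio.
#' @return data.frame with columns `gene`, `log2fc`, `fc` (linear),
#'   `pct_A`, `pct_B`, `p`, `p_adj`, `direction` (`"A-high"`/`"B-high"`),
#'   ordered by `p_adj` then `p`.
#' @export
differential_expression <- function(norm, cellsA, cellsB, min_pct = 0.2,
                                    logfc_threshold = 0.2,
                                    p_adjust = c("BH", "bonferroni"),
                                    pseudo = 0.01) {
  p_adjust <- match.arg(p_adjust)
  if (is.character(cellsA)) cellsA <- match(cellsA, rownames(norm))
  if (is.character(cellsB)) cellsB <- match(cellsB, rownames(norm))
  if (is.logical(cellsA)) cellsA <- which(cellsA)
  if (is.logical(cellsB)) cellsB <- which(cellsB)
  if (length(cellsA) == 0 || length(cellsB) == 0)
    stop_regioglia("empty group in differential_expression")
  pctA <- detection_fraction(norm, cellsA)
  pctB <- detection_fraction(norm, cellsB)
  fc <- fold_change_linear(norm, cellsA, cellsB, pseudo)
  l2fc <- log2(fc)
  tested <- (pctA >= min_pct | pctB >= min_pct) &
    abs(l2fc) >= logfc_threshold
  genes <- colnames(norm) %||% as.character(seq_len(ncol(norm)))
  if (!any(tested)) {
    return(data.frame(gene = character(), log2fc = numeric(),
                      fc = numeric(), pct_A = numeric(), pct_B = numeric(),
                      p = numeric(), p_adj = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  p <- wilcoxon_pvalues(norm[, tested, drop = FALSE], cellsA, cellsB)
  out <- data.frame(gene = genes[tested],
                    log2fc = l2fc[tested], fc = fc[tested],
                    pct_A = pctA[tested], pct_B = pctB[tested],
                    p = p,
                    p_adj = stats::p.adjust(p, method = p_adjust),
                    direction = ifelse(l2fc[tested] >= 0, "A-high",
                                       "B-high"),
                    stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p, out$gene), , drop = FALSE]
}

#' Regional high-expression categories (m-HX / p-HX)
#'
#' Given a DEG table computed macula (A) vs periphery (B) within one cell
#' type, a gene is `m-HX` iff its macula/periphery fold change exceeds
#' `fc_cutoff` with adjusted p below `alpha`; `p-HX` is symmetric
#' (periphery/macula fold change above the cutoff). The fold-change cutoff
#' is on the linear scale.
#'
#' @param deg DEG table from [differential_expression()] (A = macula,
#'   B = periphery).
#' @param fc_cutoff linear fold-change cutoff.
#' @param alpha adjusted-p significance level.
#' @return data.frame `gene`, `category` in `{"m-HX", "p-HX", "none"}`.
#' @export
categorize_regional <- function(deg, fc_cutoff = 1.5, alpha = 0.05) {
  sig <- deg$p_adj < alpha
  category <- rep("none", nrow(deg))
  category[sig & deg$fc > fc_cutoff] <- "m-HX"
  category[sig & deg$fc < 1 / fc_cutoff] <- "p-HX"
  data.frame(gene = deg$gene, category = category,
             stringsAsFactors = FALSE)
}

#' Flag light-induced expression changes
#'
#' Given a DEG table computed stress (A) vs control (B), a gene is flagged
#' `up` iff its adjusted p is below `alpha` and its linear fold change
#' exceeds 1 by more than `min_change` (default the 9 % rule), `down`
#' symmetrically, else `none`.
#'
#' @param deg DEG table from [differential_expression()] (A = stress,
#'   B = control).
#' @param alpha adjusted-p significance level.
#' @param min_change minimum |FC - 1| on the linear scale.
#' @return data.frame `gene`, `flag` in `{"up", "down", "none"}`.
#' @export
flag_light_induced <- function(deg, alpha = 0.05, min_change = 0.09) {
  sig <- deg$p_adj < alpha
  flag <- rep("none", nrow(deg))
  flag[sig & (deg$fc - 1) > min_change] <- "up"
  flag[sig & (1 - deg$fc) > min_change] <- "down"
  data.frame(gene = deg$gene, flag = flag, stringsAsFactors = FALSE)
}

#' Top-k genes by fold change on one side
#'
#' Among genes significant at `alpha`, returns the `k` with the largest
#' fold change in the requested direction; ties broken by adjusted p, then
#' lexicographic gene id, so the ordering is reproducible.
#'
#' @param deg DEG table from [differential_expression()].
#' @param k number of genes.
#' @param side `"A-high"` (fc > 1) or `"B-high"` (fc < 1).
#' @param alpha adjusted-p significance level.
#' @return character vector of up to `k` gene ids, strongest first.
#' @export
top_k_by_fold_change <- function(deg, k = 40,
                                 side = c("A-high", "B-high"),
                                 alpha = 0.05) {
  if (k < 1) stop_regioglia("k must be >= 1")
  side <- match.arg(side)
  sig <- deg[deg$p_adj < alpha, , drop = FALSE]
  sig <- if (side == "A-high") sig[sig$fc > 1, , drop = FALSE] else
    sig[sig$fc < 1, , drop = FALSE]
  eff <- if (side == "A-high") -sig$fc else sig$fc
  ord <- order(eff, sig$p_adj, sig$gene)
  utils::head(sig$gene[ord], k)
}

#' Marker-normalized mean expression
#'
#' Per group, the mean (linear-scale) expression of each target gene is
#' divided by the mean expression of a structural reference gene, the
#' standard way to compare a stress gene across regions while controlling
#' for the reference cell type's abundance.
#'
#' @param norm normalized matrix (cells x genes).
#' @param targets character vector of target gene ids.
#' @param reference reference gene id.
#' @param groups named list of cell indices (or cell-id vectors), one entry
#'   per group.
#' @return data.frame `group`, `gene`, `ratio`; `ratio` is `NA` with a
#'   warning for a group whose reference mean is zero.
#' @export
marker_normalized_expression <- function(norm, targets, reference, groups) {
  if (!reference %in% colnames(norm))
    stop_regioglia("reference gene '%s' absent", reference)
  miss <- setdiff(targets, colnames(norm))
  if (length(miss)) stop_regioglia("target gene(s) absent: %s",
                                   paste(miss, collapse = ", "))
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (is.character(idx)) idx <- match(idx, rownames(norm))
    ref_mean <- mean(expm1(norm[idx, reference]))
    tgt_mean <- vapply(targets, function(tg)
      mean(expm1(norm[idx, tg])), numeric(1))
    if (ref_mean == 0) {
      warning(sprintf("reference mean is zero in group '%s'", g),
              call. = FALSE)
      ratio <- rep(NA_real_, length(targets))
    } else {
      ratio <- tgt_mean / ref_mean
    }
    rows[[g]] <- data.frame(group = g, gene = targets, ratio = ratio,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sizes of all intersection regions of named gene sets
#'
#' Computes the Venn-diagram region counts: for every non-empty combination
#' of the sets, the number of elements belonging to exactly those sets.
#'
#' @param sets named list of character vectors (at least two).
#' @return data.frame `region` (set names joined by `&`), `count`.
#' @export
deg_set_overlap <- function(sets) {
  if (length(sets) < 2) stop_regioglia("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_regioglia("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  region <- apply(combos, 1, function(cc)
    paste(names(sets)[as.logical(cc)], collapse = "&"))
  count <- apply(combos, 1, function(cc) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(m) all(m == as.logical(cc))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Annotate cells by marker-gene score
#'
#' Each gene is z-scored across cells; a cell's score for a type is the
#' mean z-score of that type's markers, and the cell is labeled with the
#' argmax type when its margin over the runner-up reaches `min_margin`
#' (ties and narrow margins are left unassigned).
#'
#' @param norm normalized matrix (cells x genes).
#' @param markers named list: type -> character vector of marker gene ids.
#' @param min_margin minimum score margin over the second-best type.
#' @return character vector of type labels (`NA` = unassigned), one per
#'   cell, with the score matrix as attribute `"scores"`.
#' @export
annotate_by_markers <- function(norm, markers, min_margin = 0) {
  if (!length(markers) || any(!lengths(markers)))
    stop_regioglia("marker sets must be non-empty")
  mat <- as.matrix(norm)
  mu <- colMeans(mat)
  s <- apply(mat, 2, stats::sd)
  s[s == 0] <- 1
  z <- sweep(sweep(mat, 2, mu), 2, s, "/")
  scores <- vapply(markers, function(gs) {
    gs <- intersect(gs, colnames(mat))
    if (!length(gs)) return(rep(NA_real_, nrow(mat)))
    rowMeans(z[, gs, drop = FALSE])
  }, numeric(nrow(mat)))
  scores <- matrix(scores, nrow = nrow(mat),
                   dimnames = list(rownames(mat), names(markers)))
  labels <- apply(scores, 1, function(sc) {
    if (all(is.na(sc))) return(NA_character_)
    ord <- order(sc, decreasing = TRUE)
    margin <- if (length(sc) > 1) sc[ord[1]] - sc[ord[2]] else Inf
    # exact ties are always unassigned, regardless of min_margin
    if (margin > 0 && margin >= min_margin) names(sc)[ord[1]] else
      NA_character_
  })
  structure(labels, scores = scores)
}
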