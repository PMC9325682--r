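## Cross-modality label transfer: chromatin cells annotated from expression
## clusters through a shared gene feature space.

#' Shared standardized feature space across modalities
#'
#' Intersects gene names between a chromatin gene-activity matrix and an
#' expression matrix, restricts to the most variable expression genes
#' present in both, and standardizes each gene within each modality
#' separately (mean 0, sd 1 across that modality's cells). Genes with zero
#' variance in either modality are dropped.
#'
#' @param gene_scores genes x chromatin-cells gene activity matrix.
#' @param expression genes x expression-cells (log-normalized) matrix.
#' @param n_features number of variable genes to keep.
#' @param min_shared minimum required shared gene count.
#' @return list: `atac`, `rna` (standardized genes x cells matrices over
#'   the same genes).
#' @export
common_feature_space <- function(gene_scores, expression,
                                 n_features = 2000L, min_shared = 200L) {
  shared <- intersect(rownames(gene_scores), rownames(expression))
  if (length(shared) < min_shared)
    stop("too few shared genes (", length(shared), " < ", min_shared, ")")
  v <- apply(as.matrix(expression[shared, , drop = FALSE]), 1L, stats::var)
  genes <- names(sort(v, decreasing = TRUE))[seq_len(min(n_features,
                                                         length(shared)))]
  a <- row_zscore(as.matrix(gene_scores[genes, , drop = FALSE]))
  r <- row_zscore(as.matrix(expression[genes, , drop = FALSE]))
  ok <- stats::complete.cases(a) & stats::complete.cases(r)
  list(atac = a[ok, , drop = FALSE], rna = r[ok, , drop = FALSE])
}

#' Cross-modality anchors
#'
#' Canonical correlation directions are obtained from the SVD of the
#' cross-modality product of the standardized matrices; cells are embedded
#' by the corresponding singular vectors and L2-normalized. Anchors are
#' mutual nearest neighbor pairs (k = `k_anchor`) in the canonical space;
#' each anchor is scored by the overlap fraction of the two cells'
#' `k_filter`-nearest chromatin neighborhoods in the shared feature space,
#' clipped to [0, 1].
#'
#' @param spaces list from [common_feature_space()].
#' @param n_cc number of canonical components.
#' @param k_anchor mutual-nearest-neighbor k.
#' @param k_filter neighborhood size for anchor scoring.
#' @return list: `anchors` (data.frame rna, atac, score), `rna_embed`,
#'   `atac_embed` (L2-normalized canonical coordinates).
#' @export
find_anchors <- function(spaces, n_cc = 20L, k_anchor = 5L, k_filter = 50L) {
  rna <- spaces$rna; atac <- spaces$atac
  n_cc_eff <- min(n_cc, ncol(rna) - 1L, ncol(atac) - 1L, nrow(rna) - 1L)
  if (n_cc_eff < n_cc)
    warning("rank limits canonical components to ", n_cc_eff)
  cc <- crossprod(rna, atac)           # rna-cells x atac-cells
  s <- svd(cc, nu = n_cc_eff, nv = n_cc_eff)
  re <- l2_normalize(s$u)
  ae <- l2_normalize(s$v)
  rownames(re) <- colnames(rna); rownames(ae) <- colnames(atac)
  k <- min(k_anchor, nrow(re) - 1L, nrow(ae) - 1L)
  nn_ra <- FNN::get.knnx(ae, re, k = k)$nn.index  # per rna cell: atac nbrs
  nn_ar <- FNN::get.knnx(re, ae, k = k)$nn.index
  pairs <- list()
  for (r in seq_len(nrow(re))) {
    for (a in nn_ra[r, ]) {
      if (r %in% nn_ar[a, ]) pairs[[length(pairs) + 1L]] <- c(r, a)
    }
  }
  if (length(pairs) == 0L)
    return(list(anchors = data.frame(rna = integer(), atac = integer(),
                                     score = numeric()),
                rna_embed = re, atac_embed = ae))
  pr <- do.call(rbind, pairs)
  kf <- min(k_filter, ncol(spaces$atac))
  # neighborhoods among chromatin cells in the shared feature space
  nb_r <- FNN::get.knnx(t(atac), t(rna[, pr[, 1L], drop = FALSE]),
                        k = kf)$nn.index
  nb_a <- FNN::get.knnx(t(atac), t(atac[, pr[, 2L], drop = FALSE]),
                        k = kf)$nn.index
  score <- vapply(seq_len(nrow(pr)), function(i)
    length(intersect(nb_r[i, ], nb_a[i, ])) / kf, numeric(1))
  list(anchors = data.frame(rna = pr[, 1L], atac = pr[, 2L],
                            score = pmin(pmax(score, 0), 1)),
       rna_embed = re, atac_embed = ae)
}

l2_normalize <- function(m) {
  nr <- sqrt(rowSums(m^2))
  nr[nr == 0] <- 1
  m / nr
}

#' Transfer expression cluster labels to chromatin cells
#'
#' Each chromatin cell's label-score vector is the kernel-weighted average
#' of the one-hot cluster labels of its `k_weight` nearest anchors in the
#' canonical space (Gaussian kernel on distance, bandwidth the mean
#' distance to the k-th anchor, multiplied by the anchor score) and is
#' renormalized to sum 1. Cells are confident iff the maximal score
#' exceeds 0.5.
#'
#' @param anchor_set list from [find_anchors()].
#' @param rna_labels factor (or vector) of expression cluster labels,
#'   aligned to the rna cells of the feature space.
#' @param k_weight number of anchors used per chromatin cell.
#' @param score_threshold confidence threshold on the max label score.
#' @return object of class `transfer_result`: data.frame (cell, label,
#'   score, confident) with the full score matrix in the `scores`
#'   attribute.
#' @export
transfer_labels <- function(anchor_set, rna_labels, k_weight = 50L,
                            score_threshold = 0.5) {
  an <- anchor_set$anchors
  ae <- anchor_set$atac_embed
  labels <- as.factor(rna_labels)
  n_atac <- nrow(ae)
  lv <- levels(labels)
  scores <- matrix(1 / length(lv), n_atac, length(lv),
                   dimnames = list(rownames(ae), lv))
  if (nrow(an) == 0L) {
    warning("no anchors; all cells unconfident")
    res <- data.frame(cell = rownames(ae), label = NA_character_,
                      score = NA_real_, confident = FALSE,
                      stringsAsFactors = FALSE)
    attr(res, "scores") <- scores
    class(res) <- c("transfer_result", "data.frame")
    return(res)
  }
  anchor_pos <- ae[an$atac, , drop = FALSE]
  onehot <- outer(labels[an$rna], lv, "==") * 1
  k <- min(k_weight, nrow(an))
  nn <- FNN::get.knnx(anchor_pos, ae, k = k)
  bw <- mean(nn$nn.dist[, k])
  if (bw == 0) bw <- 1
  for (i in seq_len(n_atac)) {
    idx <- nn$nn.index[i, ]
    w <- exp(-nn$nn.dist[i, ]^2 / (2 * bw^2)) * pmax(an$score[idx], 1e-6)
    sv <- colSums(onehot[idx, , drop = FALSE] * w)
    tot <- sum(sv)
    scores[i, ] <- if (tot > 0) sv / tot else 1 / length(lv)
  }
  best <- max.col(scores, ties.method = "first")
  res <- data.frame(cell = rownames(ae), label = lv[best],
                    score = scores[cbind(seq_len(n_atac), best)],
                    confident = scores[cbind(seq_len(n_atac), best)] >
                      score_threshold,
                    stringsAsFactors = FALSE)
  attr(res, "scores") <- scores
  class(res) <- c("transfer_result", "data.frame")
  res
}

#' Cross-tabulation of chromatin clusters vs transferred labels
#'
#' The alluvial-style summary: counts of cells per (chromatin cluster,
#' transferred label) pair, keeping only ribbons wider than `min_cells`.
#'
#' @param atac_clusters `cluster_assignment` or factor per chromatin cell.
#' @param transfer a `transfer_result`.
#' @param min_cells ribbon width threshold (pairs with more than this many
#'   cells are kept).
#' @return data.frame: atac_cluster, label, n_cells.
#' @export
transfer_crosstab <- function(atac_clusters, transfer, min_cells = 20L) {
  cl <- if (inherits(atac_clusters, "cluster_assignment"))
    atac_clusters$cluster else as.factor(atac_clusters)
  tb <- as.data.frame(table(atac_cluster = cl[transfer$cell],
                            label = transfer$label),
                      stringsAsFactors = FALSE)
  names(tb)[3L] <- "n_cells"
  tb[tb$n_cells > min_cells, , drop = FALSE]
}
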