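## Gene activity: accessibility aggregated around genes with exponential
## distance decay and neighbor-boundary filtering.

# Strand-resolved extended gene body: TSS extended 5 kb upstream, through the
# TTS. Returns matrix with columns left/right (0-based, inclusive bounds).
extended_body <- function(genes, upstream = 5000L) {
  left <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tts)
  right <- ifelse(genes$strand == "+", genes$tts, genes$tss + upstream)
  cbind(left = left, right = right)
}

#' Distance-decay weight of a genomic position for a gene
#'
#' Weight 1 inside the extended gene body (TSS - 5 kb upstream through the
#' TTS, strand-resolved); outside, exp(-d / tau) of the distance d to the
#' nearer extended-body boundary, truncated to 0 beyond `max_dist`; and 0
#' for positions lying inside another gene's extended body or past the
#' midpoint between the two extended bodies (neighbor-boundary filtering).
#'
#' @param annotation a `genome_annotation`.
#' @param gene gene name.
#' @param position vector of 0-based positions on the gene's chromosome.
#' @param tau exponential decay constant (bp).
#' @param upstream TSS upstream extension (bp).
#' @param max_dist truncation distance (bp).
#' @return numeric weights in [0, 1].
#' @export
#' @examples
#' gn <- make_genome(1, 1e6, 5, seed = 1)
#' g <- gn$genes$gene[1]
#' gene_score_weight(gn, g, gn$genes$tss[1])
gene_score_weight <- function(annotation, gene, position, tau = 5000,
                              upstream = 5000L, max_dist = 1e5) {
  genes <- annotation$genes
  gi <- match(gene, genes$gene)
  if (is.na(gi)) stop("unknown gene: ", gene)
  eb <- extended_body(genes, upstream)
  same_chr <- which(genes$chrom == genes$chrom[gi])
  w <- weight_one_gene(position, gi, same_chr, eb, tau, max_dist)
  w
}

# core weight computation shared by gene_score_weight / compute_gene_scores
weight_one_gene <- function(position, gi, same_chr, eb, tau, max_dist) {
  L <- eb[gi, "left"]; R <- eb[gi, "right"]
  d <- ifelse(position < L, L - position,
              ifelse(position > R, position - R, 0))
  w <- ifelse(d == 0, 1, exp(-d / tau))
  w[d > max_dist] <- 0
  others <- setdiff(same_chr, gi)
  if (length(others) > 0L) {
    for (oi in others) {
      oL <- eb[oi, "left"]; oR <- eb[oi, "right"]
      inside_other <- position >= oL & position <= oR
      # midpoint between the two extended bodies (only on the facing side)
      if (oL > R) {            # neighbor to the right
        mid <- (R + oL) / 2
        w[position > mid] <- ifelse(
          position[position > mid] > R, 0, w[position > mid])
      } else if (oR < L) {     # neighbor to the left
        mid <- (oR + L) / 2
        w[position < mid] <- ifelse(
          position[position < mid] < L, 0, w[position < mid])
      }
      w[inside_other] <- 0
    }
  }
  unname(w)
}

#' Gene activity score matrix from fragments
#'
#' Per cell, each Tn5 insertion contributes its distance-decay weight (see
#' [gene_score_weight()]) to every gene on its chromosome; per-cell totals
#' are then normalized to `target_depth` and log1p-transformed ("scaled"
#' expression-like values). The raw, unnormalized scores are kept in the
#' `raw` attribute.
#'
#' @param frags fragment data.frame (QC-passing cells).
#' @param annotation a `genome_annotation`.
#' @param target_depth per-cell normalization target.
#' @param tau,upstream,max_dist weight-function parameters.
#' @param log1p logical; apply log1p after depth normalization.
#' @param barcodes column order; defaults to barcodes present in `frags`.
#' @return dense matrix genes x cells (normalized), with attribute `raw`.
#' @export
compute_gene_scores <- function(frags, annotation, target_depth = 1e4,
                                tau = 5000, upstream = 5000L, max_dist = 1e5,
                                log1p = TRUE, barcodes = NULL) {
  genes <- annotation$genes
  if (is.null(barcodes)) barcodes <- sort(unique(frags$barcode))
  ins <- insertion_sites(frags)
  cell <- match(ins$barcode, barcodes)
  ins <- ins[!is.na(cell), ]; cell <- cell[!is.na(cell)]
  eb <- extended_body(genes, upstream)
  raw <- matrix(0, nrow = nrow(genes), ncol = length(barcodes),
                dimnames = list(genes$gene, barcodes))
  for (cn in unique(genes$chrom)) {
    same_chr <- which(genes$chrom == cn)
    ii <- which(ins$chrom == cn)
    if (length(ii) == 0L) next
    pos <- ins$pos[ii]; cc <- cell[ii]
    ord <- order(pos)
    pos <- pos[ord]; cc <- cc[ord]
    for (gi in same_chr) {
      lo <- eb[gi, "left"] - max_dist; hi <- eb[gi, "right"] + max_dist
      a <- findInterval(lo - 1L, pos) + 1L
      b <- findInterval(hi, pos)
      if (b < a) next
      idx <- a:b
      w <- weight_one_gene(pos[idx], gi, same_chr, eb, tau, max_dist)
      nz <- w > 0
      if (!any(nz)) next
      acc <- rowsum(w[nz], cc[idx][nz])
      raw[gi, as.integer(rownames(acc))] <-
        raw[gi, as.integer(rownames(acc))] + acc[, 1L]
    }
  }
  zero_dom <- rowSums(raw) == 0
  if (any(zero_dom))
    warning(sum(zero_dom), " gene(s) with zero accessible signal")
  tot <- colSums(raw)
  norm <- sweep(raw, 2L, ifelse(tot > 0, tot, 1), "/") * target_depth
  if (log1p) norm <- log1p(norm)
  attr(norm, "raw") <- raw
  attr(norm, "target_depth") <- target_depth
  norm
}

#' Differential gene-score testing (cluster vs rest)
#'
#' Two-sided Wilcoxon rank-sum test of each gene's scores in a cluster
#' against all other cells; log2 fold change of (pseudocount-shifted)
#' means; Benjamini-Hochberg FDR across genes within each cluster; a gene
#' passes in a cluster iff LFC >= `lfc_min` and FDR <= `fdr_max`.
#'
#' @param scores genes x cells matrix (normalized gene scores or
#'   log-normalized expression).
#' @param clusters `cluster_assignment` or factor aligned to columns.
#' @param lfc_min,fdr_max pass thresholds (defaults LFC >= 1, FDR <= 0.05).
#' @param eps pseudocount for the fold-change means.
#' @return data.frame: gene, cluster, lfc, p, fdr, pass.
#' @export
differential_gene_scores <- function(scores, clusters, lfc_min = 1,
                                     fdr_max = 0.05, eps = 1e-5) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.factor(clusters)
  stopifnot(length(cl) == ncol(scores))
  if (nlevels(droplevels(cl)) < 2L) stop("need >= 2 clusters")
  out <- list()
  for (cli in levels(droplevels(cl))) {
    inside <- which(cl == cli)
    if (length(inside) < 2L) {
      warning("cluster ", cli, " has < 2 cells; tests skipped")
      next
    }
    outside <- which(cl != cli)
    p <- apply(scores, 1L, function(x)
      suppressWarnings(stats::wilcox.test(x[inside], x[outside])$p.value))
    p[is.na(p)] <- 1
    m_in <- rowMeans(scores[, inside, drop = FALSE])
    m_out <- rowMeans(scores[, outside, drop = FALSE])
    lfc <- log2((m_in + eps) / (m_out + eps))
    fdr <- stats::p.adjust(p, "BH")
    out[[cli]] <- data.frame(gene = rownames(scores), cluster = cli,
                             lfc = lfc, p = p, fdr = fdr,
                             pass = lfc >= lfc_min & fdr <= fdr_max,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Marker-dictionary cluster annotation
#'
#' Standardizes each gene's score across cells, averages per cluster over
#' each dictionary entry's genes, and labels each cluster by the entry with
#' the highest mean standardized score. The margin to the runner-up is
#' reported; exact ties yield the label "ambiguous" with both candidates
#' listed. An optional pair of subtype genes (e.g. CD4 vs CD8A) appends a
#' subtype call comparing their standardized scores.
#'
#' @param scores genes x cells matrix.
#' @param clusters `cluster_assignment` or factor aligned to columns.
#' @param marker_dictionary named list: label -> character vector of genes.
#' @param subtype_genes optional named character vector of length >= 2
#'   (subtype label -> gene); the subtype with the higher mean standardized
#'   score is appended as `subtype`.
#' @return data.frame: cluster, label, margin, runner_up (and `subtype`).
#' @export
annotate_clusters <- function(scores, clusters, marker_dictionary,
                              subtype_genes = NULL) {
  if (length(marker_dictionary) == 0L) stop("empty marker dictionary")
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.factor(clusters)
  need <- unique(c(unlist(marker_dictionary), subtype_genes))
  missing <- setdiff(need, rownames(scores))
  if (length(missing) > 0L)
    stop("dictionary gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  z <- row_zscore(as.matrix(scores))
  z[is.na(z)] <- 0
  out <- lapply(levels(droplevels(cl)), function(cli) {
    cols <- which(cl == cli)
    entry_score <- vapply(marker_dictionary, function(gs)
      mean(z[gs, cols, drop = FALSE]), numeric(1))
    ord <- order(entry_score, decreasing = TRUE)
    top <- entry_score[ord[1L]]
    second <- if (length(entry_score) > 1L) entry_score[ord[2L]] else -Inf
    margin <- top - second
    label <- if (length(entry_score) > 1L && margin == 0)
      "ambiguous" else names(entry_score)[ord[1L]]
    row <- data.frame(cluster = cli, label = label, margin = margin,
                      runner_up = if (length(entry_score) > 1L)
                        names(entry_score)[ord[2L]] else NA_character_,
                      stringsAsFactors = FALSE)
    if (label == "ambiguous")
      row$runner_up <- paste(names(entry_score)[ord[1:2]], collapse = "|")
    if (!is.null(subtype_genes)) {
      ss <- vapply(subtype_genes, function(g)
        mean(z[g, cols]), numeric(1))
      row$subtype <- names(ss)[which.max(ss)]
    }
    row
  })
  do.call(rbind, out)
}
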