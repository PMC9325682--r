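## scRNA-seq quality filtering, normalization, clustering, markers, signed
## co-expression modules and the dysfunction z-score comparison.

#' Per-cell expression QC metrics
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return data.frame: barcode, n_features, n_counts, percent_mito.
#' @export
expression_qc_metrics <- function(counts, mito_prefix = "MT-") {
  mito <- startsWith(rownames(counts), mito_prefix)
  tot <- Matrix::colSums(counts)
  data.frame(barcode = colnames(counts),
             n_features = Matrix::colSums(counts > 0),
             n_counts = tot,
             percent_mito = ifelse(tot > 0,
                                   Matrix::colSums(counts[mito, , drop = FALSE]) / tot,
                                   0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression quality filter
#'
#' Applies the strict per-cell filter nFeature > 500 & nFeature < 5000 &
#' percent mito < 0.25 & nCount < 50000, and removes cells carrying more
#' than one productive chain of the same TCR locus. Cells with at least one
#' productive beta chain form the T cell subset (`t_cells` attribute).
#'
#' @param counts genes x cells count matrix.
#' @param contigs optional TCR contig data.frame (barcode, chain,
#'   productive) for the multi-chain filter.
#' @param min_features,max_features,max_mito,max_counts strict thresholds.
#' @param mito_prefix mitochondrial gene-name prefix.
#' @return filtered count matrix with attributes `metrics` and `t_cells`
#'   (barcodes with >= 1 productive beta chain, after filtering).
#' @export
qc_filter_expression <- function(counts, contigs = NULL,
                                 min_features = 500L, max_features = 5000L,
                                 max_mito = 0.25, max_counts = 50000L,
                                 mito_prefix = "MT-") {
  qc <- expression_qc_metrics(counts, mito_prefix)
  keep <- qc$n_features > min_features & qc$n_features < max_features &
    qc$percent_mito < max_mito & qc$n_counts < max_counts
  keep_bc <- qc$barcode[keep]
  t_cells <- character(0)
  if (!is.null(contigs)) {
    prod <- contigs[productive_flag(contigs$productive), ]
    n_a <- table(prod$barcode[prod$chain == "TRA"])
    n_b <- table(prod$barcode[prod$chain == "TRB"])
    multi <- union(names(n_a)[n_a > 1L], names(n_b)[n_b > 1L])
    keep_bc <- setdiff(keep_bc, multi)
    t_cells <- intersect(keep_bc, names(n_b)[n_b >= 1L])
  }
  out <- counts[, colnames(counts) %in% keep_bc, drop = FALSE]
  attr(out, "metrics") <- qc
  attr(out, "t_cells") <- t_cells
  out
}

productive_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("TRUE", "T", "YES", "1")
}

#' Counts-per-10k log normalization
#'
#' @param counts genes x cells count matrix.
#' @param target per-cell total after scaling (default 1e4).
#' @return dgCMatrix of log1p-normalized values.
#' @export
normalize_expression <- function(counts, target = 1e4) {
  tot <- Matrix::colSums(counts)
  m <- methods::as(counts, "CsparseMatrix") %*%
    Matrix::Diagonal(x = ifelse(tot > 0, target / tot, 0))
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(counts)
  m
}

#' Normalize, reduce and cluster an expression matrix
#'
#' Counts-per-10k log normalization; highly variable gene selection by the
#' variance of the standardized log-normalized values; PCA on the scaled
#' HVG submatrix; SNN graph clustering (see [snn_cluster()]) on the
#' principal-component space.
#'
#' @param counts filtered genes x cells count matrix.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param resolutions,min_size,k_neighbors,seed passed to [snn_cluster()].
#' @return list: `clusters` (a `cluster_assignment`), `pca` (cells x
#'   n_pcs), `normalized` (log-normalized matrix), `hvg`.
#' @export
normalize_and_cluster <- function(counts, n_hvg = 2000L, n_pcs = 25L,
                                  resolutions = c(0.8, 0.6, 0.5, 0.4, 0.3,
                                                  0.2, 0.1),
                                  min_size = 10L, k_neighbors = 20L,
                                  seed = 1L) {
  norm <- normalize_expression(counts)
  x <- as.matrix(norm)
  v <- apply(row_zscore_safe(x), 1L, stats::var)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  xs <- row_zscore_safe(x[hvg, , drop = FALSE])
  n_pcs <- min(n_pcs, nrow(xs) - 1L, ncol(xs) - 1L)
  pc <- with_seed(seed, {
    s <- svd(xs, nu = n_pcs, nv = n_pcs)
    sweep(s$v, 2L, s$d[seq_len(n_pcs)], "*")
  })
  rownames(pc) <- colnames(xs)
  colnames(pc) <- paste0("PC", seq_len(n_pcs))
  cl <- snn_cluster(pc, resolutions = resolutions, min_size = min_size,
                    k_neighbors = k_neighbors, seed = seed)
  list(clusters = cl, pca = pc, normalized = norm, hvg = hvg)
}

# row z-score with zero-variance rows mapped to 0 rather than NA
row_zscore_safe <- function(m) {
  z <- row_zscore(m)
  z[is.na(z)] <- 0
  z
}

#' Top marker genes per cluster
#'
#' Cluster-vs-rest Wilcoxon rank-sum tests with BH correction; among genes
#' with FDR <= `fdr_max`, the `n_top` with the largest positive log2 fold
#' change are reported per cluster.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clusters `cluster_assignment` or factor.
#' @param n_top markers per cluster.
#' @param fdr_max FDR cut-off for candidate markers.
#' @return named list (per cluster) of marker gene character vectors.
#' @export
top_markers <- function(norm, clusters, n_top = 5L, fdr_max = 0.05) {
  tab <- differential_gene_scores(norm, clusters, lfc_min = 0,
                                  fdr_max = fdr_max)
  out <- lapply(split(tab, tab$cluster), function(d) {
    d <- d[d$fdr <= fdr_max & d$lfc > 0, ]
    d <- d[order(-d$lfc), ]
    utils::head(d$gene, n_top)
  })
  out
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation with the standard 9-MAD outlier cut-off; columns with
#' zero MAD fall back to Pearson against all others.
#'
#' @param x cells x genes matrix (correlations between columns).
#' @return genes x genes correlation matrix.
#' @export
bicor_matrix <- function(x) {
  n <- nrow(x); p <- ncol(x)
  med <- apply(x, 2L, stats::median)
  madv <- apply(x, 2L, stats::mad)
  const_mad <- madv == 0
  w <- matrix(0, n, p)
  u <- sweep(sweep(x, 2L, med, "-"), 2L,
             ifelse(const_mad, 1, 9 * madv), "/")
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xc <- sweep(x, 2L, med, "-") * w
  if (any(const_mad)) {
    # Pearson fallback: center by mean, unit weights
    xc[, const_mad] <- sweep(x[, const_mad, drop = FALSE], 2L,
                             colMeans(x[, const_mad, drop = FALSE]), "-")
  }
  norms <- sqrt(colSums(xc^2))
  norms[norms == 0] <- 1
  xs <- sweep(xc, 2L, norms, "/")
  crossprod(xs)
}

#' Signed co-expression module detection
#'
#' Biweight midcorrelation between genes; signed adjacency
#' a = ((1 + bicor)/2)^power; topological overlap similarity; average-
#' linkage hierarchical clustering of (1 - TOM); fixed-height cut with
#' minimum module size (clusters below `min_module` are left unassigned);
#' module eigengene = first principal component of the module's
#' standardized expression (oriented to correlate positively with the
#' module mean); modules whose eigengene correlation is >= 1 - `merge_cut`
#' are merged iteratively.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param power soft-threshold exponent (default 10).
#' @param min_module minimum module size (default 10).
#' @param merge_cut eigengene dissimilarity below which modules merge
#'   (default 0.15).
#' @param cut_height tree cut height on the 1 - TOM dendrogram.
#' @return object of class `gene_module_set`: list with `modules` (named
#'   list label -> genes), `eigengenes` (cells x modules), `unassigned`.
#' @export
detect_modules <- function(norm, power = 10, min_module = 10L,
                           merge_cut = 0.15, cut_height = 0.95) {
  x <- t(as.matrix(norm))              # cells x genes
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L * min_module)
    stop("need >= ", 2L * min_module, " variable genes")
  bc <- bicor_matrix(x)
  adj <- ((1 + bc) / 2)^power
  diag(adj) <- 0
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  grp <- stats::cutree(hc, h = cut_height)
  sizes <- table(grp)
  keep_grp <- names(sizes)[sizes >= min_module]
  modules <- lapply(keep_grp, function(g) colnames(x)[grp == as.integer(g)])
  if (length(modules) == 0L)
    return(structure(list(modules = list(),
                          eigengenes = matrix(nrow = nrow(x), ncol = 0),
                          unassigned = colnames(x)),
                     class = "gene_module_set"))
  names(modules) <- paste0("M", seq_along(modules))
  unassigned <- setdiff(colnames(x), unlist(modules))
  # iterative eigengene merging
  repeat {
    eig <- sapply(modules, function(gs) module_eigengene(x[, gs, drop = FALSE]))
    if (length(modules) < 2L) break
    cm <- stats::cor(eig)
    diag(cm) <- -Inf
    mx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    if (cm[mx[1L], mx[2L]] < 1 - merge_cut) break
    i <- min(mx); j <- max(mx)
    modules[[i]] <- c(modules[[i]], modules[[j]])
    modules[[j]] <- NULL
  }
  names(modules) <- paste0("M", seq_along(modules))
  eig <- sapply(modules, function(gs) module_eigengene(x[, gs, drop = FALSE]))
  rownames(eig) <- rownames(x)
  structure(list(modules = modules, eigengenes = eig,
                 unassigned = unassigned),
            class = "gene_module_set")
}

#' @export
print.gene_module_set <- function(x, ...) {
  cat("gene_module_set:", length(x$modules), "module(s) of sizes",
      paste(lengths(x$modules), collapse = ", "), ";",
      length(x$unassigned), "unassigned gene(s)\n")
  invisible(x)
}

# topological overlap similarity of an adjacency matrix (diag 0)
tom_similarity <- function(adj) {
  L <- adj %*% adj
  k <- colSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

# first PC of column-standardized expression, sign-aligned to the mean
module_eigengene <- function(xm) {
  xs <- scale(xm)
  xs[is.na(xs)] <- 0
  s <- svd(xs, nu = 1L, nv = 0L)
  e <- s$u[, 1L]
  if (stats::cor(e, rowMeans(xs)) < 0) e <- -e
  e
}

#' Dysfunction-module z-scores across clusters
#'
#' For each module gene, the vector of per-cluster mean expressions is
#' converted to a z-score across clusters (sample sd); genes with zero
#' spread are masked. The per-cluster distributions of module-gene z-scores
#' are compared by one-way ANOVA with Holm-Sidak-adjusted pairwise t-test
#' contrasts.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clusters `cluster_assignment` or factor aligned to columns.
#' @param module_genes character vector of module gene names.
#' @return list: `z` (genes x clusters z table, masked rows NA), `anova_p`
#'   (global one-way ANOVA p), `pairwise` (data.frame cluster_a, cluster_b,
#'   p, p_adj Holm-Sidak).
#' @export
dysfunction_score <- function(norm, clusters, module_genes) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.factor(clusters)
  missing <- setdiff(module_genes, rownames(norm))
  if (length(missing) > 0L)
    stop("module gene(s) absent: ", paste(missing, collapse = ", "))
  x <- as.matrix(norm[module_genes, , drop = FALSE])
  lv <- levels(droplevels(cl))
  means <- sapply(lv, function(cli)
    rowMeans(x[, cl == cli, drop = FALSE]))
  z <- row_zscore(means)   # masked (NA) where sd over clusters is 0
  zl <- as.vector(z)
  grp <- factor(rep(lv, each = nrow(z)))
  ok <- !is.na(zl)
  an <- stats::oneway.test(zl[ok] ~ grp[ok], var.equal = TRUE)
  pairs <- utils::combn(lv, 2L)
  praw <- apply(pairs, 2L, function(pp) {
    a <- z[, pp[1L]]; b <- z[, pp[2L]]
    stats::t.test(a[!is.na(a)], b[!is.na(b)])$p.value
  })
  list(z = z, anova_p = an$p.value,
       pairwise = data.frame(cluster_a = pairs[1L, ],
                             cluster_b = pairs[2L, ],
                             p = praw, p_adj = holm_sidak(praw),
                             stringsAsFactors = FALSE))
}
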