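#' Binarized tile accessibility matrix
#'
#' Tiles the genome into fixed-width windows and records, per cell, whether
#' any Tn5 insertion (fragment start or end - 1) falls in the tile. Cells
#' with zero fragments keep an all-zero column.
#'
#' @param frags fragment data.frame.
#' @param annotation a `genome_annotation` (chromosome lengths).
#' @param tile_width tile width in bp (default 2500).
#' @param barcodes cell barcodes defining column order; defaults to the
#'   barcodes present in `frags`.
#' @return sparse 0/1 dgCMatrix (tiles x cells) with attributes `tiles`
#'   (data.frame chrom, start, end) and `tile_width`.
#' @export
build_tile_matrix <- function(frags, annotation, tile_width = 2500L,
                              barcodes = NULL) {
  chroms <- annotation$chromosomes
  n_tiles_per <- ceiling(chroms$length / tile_width)
  tile_off <- c(0L, cumsum(n_tiles_per))
  if (is.null(barcodes)) barcodes <- sort(unique(frags$barcode))
  ins <- insertion_sites(frags)
  ci <- match(ins$chrom, chroms$name)
  if (anyNA(ci)) stop("fragment chromosome not in annotation")
  if (any(ins$pos < 0L) || any(ins$pos >= chroms$length[ci]))
    stop("insertion position beyond chromosome length")
  tile <- tile_off[ci] + ins$pos %/% tile_width + 1L
  cell <- match(ins$barcode, barcodes)
  tile <- tile[!is.na(cell)]; cell <- cell[!is.na(cell)]
  n_tiles <- tile_off[length(tile_off)]
  m <- Matrix::sparseMatrix(i = tile, j = cell, x = 1,
                            dims = c(n_tiles, length(barcodes)))
  m@x[] <- 1  # binarize (duplicate triplets are summed on construction)
  rep_chr <- rep(chroms$name, n_tiles_per)
  starts <- unlist(lapply(n_tiles_per, function(k) (seq_len(k) - 1L))) * tile_width
  tiles <- data.frame(chrom = rep_chr, start = starts,
                      end = pmin(starts + tile_width,
                                 rep(chroms$length, n_tiles_per)),
                      stringsAsFactors = FALSE)
  dimnames(m) <- list(paste0(tiles$chrom, ":", tiles$start, "-", tiles$end),
                      barcodes)
  attr(m, "tiles") <- tiles
  attr(m, "tile_width") <- tile_width
  m
}

#' Term frequency - inverse document frequency weighting
#'
#' For a binary features x cells matrix: TF(i, j) = x_ij / colsum_j and
#' IDF(i) = log(1 + n_cells / n_cells_with_feature_i). Features observed in
#' no cell carry no information and are dropped (their indices are recorded
#' in the `kept_features` attribute).
#'
#' @param x binary sparse matrix (features x cells).
#' @return weighted dgCMatrix with attribute `kept_features`.
#' @export
tfidf <- function(x) {
  x <- methods::as(x, "CsparseMatrix")
  cs <- Matrix::colSums(x)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0]
    stop("all-zero cell column(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  nf <- Matrix::rowSums(x > 0)
  keep <- which(nf > 0)
  x <- x[keep, , drop = FALSE]
  idf <- log(1 + ncol(x) / nf[keep])
  out <- Matrix::Diagonal(x = idf) %*% x %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(out) <- dimnames(x)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "kept_features") <- keep
  out
}

#' Truncated SVD embedding (LSI)
#'
#' Partial SVD of the TF-IDF matrix; cell coordinates are the right singular
#' vectors scaled by the singular values, restricted to the retained
#' components (2..25 by default, dropping the depth-correlated first
#' component). Each component is sign-oriented so that the largest-magnitude
#' entry of its feature loading vector is positive, making the embedding
#' reproducible across solvers.
#'
#' @param w weighted features x cells matrix (from [tfidf()]).
#' @param n_components number of singular vectors to compute.
#' @param keep component indices retained for the embedding.
#' @param seed seed for the iterative solver.
#' @return object of class `lsi_embedding`: list with `coords` (cells x
#'   length(keep)), `d` (singular values), `keep`.
#' @export
svd_embed <- function(w, n_components = 25L, keep = 2:25, seed = 1L) {
  if (min(dim(w)) < n_components + 1L)
    stop("matrix rank too small for ", n_components,
         " components; reduce n_components")
  stopifnot(all(keep >= 1), all(keep <= n_components))
  # irlba needs the requested rank well below min(dim); fall back to a dense
  # SVD for small problems, where it is exact and just as fast
  sv <- if (n_components >= 0.5 * min(dim(w)) || min(dim(w)) < 100L) {
    s <- svd(as.matrix(w), nu = n_components, nv = n_components)
    list(u = s$u, v = s$v, d = s$d[seq_len(n_components)])
  } else {
    with_seed(seed, irlba::irlba(w, nv = n_components, nu = n_components,
                                 tol = 1e-10, maxit = 1000L))
  }
  # orient: largest |loading| entry of each left singular vector positive
  flip <- vapply(seq_len(n_components), function(k) {
    u <- sv$u[, k]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  v <- sweep(sv$v, 2L, flip, "*")
  coords <- sweep(v[, keep, drop = FALSE], 2L, sv$d[keep], "*")
  rownames(coords) <- colnames(w)
  colnames(coords) <- paste0("LSI", keep)
  structure(list(coords = coords, d = sv$d, keep = keep),
            class = "lsi_embedding")
}

#' @export
print.lsi_embedding <- function(x, ...) {
  cat("lsi_embedding:", nrow(x$coords), "cells x", ncol(x$coords),
      "components (", paste(range(x$keep), collapse = ".."), ")\n")
  invisible(x)
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

# Shared-nearest-neighbor graph: kNN in the embedding, edges reweighted by
# Jaccard overlap of (self-inclusive) neighbor sets, pruned below `prune`.
snn_graph <- function(coords, k = 20L, prune = 1 / 15) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(coords, k = k)$nn.index
  # neighbor membership incidence (self included)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k + 1L),
    j = c(as.vector(nn), seq_len(n)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(inc)          # counts of shared neighbors
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)    # |A n B| / |A u B|
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' SNN graph clustering with size-constrained resolution selection
#'
#' Builds a shared-nearest-neighbor graph on the embedding (k nearest
#' neighbors, Jaccard edge weights), runs Leiden modularity community
#' detection at each candidate resolution in the given (descending) order,
#' and reports the first resolution whose partition is admissible:
#' every cluster holds at least `min_size` cells and, when
#' `stability_restarts > 1`, the partition is reproduced exactly (up to
#' label permutation) by independent random restarts. The stability
#' condition guards against the well-known tendency of modularity
#' optimization to carve a homogeneous cell population into arbitrary
#' same-sized pieces: such splits differ between restarts, whereas real
#' population structure is restart-stable. If no candidate is admissible,
#' the candidate with the fewest undersized clusters is returned with
#' `fallback = TRUE`.
#'
#' @param embedding an `lsi_embedding` or a plain cells x dims matrix.
#' @param resolutions candidate resolutions, tried in the given order
#'   (conventionally descending from the 0.8 starting resolution).
#' @param min_size minimum admissible cluster size.
#' @param k_neighbors kNN parameter of the SNN graph.
#' @param seed seed for the community detection.
#' @param prune Jaccard pruning threshold of SNN edge weights.
#' @param stability_restarts number of random restarts that must agree for
#'   a resolution to be admissible (1 disables the stability condition).
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named factor per cell), `resolution`, `fallback`, `sizes`.
#' @export
snn_cluster <- function(embedding, resolutions = c(0.8, 0.6, 0.5, 0.4,
                                                   0.3, 0.2, 0.1),
                        min_size = 200L, k_neighbors = 20L, seed = 1L,
                        prune = 1 / 15, stability_restarts = 3L) {
  coords <- if (inherits(embedding, "lsi_embedding")) embedding$coords
            else as.matrix(embedding)
  if (nrow(coords) < min_size)
    warning("fewer cells than min_size; a single cluster cannot satisfy it")
  g <- snn_graph(coords, k = k_neighbors)
  leiden_run <- function(res, s) {
    with_seed(s, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 10L))$membership
  }
  best <- NULL
  for (res in resolutions) {
    memb <- leiden_run(res, seed)
    sizes <- table(memb)
    n_viol <- sum(sizes < min_size)
    stable <- TRUE
    if (n_viol == 0L && stability_restarts > 1L) {
      for (r in seq_len(stability_restarts - 1L)) {
        memb_r <- leiden_run(res, seed + 7919L * r)
        if (adjusted_rand(memb, memb_r) < 1 - 1e-12) { stable <- FALSE; break }
      }
    }
    cand <- list(membership = memb, resolution = res, n_viol = n_viol,
                 sizes = sizes)
    if (n_viol == 0L && stable) { best <- cand; best$fallback <- FALSE; break }
    if (is.null(best) || n_viol < best$n_viol) { best <- cand; best$fallback <- TRUE }
  }
  cl <- factor(paste0("C", best$membership),
               levels = paste0("C", sort(unique(best$membership))))
  names(cl) <- rownames(coords)
  structure(list(cluster = cl, resolution = best$resolution,
                 fallback = best$fallback,
                 sizes = table(cl)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$cluster), "cells,",
      nlevels(x$cluster), "clusters at resolution", x$resolution,
      if (isTRUE(x$fallback)) "(min-size fallback)" else "", "\n")
  print(x$sizes)
  invisible(x)
}

#' Two-round iterative LSI clustering
#'
#' Round 1: binarized tile matrix -> TF-IDF -> truncated SVD (components
#' 2..25) -> SNN clustering ("crude" clusters). Per-crude-cluster pseudobulk
#' peaks are called, merged into a union peak set, and a peak x cell counts
#' matrix is built; round 2 repeats TF-IDF/SVD/clustering on the binarized
#' peak matrix. An externally supplied peak set bypasses the built-in caller.
#'
#' @param frags fragment data.frame (QC-passing cells only).
#' @param annotation a `genome_annotation`.
#' @param tile_width round-1 tile width (bp).
#' @param min_size minimum cluster size (both rounds).
#' @param resolutions candidate resolution ladder (descending).
#' @param n_components,keep SVD parameters (see [svd_embed()]).
#' @param k_neighbors SNN graph kNN parameter.
#' @param peak_width,fdr pseudobulk peak-calling parameters
#'   (see [call_peaks_pseudobulk()]).
#' @param peaks optional externally supplied peak data.frame (chrom, start,
#'   end, score); skips the pseudobulk caller.
#' @param seed integer seed for SVD and clustering.
#' @return list: `clusters` (final `cluster_assignment`), `round1`
#'   (crude assignment), `peaks` (union peak set), `peak_matrix`,
#'   `embedding` (round-2 `lsi_embedding`).
#' @export
iterative_cluster <- function(frags, annotation, tile_width = 2500L,
                              min_size = 200L,
                              resolutions = c(0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
                              n_components = 25L, keep = 2:25,
                              k_neighbors = 20L, peak_width = 500L,
                              fdr = 0.01, peaks = NULL, seed = 1L) {
  tiles <- build_tile_matrix(frags, annotation, tile_width)
  w1 <- tfidf(tiles)
  nc1 <- min(n_components, min(dim(w1)) - 1L)
  emb1 <- svd_embed(w1, n_components = nc1,
                    keep = keep[keep <= nc1], seed = seed)
  round1 <- snn_cluster(emb1, resolutions = resolutions, min_size = min_size,
                        k_neighbors = k_neighbors, seed = seed)
  if (is.null(peaks)) {
    per_cluster <- call_peaks_pseudobulk(frags, round1, annotation,
                                         peak_width = peak_width, fdr = fdr)
    peaks <- union_peaks(per_cluster)
  }
  pm <- build_peak_matrix(frags, peaks, annotation,
                          barcodes = colnames(tiles))
  w2 <- tfidf(methods::as(pm > 0, "CsparseMatrix") * 1)
  nc2 <- min(n_components, min(dim(w2)) - 1L)
  emb2 <- svd_embed(w2, n_components = nc2,
                    keep = keep[keep <= nc2], seed = seed)
  final <- snn_cluster(emb2, resolutions = resolutions, min_size = min_size,
                       k_neighbors = k_neighbors, seed = seed)
  list(clusters = final, round1 = round1, peaks = peaks,
       peak_matrix = pm, embedding = emb2)
}
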