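#' Supervised pseudotime along an ordered cluster backbone
#'
#' Cells of each backbone cluster j are projected onto the unit vector from
#' that cluster's embedding centroid toward the next backbone centroid (for
#' the last cluster, away from the previous centroid); the scalar projection
#' is converted to a within-cluster rank fraction r in [0, 1), and the
#' pseudotime is 100 * (j - 1 + r) / K for K backbone clusters. Cells
#' outside the backbone are excluded.
#'
#' @param embedding `lsi_embedding` or cells x dims matrix with rownames.
#' @param clusters `cluster_assignment` or named factor per cell.
#' @param backbone ordered character vector of cluster ids (length >= 2).
#' @return object of class `trajectory_result`: list with `pseudotime`
#'   (named numeric in [0, 100]) and `backbone`.
#' @export
fit_trajectory <- function(embedding, clusters, backbone) {
  coords <- if (inherits(embedding, "lsi_embedding")) embedding$coords
            else as.matrix(embedding)
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  stopifnot(length(backbone) >= 2L)
  if (!all(backbone %in% cl))
    stop("backbone cluster(s) absent: ",
         paste(setdiff(backbone, unique(cl)), collapse = ", "))
  K <- length(backbone)
  cent <- t(vapply(backbone, function(b)
    colMeans(coords[cl == b, , drop = FALSE]), numeric(ncol(coords))))
  pt <- numeric(0)
  for (j in seq_len(K)) {
    cells <- names(cl)[cl == backbone[j]]
    dirv <- if (j < K) cent[j + 1L, ] - cent[j, ] else cent[j, ] - cent[j - 1L, ]
    nv <- sqrt(sum(dirv^2))
    proj <- if (nv > 0) {
      as.numeric((coords[cells, , drop = FALSE] -
                    matrix(cent[j, ], length(cells), ncol(coords),
                           byrow = TRUE)) %*% (dirv / nv))
    } else rep(0, length(cells))
    r <- (rank(proj, ties.method = "first") - 1) / length(proj)
    pt_j <- 100 * (j - 1 + r) / K
    names(pt_j) <- cells
    pt <- c(pt, pt_j)
  }
  structure(list(pseudotime = pt, backbone = backbone),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result:", length(x$pseudotime), "cells along backbone",
      paste(x$backbone, collapse = " -> "), "\n")
  invisible(x)
}

#' Smoothed feature profiles over pseudotime bins
#'
#' Cells are assigned to `n_bins` pseudotime quantile bins (approximately
#' equal occupancy); per-bin feature means are smoothed by a centered moving
#' average of `window_bins` bins (truncated at the edges) and z-scored per
#' feature for display. Profiles of constant features have undefined z and
#' are masked (NA). Bins left empty by ties are filled by linear
#' interpolation and flagged.
#'
#' @param features features x cells matrix (columns named).
#' @param pseudotime named numeric from [fit_trajectory()].
#' @param n_bins number of pseudotime bins.
#' @param window_bins moving-average window (odd, <= n_bins).
#' @return list: `profile` (features x bins smoothed means), `z` (z-scored
#'   profiles), `bin` (per-cell bin index), `filled` (interpolated bins).
#' @export
smooth_along_pseudotime <- function(features, pseudotime, n_bins = 100L,
                                    window_bins = 11L) {
  stopifnot(n_bins >= window_bins)
  cells <- intersect(colnames(features), names(pseudotime))
  x <- as.matrix(features[, cells, drop = FALSE])
  pt <- pseudotime[cells]
  n <- length(pt)
  nb <- min(n_bins, n)
  bin <- ceiling(rank(pt, ties.method = "first") / (n / nb))
  bin <- pmin(pmax(bin, 1L), nb)
  sums <- rowsum(t(x), bin)                       # bins x features
  cnt <- as.integer(table(factor(bin, levels = seq_len(nb))))
  present <- sort(unique(bin))
  means <- matrix(NA_real_, nb, nrow(x))
  means[present, ] <- sums / cnt[present]
  filled <- which(cnt == 0L)
  if (length(filled) > 0L) {
    for (fi in seq_len(ncol(means)))
      means[, fi] <- stats::approx(present, means[present, fi],
                                   xout = seq_len(nb), rule = 2)$y
  }
  half <- (window_bins - 1L) %/% 2L
  sm <- apply(means, 2L, function(v) {
    vapply(seq_len(nb), function(b)
      mean(v[max(1L, b - half):min(nb, b + half)]), numeric(1))
  })
  profile <- t(sm)
  rownames(profile) <- rownames(x)
  colnames(profile) <- paste0("bin", seq_len(nb))
  z <- row_zscore(profile)
  list(profile = profile, z = z, bin = stats::setNames(bin, cells),
       filled = filled)
}

#' Select and order the most pseudotime-variable features
#'
#' Ranks features by the variance of their smoothed pseudotime profile,
#' keeps the top fraction, and orders the selected features by the bin of
#' their profile maximum (ties broken by feature name).
#'
#' @param features features x cells matrix.
#' @param pseudotime named numeric pseudotime.
#' @param top_frac fraction of features to keep (default 0.10).
#' @param n_bins,window_bins smoothing parameters.
#' @return character vector of selected features in peak order.
#' @export
order_variable_features <- function(features, pseudotime, top_frac = 0.10,
                                    n_bins = 100L, window_bins = 11L) {
  sm <- smooth_along_pseudotime(features, pseudotime, n_bins, window_bins)
  v <- apply(sm$profile, 1L, stats::var)
  n_top <- max(1L, floor(top_frac * nrow(sm$profile)))
  sel <- names(sort(v, decreasing = TRUE))[seq_len(n_top)]
  peak_bin <- apply(sm$profile[sel, , drop = FALSE], 1L, which.max)
  sel[order(peak_bin, sel)]
}
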