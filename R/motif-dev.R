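## Motif-level TF activity: GC/accessibility-matched background sampling,
## raw deviations and bias-corrected deviation z-scores.

#' Scan peak sequences for motif matches
#'
#' Log-odds scan of each position weight matrix against a 0-order uniform
#' background; a peak matches iff its maximal window score exceeds the score
#' threshold whose upper-tail probability under the background model is
#' `p_threshold` (computed by exact discretized convolution of the
#' per-position score distributions). Alternatively, a precomputed logical
#' match matrix may be passed through [as_motif_annotation()] verbatim.
#'
#' @param pwms named list of 4 x width probability matrices (rows A, C, G, T).
#' @param peak_sequences character vector of equal-length peak sequences
#'   (alphabet A/C/G/T/N; N never matches).
#' @param p_threshold per-window match p-value under the background model.
#' @param pseudo pseudo-probability added to PWM entries before log-odds.
#' @return logical motifs x peaks matrix.
#' @export
match_motifs <- function(pwms, peak_sequences, p_threshold = 5e-5,
                         pseudo = 1e-3) {
  bases <- c("A", "C", "G", "T")
  seqs <- toupper(peak_sequences)
  if (any(grepl("[^ACGTN]", seqs))) stop("sequence alphabet must be ACGTN")
  out <- matrix(FALSE, nrow = length(pwms), ncol = length(seqs),
                dimnames = list(names(pwms), NULL))
  for (mi in seq_along(pwms)) {
    pwm <- pwms[[mi]]
    stopifnot(nrow(pwm) == 4L)
    p <- sweep(pwm + pseudo, 2L, colSums(pwm + pseudo), "/")
    lo <- log2(p / 0.25)
    thr <- if (p_threshold >= 1) -Inf else lo_threshold(lo, p_threshold)
    w <- ncol(lo)
    for (si in seq_along(seqs)) {
      s <- strsplit(seqs[si], "")[[1]]
      n <- length(s)
      if (n < w) next
      code <- match(s, bases)  # NA for N
      best <- -Inf
      for (st in seq_len(n - w + 1L)) {
        idx <- code[st:(st + w - 1L)]
        if (anyNA(idx)) next
        sc <- sum(lo[cbind(idx, seq_len(w))])
        if (sc > best) best <- sc
      }
      out[mi, si] <- best >= thr
    }
  }
  out
}

# score threshold at upper-tail probability p under a uniform 0-order
# background, by discretized convolution (resolution `res` bits)
lo_threshold <- function(lo, p, res = 0.01) {
  q <- round(lo / res)  # 4 x w integer score grid
  dist <- 1
  min_sum <- 0L
  for (j in seq_len(ncol(q))) {
    qj <- q[, j]
    step <- numeric(max(qj) - min(qj) + 1L)
    for (b in 1:4)
      step[qj[b] - min(qj) + 1L] <- step[qj[b] - min(qj) + 1L] + 0.25
    dist <- convolve_pmf(dist, step)
    min_sum <- min_sum + min(qj)
  }
  grid <- (min_sum + seq_along(dist) - 1L) * res
  tail_p <- rev(cumsum(rev(dist)))
  idx <- which(tail_p <= p)
  if (length(idx) == 0L) max(grid) + res else grid[min(idx)]
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) if (b[i] > 0)
    out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  out
}

#' Bundle a match matrix with per-peak GC content
#'
#' @param matches logical motifs x peaks matrix.
#' @param gc numeric per-peak GC fraction in [0, 1].
#' @return list of class `motif_annotation`.
#' @export
as_motif_annotation <- function(matches, gc) {
  stopifnot(ncol(matches) == length(gc), all(gc >= 0 & gc <= 1))
  structure(list(matches = matches != 0, gc = gc),
            class = "motif_annotation")
}

#' GC- and accessibility-matched background peaks
#'
#' Embeds peaks in the plane of (standardized log mean accessibility,
#' standardized GC fraction), grids each axis into `n_bins` bins, and for
#' each peak samples `n_background` peaks with probability proportional to a
#' Gaussian kernel on the distance between bin centers (bandwidth `bw` in
#' standardized units). Self-sampling is allowed. Degenerate variance on
#' both axes falls back to uniform sampling with a warning.
#'
#' @param peak_matrix peaks x cells counts.
#' @param gc per-peak GC fraction.
#' @param n_background background draws per peak.
#' @param n_bins grid bins per axis.
#' @param bw kernel bandwidth (standardized units).
#' @param seed integer seed.
#' @return integer peaks x n_background matrix of peak indices.
#' @export
background_peaks <- function(peak_matrix, gc, n_background = 50L,
                             n_bins = 50L, bw = 0.25, seed = 1L) {
  n <- nrow(peak_matrix)
  stopifnot(n >= 2L, length(gc) == n)
  acc <- log1p(Matrix::rowMeans(peak_matrix))
  z1 <- if (stats::sd(acc) > 0) as.numeric(scale(acc)) else rep(0, n)
  z2 <- if (stats::sd(gc) > 0) as.numeric(scale(gc)) else rep(0, n)
  with_seed(seed, {
    if (stats::sd(acc) == 0 && stats::sd(gc) == 0) {
      warning("degenerate GC and accessibility; uniform background sampling")
      return(matrix(sample.int(n, n * n_background, replace = TRUE),
                    nrow = n))
    }
    b1 <- bin_index(z1, n_bins); b2 <- bin_index(z2, n_bins)
    centers1 <- attr(b1, "centers"); centers2 <- attr(b2, "centers")
    bin_of <- (b1 - 1L) * n_bins + b2
    occupied <- sort(unique(bin_of))
    members <- split(seq_len(n), factor(bin_of, levels = occupied))
    occ_c1 <- centers1[(occupied - 1L) %/% n_bins + 1L]
    occ_c2 <- centers2[(occupied - 1L) %% n_bins + 1L]
    occ_n <- lengths(members)
    out <- matrix(0L, nrow = n, ncol = n_background)
    for (bi in seq_along(occupied)) {
      d2 <- (occ_c1 - occ_c1[bi])^2 + (occ_c2 - occ_c2[bi])^2
      wt <- exp(-d2 / (2 * bw^2)) * occ_n
      rows <- members[[bi]]
      k <- length(rows) * n_background
      pick_bin <- sample.int(length(occupied), k, replace = TRUE, prob = wt)
      pick <- vapply(pick_bin, function(pb) {
        m <- members[[pb]]
        m[sample.int(length(m), 1L)]
      }, integer(1))
      out[rows, ] <- matrix(pick, nrow = length(rows))
    }
    out
  })
}

bin_index <- function(z, n_bins) {
  rng <- range(z)
  if (diff(rng) == 0) {
    b <- rep(1L, length(z))
    attr(b, "centers") <- rep(rng[1L], n_bins)
    return(b)
  }
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  b <- pmin(pmax(findInterval(z, brk, rightmost.closed = TRUE), 1L), n_bins)
  attr(b, "centers") <- (brk[-1L] + brk[-length(brk)]) / 2
  b
}

#' Motif deviation scores and variability
#'
#' For motif m and cell i with X = summed counts over matched peaks,
#' expectation E = f_m * T_i where f_m is the matched peaks' share of the
#' grand count total and T_i the cell total: raw deviation Y = (X - E)/E.
#' The same quantity on each GC/accessibility-matched background draw gives
#' the bias-corrected z = (Y - mean_b Y_b) / sd_b Y_b; per-motif variability
#' is the standard deviation of z across cells. Motifs with E = 0 (or zero
#' background spread) are masked with a warning.
#'
#' @param peak_matrix peaks x cells counts.
#' @param motif_annotation a `motif_annotation` (or logical motifs x peaks
#'   matrix).
#' @param background integer peaks x n_background index matrix from
#'   [background_peaks()].
#' @return object of class `deviation_matrix`: list with `raw` (motifs x
#'   cells), `z` (motifs x cells), `variability` (named numeric).
#' @export
compute_deviations <- function(peak_matrix, motif_annotation, background) {
  M <- if (inherits(motif_annotation, "motif_annotation"))
    motif_annotation$matches else (motif_annotation != 0)
  stopifnot(ncol(M) == nrow(peak_matrix),
            nrow(background) == nrow(peak_matrix))
  M <- methods::as(Matrix::Matrix(M * 1, sparse = TRUE), "CsparseMatrix")
  Tcell <- Matrix::colSums(peak_matrix)
  peak_tot <- Matrix::rowSums(peak_matrix)
  grand <- sum(peak_tot)
  if (grand == 0) stop("empty peak matrix")
  X <- as.matrix(M %*% peak_matrix)
  f <- as.numeric(M %*% peak_tot) / grand
  E <- outer(f, Tcell)
  bad <- f == 0
  raw <- (X - E) / E
  raw[bad, ] <- NA_real_
  if (any(bad)) warning(sum(bad), " motif(s) with zero expected counts; masked")
  nb <- ncol(background)
  sumYb <- matrix(0, nrow(M), ncol(peak_matrix))
  sumYb2 <- sumYb
  for (b in seq_len(nb)) {
    P <- Matrix::sparseMatrix(i = seq_len(nrow(peak_matrix)),
                              j = background[, b], x = 1,
                              dims = rep(nrow(peak_matrix), 2L))
    Mb <- M %*% P
    Xb <- as.matrix(Mb %*% peak_matrix)
    fb <- as.numeric(Mb %*% peak_tot) / grand
    Eb <- outer(fb, Tcell)
    Yb <- (Xb - Eb) / Eb
    Yb[fb == 0, ] <- 0
    sumYb <- sumYb + Yb
    sumYb2 <- sumYb2 + Yb^2
  }
  mb <- sumYb / nb
  sdb <- sqrt(pmax(0, (sumYb2 - nb * mb^2) / (nb - 1L)))
  z <- (raw - mb) / sdb
  z[sdb == 0] <- NA_real_
  rownames(raw) <- rownames(z) <- rownames(M)
  colnames(raw) <- colnames(z) <- colnames(peak_matrix)
  variability <- apply(z, 1L, stats::sd, na.rm = TRUE)
  structure(list(raw = raw, z = z, variability = variability),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("deviation_matrix:", nrow(x$raw), "motifs x", ncol(x$raw), "cells\n")
  invisible(x)
}
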