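#' Pseudobulk Poisson peak calling per crude cluster
#'
#' Pools Tn5 insertions per cluster, counts them in sliding windows
#' (`peak_width` wide, `step` bp apart), and tests each window's count
#' against the cluster's genome-wide insertion rate times `peak_width` with
#' a Poisson upper-tail test. P-values are Benjamini-Hochberg adjusted
#' across windows; significant windows are reduced to fixed-width peaks
#' centered at the window's insertion summit, and within-cluster overlaps
#' are resolved by iteratively keeping the higher-scoring peak.
#'
#' @param frags fragment data.frame.
#' @param clusters a `cluster_assignment` (or named factor per barcode).
#' @param annotation a `genome_annotation`.
#' @param peak_width fixed peak/window width (bp).
#' @param fdr BH-adjusted significance threshold.
#' @param step window step (bp).
#' @return named list (per cluster) of peak data.frames (chrom, start, end,
#'   summit, score, cluster); `score` is the window insertion count.
#' @export
call_peaks_pseudobulk <- function(frags, clusters, annotation,
                                  peak_width = 500L, fdr = 0.01,
                                  step = 100L) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  stopifnot(!is.null(names(cl)))
  chroms <- annotation$chromosomes
  glen <- sum(chroms$length)
  ins <- insertion_sites(frags)
  ins$cluster <- cl[ins$barcode]
  out <- list()
  for (cli in levels(factor(cl))) {
    sub <- ins[!is.na(ins$cluster) & ins$cluster == cli, ]
    if (nrow(sub) == 0L) {
      warning("cluster ", cli, " has no insertions; empty peak set")
      out[[cli]] <- empty_peaks(cli)
      next
    }
    lambda <- nrow(sub) / glen * peak_width
    peaks <- list()
    for (ci in seq_len(nrow(chroms))) {
      pos <- sort(sub$pos[sub$chrom == chroms$name[ci]])
      if (length(pos) == 0L) next
      len <- chroms$length[ci]
      starts <- seq(0L, max(0L, len - peak_width), by = step)
      # insertions in [s, s + peak_width) via cumulative counts
      n_in <- findInterval(starts + peak_width - 1L, pos) -
        findInterval(starts - 1L, pos)
      p <- stats::ppois(n_in - 1L, lambda, lower.tail = FALSE)
      sig <- which(stats::p.adjust(p, "BH") <= fdr)
      if (length(sig) == 0L) next
      summit <- vapply(sig, function(si) {
        w <- pos[pos >= starts[si] & pos < starts[si] + peak_width]
        tb <- table(w)
        as.integer(names(tb)[which.max(tb)])
      }, integer(1))
      pk <- data.frame(chrom = chroms$name[ci],
                       start = pmax(0L, summit - peak_width %/% 2L),
                       summit = summit, score = n_in[sig],
                       stringsAsFactors = FALSE)
      pk$end <- pk$start + peak_width
      over <- pk$end > len
      pk$start[over] <- len - peak_width
      pk$end[over] <- len
      peaks[[length(peaks) + 1L]] <- pk
    }
    if (length(peaks) == 0L) {
      out[[cli]] <- empty_peaks(cli)
      next
    }
    pk <- do.call(rbind, peaks)
    pk$cluster <- cli
    out[[cli]] <- resolve_overlaps(pk)
  }
  out
}

empty_peaks <- function(cluster = character(0)) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), score = numeric(),
             cluster = character(), stringsAsFactors = FALSE)
}

# iterative score-ranked overlap removal: keep the best-scoring peak, drop
# everything overlapping it, recurse on the survivors
resolve_overlaps <- function(pk) {
  if (nrow(pk) <= 1L) return(sort_peaks(pk))
  ord <- order(-pk$score, pk$chrom, pk$start)
  pk <- pk[ord, ]
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (any(keep & pk$chrom == pk$chrom[i] &
            pk$start < pk$end[i] & pk$end > pk$start[i])) next
    keep[i] <- TRUE
  }
  sort_peaks(pk[keep, ])
}

sort_peaks <- function(pk) {
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Union peak set across clusters
#'
#' Concatenates per-cluster fixed-width peak sets and resolves cross-cluster
#' overlaps by score-ranked iterative removal (highest score wins), returning
#' a non-overlapping, coordinate-sorted set.
#'
#' @param peak_sets list of peak data.frames of identical width.
#' @return single peak data.frame.
#' @export
union_peaks <- function(peak_sets) {
  peak_sets <- Filter(function(p) nrow(p) > 0, peak_sets)
  if (length(peak_sets) == 0L) return(empty_peaks())
  widths <- unique(unlist(lapply(peak_sets, function(p) unique(p$end - p$start))))
  if (length(widths) > 1L)
    stop("peak width mismatch across sets: ", paste(widths, collapse = ", "))
  resolve_overlaps(do.call(rbind, peak_sets))
}

#' Peak x cell insertion count matrix
#'
#' Counts Tn5 insertions per peak per cell; intervals are half-open
#' `[start, end)`. Counts are retained; binarize with `m > 0` for the
#' second-round TF-IDF.
#'
#' @param frags fragment data.frame.
#' @param peaks non-overlapping peak data.frame (chrom, start, end).
#' @param annotation a `genome_annotation`.
#' @param barcodes column order; defaults to barcodes present in `frags`.
#' @return sparse dgCMatrix (peaks x cells) with rownames
#'   "chrom:start-end".
#' @export
build_peak_matrix <- function(frags, peaks, annotation, barcodes = NULL) {
  if (is.null(barcodes)) barcodes <- sort(unique(frags$barcode))
  ins <- insertion_sites(frags)
  trips <- list()
  for (cn in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == cn, ]
    ord <- order(pk$start)
    pk <- pk[ord, ]
    row_id <- which(peaks$chrom == cn)[ord]
    ii <- which(ins$chrom == cn)
    if (length(ii) == 0L) next
    idx <- findInterval(ins$pos[ii], pk$start)
    hit <- idx >= 1L & ins$pos[ii] < pk$end[pmax(idx, 1L)]
    jj <- match(ins$barcode[ii], barcodes)
    hit <- hit & !is.na(jj)
    if (!any(hit)) next
    trips[[cn]] <- data.frame(i = row_id[idx[hit]], j = jj[hit])
  }
  tr <- do.call(rbind, trips)
  m <- if (is.null(tr)) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(nrow(peaks), length(barcodes)))
  } else {
    Matrix::sparseMatrix(i = tr$i, j = tr$j, x = 1,
                         dims = c(nrow(peaks), length(barcodes)))
  }
  dimnames(m) <- list(paste0(peaks$chrom, ":", peaks$start, "-", peaks$end),
                      barcodes)
  m
}
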