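#' Read a 5-column single-cell ATAC fragment file
#'
#' Parses the de-facto fragment standard: tab-separated chrom, start, end,
#' barcode, duplicate count; 0-based half-open coordinates; plain or
#' (block-)gzipped. Coordinates are validated (`start < end`, count >= 1).
#'
#' @param path fragment file path.
#' @return data.frame with columns chrom, start, end, barcode, count, sorted
#'   as stored.
#' @export
read_fragments <- function(path) {
  input <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    paste(readLines(con), collapse = "\n")
  } else path
  cols <- c("chrom", "start", "end", "barcode", "count")
  if (identical(input, "") ||
      (!grepl("\\.gz$", path) && file.size(path) == 0)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), barcode = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  frags <- if (grepl("\\.gz$", path)) {
    data.table::fread(text = input, header = FALSE, sep = "\t",
                      col.names = cols, data.table = FALSE)
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = cols, data.table = FALSE)
  }
  if (!is.numeric(frags$start) || !is.numeric(frags$end) ||
      !is.numeric(frags$count))
    stop("malformed fragment file: non-numeric coordinate or count column")
  if (nrow(frags) == 0L) return(frags)
  bad <- which(frags$end <= frags$start)
  if (length(bad) > 0L)
    stop("fragment end <= start at line ", bad[1L], " (",
         frags$chrom[bad[1L]], ":", frags$start[bad[1L]], "-",
         frags$end[bad[1L]], ")")
  bad <- which(frags$count < 1L | is.na(frags$count))
  if (length(bad) > 0L)
    stop("duplicate count < 1 at line ", bad[1L])
  frags
}

#' TSS enrichment score of a set of fragments
#'
#' Each fragment contributes two Tn5 insertion sites (start and end - 1).
#' The score is the mean insertion density per bp within +/-
#' `center_halfwidth` of any TSS, divided by the mean density in the distal
#' 100-bp flank windows at +/- `flank` bp (pooled over TSSs). The flank mean
#' is floored at `pseudocount` insertions/bp so the ratio is always finite.
#'
#' @param frags fragment data.frame (chrom, start, end, ...).
#' @param tss data.frame of TSS positions (columns chrom, tss), e.g.
#'   `annotation$genes`.
#' @param flank distance (bp) of the background flank windows from the TSS.
#' @param center_halfwidth half-width (bp) of the TSS-proximal window.
#' @param pseudocount floor (insertions/bp) for the flank density.
#' @return a single nonnegative enrichment ratio.
#' @export
compute_tss_enrichment <- function(frags, tss, flank = 2000L,
                                   center_halfwidth = 50L,
                                   pseudocount = 0.01) {
  if (nrow(tss) == 0L) stop("no TSS positions supplied")
  d <- tss_distances(frags, tss)
  tss_score_from_distances(d, length(unique(paste(tss$chrom, tss$tss))),
                           flank, center_halfwidth, pseudocount)
}

# signed distance from each insertion to the nearest TSS on its chromosome
# (NA for insertions on TSS-free chromosomes)
tss_distances <- function(frags, tss) {
  ins <- insertion_sites(frags)
  d <- rep(NA_real_, nrow(ins))
  for (cn in unique(ins$chrom)) {
    tp <- sort(tss$tss[tss$chrom == cn])
    if (length(tp) == 0L) next
    ii <- which(ins$chrom == cn)
    pos <- ins$pos[ii]
    right <- findInterval(pos, tp) # index of largest tss <= pos
    lo <- pmax(right, 1L); hi <- pmin(right + 1L, length(tp))
    d_lo <- pos - tp[lo]; d_hi <- pos - tp[hi]
    d[ii] <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
  }
  d
}

tss_score_from_distances <- function(d, n_tss, flank, center_halfwidth,
                                     pseudocount) {
  d <- d[!is.na(d)]
  n_center <- sum(abs(d) <= center_halfwidth)
  n_flank <- sum(abs(d) >= flank - 100L & abs(d) <= flank)
  center_bp <- (2L * center_halfwidth + 1L) * n_tss
  flank_bp <- 2L * 101L * n_tss
  center_rate <- n_center / center_bp
  flank_rate <- max(n_flank / flank_bp, pseudocount)
  center_rate / flank_rate
}

#' Per-barcode ATAC quality metrics
#'
#' Counts unique fragments per barcode (each record counts once; duplicate
#' counts are ignored, the records being already deduplicated) and computes
#' the per-barcode TSS enrichment score, then applies the joint filter
#' (both thresholds inclusive).
#'
#' @param frags fragment data.frame from [read_fragments()].
#' @param annotation a `genome_annotation` providing TSS positions.
#' @param min_frags minimum unique fragments per retained cell.
#' @param min_tss minimum TSS enrichment score per retained cell.
#' @inheritParams compute_tss_enrichment
#' @return data.frame: barcode, n_unique_fragments, tss_enrichment,
#'   passes_filter.
#' @export
fragments_qc <- function(frags, annotation, min_frags = 1000L, min_tss = 8,
                         flank = 2000L, center_halfwidth = 50L,
                         pseudocount = 0.01) {
  tss <- annotation$genes
  if (nrow(tss) == 0L) stop("no TSS positions supplied")
  barcodes <- sort(unique(frags$barcode))
  if (length(barcodes) == 0L) {
    return(data.frame(barcode = character(), n_unique_fragments = integer(),
                      tss_enrichment = numeric(), passes_filter = logical(),
                      stringsAsFactors = FALSE))
  }
  n_frag <- table(factor(frags$barcode, levels = barcodes))
  d <- tss_distances(frags, tss)
  bc2 <- factor(rep(frags$barcode, 2L), levels = barcodes)
  n_tss <- nrow(unique(tss[, c("chrom", "tss")]))
  keep <- !is.na(d)
  center <- tapply(abs(d[keep]) <= center_halfwidth, bc2[keep], sum)
  flankn <- tapply(abs(d[keep]) >= flank - 100L & abs(d[keep]) <= flank,
                   bc2[keep], sum)
  center[is.na(center)] <- 0; flankn[is.na(flankn)] <- 0
  center_bp <- (2L * center_halfwidth + 1L) * n_tss
  flank_bp <- 2L * 101L * n_tss
  enr <- (center[barcodes] / center_bp) /
    pmax(flankn[barcodes] / flank_bp, pseudocount)
  enr[is.na(enr)] <- 0
  out <- data.frame(barcode = barcodes,
                    n_unique_fragments = as.integer(n_frag[barcodes]),
                    tss_enrichment = as.numeric(enr),
                    stringsAsFactors = FALSE)
  out$passes_filter <- out$n_unique_fragments >= min_frags &
    out$tss_enrichment >= min_tss
  rownames(out) <- NULL
  out
}

#' Barcodes passing the per-cell quality filter
#'
#' A barcode is retained iff `n_unique_fragments >= min_frags` and
#' `tss_enrichment >= min_tss` (both inclusive). An optional externally
#' supplied exclusion list (e.g. doublet flags) is removed afterwards.
#'
#' @param metrics data.frame from [fragments_qc()].
#' @param min_frags,min_tss inclusive thresholds.
#' @param exclude optional barcodes to drop regardless of metrics.
#' @return character vector of passing barcodes.
#' @export
filter_cells <- function(metrics, min_frags = 1000L, min_tss = 8,
                         exclude = NULL) {
  keep <- metrics$barcode[metrics$n_unique_fragments >= min_frags &
                            metrics$tss_enrichment >= min_tss]
  setdiff(keep, exclude)
}

#' Fragment-size histogram and nucleosomal-mode diagnostic
#'
#' Tabulates fragment lengths and reports the fraction of fragments in the
#' mono-nucleosomal 150-300 bp band, a cheap stand-in diagnostic for the
#' nucleosomal periodicity expected of a good ATAC library.
#'
#' @param frags fragment data.frame.
#' @return list: `histogram` (named integer vector, length -> count) and
#'   `periodicity` (fraction of mass in 150-300 bp).
#' @export
fragment_size_histogram <- function(frags) {
  len <- frags$end - frags$start
  if (length(len) == 0L)
    return(list(histogram = integer(0), periodicity = NA_real_))
  h <- table(len)
  list(histogram = stats::setNames(as.integer(h), names(h)),
       periodicity = sum(len >= 150L & len <= 300L) / length(len))
}
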