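#' Default per-type accessible peak plan
#'
#' Assigns each cell type a set of fixed-width accessible intervals: a pool
#' shared by all types plus type-specific intervals, placed away from each
#' other on a regular grid over the genome.
#'
#' @param annotation a `genome_annotation`.
#' @param cell_types character vector of type names.
#' @param n_shared number of peaks accessible in every type.
#' @param n_specific number of peaks private to each type.
#' @param peak_width width of each accessible interval (bp).
#' @param seed integer seed.
#' @return named list (per type) of data.frames (chrom, start, end).
#' @export
make_peak_plan <- function(annotation, cell_types, n_shared = 100L,
                           n_specific = 25L, peak_width = 500L, seed = 1L) {
  n_types <- length(cell_types)
  total <- n_shared + n_specific * n_types
  chroms <- annotation$chromosomes
  glen <- sum(chroms$length)
  stopifnot(total * peak_width * 2 < glen)
  with_seed(seed, {
    # grid of candidate centers across concatenated genome, randomized order
    centers <- round(seq(peak_width, glen - peak_width, length.out = total))
    centers <- sample(centers)
    offs <- c(0, cumsum(chroms$length))
    ci <- findInterval(centers, offs, rightmost.closed = TRUE)
    pos <- centers - offs[ci]
    pos <- pmin(pmax(pos, peak_width), chroms$length[ci] - peak_width)
    all_peaks <- data.frame(chrom = chroms$name[ci],
                            start = as.integer(pos - peak_width %/% 2),
                            end   = as.integer(pos + peak_width %/% 2),
                            stringsAsFactors = FALSE)
    shared <- all_peaks[seq_len(n_shared), , drop = FALSE]
    plan <- vector("list", n_types)
    names(plan) <- cell_types
    for (i in seq_len(n_types)) {
      idx <- n_shared + (i - 1L) * n_specific + seq_len(n_specific)
      plan[[i]] <- rbind(shared, all_peaks[idx, , drop = FALSE])
      rownames(plan[[i]]) <- NULL
    }
    plan
  })
}

#' Simulate a single-cell ATAC fragment file with ground truth
#'
#' Emits a sorted, block-gzipped 5-column fragment file (chrom, start, end,
#' barcode, duplicate count; 0-based half-open) emulating a single-cell ATAC
#' library. Good-quality cells draw most fragments from their cell type's
#' accessible peaks and from TSS-proximal windows (giving high TSS enrichment
#' and type-separable accessibility); low-quality cells draw uniformly from
#' background at reduced depth. Fragment lengths follow a two-component
#' mixture (shifted-exponential sub-nucleosomal mode, min 30 bp, mean 80 bp;
#' Normal(200, 30) mono-nucleosomal mode; weights 0.6/0.4), so the size
#' histogram is bimodal.
#'
#' @param annotation a `genome_annotation` (needs >= 1 gene for TSS signal).
#' @param cell_plan data.frame with columns `cell_type`, `n_cells`, `depth`
#'   (mean unique fragments per good cell; actual depths are Poisson).
#' @param peak_plan named list (per cell type) of accessible intervals
#'   (data.frames chrom/start/end), e.g. from [make_peak_plan()].
#' @param quality_mix fraction of barcodes that are low-quality.
#' @param seed integer seed; output is byte-identical across reruns.
#' @param path output path for the fragment file (".tsv.gz" added if absent);
#'   `NULL` writes to a tempfile.
#' @param frac_peak,frac_tss fraction of a good cell's fragments centered in
#'   accessible peaks / in TSS-proximal windows (remainder is uniform
#'   background).
#' @param lowq_depth_factor depth multiplier for low-quality cells.
#' @param tss_sd s.d. (bp) of good-cell insertion placement around the TSS.
#' @return list with `path` (fragment file) and `truth` (data.frame: barcode,
#'   cell_type, quality, depth_drawn).
#' @export
simulate_fragments <- function(annotation, cell_plan, peak_plan,
                               quality_mix = 0, seed = 1L, path = NULL,
                               frac_peak = 0.45, frac_tss = 0.40,
                               lowq_depth_factor = 0.5, tss_sd = 25) {
  stopifnot(is.data.frame(cell_plan),
            all(c("cell_type", "n_cells", "depth") %in% names(cell_plan)),
            quality_mix >= 0, quality_mix <= 1,
            all(cell_plan$cell_type %in% names(peak_plan)))
  chroms <- annotation$chromosomes
  clen <- stats::setNames(chroms$length, chroms$name)
  for (pp in peak_plan) {
    if (!all(pp$chrom %in% chroms$name) ||
        any(pp$start < 0) || any(pp$end > clen[pp$chrom]))
      stop("peak_plan interval outside chromosome bounds")
  }
  if (is.null(path)) path <- tempfile(fileext = ".tsv.gz")
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")

  tss <- annotation$genes[, c("chrom", "tss")]
  n_total <- sum(cell_plan$n_cells)
  res <- if (n_total == 0L) {
    list(frags = NULL,
         truth = data.frame(barcode = character(), cell_type = character(),
                            quality = character(), depth_drawn = integer(),
                            stringsAsFactors = FALSE))
  } else with_seed(seed, {
    barcode <- sprintf("CELL%05d", seq_len(n_total))
    cell_type <- rep(cell_plan$cell_type, cell_plan$n_cells)
    depth_mean <- rep(cell_plan$depth, cell_plan$n_cells)
    lowq <- stats::runif(n_total) < quality_mix
    quality <- ifelse(lowq, "low", "good")
    depth <- stats::rpois(n_total,
                          ifelse(lowq, depth_mean * lowq_depth_factor, depth_mean))
    pieces <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      d <- depth[i]
      if (d == 0L) next
      if (lowq[i]) {
        centers <- draw_uniform_positions(d, chroms)
      } else {
        n_pk <- stats::rbinom(1L, d, frac_peak)
        n_ts <- stats::rbinom(1L, d - n_pk, min(1, frac_tss / (1 - frac_peak)))
        n_bg <- d - n_pk - n_ts
        pk <- peak_plan[[cell_type[i]]]
        cpk <- if (n_pk > 0) {
          j <- sample.int(nrow(pk), n_pk, replace = TRUE)
          data.frame(chrom = pk$chrom[j],
                     pos = pk$start[j] +
                       floor(stats::runif(n_pk) * (pk$end[j] - pk$start[j])),
                     stringsAsFactors = FALSE)
        }
        cts <- if (n_ts > 0 && nrow(tss) > 0) {
          j <- sample.int(nrow(tss), n_ts, replace = TRUE)
          data.frame(chrom = tss$chrom[j],
                     pos = round(tss$tss[j] + stats::rnorm(n_ts, 0, tss_sd)),
                     stringsAsFactors = FALSE)
        }
        cbg <- if (n_bg > 0) draw_uniform_positions(n_bg, chroms)
        centers <- rbind(cpk, cts, cbg)
      }
      len <- draw_fragment_lengths(nrow(centers))
      start <- pmax(0L, as.integer(round(centers$pos - len / 2)))
      end <- start + len
      end <- pmin(end, clen[centers$chrom])
      ok <- end > start
      pieces[[i]] <- data.frame(chrom = centers$chrom[ok],
                                start = start[ok], end = as.integer(end[ok]),
                                barcode = barcode[i],
                                count = 1L + stats::rpois(sum(ok), 0.2),
                                stringsAsFactors = FALSE)
    }
    list(frags = do.call(rbind, pieces),
         truth = data.frame(barcode = barcode, cell_type = cell_type,
                            quality = quality, depth_drawn = depth,
                            stringsAsFactors = FALSE))
  })
  frags <- res$frags
  if (is.null(frags)) {
    frags <- data.frame(chrom = character(), start = integer(),
                        end = integer(), barcode = character(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  ord <- order(match(frags$chrom, chroms$name), frags$start, frags$end,
               frags$barcode)
  frags <- frags[ord, , drop = FALSE]
  tmp <- tempfile(fileext = ".tsv")
  data.table::fwrite(frags, tmp, sep = "\t", col.names = FALSE)
  if (file.exists(path)) file.remove(path)
  Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
  file.remove(tmp)
  list(path = path, truth = res$truth)
}

# Uniform genome-background fragment centers.
draw_uniform_positions <- function(n, chroms) {
  p <- chroms$length / sum(chroms$length)
  ci <- sample.int(nrow(chroms), n, replace = TRUE, prob = p)
  data.frame(chrom = chroms$name[ci],
             pos = floor(stats::runif(n) * chroms$length[ci]),
             stringsAsFactors = FALSE)
}

# Two-component fragment-length mixture: 0.6 shifted-Exp(min 30, mean 80) +
# 0.4 Normal(200, 30), truncated below at 30 bp.
draw_fragment_lengths <- function(n, p_short = 0.6) {
  short <- stats::runif(n) < p_short
  len <- numeric(n)
  len[short] <- 30 + stats::rexp(sum(short), rate = 1 / 50)
  len[!short] <- stats::rnorm(sum(!short), 200, 30)
  as.integer(pmax(30, round(len)))
}
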