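#' Simulate a compact genome annotation
#'
#' Builds a toy genome of `n_chrom` chromosomes of `chrom_len` bp each and
#' places `n_genes` genes on random strands such that no two TSS +/- 2 kb
#' windows overlap and every gene lies within its chromosome. Gene placement
#' uses a regular per-chromosome grid with random jitter, so packing either
#' succeeds deterministically or fails with a capacity error.
#'
#' TSS/TTS are strand-resolved: on `+` the TSS is the leftmost coordinate
#' (TSS < TTS), on `-` the rightmost (TSS > TTS). Coordinates are 0-based.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome in bp.
#' @param n_genes total number of genes to place.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param tss_window half-width (bp) of the exclusive TSS window (default 2000).
#' @param gene_len_range min/max gene body length in bp.
#' @return an object of class `genome_annotation`: a list with `chromosomes`
#'   (data.frame: name, length) and `genes` (data.frame: gene, chrom, strand,
#'   tss, tts, start, end).
#' @export
#' @examples
#' gn <- make_genome(n_chrom = 2, chrom_len = 5e6, n_genes = 200, seed = 7)
#' nrow(gn$genes)
make_genome <- function(n_chrom = 1L, chrom_len = 1e6, n_genes = 60L, seed = 1L,
                        tss_window = 2000L, gene_len_range = c(1000L, 10000L)) {
  stopifnot(n_chrom >= 1, chrom_len > 0, n_genes >= 0)
  chroms <- data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length = as.integer(chrom_len),
    stringsAsFactors = FALSE
  )
  slot <- 2L * tss_window + 1L  # exclusive TSS window width
  if (n_genes > 0) {
    per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1L)))
    need <- max(per_chrom)
    # each gene needs a TSS slot plus room for its body on one side
    if (need * (slot + max(gene_len_range)) > chrom_len) {
      stop("cannot place ", need, " genes with non-overlapping TSS windows of ",
           slot, " bp (plus gene bodies) on a ", chrom_len, " bp chromosome")
    }
  } else per_chrom <- integer(n_chrom)

  genes <- with_seed(seed, {
    out <- vector("list", n_chrom)
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      k <- per_chrom[ci]
      if (k == 0L) { out[[ci]] <- NULL; next }
      pitch <- floor(chrom_len / k)
      body_max <- min(max(gene_len_range), floor(pitch * 0.4))
      body_min <- min(min(gene_len_range), body_max)
      jitter_max <- max(0L, floor((pitch - slot - body_max) / 2))
      tss <- integer(k); tts <- integer(k); strand <- character(k)
      for (i in seq_len(k)) {
        center <- as.integer(round((i - 0.5) * pitch))
        strand[i] <- sample(c("+", "-"), 1L)
        jit <- if (jitter_max > 0) sample.int(2L * jitter_max + 1L, 1L) - jitter_max - 1L else 0L
        len <- if (body_max > body_min) sample(body_min:body_max, 1L) else body_min
        # keep the whole body (either side of the TSS) inside the chromosome
        t0 <- min(max(center + jit, body_max + tss_window),
                  chrom_len - body_max - tss_window)
        if (strand[i] == "+") { tss[i] <- t0; tts[i] <- t0 + len }
        else                  { tss[i] <- t0; tts[i] <- t0 - len }
      }
      gid_new <- gid + seq_len(k)
      out[[ci]] <- data.frame(
        gene = sprintf("GENE%04d", gid_new),
        chrom = chroms$name[ci], strand = strand,
        tss = tss, tts = tts,
        start = pmin(tss, tts), end = pmax(tss, tts),
        stringsAsFactors = FALSE
      )
      gid <- gid + k
    }
    do.call(rbind, out)
  })
  if (is.null(genes)) {
    genes <- data.frame(gene = character(), chrom = character(),
                        strand = character(), tss = integer(), tts = integer(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(genes$start >= 0), all(genes$end <= chrom_len),
            !anyDuplicated(genes$gene))
  # TSS +/- tss_window exclusion zones must not overlap within a chromosome
  for (cn in unique(genes$chrom)) {
    ts <- sort(genes$tss[genes$chrom == cn])
    if (length(ts) > 1L && any(diff(ts) <= 2L * tss_window))
      stop("TSS windows overlap after placement; reduce n_genes or gene length")
  }
  structure(list(chromosomes = chroms, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Write gene annotation as a BED-like file
#'
#' Six columns: chrom, start, end, name, score (0), strand. 0-based half-open.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(annotation, path) {
  g <- annotation$genes
  bed <- data.frame(g$chrom, g$start, g$end, g$gene, 0L, g$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Inverse of [write_genes_bed()]; chromosome lengths are taken from
#' `chrom_lengths` (named vector) or inferred as the max end per chromosome.
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return a `genome_annotation`.
#' @export
read_genes_bed <- function(path, chrom_lengths = NULL) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(ncol(bed) >= 6)
  names(bed)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  tss <- ifelse(bed$strand == "+", bed$start, bed$end)
  tts <- ifelse(bed$strand == "+", bed$end, bed$start)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(bed$end, bed$chrom, max)
  }
  chroms <- data.frame(name = names(chrom_lengths),
                       length = as.integer(chrom_lengths),
                       stringsAsFactors = FALSE)
  genes <- data.frame(gene = bed$gene, chrom = bed$chrom, strand = bed$strand,
                      tss = tss, tts = tts,
                      start = pmin(tss, tts), end = pmax(tss, tts),
                      stringsAsFactors = FALSE)
  structure(list(chromosomes = chroms, genes = genes),
            class = "genome_annotation")
}
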