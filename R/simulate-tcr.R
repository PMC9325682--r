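#' Simulate paired-chain TCR contigs with known clonal structure
#'
#' Produces a contig table (one row per chain: barcode, chain, v_gene, j_gene,
#' cdr3_nt, productive) in which every T cell carries exactly one productive
#' alpha and one productive beta chain unless flagged multi-chain. Clones are
#' drawn per cluster from a geometric clone-size law whose expansion is
#' controlled per cluster; `n_shared` clones are forced to span two clusters
#' (and hence typically two tissues) to create shared clonotypes.
#'
#' CDR3 sequences are arbitrary unique nucleotide tokens; V/J genes are drawn
#' from small fixed repertoires. The clonotype key is the combination
#' (V-alpha, J-alpha, CDR3-alpha, V-beta, J-beta, CDR3-beta).
#'
#' @param cell_meta data.frame with columns `barcode`, `cluster`, `tissue`
#'   (tissue in blood/normal/tumor).
#' @param expansion named numeric (per cluster), the success probability of
#'   the geometric clone-size law minus one: clone size = 1 + rgeom(p);
#'   smaller p = more expansion. Value 1 forces all-singleton clusters;
#'   use `monoclonal` to force one clone per listed cluster.
#' @param n_shared number of clones split across two clusters.
#' @param monoclonal character vector of clusters collapsed to one clone.
#' @param multi_chain_frac fraction of cells given a second productive beta
#'   chain (for QC-path testing).
#' @param seed integer seed.
#' @return list: `contigs` (data.frame), `truth` (data.frame barcode,
#'   cluster, tissue, clone_id).
#' @export
simulate_tcr <- function(cell_meta, expansion = NULL, n_shared = 0L,
                         monoclonal = character(), multi_chain_frac = 0,
                         seed = 1L) {
  stopifnot(all(c("barcode", "cluster", "tissue") %in% names(cell_meta)))
  clusters <- unique(cell_meta$cluster)
  if (is.null(expansion))
    expansion <- stats::setNames(rep(0.5, length(clusters)), clusters)
  with_seed(seed, {
    clone_of <- character(nrow(cell_meta))
    next_id <- 1L
    for (cl in clusters) {
      idx <- which(cell_meta$cluster == cl)
      n <- length(idx)
      if (cl %in% monoclonal) {
        sizes <- n
      } else {
        p <- expansion[[as.character(cl)]]
        sizes <- integer(0)
        while (sum(sizes) < n) {
          s <- if (p >= 1) 1L else 1L + stats::rgeom(1L, p)
          sizes <- c(sizes, min(s, n - sum(sizes)))
        }
      }
      ids <- sprintf("CLONE%04d", next_id - 1L + seq_along(sizes))
      next_id <- next_id + length(sizes)
      clone_of[idx] <- rep(ids, sizes)[sample.int(n)]
    }
    # force sharing: move half the cells of the n_shared largest clones
    # into a different cluster's cells (relabel those cells' clones)
    if (n_shared > 0L && length(clusters) > 1L) {
      tab <- sort(table(clone_of), decreasing = TRUE)
      take <- names(tab)[seq_len(min(n_shared, length(tab)))]
      for (cid in take) {
        cells <- which(clone_of == cid)
        home <- cell_meta$cluster[cells[1L]]
        away <- which(cell_meta$cluster != home & clone_of != cid)
        if (length(away) == 0L) next
        k <- min(max(1L, length(cells) %/% 2L), length(away))
        clone_of[away[sample.int(length(away), k)]] <- cid
      }
    }
    clone_ids <- unique(clone_of)
    v_a <- paste0("TRAV", 1:8); j_a <- paste0("TRAJ", 1:6)
    v_b <- paste0("TRBV", 1:8); j_b <- paste0("TRBJ", 1:6)
    key <- data.frame(
      clone_id = clone_ids,
      va = sample(v_a, length(clone_ids), replace = TRUE),
      ja = sample(j_a, length(clone_ids), replace = TRUE),
      cdr3a = sprintf("TGT%sNT", seq_along(clone_ids)),
      vb = sample(v_b, length(clone_ids), replace = TRUE),
      jb = sample(j_b, length(clone_ids), replace = TRUE),
      cdr3b = sprintf("TGC%sNT", seq_along(clone_ids)),
      stringsAsFactors = FALSE
    )
    k <- key[match(clone_of, key$clone_id), ]
    contigs <- rbind(
      data.frame(barcode = cell_meta$barcode, chain = "TRA",
                 v_gene = k$va, j_gene = k$ja, cdr3_nt = k$cdr3a,
                 productive = "True", stringsAsFactors = FALSE),
      data.frame(barcode = cell_meta$barcode, chain = "TRB",
                 v_gene = k$vb, j_gene = k$jb, cdr3_nt = k$cdr3b,
                 productive = "True", stringsAsFactors = FALSE)
    )
    if (multi_chain_frac > 0) {
      extra <- which(stats::runif(nrow(cell_meta)) < multi_chain_frac)
      if (length(extra) > 0L) {
        contigs <- rbind(contigs, data.frame(
          barcode = cell_meta$barcode[extra], chain = "TRB",
          v_gene = sample(v_b, length(extra), replace = TRUE),
          j_gene = sample(j_b, length(extra), replace = TRUE),
          cdr3_nt = sprintf("TGCX%sNT", extra),
          productive = "True", stringsAsFactors = FALSE))
      }
    }
    contigs <- contigs[order(contigs$barcode, contigs$chain), ]
    rownames(contigs) <- NULL
    truth <- data.frame(barcode = cell_meta$barcode,
                        cluster = cell_meta$cluster,
                        tissue = cell_meta$tissue,
                        clone_id = clone_of, stringsAsFactors = FALSE)
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate a bulk expression + survival cohort
#'
#' Five signature genes (FAS, FASLG, TNFSF10, TRAF1, TRAF2) share a common
#' latent factor; per-sample survival is exponential with the hazard
#' multiplied by `hazard_ratio` for samples whose signature score (mean of
#' the five per-gene z-scores) is at or above the cohort median. Censoring is
#' an independent exponential calibrated so that a fraction `censoring_rate`
#' of samples is censored under unit hazard ratio. A three-level stage label
#' correlates with the latent factor when `stage_effect > 0`.
#'
#' @param n_samples number of samples (>= 4).
#' @param hazard_ratio hazard multiplier for the high-score group (> 0).
#' @param censoring_rate target fraction censored in [0, 1).
#' @param stage_effect strength of the stage-score association (0 = none).
#' @param factor_loading loading of the common latent factor on each gene.
#' @param base_hazard baseline exponential hazard (per day).
#' @param seed integer seed.
#' @return data.frame: sample_id, FAS, FASLG, TNFSF10, TRAF1, TRAF2,
#'   os_time (days), os_event (1 = death), stage.
#' @export
simulate_cohort <- function(n_samples = 200L, hazard_ratio = 1,
                            censoring_rate = 0.3, stage_effect = 0,
                            factor_loading = 0.8, base_hazard = 1 / 1000,
                            seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  stopifnot(n_samples >= 4, censoring_rate >= 0, censoring_rate < 1)
  genes <- c("FAS", "FASLG", "TNFSF10", "TRAF1", "TRAF2")
  with_seed(seed, {
    f <- stats::rnorm(n_samples)
    expr <- sapply(genes, function(g)
      factor_loading * f + sqrt(1 - factor_loading^2) * stats::rnorm(n_samples))
    z <- scale(expr)
    score <- rowMeans(z)
    high <- score >= stats::median(score)
    haz <- base_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- stats::rexp(n_samples, haz)
    if (censoring_rate > 0) {
      cens_haz <- base_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n_samples, cens_haz)
    } else t_cens <- rep(Inf, n_samples)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    stage_score <- stage_effect * f + stats::rnorm(n_samples)
    stage <- cut(stage_score, stats::quantile(stage_score, c(0, .6, .85, 1)),
                 labels = c("early", "locally_advanced", "metastatic"),
                 include.lowest = TRUE)
    out <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                      expr, os_time = os_time, os_event = os_event,
                      stage = as.character(stage), stringsAsFactors = FALSE)
    names(out)[2:6] <- genes
    out
  })
}
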