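# Shared fixtures and small oracles used across test files.

# adjusted Rand index (independent closed-form oracle for label recovery)
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# small 2-type fragment fixture shared by several unit tests
small_frag_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gn <- make_genome(n_chrom = 1, chrom_len = 5e5, n_genes = 20, seed = 3)
    types <- c("alpha", "beta")
    pp <- make_peak_plan(gn, types, n_shared = 30, n_specific = 15, seed = 2)
    plan <- data.frame(cell_type = types, n_cells = 60, depth = 1500)
    sim <- simulate_fragments(gn, plan, pp, quality_mix = 0, seed = 11)
    cache <<- list(genome = gn, peak_plan = pp, sim = sim,
                   frags = read_fragments(sim$path))
    cache
  }
})

# three well-separated Gaussian blobs in 2-D with labelled rows
blob_embedding <- function(n_per = 100, centers = rbind(c(0, 0), c(10, 0),
                                                        c(0, 10)),
                           sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  rownames(coords) <- sprintf("cell%04d", seq_len(k * n_per))
  list(coords = coords,
       labels = factor(rep(paste0("blob", seq_len(k)), each = n_per)))
}

# paired-modality fixture: shared type profiles + modality-specific noise
paired_modality_fixture <- function(n_genes = 250, n_per_type = 40,
                                    n_types = 3, noise = 0.5, seed = 1) {
  set.seed(seed)
  types <- factor(rep(paste0("T", seq_len(n_types)), each = n_per_type))
  prof <- matrix(rnorm(n_genes * n_types), n_genes, n_types,
                 dimnames = list(paste0("G", seq_len(n_genes)), NULL))
  base <- prof[, as.integer(types)]
  rna <- base + matrix(rnorm(length(base), 0, noise), n_genes)
  atac <- base + matrix(rnorm(length(base), 0, noise), n_genes)
  colnames(rna) <- paste0("R", seq_along(types))
  colnames(atac) <- paste0("A", seq_along(types))
  list(rna = rna, atac = atac, types = types)
}

# gaussian matrix with two planted correlated modules plus noise genes
planted_module_matrix <- function(n_cells = 500, module_size = 30,
                                  n_noise = 140, r = 0.6, seed = 4) {
  set.seed(seed)
  mk <- function(f, k) sapply(seq_len(k), function(i)
    sqrt(r) * f + sqrt(1 - r) * rnorm(n_cells))
  f1 <- rnorm(n_cells); f2 <- rnorm(n_cells)
  x <- cbind(mk(f1, module_size), mk(f2, module_size),
             matrix(rnorm(n_cells * n_noise), n_cells))
  colnames(x) <- c(paste0("A", seq_len(module_size)),
                   paste0("B", seq_len(module_size)),
                   paste0("N", seq_len(n_noise)))
  rownames(x) <- paste0("cell", seq_len(n_cells))
  t(x)  # genes x cells
}

# clonotype table literal for index identity tests
clonotype_fixture <- function(clonotype, cluster, tissue = "tumor") {
  ct <- data.frame(barcode = sprintf("b%03d", seq_along(clonotype)),
                   clonotype = clonotype, cluster = cluster,
                   tissue = rep_len(tissue, length(clonotype)),
                   stringsAsFactors = FALSE)
  class(ct) <- c("clonotype_table", "data.frame")
  ct
}
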