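#' Simulate a single-cell expression count matrix with ground truth
#'
#' Draws negative-binomial counts (dispersion 0.5 by default) for a set of
#' cells with known types: housekeeping background genes, per-type marker
#' genes elevated by `marker_log2fc`, mitochondrial genes (prefix "MT-")
#' tuned to a target per-cell mitochondrial fraction, and a correlated
#' "dysfunction" gene module whose means increase with a latent pseudotime
#' in [0, 1]. Pseudotime is drawn only for cells whose type is listed in
#' `gradient_types` (all types if `NULL`).
#'
#' @param truth data.frame with columns `barcode` and `cell_type` (e.g. the
#'   `truth` component of [simulate_fragments()]).
#' @param n_genes total number of genes (module, marker and mito genes are
#'   carved out of this total).
#' @param module_size number of genes in the latent-gradient module.
#' @param gradient_loading log2 fold range of module-gene means across the
#'   pseudotime gradient (0 = null module).
#' @param markers_per_type number of marker genes per cell type.
#' @param marker_log2fc log2 fold change of a marker in its own type.
#' @param n_mito number of mitochondrial genes.
#' @param mito_shape shape parameters (length 2) of the Beta distribution of
#'   the per-cell mitochondrial fraction.
#' @param base_mean baseline negative-binomial mean per gene.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param gradient_types cell types carrying the latent gradient, or `NULL`.
#' @param seed integer seed.
#' @return list: `counts` (dgCMatrix genes x cells), `truth` (input plus
#'   `pseudotime`, NA outside gradient types), `module_genes`,
#'   `marker_genes` (named list per type), `mito_genes`.
#' @export
simulate_expression <- function(truth, n_genes = 500L, module_size = 75L,
                                gradient_loading = 2, markers_per_type = 10L,
                                marker_log2fc = 3, n_mito = 10L,
                                mito_shape = c(2, 30), base_mean = 1,
                                dispersion = 0.5, gradient_types = NULL,
                                seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("barcode", "cell_type") %in% names(truth)))
  types <- unique(truth$cell_type)
  reserved <- module_size + markers_per_type * length(types) + n_mito
  if (reserved > n_genes)
    stop("module_size + markers + mito genes (", reserved,
         ") exceed n_genes (", n_genes, ")")
  n_cells <- nrow(truth)
  with_seed(seed, {
    module_genes <- sprintf("MOD%03d", seq_len(module_size))
    marker_genes <- stats::setNames(lapply(seq_along(types), function(i) {
      sprintf("MK%s_%02d", i, seq_len(markers_per_type))
    }), types)
    mito_genes <- sprintf("MT-G%02d", seq_len(n_mito))
    n_bg <- n_genes - reserved
    bg_genes <- sprintf("BG%04d", seq_len(n_bg))
    genes <- c(module_genes, unlist(marker_genes, use.names = FALSE),
               mito_genes, bg_genes)

    pt <- rep(NA_real_, n_cells)
    in_grad <- if (is.null(gradient_types)) rep(TRUE, n_cells)
               else truth$cell_type %in% gradient_types
    pt[in_grad] <- stats::runif(sum(in_grad))

    # per-gene x per-cell log2 mean offsets
    mu <- matrix(base_mean, nrow = length(genes), ncol = n_cells,
                 dimnames = list(genes, truth$barcode))
    if (module_size > 0) {
      t_eff <- ifelse(is.na(pt), 0, pt)
      # gene-specific loading in [0.5, 1] * gradient_loading keeps genes correlated
      gl <- stats::runif(module_size, 0.5, 1) * gradient_loading
      mu[module_genes, ] <- base_mean * 2^(outer(gl, t_eff))
    }
    for (ty in types) {
      cols <- truth$cell_type == ty
      mu[marker_genes[[ty]], cols] <- base_mean * 2^marker_log2fc
    }
    # mito genes: scale so that expected mito fraction matches the Beta draw
    mf <- stats::rbeta(n_cells, mito_shape[1], mito_shape[2])
    nonmito_tot <- colSums(mu[setdiff(genes, mito_genes), , drop = FALSE])
    mu[mito_genes, ] <- rep(mf / (1 - mf) * nonmito_tot / n_mito,
                            each = n_mito)

    counts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion,
                                    mu = as.vector(mu)),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    truth$pseudotime <- pt
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         truth = truth, module_genes = module_genes,
         marker_genes = marker_genes, mito_genes = mito_genes)
  })
}

#' Write a count matrix in MatrixMarket triplet form
#'
#' Writes `matrix.mtx`, `features.tsv` (gene names) and `barcodes.tsv` into
#' `dir`, the conventional single-cell exchange layout.
#'
#' @param counts a genes x cells matrix (sparse or dense, with dimnames).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket triplet directory
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return dgCMatrix with gene/barcode dimnames.
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
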