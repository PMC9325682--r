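#' Build a clonotype table from paired-chain contigs
#'
#' Retains cells with exactly one productive alpha and one productive beta
#' chain; the clonotype key is the combination (V-alpha, J-alpha,
#' CDR3-alpha-nt, V-beta, J-beta, CDR3-beta-nt). Cells lacking a productive
#' beta chain are excluded from the T cell set.
#'
#' @param contigs data.frame: barcode, chain (TRA/TRB), v_gene, j_gene,
#'   cdr3_nt, productive.
#' @param cell_meta optional data.frame (barcode, tissue, cluster) merged in.
#' @return object of class `clonotype_table`: data.frame with one row per
#'   retained cell (barcode, clonotype, and any metadata columns).
#' @export
build_clonotypes <- function(contigs, cell_meta = NULL) {
  stopifnot(all(c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                  "productive") %in% names(contigs)))
  bad_chain <- setdiff(unique(contigs$chain), c("TRA", "TRB"))
  if (length(bad_chain) > 0L)
    stop("unknown chain label(s): ", paste(bad_chain, collapse = ", "))
  prod <- contigs[productive_flag(contigs$productive), ]
  n_a <- table(factor(prod$barcode[prod$chain == "TRA"]))
  n_b <- table(factor(prod$barcode[prod$chain == "TRB"]))
  keep <- intersect(names(n_a)[n_a == 1L], names(n_b)[n_b == 1L])
  a <- prod[prod$chain == "TRA" & prod$barcode %in% keep, ]
  b <- prod[prod$chain == "TRB" & prod$barcode %in% keep, ]
  a <- a[match(keep, a$barcode), ]
  b <- b[match(keep, b$barcode), ]
  out <- data.frame(
    barcode = keep,
    clonotype = paste(a$v_gene, a$j_gene, a$cdr3_nt,
                      b$v_gene, b$j_gene, b$cdr3_nt, sep = "|"),
    stringsAsFactors = FALSE)
  if (!is.null(cell_meta))
    out <- merge(out, cell_meta, by = "barcode", sort = TRUE)
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' Clonal expansion index of a cluster
#'
#' For the N_c clonotypes in a cluster with cell fractions p_k:
#' expa = 1 - H / log(N_c) with H the Shannon entropy (nats); defined as 1
#' for a monoclonal cluster (N_c = 1) and 0 when every clone is a
#' singleton.
#'
#' @param ct a `clonotype_table` with a `cluster` column.
#' @param cluster cluster id (default: all clusters).
#' @return data.frame: cluster, expa, n_cells, n_clonotypes.
#' @export
expansion_index <- function(ct, cluster = NULL) {
  cls <- if (is.null(cluster)) unique(ct$cluster) else cluster
  out <- lapply(cls, function(cl) {
    sizes <- table(ct$clonotype[ct$cluster == cl])
    n <- sum(sizes); nc <- length(sizes)
    if (n == 0L) return(data.frame(cluster = cl, expa = NA_real_,
                                   n_cells = 0L, n_clonotypes = 0L))
    expa <- if (nc == 1L) 1 else 1 - shannon_entropy(sizes) / log(nc)
    data.frame(cluster = cl, expa = expa, n_cells = n, n_clonotypes = nc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tissue migration index of a cluster
#'
#' Each clonotype's migration entropy is the Shannon entropy (nats) of its
#' tissue distribution computed over all of its cells dataset-wide; the
#' cluster index is the cell-weighted mean over clonotypes present in the
#' cluster (weights n_k / n, with n_k the clone's cells in the cluster).
#'
#' @param ct a `clonotype_table` with `tissue` and `cluster` columns.
#' @param cluster cluster id (default: all clusters).
#' @return data.frame: cluster, migr.
#' @export
migration_index <- function(ct, cluster = NULL) {
  clone_ent <- vapply(split(ct$tissue, ct$clonotype),
                      function(tt) shannon_entropy(table(tt)), numeric(1))
  cls <- if (is.null(cluster)) unique(ct$cluster) else cluster
  out <- lapply(cls, function(cl) {
    sub <- ct[ct$cluster == cl, ]
    n_k <- table(sub$clonotype)
    migr <- if (nrow(sub) == 0L) NA_real_
            else sum(as.numeric(n_k) / nrow(sub) * clone_ent[names(n_k)])
    data.frame(cluster = cl, migr = migr, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' State transition index across clusters
#'
#' Each clonotype's transition entropy is the Shannon entropy (nats) of its
#' cluster-membership distribution dataset-wide; per-cluster tran is the
#' cell-weighted mean over clonotypes with at least one cell in the
#' cluster. `pair` restricts the computation to cells of two clusters.
#'
#' @param ct a `clonotype_table` with a `cluster` column.
#' @param pair optional length-2 cluster pair for the pairwise variant.
#' @return data.frame: cluster, tran.
#' @export
transition_index <- function(ct, pair = NULL) {
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L)
    ct <- ct[ct$cluster %in% pair, ]
  }
  clone_ent <- vapply(split(ct$cluster, ct$clonotype),
                      function(cc) shannon_entropy(table(cc)), numeric(1))
  out <- lapply(unique(ct$cluster), function(cl) {
    sub <- ct[ct$cluster == cl, ]
    n_k <- table(sub$clonotype)
    data.frame(cluster = cl,
               tran = sum(as.numeric(n_k) / nrow(sub) * clone_ent[names(n_k)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cells per clonal frequency range, by cluster
#'
#' Clone sizes are computed dataset-wide; each cell is binned by its
#' clone's size into the supplied inclusive ranges.
#'
#' @param ct a `clonotype_table` with a `cluster` column.
#' @param ranges list of inclusive c(lo, hi) clone-size ranges.
#' @return data.frame: cluster, range, n_cells.
#' @export
frequency_ranges <- function(ct, ranges = list(c(1, 1), c(2, 5), c(6, 20),
                                               c(21, Inf))) {
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  stopifnot(!is.unsorted(lo, strictly = TRUE))
  lab <- vapply(ranges, function(r)
    if (is.infinite(r[2L])) paste0(">=", r[1L]) else paste0(r[1L], "-", r[2L]),
    character(1))
  if (nrow(ct) == 0L)
    return(data.frame(cluster = character(), range = character(),
                      n_cells = integer(), stringsAsFactors = FALSE))
  clone_size <- table(ct$clonotype)
  sz <- as.numeric(clone_size[ct$clonotype])
  out <- expand.grid(cluster = unique(ct$cluster), range = lab,
                     stringsAsFactors = FALSE)
  out$n_cells <- mapply(function(cl, rg) {
    r <- ranges[[match(rg, lab)]]
    sum(ct$cluster == cl & sz >= r[1L] & sz <= r[2L])
  }, out$cluster, out$range)
  out
}

#' Clonotypes shared between two cluster sets
#'
#' Clonotypes with at least one cell in each of two disjoint cluster sets,
#' annotated with per-tissue occupancy.
#'
#' @param ct a `clonotype_table` with `cluster` (and optionally `tissue`).
#' @param set_a,set_b disjoint cluster id vectors.
#' @return data.frame: clonotype, n_in_a, n_in_b, and per-tissue counts.
#' @export
shared_clonotypes <- function(ct, set_a, set_b) {
  if (length(intersect(set_a, set_b)) > 0L)
    stop("cluster sets overlap: ",
         paste(intersect(set_a, set_b), collapse = ", "))
  in_a <- ct$clonotype[ct$cluster %in% set_a]
  in_b <- ct$clonotype[ct$cluster %in% set_b]
  shared <- intersect(unique(in_a), unique(in_b))
  out <- data.frame(clonotype = shared,
                    n_in_a = as.integer(table(in_a)[shared]),
                    n_in_b = as.integer(table(in_b)[shared]),
                    stringsAsFactors = FALSE)
  if ("tissue" %in% names(ct) && length(shared) > 0L) {
    tis <- table(ct$clonotype, ct$tissue)
    for (tn in colnames(tis))
      out[[paste0("n_", tn)]] <- as.integer(tis[shared, tn])
  }
  out
}
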