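test_that("expression QC applies the strict filter string", {
  genes <- c(sprintf("G%04d", 1:6000), paste0("MT-", 1:10))
  cells <- paste0("c", 1:5)
  m <- Matrix::Matrix(0, length(genes), length(cells), sparse = TRUE,
                      dimnames = list(genes, cells))
  m[1:1000, 1] <- 1          # fine: 1000 features
  m[1:400, 2] <- 1           # too few features (400)
  m[1:5200, 3] <- 1          # too many features
  m[1:999, 4] <- 1; m[6001:6009, 4] <- 37  # mito fraction exactly 0.25
  m[1:1000, 5] <- 60         # 60000 counts: too many
  filt <- qc_filter_expression(m)
  expect_setequal(colnames(filt), "c1")
  # multi-chain removal and T cell subset
  contigs <- data.frame(
    barcode = c("c1", "c1", "c1"),
    chain = c("TRA", "TRB", "TRB"),
    v_gene = "V", j_gene = "J", cdr3_nt = c("a", "b", "c"),
    productive = "True")
  filt2 <- qc_filter_expression(m, contigs)
  expect_equal(ncol(filt2), 0)  # the only passing cell has 2 beta chains
})

test_that("normalization and clustering recover planted expression types", {
  truth <- data.frame(barcode = sprintf("c%04d", 1:750),
                      cell_type = rep(paste0("T", 1:5), each = 150))
  sim <- simulate_expression(truth, n_genes = 300, module_size = 0,
                             markers_per_type = 15, marker_log2fc = 4,
                             gradient_loading = 0, seed = 6)
  res <- normalize_and_cluster(sim$counts, n_hvg = 150, n_pcs = 15,
                               min_size = 50, seed = 2)
  expect_gte(ari(truth$cell_type, res$clusters$cluster), 0.9)
  res2 <- normalize_and_cluster(sim$counts, n_hvg = 150, n_pcs = 15,
                                min_size = 50, seed = 2)
  expect_identical(res$clusters$cluster, res2$clusters$cluster)
  # planted markers surface in the top-5 lists
  mk <- top_markers(as.matrix(res$normalized), res$clusters, n_top = 5)
  ann <- table(truth$cell_type, res$clusters$cluster)
  for (cl in colnames(ann)) {
    ty <- rownames(ann)[which.max(ann[, cl])]
    expect_gt(length(intersect(mk[[cl]], sim$marker_genes[[ty]])), 0)
  }
})

test_that("top_markers returns empty lists for exchangeable genes", {
  set.seed(3)
  x <- matrix(rexp(50 * 80), 50, dimnames = list(paste0("g", 1:50), NULL))
  cl <- factor(rep(c("A", "B"), each = 40))
  mk <- top_markers(x, cl, n_top = 5)
  expect_true(all(lengths(mk) == 0))
  expect_true(all(lengths(top_markers(x, cl, n_top = 0)) == 0))
})

test_that("module detection recovers planted modules, nulls and merges", {
  x <- planted_module_matrix()   # genes x cells, modules A* and B*
  ms <- detect_modules(x)
  expect_equal(length(ms$modules), 2)
  recall_a <- max(sapply(ms$modules, function(g)
    mean(paste0("A", 1:30) %in% g)))
  recall_b <- max(sapply(ms$modules, function(g)
    mean(paste0("B", 1:30) %in% g)))
  expect_gte(recall_a, 0.8)
  expect_gte(recall_b, 0.8)
  # gene-order permutation invariance (up to module labels)
  perm <- sample(nrow(x))
  msp <- detect_modules(x[perm, ])
  expect_setequal(unname(unlist(lapply(msp$modules, sort))),
                  unname(unlist(lapply(ms$modules, sort))))
  # independent noise -> no modules
  set.seed(11)
  noise <- matrix(rnorm(500 * 100), 100,
                  dimnames = list(paste0("g", 1:100), NULL))
  expect_equal(length(detect_modules(noise)$modules), 0)
  # strongly correlated eigengenes merge at merge_cut 0.15
  set.seed(12)
  n <- 500; f1 <- rnorm(n)
  f3 <- sqrt(0.81) * f1 + sqrt(0.19) * rnorm(n)
  mk <- function(f, k, r) sapply(seq_len(k), function(i)
    sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  xm <- t(cbind(mk(f1, 30, 0.7), mk(f3, 30, 0.7)))
  rownames(xm) <- paste0("G", 1:60)
  msm <- detect_modules(xm)
  expect_equal(length(msm$modules), 1)
})

test_that("bicor is a valid correlation and falls back for constant MADs", {
  set.seed(4)
  x <- matrix(rnorm(200 * 6), 200)
  b <- bicor_matrix(x)
  expect_equal(diag(b), rep(1, 6))
  expect_true(all(abs(b) <= 1 + 1e-12))
  expect_equal(b, t(b))
  # near-Pearson on clean Gaussian data
  expect_equal(b[1, 2], cor(x[, 1], x[, 2]), tolerance = 0.1)
  # constant-MAD column falls back to Pearson without error
  xc <- cbind(x[, 1:2], c(rep(0, 199), 1))
  expect_silent(bc <- bicor_matrix(xc))
  expect_true(all(is.finite(bc)))
})

test_that("dysfunction z-table and Holm-Sidak contrasts match hand values", {
  norm <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(4, 2, 0))
  colnames(norm) <- c("a", "b", "c")
  cl <- factor(c("C1", "C2", "C3"))
  ds <- dysfunction_score(norm, cl, c("g1", "g2", "g3"))
  expect_equal(unname(ds$z["g1", ]), c(-1, 0, 1))     # ddof-1 z-score
  expect_true(all(is.na(ds$z["g2", ])))               # constant gene masked
  # rows have mean 0 and sd 1 exactly
  ok <- !apply(is.na(ds$z), 1, any)
  expect_equal(unname(rowMeans(ds$z[ok, ])), rep(0, sum(ok)))
  expect_equal(unname(apply(ds$z[ok, ], 1, sd)), rep(1, sum(ok)))
  # Holm-Sidak step-down hand example
  expect_equal(holm_sidak(c(0.01, 0.03, 0.04)),
               c(1 - 0.99^3, max(1 - 0.99^3, 1 - 0.97^2),
                 max(1 - 0.99^3, 1 - 0.97^2, 1 - 0.96)),
               tolerance = 1e-10)
  expect_equal(round(holm_sidak(c(0.01, 0.03, 0.04)), 4),
               c(0.0297, 0.0591, 0.0591))
})
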