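make_cluster_factor <- function(barcodes, labels) {
  cl <- factor(labels)
  names(cl) <- barcodes
  cl
}

test_that("pseudobulk caller is null-calibrated and detects strong windows", {
  gn <- make_genome(1, 2e5, 0, seed = 1)
  set.seed(8)
  # uniform background: ~4 insertions per 500-bp window
  pos <- sample(0:199000, 800, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = pos, end = pos + 100,
                   barcode = "BC1", count = 1L)
  cl <- make_cluster_factor("BC1", "C1")
  pk0 <- call_peaks_pseudobulk(fr, cl, gn)[["C1"]]
  expect_lte(nrow(pk0), 2)  # <= fdr * n_windows expected false calls
  # a 100-insertion spike over background lambda ~ 2 is always called
  spike <- data.frame(chrom = "chr1", start = rep(50100L, 50),
                      end = rep(50200L, 50), barcode = "BC1", count = 1L)
  pk1 <- call_peaks_pseudobulk(rbind(fr, spike), cl, gn)[["C1"]]
  expect_true(any(pk1$start <= 50100 & pk1$end >= 50200))
  # zero-insertion cluster warns and returns empty set
  cl2 <- make_cluster_factor(c("BC1", "BC2"), c("C1", "C2"))
  expect_warning(pk2 <- call_peaks_pseudobulk(fr, cl2, gn), "no insertions")
  expect_equal(nrow(pk2[["C2"]]), 0)
})

test_that("overlap resolution keeps the higher-scoring peak", {
  pk <- data.frame(chrom = "chr1", start = c(1000L, 1200L),
                   end = c(1500L, 1700L), summit = c(1250L, 1450L),
                   score = c(10, 5), cluster = "C1")
  res <- union_peaks(list(pk))
  expect_equal(nrow(res), 1)
  expect_equal(res$score, 10)
})

test_that("union_peaks: disjoint union, dedup, score-greedy chains", {
  a <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                  summit = 1250L, score = 3, cluster = "C1")
  b <- data.frame(chrom = "chr1", start = 5000L, end = 5500L,
                  summit = 5250L, score = 4, cluster = "C2")
  u <- union_peaks(list(a, b))
  expect_equal(u$start, c(1000L, 5000L))
  # identical peak in two clusters -> one copy, max score kept
  a2 <- a; a2$score <- 9; a2$cluster <- "C2"
  u2 <- union_peaks(list(a, a2))
  expect_equal(nrow(u2), 1)
  expect_equal(u2$score, 9)
  # chain 10-5-8: keep 10, drop the 5 overlapping it, keep the 8
  chain <- data.frame(chrom = "chr1",
                      start = c(1000L, 1300L, 1600L),
                      end = c(1500L, 1800L, 2100L),
                      summit = c(1250L, 1550L, 1850L),
                      score = c(10, 5, 8), cluster = "C1")
  u3 <- union_peaks(list(chain))
  expect_equal(sort(u3$score), c(8, 10))
  # brute-force greedy oracle on random peak sets
  set.seed(5)
  for (rep in 1:5) {
    st <- sample(seq(0, 20000, by = 100), 30)
    rnd <- data.frame(chrom = "chr1", start = st, end = st + 500L,
                      summit = st + 250L, score = runif(30), cluster = "C1")
    got <- union_peaks(list(rnd))
    # oracle: repeatedly take the best-scoring survivor, delete its overlaps
    left <- rnd[order(-rnd$score), ]
    keep_start <- integer(0)
    while (nrow(left) > 0) {
      top <- left[1, ]
      keep_start <- c(keep_start, top$start)
      left <- left[!(left$start < top$end & left$end > top$start), ]
    }
    expect_setequal(got$start, keep_start)
    # non-overlapping and sorted
    expect_true(all(diff(got$start) >= 500))
    expect_false(is.unsorted(got$start))
  }
  expect_error(union_peaks(list(a, transform(b, end = end + 100))),
               "width mismatch")
})

test_that("build_peak_matrix uses half-open intervals and exact totals", {
  gn <- make_genome(1, 10000, 0, seed = 1)
  peaks <- data.frame(chrom = "chr1", start = 1000L, end = 1500L)
  # insertion exactly at start counts; at end does not
  fr <- data.frame(chrom = "chr1",
                   start = c(1000L, 1500L), end = c(1101L, 1601L),
                   barcode = c("a", "b"), count = 1L)
  m <- build_peak_matrix(fr, peaks, gn)
  expect_equal(as.numeric(m[1, "a"]), 2)  # insertions 1000 and 1100
  expect_equal(as.numeric(m[1, "b"]), 0)  # insertions 1500 and 1600
  # totals equal direct interval intersection
  set.seed(3)
  pos <- sample(0:9900, 500, replace = TRUE)
  fr2 <- data.frame(chrom = "chr1", start = pos, end = pos + 50,
                    barcode = sample(c("a", "b"), 500, TRUE), count = 1L)
  pk2 <- data.frame(chrom = "chr1", start = c(2000L, 7000L),
                    end = c(2500L, 7500L))
  m2 <- build_peak_matrix(fr2, pk2, gn)
  ins <- c(fr2$start, fr2$end - 1L)
  bc <- rep(fr2$barcode, 2)
  for (b in c("a", "b")) {
    direct <- sum((ins >= 2000 & ins < 2500 | ins >= 7000 & ins < 7500) &
                    bc == b)
    expect_equal(sum(m2[, b]), direct)
  }
})

test_that("two-round clustering collapses a single cell type to one cluster", {
  gn <- make_genome(1, 3e5, 10, seed = 6)
  pp <- make_peak_plan(gn, "solo", n_shared = 25, n_specific = 0, seed = 1)
  plan <- data.frame(cell_type = "solo", n_cells = 80, depth = 1200)
  sim <- simulate_fragments(gn, plan, pp, seed = 13)
  fr <- read_fragments(sim$path)
  res <- iterative_cluster(fr, gn, min_size = 50,
                           resolutions = c(0.8, 0.4, 0.1), seed = 2)
  expect_equal(nlevels(res$clusters$cluster), 1)
  # rerun determinism
  res2 <- iterative_cluster(fr, gn, min_size = 50,
                            resolutions = c(0.8, 0.4, 0.1), seed = 2)
  expect_identical(res$clusters$cluster, res2$clusters$cluster)
  # union peak properties: constant width, non-overlapping, sorted
  w <- res$peaks$end - res$peaks$start
  expect_true(all(w == w[1]))
  by_chr <- split(res$peaks, res$peaks$chrom)
  for (p in by_chr) {
    expect_false(is.unsorted(p$start))
    if (nrow(p) > 1) expect_true(all(diff(p$start) >= w[1]))
  }
})
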