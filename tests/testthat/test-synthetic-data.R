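test_that("make_genome places genes within bounds, deterministically", {
  gn <- make_genome(n_chrom = 2, chrom_len = 5e6, n_genes = 200, seed = 7)
  expect_equal(nrow(gn$genes), 200)
  expect_true(all(gn$genes$start >= 0))
  expect_true(all(gn$genes$end <= 5e6))
  expect_true(all(c("+", "-") %in% gn$genes$strand))
  # strand resolution: TSS < TTS on '+', TSS > TTS on '-'
  plus <- gn$genes$strand == "+"
  expect_true(all(gn$genes$tss[plus] < gn$genes$tts[plus]))
  expect_true(all(gn$genes$tss[!plus] > gn$genes$tts[!plus]))
  expect_false(anyDuplicated(gn$genes$gene) > 0)
  gn2 <- make_genome(n_chrom = 2, chrom_len = 5e6, n_genes = 200, seed = 7)
  expect_identical(gn, gn2)
})

test_that("make_genome handles the empty case and impossible packing", {
  gn <- make_genome(1, 1e6, 0, seed = 1)
  expect_equal(nrow(gn$genes), 0)
  # 60 TSS windows of 4001 bp cannot fit in 1e5 bp (60 * 4001 > 1e5)
  expect_error(make_genome(1, 1e5, 60, seed = 3), "cannot place")
})

test_that("gene BED round-trips through write/read", {
  gn <- make_genome(1, 1e6, 30, seed = 5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(gn, path)
  gn2 <- read_genes_bed(path, chrom_lengths = c(chr1 = 1e6))
  expect_equal(gn2$genes[, c("gene", "chrom", "strand", "tss", "tts")],
               gn$genes[, c("gene", "chrom", "strand", "tss", "tts")])
})

test_that("simulate_fragments output is sorted, valid and deterministic", {
  fx <- small_frag_fixture()
  fr <- fx$frags
  expect_true(all(fr$start < fr$end))
  expect_true(all(fr$count >= 1))
  expect_false(is.unsorted(fr$start[fr$chrom == "chr1"]))
  # every emitted barcode is covered by ground truth
  expect_true(all(fr$barcode %in% fx$sim$truth$barcode))
  # byte-identical rerun
  p2 <- simulate_fragments(fx$genome,
                           data.frame(cell_type = c("alpha", "beta"),
                                      n_cells = 60, depth = 1500),
                           fx$peak_plan, quality_mix = 0, seed = 11)$path
  expect_identical(unname(tools::md5sum(fx$sim$path)),
                   unname(tools::md5sum(p2)))
})

test_that("simulate_fragments rejects peaks outside chromosomes and handles n_cells = 0", {
  gn <- make_genome(1, 2e5, 5, seed = 1)
  bad_plan <- list(tt = data.frame(chrom = "chr1", start = 199900,
                                   end = 200500))
  expect_error(simulate_fragments(gn, data.frame(cell_type = "tt",
                                                 n_cells = 2, depth = 100),
                                  bad_plan, seed = 1),
               "outside chromosome")
  pp <- make_peak_plan(gn, "tt", n_shared = 5, n_specific = 2, seed = 1)
  empty <- simulate_fragments(gn, data.frame(cell_type = "tt", n_cells = 0,
                                             depth = 100), pp, seed = 1)
  expect_equal(nrow(read_fragments(empty$path)), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("fragment-length mixture yields a mono-nucleosomal mode", {
  fx <- small_frag_fixture()
  h <- fragment_size_histogram(fx$frags)
  len <- as.integer(names(h$histogram))
  # local maximum within 170-230 bp (mono-nucleosomal mode of the mixture)
  dens <- sapply(seq(50, 350, by = 20), function(lo)
    sum(h$histogram[len >= lo & len < lo + 20]))
  peak_bin <- seq(50, 350, by = 20)[which.max(dens[seq(6, 10)]) + 5]
  expect_true(peak_bin >= 170 && peak_bin <= 230)
  expect_gt(h$periodicity, 0.2)
})

test_that("simulate_expression: null loading, module correlation, determinism", {
  truth <- data.frame(barcode = sprintf("c%04d", 1:2000),
                      cell_type = rep(c("dys", "eff"), each = 1000))
  null <- simulate_expression(truth, n_genes = 120, module_size = 20,
                              gradient_loading = 0, markers_per_type = 5,
                              seed = 2)
  pt <- null$truth$pseudotime
  cors <- apply(as.matrix(null$counts[null$module_genes[1:10], ]), 1,
                function(x) cor(x, pt))
  expect_true(all(abs(cors) < 0.1))

  strong <- simulate_expression(truth, n_genes = 200, module_size = 75,
                                gradient_loading = 5, seed = 3)
  mm <- log1p(as.matrix(strong$counts[strong$module_genes, ]))
  cm <- cor(t(mm))
  expect_gt(mean(cm[upper.tri(cm)]), 0.3)
  # module-gene means increase with latent pseudotime
  ord <- order(strong$truth$pseudotime)
  lo <- mean(mm[, ord[1:500]]); hi <- mean(mm[, ord[1501:2000]])
  expect_gt(hi, lo)

  # identical MTX bytes on rerun
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_expression(truth[1:100, ], n_genes = 50, module_size = 10,
                            markers_per_type = 2, seed = 5)
  s2 <- simulate_expression(truth[1:100, ], n_genes = 50, module_size = 10,
                            markers_per_type = 2, seed = 5)
  write_mtx(s1$counts, d1); write_mtx(s2$counts, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "matrix.mtx"))),
                   unname(tools::md5sum(file.path(d2, "matrix.mtx"))))
  expect_equal(as.matrix(read_mtx(d1)), as.matrix(s1$counts),
               ignore_attr = TRUE)
  expect_error(simulate_expression(truth, n_genes = 30, module_size = 75),
               "exceed")
})

test_that("simulate_tcr respects clone-size laws and sharing", {
  meta <- data.frame(barcode = sprintf("t%03d", 1:120),
                     cluster = rep(c("C1", "C2"), each = 60),
                     tissue = rep(c("blood", "tumor"), 60))
  # all singletons -> expa 0; monoclonal -> expa 1
  sim <- simulate_tcr(meta, expansion = c(C1 = 1, C2 = 1),
                      monoclonal = "C2", seed = 4)
  ct <- build_clonotypes(sim$contigs, meta)
  ei <- expansion_index(ct)
  expect_equal(ei$expa[ei$cluster == "C1"], 0)
  expect_equal(ei$expa[ei$cluster == "C2"], 1)
  # each cell has exactly one alpha and one beta
  expect_equal(nrow(sim$contigs), 240)
  # sharing plan puts a clone in both clusters
  sim2 <- simulate_tcr(meta, expansion = c(C1 = 0.2, C2 = 0.2),
                       n_shared = 2, seed = 9)
  ct2 <- build_clonotypes(sim2$contigs, meta)
  sh <- shared_clonotypes(ct2, "C1", "C2")
  truth_shared <- names(which(rowSums(table(sim2$truth$clone_id,
                                            sim2$truth$cluster) > 0) == 2))
  # set intersection on truth equals pipeline output
  key_of <- unique(ct2[, c("barcode", "clonotype")])
  truth_keys <- unique(ct2$clonotype[match(
    sim2$truth$barcode[sim2$truth$clone_id %in% truth_shared],
    ct2$barcode)])
  expect_setequal(sh$clonotype, truth_keys[!is.na(truth_keys)])
  expect_gt(nrow(sh), 0)
})

test_that("simulate_cohort validates arguments and censoring behaviour", {
  expect_error(simulate_cohort(100, hazard_ratio = 0), "hazard_ratio")
  ch <- simulate_cohort(100, censoring_rate = 0, seed = 2)
  expect_true(all(ch$os_event == 1))
  ch2 <- simulate_cohort(400, censoring_rate = 0.4, seed = 3)
  expect_gt(mean(ch2$os_event == 0), 0.2)
  expect_true(all(ch2$os_time > 0))
  expect_identical(simulate_cohort(50, seed = 7), simulate_cohort(50, seed = 7))
})
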