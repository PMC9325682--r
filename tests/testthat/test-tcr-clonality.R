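test_that("clonotype construction keeps exactly-paired productive chains", {
  contigs <- data.frame(
    barcode = c("b1", "b1", "b2", "b2", "b2", "b3", "b4", "b4"),
    chain = c("TRA", "TRB", "TRA", "TRB", "TRB", "TRA", "TRA", "TRB"),
    v_gene = "V1", j_gene = "J1",
    cdr3_nt = c("x", "y", "x", "y", "z", "x", "x", "y"),
    productive = "True", stringsAsFactors = FALSE)
  ct <- build_clonotypes(contigs)
  # b1 kept; b2 has two productive betas; b3 lacks a beta; b4 kept
  expect_setequal(ct$barcode, c("b1", "b4"))
  # identical six-field keys collapse to one clonotype
  expect_equal(ct$clonotype[ct$barcode == "b1"],
               ct$clonotype[ct$barcode == "b4"])
  bad <- contigs; bad$chain[1] <- "IGH"
  expect_error(build_clonotypes(bad), "unknown chain")
})

test_that("expansion index entropy identities", {
  # all singletons -> 0
  ct <- clonotype_fixture(paste0("k", 1:6), "A")
  expect_equal(expansion_index(ct)$expa, 0)
  # monoclonal -> 1
  ct2 <- clonotype_fixture(rep("k", 5), "A")
  expect_equal(expansion_index(ct2)$expa, 1)
  # clone sizes (3, 1): H = 0.5623 nats, expa = 1 - H/log 2
  ct3 <- clonotype_fixture(c("x", "x", "x", "y"), "A")
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(expansion_index(ct3)$expa, 1 - H / log(2))
  expect_equal(round(expansion_index(ct3)$expa, 4), 0.1887)
  # invariant to uniform replication of every cell
  ct3x <- clonotype_fixture(rep(c("x", "x", "x", "y"), 3), "A")
  expect_equal(expansion_index(ct3x)$expa, expansion_index(ct3)$expa)
})

test_that("migration index entropy identities", {
  # clonotypes confined to one tissue -> 0
  ct <- clonotype_fixture(c("x", "x", "y"), "A",
                          tissue = c("blood", "blood", "tumor"))
  expect_equal(migration_index(ct)$migr, 0)
  # a 50/50 two-tissue clone alone in the cluster -> log 2
  ct2 <- clonotype_fixture(c("x", "x"), "A", tissue = c("blood", "tumor"))
  expect_equal(migration_index(ct2)$migr, log(2))
  # bounded by log(3) with three tissues
  ct3 <- clonotype_fixture(rep("x", 3), "A",
                           tissue = c("blood", "normal", "tumor"))
  expect_equal(migration_index(ct3)$migr, log(3))
  # adding cells of the same single-tissue clonotype leaves migr unchanged
  ct4 <- clonotype_fixture(c("x", "x", "x", "y"), c("A", "A", "A", "A"),
                           tissue = c("blood", "blood", "blood", "tumor"))
  expect_equal(migration_index(ct4)$migr, 0)
})

test_that("transition index identities and coarsening inequality", {
  # cluster-confined clones -> 0 everywhere
  ct <- clonotype_fixture(c("x", "x", "y", "y"), c("A", "A", "B", "B"))
  expect_true(all(transition_index(ct)$tran == 0))
  # an equally split clone contributes log 2 to both clusters
  ct2 <- clonotype_fixture(c("x", "x"), c("A", "B"))
  tr <- transition_index(ct2)
  expect_equal(tr$tran, c(log(2), log(2)))
  # pairwise variant restricts to the two clusters
  ct3 <- clonotype_fixture(c("x", "x", "x"), c("A", "B", "C"))
  trp <- transition_index(ct3, pair = c("A", "B"))
  expect_equal(sort(trp$cluster), c("A", "B"))
  expect_equal(trp$tran, rep(log(2), 2))
  # merging two clusters never increases the dataset-mean tran
  set.seed(9)
  for (rep in 1:10) {
    n <- 60
    ctr <- clonotype_fixture(sample(paste0("k", 1:12), n, TRUE),
                             sample(c("A", "B", "C"), n, TRUE))
    t_fine <- transition_index(ctr)
    sizes <- table(ctr$cluster)[t_fine$cluster]
    mean_fine <- sum(t_fine$tran * as.numeric(sizes)) / sum(sizes)
    ctc <- ctr; ctc$cluster[ctc$cluster == "B"] <- "A"
    t_coarse <- transition_index(ctc)
    sizes_c <- table(ctc$cluster)[t_coarse$cluster]
    mean_coarse <- sum(t_coarse$tran * as.numeric(sizes_c)) / sum(sizes_c)
    expect_lte(mean_coarse, mean_fine + 1e-12)
  }
})

test_that("frequency ranges bin cells by dataset-wide clone size", {
  ct <- clonotype_fixture(c(rep("big", 5), "s1", "s2"),
                          c(rep("A", 5), "A", "B"))
  fr <- frequency_ranges(ct, ranges = list(c(1, 1), c(2, 5)))
  get <- function(cl, rg) fr$n_cells[fr$cluster == cl & fr$range == rg]
  expect_equal(get("A", "1-1"), 1)   # s1
  expect_equal(get("A", "2-5"), 5)   # the expanded clone
  expect_equal(get("B", "1-1"), 1)
  # all singletons land in the first range
  ct2 <- clonotype_fixture(paste0("k", 1:4), "A")
  fr2 <- frequency_ranges(ct2, ranges = list(c(1, 1), c(2, Inf)))
  expect_equal(fr2$n_cells[fr2$range == "1-1"], 4)
  expect_equal(nrow(frequency_ranges(ct2[0, ], list(c(1, 1)))), 0)
})

test_that("shared clonotypes require presence in both disjoint sets", {
  ct <- clonotype_fixture(c("x", "x", "y", "z", "z"),
                          c("A", "B", "A", "B", "C"),
                          tissue = c("blood", "tumor", "blood",
                                     "tumor", "tumor"))
  sh <- shared_clonotypes(ct, "A", c("B", "C"))
  expect_equal(sh$clonotype, "x")       # y in A only, z in B/C only
  expect_equal(sh$n_blood, 1)
  expect_equal(sh$n_tumor, 1)
  expect_error(shared_clonotypes(ct, c("A", "B"), c("B", "C")), "overlap")
})
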