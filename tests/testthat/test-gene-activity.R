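test_that("gene weight follows the decay model with hard truncation", {
  gn <- make_genome(1, 1e6, 3, seed = 1)
  g <- gn$genes[1, ]
  # weight 1 anywhere in the extended body
  mid <- (g$start + g$end) %/% 2
  expect_equal(gene_score_weight(gn, g$gene, mid), 1)
  expect_equal(gene_score_weight(gn, g$gene, g$tss), 1)
  # exp(-d / tau) outside; e^-1 at d = 5 kb
  eb_left <- if (g$strand == "+") g$tss - 5000 else g$tts
  expect_equal(gene_score_weight(gn, g$gene, eb_left - 5000), exp(-1))
  expect_equal(gene_score_weight(gn, g$gene, eb_left - 1), exp(-1 / 5000))
  # compact support: zero beyond 100 kb
  expect_equal(gene_score_weight(gn, g$gene, eb_left - 120000), 0)
  expect_equal(gene_score_weight(gn, g$gene, eb_left - 100001), 0)
  expect_gt(gene_score_weight(gn, g$gene, eb_left - 99999), 0)
  # monotone nonincreasing in distance
  d <- seq(0, 110000, by = 1000)
  w <- gene_score_weight(gn, g$gene, eb_left - d)
  expect_true(all(diff(w) <= 1e-12))
  expect_error(gene_score_weight(gn, "NOPE", 100), "unknown gene")
})

test_that("neighbor boundary filtering zeroes signal past the midpoint", {
  # hand-built two-gene annotation 40 kb apart on '+'
  gn <- make_genome(1, 1e6, 0, seed = 1)
  gn$genes <- data.frame(
    gene = c("g1", "g2"), chrom = "chr1", strand = "+",
    tss = c(100000L, 160000L), tts = c(110000L, 170000L),
    start = c(100000L, 160000L), end = c(110000L, 170000L))
  # extended bodies: [95000,110000] and [155000,170000]; midpoint 132500
  expect_gt(gene_score_weight(gn, "g1", 130000), 0)
  expect_equal(gene_score_weight(gn, "g1", 135000), 0) # past midpoint
  expect_equal(gene_score_weight(gn, "g2", 130000), 0)
  expect_gt(gene_score_weight(gn, "g2", 135000), 0)
  # inside the neighbor's extended body
  expect_equal(gene_score_weight(gn, "g1", 160000), 0)
})

test_that("gene scores equal a brute-force per-insertion oracle", {
  gn <- make_genome(1, 8e5, 8, seed = 4)
  set.seed(2)
  pos <- sample(0:799000, 400, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = pos, end = pos + 80,
                   barcode = sample(c("x", "y"), 400, TRUE), count = 1L)
  gs <- compute_gene_scores(fr, gn, log1p = FALSE)
  raw <- attr(gs, "raw")
  ins <- data.frame(pos = c(fr$start, fr$end - 1L),
                    bc = rep(fr$barcode, 2))
  for (g in gn$genes$gene) {
    w <- gene_score_weight(gn, g, ins$pos)
    for (b in c("x", "y"))
      expect_equal(raw[g, b], sum(w[ins$bc == b]), tolerance = 1e-12)
  }
  # depth-normalization invariance: doubling all fragments changes nothing
  gs2 <- compute_gene_scores(rbind(fr, fr), gn, log1p = FALSE)
  expect_equal(as.numeric(gs2), as.numeric(gs), tolerance = 1e-12)
  # a cell concentrated in one gene body puts its whole mass there
  g1 <- gn$genes[1, ]
  frc <- data.frame(chrom = "chr1",
                    start = seq(g1$start, g1$end - 100, length.out = 20),
                    end = seq(g1$start, g1$end - 100, length.out = 20) + 50,
                    barcode = "solo", count = 1L)
  gsc <- compute_gene_scores(frc, gn, log1p = FALSE)
  expect_equal(gsc[g1$gene, "solo"], 1e4)
})

test_that("differential gene scores match null and planted cases", {
  set.seed(6)
  n <- 200
  cl <- factor(rep(c("in", "out"), each = n))
  # null: identical nonnegative score distributions
  x <- matrix(rexp(2 * n * 20), 20,
              dimnames = list(paste0("g", 1:20), NULL))
  tab <- differential_gene_scores(x, cl)
  expect_gt(min(tab$p), 0.001)
  expect_true(all(abs(tab$lfc[tab$cluster == "in"]) < 1))
  expect_true(!any(tab$pass))
  # planted: scores 4 vs 1 at n = 50/side -> pass (LFC = 2, p tiny)
  cl2 <- factor(rep(c("in", "out"), each = 50))
  x2 <- rbind(planted = c(rep(4, 50), rep(1, 50)),
              flat = rep(1, 100))
  tab2 <- differential_gene_scores(x2, cl2)
  row <- tab2[tab2$gene == "planted" & tab2$cluster == "in", ]
  expect_true(row$pass)
  expect_equal(row$lfc, 2, tolerance = 1e-4)
  # BH hand example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_error(differential_gene_scores(x, factor(rep("one", 2 * n))),
               "clusters")
})

test_that("annotate_clusters labels by marker dictionaries with tie handling", {
  set.seed(8)
  genes <- c("LEF1", "SELL", "TCF7", "GZMB", "PRF1", "CD4", "CD8A")
  n <- 60
  cl <- factor(rep(c("C1", "C2"), each = n))
  x <- matrix(rnorm(length(genes) * 2 * n), length(genes),
              dimnames = list(genes, NULL))
  x[c("LEF1", "SELL", "TCF7"), cl == "C1"] <-
    x[c("LEF1", "SELL", "TCF7"), cl == "C1"] + 3
  x[c("GZMB", "PRF1"), cl == "C2"] <- x[c("GZMB", "PRF1"), cl == "C2"] + 3
  x["CD8A", cl == "C2"] <- x["CD8A", cl == "C2"] + 2
  dict <- list(naive = c("LEF1", "SELL", "TCF7"),
               effector = c("GZMB", "PRF1"))
  ann <- annotate_clusters(x, cl, dict,
                           subtype_genes = c(CD4 = "CD4", CD8 = "CD8A"))
  expect_equal(ann$label[ann$cluster == "C1"], "naive")
  expect_equal(ann$label[ann$cluster == "C2"], "effector")
  expect_equal(ann$subtype[ann$cluster == "C2"], "CD8")
  expect_true(all(ann$margin > 0))
  expect_error(annotate_clusters(x, cl, list()), "empty")
  expect_error(annotate_clusters(x, cl, list(a = "MISSING")), "absent")
  # exact tie -> ambiguous
  xt <- matrix(0, 2, 4, dimnames = list(c("m1", "m2"), NULL))
  xt[1, ] <- c(1, 0, 1, 0); xt[2, ] <- c(1, 0, 1, 0)
  annt <- annotate_clusters(xt, factor(c("A", "A", "B", "B")),
                            list(l1 = "m1", l2 = "m2"))
  expect_true(all(annt$label == "ambiguous"))
})
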