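# independent per-base oracle: 1-based position p is in gene g's promoter
# iff the strand-relative offset of p from the TSS lies in [-1500, +500),
# with the TSS base itself at offset 0
inPromoterOracle <- function(p, tssPos, strand, up = 1500, down = 500) {
  off <- if (strand == "+") p - tssPos else tssPos - p
  off >= -up && off < down
}

test_that("promoter windows follow the strand-relative -1500/+500 rule", {
  tss <- GRanges(c("chr1", "chr1"), IRanges(c(10001, 10001), width = 1),
                 strand = c("+", "-"), gene_id = c("gp", "gm"))
  pr <- makePromoters(tss)
  # + strand: BED [8500, 10500) -> 1-based [8501, 10500]
  expect_equal(start(pr)[1], 8501L)
  expect_equal(end(pr)[1], 10500L)
  # - strand: BED [9501, 11501) -> 1-based [9502, 11501]
  expect_equal(start(pr)[2], 9502L)
  expect_equal(end(pr)[2], 11501L)
  # edge clip at chromosome start
  edge <- makePromoters(GRanges("chr1", IRanges(100, width = 1),
                                strand = "+", gene_id = "ge"))
  expect_equal(start(edge), 1L)
  expect_equal(end(edge), 599L)
  expect_error(makePromoters(GRanges("chr1", IRanges(5, width = 1),
                                     gene_id = "gx")), "strand")
})

test_that("promoter membership matches the per-base offset oracle", {
  for (strand in c("+", "-")) {
    tss <- GRanges("chr1", IRanges(5000, width = 1), strand = strand,
                   gene_id = "g")
    pr <- makePromoters(tss)
    for (p in c(3498, 3499, 3500, 3501, 5000, 5498, 5499, 5500, 5501,
                4499, 4500, 6499, 6500, 6501)) {
      expect_equal(p >= start(pr) && p <= end(pr),
                   inPromoterOracle(p, 5000, strand),
                   info = paste(strand, p))
    }
  }
})

test_that("feature annotation is multi-label with half-open BED semantics", {
  ann <- AnnotationSet(
    elements = list(
      promoter = GRanges("chr1", IRanges(1, 150)),    # BED [0,150)
      "repeat" = GRanges("chr1", IRanges(120, 300))),
    tss = GRanges("chr1", IRanges(1, width = 1), strand = "+",
                  gene_id = "g1"))
  # DMR over BED [100,160) -> 1-based [101,160]: overlaps both classes
  both <- annotateFeatures(GRanges("chr1", IRanges(101, 160)), ann)
  expect_true(both$labels[1, "promoter"])
  expect_true(both$labels[1, "repeat"])
  expect_false(both$labels[1, "intergenic"])
  # BED [150,160) does not touch promoter BED [0,150)
  off <- annotateFeatures(GRanges("chr1", IRanges(151, 160)), ann)
  expect_false(off$labels[1, "promoter"])
  # nothing overlapped -> intergenic
  nowhere <- annotateFeatures(GRanges("chr1", IRanges(5000, 5100)), ann)
  expect_true(nowhere$labels[1, "intergenic"])
  # exclusive mode picks the highest-priority class only
  excl <- annotateFeatures(GRanges("chr1", IRanges(101, 160)), ann,
                           mode = "exclusive")
  expect_true(excl$labels[1, "promoter"])
  expect_false(excl$labels[1, "repeat"])
})

test_that("annotation equals a brute-force all-pairs overlap scan", {
  set.seed(31)
  feats <- GRanges("chr1", IRanges(sample(1:5000, 200), width = 80))
  ann <- AnnotationSet(
    elements = list(
      promoter = GRanges("chr1", IRanges(sample(1:5000, 30), width = 120)),
      "repeat" = GRanges("chr1", IRanges(sample(1:5000, 50), width = 60))),
    tss = GRanges())
  got <- annotateFeatures(feats, ann)$labels
  for (cl in c("promoter", "repeat")) {
    iv <- elementClasses(ann)[[cl]]
    brute <- vapply(seq_along(feats), function(i)
      any(start(feats)[i] <= end(iv) & end(feats)[i] >= start(iv)), TRUE)
    expect_equal(unname(got[, cl]), brute, info = cl)
  }
})

test_that("per-class counts split planted directions correctly", {
  ann <- AnnotationSet(
    elements = list(promoter = GRanges("chr1", IRanges(1, 1000)),
                    "repeat" = GRanges("chr1", IRanges(2000, 4000))),
    tss = GRanges())
  dmrs <- GRanges("chr1",
                  IRanges(c(10, 200, 500, 900, 2100, 2300, 2500, 2700,
                            2900, 3100),
                          width = 50),
                  direction = c(rep("hypo", 4), rep("hyper", 6)))
  counts <- annotateFeatures(dmrs, ann)$counts
  expect_equal(counts$hypo[counts$element_class == "promoter"], 4)
  expect_equal(counts$hyper[counts$element_class == "repeat"], 6)
  expect_equal(counts$hyper[counts$element_class == "promoter"], 0)
})

test_that("promoter methylation means and bins follow the stated edges", {
  prom <- GRanges("chr1", IRanges(c(1, 1000), c(500, 1500)),
                  gene_id = c("gA", "gB"))
  m <- toyMethylome("S", "control", "chr1", c(100, 200, 300, 2000),
                    c(8, 6, 4, 5), c(2, 4, 6, 5))
  pm <- promoterMethylation(m, prom)
  expect_equal(pm$gene_id, "gA")                 # gB has no covered CpGs
  expect_equal(pm$mean_meth_pct, 60)
  expect_equal(pm$n_cpgs, 3L)
  expect_equal(pm$bin, "51-75")
  # a mean of exactly 25 belongs to the lowest bin
  m25 <- toyMethylome("S", "control", "chr1", 100, 25, 75)
  expect_equal(promoterMethylation(m25, prom)$bin, "0-25")
})

test_that("bin counts conserve totals and match direct tabulation", {
  expect_equal(unname(methBinCounts(c(10, 30, 60, 90))), rep(1L, 4))
  expect_equal(sum(methBinCounts(numeric(0))), 0L)
  set.seed(5)
  v <- 100 * c(rbeta(600, 8, 1), rbeta(400, 1, 8))
  got <- methBinCounts(v)
  expect_equal(sum(got), 1000L)
  expect_equal(unname(got["0-25"]), sum(v <= 25))
  expect_equal(unname(got["76-100"]), sum(v > 75))
  expect_equal(unname(got["26-50"]), sum(v > 25 & v <= 50))
})

test_that("pairwise Pearson is symmetric, bounded and exact on identity", {
  set.seed(9)
  m <- cbind(a = rnorm(200, 50, 20), b = rnorm(200, 50, 20))
  m <- cbind(m, c = -m[, "a"] + 100)
  m[sample(200, 10), "b"] <- NA
  r <- pairwisePearson(m)
  expect_equal(r$r["a", "a"], 1)
  expect_equal(r$r["a", "c"], -1)
  expect_equal(r$r, t(r$r))
  expect_true(all(abs(r$r) <= 1 + 1e-12))
  expect_equal(r$n["a", "b"], 190L)
})

test_that("correlation between noisy replicate methylomes tracks truth", {
  set.seed(13)
  n <- 5000
  latent <- 100 * rbeta(n, 2, 2)
  s1 <- latent + rnorm(n, 0, 5)
  s2 <- latent + rnorm(n, 0, 5)
  expected <- var(latent) / (var(latent) + 25)   # attenuation by noise
  got <- pairwisePearson(cbind(s1, s2))$r[1, 2]
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("expression differs across methylation bins as planted", {
  set.seed(17)
  n <- 200
  pm <- data.frame(
    gene_id = paste0("g", 1:(4 * n)),
    mean_meth_pct = rep(c(10, 40, 60, 90), each = n),
    n_cpgs = 5L,
    bin = rep(c("0-25", "26-50", "51-75", "76-100"), each = n))
  fpkm <- setNames(rlnorm(4 * n, rep(log(c(50, 20, 8, 3)), each = n), 0.5),
                   pm$gene_id)
  r <- expressionByBin(pm, fpkm)
  low_high <- r$tests[r$tests$bin1 == "0-25" & r$tests$bin2 == "76-100", ]
  expect_lt(low_high$p_value, 0.01)
  expect_true(r$monotoneDecreasing)
  # equal groups: t = 0, p = 1
  pm2 <- pm[pm$bin %in% c("0-25", "26-50"), ]
  fpkm2 <- fpkm[pm2$gene_id]
  fpkm2[pm2$bin == "26-50"] <- fpkm2[pm2$bin == "0-25"]
  r2 <- expressionByBin(pm2, fpkm2)
  t12 <- r2$tests[r2$tests$bin1 == "0-25" & r2$tests$bin2 == "26-50", ]
  expect_equal(t12$t, 0)
  expect_equal(t12$p_value, 1)
  # a bin with < 2 genes yields NA comparisons, not an error
  empty34 <- r2$tests[r2$tests$bin1 == "51-75", ]
  expect_true(all(is.na(empty34$p_value)))
})
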