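test_that("exact MWU equals full rank-assignment enumeration", {
  # 3-vs-3 complete separation: 1 of C(6,3)=20 assignments
  r1 <- mwuTest(c(10, 12, 15), c(80, 85, 90), "less")
  expect_true(r1$exact)
  expect_equal(r1$p.value, 0.05)
  expect_equal(r1$p.value, enumMwuP(c(10, 12, 15), c(80, 85, 90), "less"))
  # 4-vs-4 complete separation: 1/70
  r2 <- mwuTest(1:4, 11:14, "less")
  expect_equal(r2$p.value, 1 / 70)
  expect_equal(r2$p.value, enumMwuP(1:4, 11:14, "less"))
  # random cases with and without ties, all alternatives
  set.seed(42)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq(0, 100, by = 5), nx, replace = TRUE)
    y <- sample(seq(0, 100, by = 5), ny, replace = TRUE)
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(mwuTest(x, y, alt)$p.value, enumMwuP(x, y, alt),
                   info = paste(alt, i))
    }
  }
})

test_that("exact MWU agrees with wilcox.test when there are no ties", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(5); y <- runif(6)
    expect_equal(mwuTest(x, y, "less")$p.value,
                 wilcox.test(x, y, alternative = "less",
                             exact = TRUE)$p.value)
    expect_equal(mwuTest(x, y, "two.sided")$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large-sample MWU path matches the corrected normal approximation", {
  set.seed(8)
  x <- round(runif(15, 0, 100)); y <- round(runif(12, 0, 100))
  r <- mwuTest(x, y, "less")
  expect_false(r$exact)
  w <- wilcox.test(x, y, alternative = "less", exact = FALSE,
                   correct = TRUE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p.value, w$p.value, tolerance = 1e-10)
})

test_that("identical tumor and control series are not called", {
  r <- mwuTest(c(40, 50, 60, 70), c(40, 50, 60, 70), "less")
  expect_gte(r$p.value, 0.5)
})

test_that("segmentation emits maximal same-direction runs within the gap", {
  cand <- segmentDmrs(dmcGr(c(10, 60, 140), "hypo"))
  expect_equal(length(cand), 1L)
  expect_equal(start(cand), 10L)
  expect_equal(end(cand), 140L)
  expect_equal(mcols(cand)$n_cpgs, 3L)
  # direction flip splits the run below the minimum
  expect_equal(length(segmentDmrs(
    dmcGr(c(10, 60, 100), c("hypo", "hypo", "hyper")))), 0L)
  # 101 bp gap exceeds the 100 bp cutoff
  expect_equal(length(segmentDmrs(dmcGr(c(10, 60, 161), "hypo"))), 0L)
  # 100 bp gap is allowed (boundary inclusive)
  expect_equal(length(segmentDmrs(dmcGr(c(10, 60, 160), "hypo"))), 1L)
  expect_equal(length(segmentDmrs(dmcGr(integer(0), character(0)))), 0L)
})

test_that("segmentation equals brute-force maximal-run search", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    pos <- sort(sample(1:2000, n))
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    dir <- sample(c("hypo", "hyper"), n, replace = TRUE)
    dmcs <- GRanges(chrom, IRanges(pos, width = 1), direction = dir,
                    tumor_pct = 0, control_pct = 0, delta = 0)
    got <- segmentDmrs(dmcs)
    want <- bruteForceSegments(dmcs)
    if (is.null(want)) {
      expect_equal(length(got), 0L, info = i)
    } else {
      gotDf <- data.frame(chrom = as.character(seqnames(got)),
                          start = start(got), end = end(got),
                          direction = mcols(got)$direction,
                          n_cpgs = mcols(got)$n_cpgs)
      o1 <- order(gotDf$chrom, gotDf$start)
      o2 <- order(want$chrom, want$start)
      expect_equal(gotDf[o1, ], want[o2, ], ignore_attr = TRUE, info = i)
    }
  }
})

test_that("region test accepts at exactly p = 0.05 (inclusive threshold)", {
  dmcs <- dmcGr(c(10, 50, 90), "hypo", tumor_pct = c(10, 12, 15),
                control_pct = c(80, 85, 90))
  mcols(dmcs)$tumor_pct <- c(10, 12, 15)
  mcols(dmcs)$control_pct <- c(80, 85, 90)
  mcols(dmcs)$delta <- mcols(dmcs)$tumor_pct - mcols(dmcs)$control_pct
  cand <- segmentDmrs(dmcs)
  acc <- testDmr(cand, dmcs, alpha = 0.05)
  expect_false(is.null(acc))
  expect_equal(mcols(acc)$p_value, 0.05)
  expect_equal(mcols(acc)$mean_delta, mean(c(10, 12, 15) - c(80, 85, 90)))
  # two-sided doubles the exact tail and the 3-CpG region becomes uncallable
  expect_null(testDmr(cand, dmcs, alpha = 0.05, sided = "two"))
})

test_that("full DMR calling recovers a clean planted block end to end", {
  pos <- seq(100, 1000, by = 50)
  ctrPct <- rep(80, length(pos))
  ctr <- toyControls("chr1", pos, list(ctrPct, ctrPct, ctrPct))
  tumorPct <- ctrPct
  tumorPct[5:9] <- 40                       # 5 CpGs shifted by -40
  tum <- Methylome("T1", "tumor",
                   cpgGr("chr1", pos, round(tumorPct / 5), 20 - round(tumorPct / 5)))
  prof <- buildControlProfile(ctr, minCoverage = 5)
  dmrs <- callSampleDmrs(tum, prof)
  expect_equal(length(dmrs), 1L)
  expect_equal(mcols(dmrs)$direction, "hypo")
  expect_equal(start(dmrs), pos[5])
  expect_equal(end(dmrs), pos[9])
  expect_equal(mcols(dmrs)$n_cpgs, 5L)
  expect_equal(mcols(dmrs)$sample_id, "T1")
})

test_that("widening the gap never shrinks recovered regions", {
  set.seed(23)
  pos <- sort(sample(1:3000, 60))
  dir <- sample(c("hypo", "hyper"), 60, replace = TRUE, prob = c(.7, .3))
  dmcs <- GRanges("chr1", IRanges(pos, width = 1), direction = dir)
  a <- segmentDmrs(dmcs, maxGap = 100)
  b <- segmentDmrs(dmcs, maxGap = 200)
  # every region at gap 100 is contained in a region at gap 200 with at
  # least as many member CpGs
  if (length(a)) {
    hits <- findOverlaps(a, b)
    expect_equal(length(unique(queryHits(hits))), length(a))
    expect_true(all(mcols(b)$n_cpgs[subjectHits(hits)] >=
                      mcols(a)$n_cpgs[queryHits(hits)]))
  }
})
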