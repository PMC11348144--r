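test_that("the generator is deterministic: same config, same bytes", {
  cfg <- smallConfig(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateStudy(cfg, outDir = d1)
  simulateStudy(cfg, outDir = d2)
  f1 <- sort(list.files(d1))
  expect_gt(length(f1), 5)
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("annotation has the configured shape", {
  cfg <- simConfig(seed = 2, nChroms = 2, chromLength = 5e5, nGenes = 100,
                   plantedDmrs = NULL)
  ann <- simulateAnnotation(cfg)
  tss <- annotationTss(ann$annotation)
  expect_equal(length(tss), 100L)
  expect_equal(nrow(ann$genes), 100L)
  expect_true(all(as.character(strand(tss)) %in% c("+", "-")))
  proms <- elementClasses(ann$annotation)[["promoter"]]
  expect_equal(length(proms), 100L)
  expect_true(all(width(proms) == 2000L))      # none clipped at this layout
  # repeat coverage within 2 percentage points of the configured fraction
  reps <- elementClasses(ann$annotation)[["repeat"]]
  covered <- sum(width(GenomicRanges::reduce(reps, ignore.strand = TRUE)))
  frac <- covered / (2 * 5e5)
  expect_lt(abs(frac - cfg$repeatFraction), 0.02)
})

test_that("planted blocks shift tumor methylation by the planted delta", {
  planted <- data.frame(element_class = "repeat", direction = "hypo",
                        delta = -30, n_cpgs = 10L, presence = "all",
                        coupled = FALSE)[rep(1, 5), ]
  cfg <- simConfig(seed = 5, nChroms = 1, chromLength = 2e5, nGenes = 10,
                   plantedDmrs = planted, coverageMean = 30)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylomes(cfg, ann)
  expect_equal(nrow(sim$truth), 5L)
  tum <- methSites(sim$tumors[[1]])
  ctrlMean <- rowMeans(vapply(sim$controls, function(m) {
    s <- methSites(m); 100 * mcols(s)$meth / (mcols(s)$meth + mcols(s)$unmeth)
  }, numeric(length(tum))))
  tumPct <- 100 * mcols(tum)$meth / (mcols(tum)$meth + mcols(tum)$unmeth)
  perBlock <- vapply(seq_len(nrow(sim$truth)), function(b) {
    inb <- as.character(seqnames(tum)) == sim$truth$chrom[b] &
      start(tum) >= sim$truth$start[b] & start(tum) <= sim$truth$end[b]
    expect_gte(sum(inb), 10L)
    mean(tumPct[inb] - ctrlMean[inb])
  }, 0)
  # per-block deviation is jitter + binomial noise over ~10 CpGs (sd ~3
  # points); bound each block at 3 sigma and the 5-block mean tightly
  expect_true(all(abs(perBlock - (-30)) < 10))
  expect_lt(abs(mean(perBlock) - (-30)), 3)
})

test_that("presence patterns control which tumors carry a block", {
  planted <- data.frame(element_class = "repeat", direction = "hyper",
                        delta = 40, n_cpgs = 8L, presence = "1010100",
                        coupled = FALSE)
  cfg <- simConfig(seed = 6, nChroms = 1, chromLength = 2e5, nGenes = 10,
                   nTumors = 7, plantedDmrs = planted)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylomes(cfg, ann)
  expect_equal(sim$truth$tumors, "T1,T3,T5")
  carriers <- strsplit(sim$truth$tumors, ",")[[1]]
  b <- sim$truth[1, ]
  deltas <- vapply(names(sim$tumors), function(tid) {
    s <- methSites(sim$tumors[[tid]])
    inb <- start(s) >= b$start & start(s) <= b$end
    cm <- rowMeans(vapply(sim$controls, function(m) {
      ss <- methSites(m)
      (100 * mcols(ss)$meth / (mcols(ss)$meth + mcols(ss)$unmeth))[inb]
    }, numeric(sum(inb))))
    mean(100 * mcols(s)$meth[inb] /
           (mcols(s)$meth[inb] + mcols(s)$unmeth[inb]) - cm)
  }, 0)
  expect_true(all(deltas[carriers] > 25))
  expect_true(all(abs(deltas[setdiff(names(deltas), carriers)]) < 10))
})

test_that("background methylation is bimodal with a dominant high mode", {
  cfg <- smallConfig(seed = 8)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylomes(cfg, ann)
  s <- methSites(sim$controls[[1]])
  pct <- 100 * mcols(s)$meth / (mcols(s)$meth + mcols(s)$unmeth)
  bins <- methBinCounts(pct)
  expect_gt(bins["76-100"] / sum(bins), 0.5)   # most CpGs highly methylated
  expect_gt(bins["0-25"] / sum(bins), 0.1)     # clear low mode
  expect_true(all(mcols(s)$meth + mcols(s)$unmeth >= 5))  # coverage floor
})

test_that("a held-out control is mostly unchanged and replicates correlate", {
  cfg <- smallConfig(seed = 9)
  ann <- simulateAnnotation(cfg)
  sim <- simulateMethylomes(cfg, ann)
  heldOut <- sim$controls[[1]]
  prof <- buildControlProfile(sim$controls[-1])
  asTumor <- Methylome(sampleId(heldOut), "tumor", methSites(heldOut))
  cl <- classifyCpgs(asTumor, prof)
  # at the default jitter (sigma 0.3) plus binomial noise at 30x, the
  # model itself puts ~15% of CpGs past the 10-point threshold; a held-out
  # control must still be dominated by unchanged calls and perfectly
  # balanced in direction
  expect_gt(cl$counts["unchanged"] / sum(cl$counts), 0.8)
  expect_lt(abs(cl$counts["hypo"] - cl$counts["hyper"]) / sum(cl$counts),
            0.05)
  # control-control correlation sits in the replicate range
  pcts <- vapply(sim$controls, function(m) {
    s <- methSites(m)
    100 * mcols(s)$meth / (mcols(s)$meth + mcols(s)$unmeth)
  }, numeric(length(methSites(heldOut))))
  # replicates correlate strongly but imperfectly: the bimodal latent
  # spread dominates the per-sample noise in genome-wide CpG correlations
  r <- pairwisePearson(pcts)$r
  offDiag <- r[upper.tri(r)]
  expect_true(all(offDiag > 0.9 & offDiag < 0.999))
})

test_that("uncoupled simulations plant fold-change truth only where told", {
  cfg <- smallConfig(seed = 10, nPlantedUp = 0L, nPlantedDown = 0L)
  ann <- simulateAnnotation(cfg)
  expr <- simulateExpression(cfg, ann, methTruth = NULL)
  expect_true(all(expr$fcTruth == 1))
  expect_null(expr$deTruth)
})

test_that("estimated fold change tracks planted truth, exactly when noise-free", {
  planted <- data.frame(element_class = "promoter", direction = "hypo",
                        delta = -40, n_cpgs = 8L, presence = "all",
                        coupled = TRUE)
  cfg <- simConfig(seed = 11, nChroms = 1, chromLength = 4e5, nGenes = 40,
                   plantedDmrs = planted, coupledFcUp = 4,
                   nPlantedUp = 0L, nPlantedDown = 0L, dispersion = 0.1)
  ann <- simulateAnnotation(cfg)
  meth <- simulateMethylomes(cfg, ann)
  expr <- simulateExpression(cfg, ann, meth$truth)
  fpkm <- computeFpkm(expr$se)
  groups <- SummarizedExperiment::colData(expr$se)$group
  fc <- foldChanges(fpkm, groups)$fc
  coupled <- meth$truth$gene_id[meth$truth$coupled]
  est <- rowMeans(fc[coupled, , drop = FALSE])
  expect_true(all(est >= 2.8 & est <= 5.7))
  # noise-free limit: FPKM is exact, FC recovers truth to 3 decimals
  cfgNf <- simConfig(seed = 11, nChroms = 1, chromLength = 4e5,
                     nGenes = 40, plantedDmrs = planted, coupledFcUp = 4,
                     nPlantedUp = 0L, nPlantedDown = 0L, noiseFree = TRUE)
  exprNf <- simulateExpression(cfgNf, ann, meth$truth)
  fpkmNf <- SummarizedExperiment::assay(exprNf$se, "fpkm")
  fcNf <- foldChanges(fpkmNf,
                      SummarizedExperiment::colData(exprNf$se)$group,
                      pseudocount = 0)$fc
  expect_equal(unname(fcNf[coupled, 1]), rep(4, length(coupled)),
               tolerance = 1e-4)
})

test_that("null DMC rate matches an independent noise-model prediction", {
  # Route 1: generator + profile + classification over several seeds.
  # Route 2: direct Monte-Carlo from the declared model (Beta mixture,
  # logit-normal jitter, Poisson-floored coverage, binomial counts),
  # written here without any generator code.
  observed <- 0L; total <- 0L
  for (seed in 1:10) {
    cfg <- smallConfig(seed = 300 + seed)
    ann <- simulateAnnotation(cfg)
    sim <- simulateMethylomes(cfg, ann)
    prof <- buildControlProfile(sim$controls)
    cl <- classifyCpgs(sim$tumors[[1]], prof)
    observed <- observed + sum(cl$counts[c("hypo", "hyper")])
    total <- total + sum(cl$counts)
  }
  set.seed(999)
  n <- 40000
  mu0 <- ifelse(runif(n) < 0.7, rbeta(n, 8, 1), rbeta(n, 1, 8))
  mu0 <- pmin(pmax(mu0, 0.001), 0.999)
  drawPct <- function() {
    m <- plogis(qlogis(mu0) + rnorm(n, 0, 0.3))
    cov <- pmax(rpois(n, 30), 5)
    100 * rbinom(n, cov, m) / cov
  }
  ctrlMean <- (drawPct() + drawPct() + drawPct() + drawPct() +
                 drawPct()) / 5
  predicted <- mean(abs(drawPct() - ctrlMean) >= 10)
  expect_lt(abs(observed / total - predicted), 0.02)
})
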