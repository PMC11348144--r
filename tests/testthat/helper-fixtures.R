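suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# width-1 CpG GRanges from parallel vectors
cpgGr <- function(chrom, pos, meth, unmeth) {
  GRanges(chrom, IRanges(pos, width = 1L),
          meth = as.integer(meth), unmeth = as.integer(unmeth))
}

toyMethylome <- function(id, group, chrom, pos, meth, unmeth) {
  Methylome(id, group, cpgGr(chrom, pos, meth, unmeth))
}

# controls with identical positions and given per-site percents (coverage 10)
toyControls <- function(chrom, pos, pctList) {
  lapply(seq_along(pctList), function(i) {
    m <- round(pctList[[i]] / 10)
    toyMethylome(paste0("C", i), "control", chrom, pos, m, 10L - m)
  })
}

# DMC GRanges straight from vectors (for segmentation tests)
dmcGr <- function(pos, direction, chrom = "chr1",
                  tumor_pct = 10, control_pct = 50) {
  n <- length(pos)
  if (!n)
    return(GRanges(tumor_pct = numeric(), control_pct = numeric(),
                   delta = numeric(), direction = character()))
  GRanges(chrom, IRanges(pos, width = 1L),
          tumor_pct = rep(tumor_pct, n)[seq_len(n)],
          control_pct = rep(control_pct, n)[seq_len(n)],
          delta = rep(tumor_pct - control_pct, n)[seq_len(n)],
          direction = rep(direction, length.out = n))
}

# independent brute-force maximal-run search over sorted DMCs
bruteForceSegments <- function(dmcs, minCpgs = 3L, maxGap = 100L) {
  o <- order(as.character(seqnames(dmcs)), start(dmcs))
  chrom <- as.character(seqnames(dmcs))[o]
  pos <- start(dmcs)[o]
  dir <- mcols(dmcs)$direction[o]
  n <- length(pos)
  ok <- function(i, j) {
    if (chrom[i] != chrom[j] || any(chrom[i:j] != chrom[i])) return(FALSE)
    if (any(dir[i:j] != dir[i])) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > maxGap)) return(FALSE)
    TRUE
  }
  out <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L < minCpgs) next
    if (!ok(i, j)) next
    leftMax <- i == 1L || !ok(i - 1L, j)
    rightMax <- j == n || !ok(i, j + 1L)
    if (leftMax && rightMax)
      out <- rbind(out, data.frame(chrom = chrom[i], start = pos[i],
                                   end = pos[j], direction = dir[i],
                                   n_cpgs = j - i + 1L))
  }
  out
}

# independent exact one-/two-sided MWU by full rank-assignment enumeration
enumMwuP <- function(x, y, alternative) {
  r <- rank(c(x, y))
  nx <- length(x)
  combos <- combn(length(r), nx)
  U <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  switch(alternative,
         less = mean(U <= u),
         greater = mean(U >= u),
         two.sided = mean(abs(U - mu) >= abs(u - mu)))
}

# one default-condition study + pipeline, computed once per test run
studyCache <- new.env(parent = emptyenv())
cachedStudy <- function() {
  if (is.null(studyCache$study)) {
    studyCache$study <- simulateStudy(simConfig(seed = 1))
    studyCache$run <- runPipeline(studyCache$study)
  }
  list(study = studyCache$study, run = studyCache$run)
}

smallConfig <- function(seed = 7L, nPlantedUp = 3L, nPlantedDown = 2L,
                        ...) {
  simConfig(seed = seed, nChroms = 1L, chromLength = 1.5e5L, nGenes = 12L,
            plantedDmrs = NULL, nPlantedUp = nPlantedUp,
            nPlantedDown = nPlantedDown, ...)
}
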