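siteKey <- function(gr) paste0(as.character(seqnames(gr)), ":", start(gr))

methPct <- function(gr) {
  cov <- mcols(gr)$meth + mcols(gr)$unmeth
  100 * mcols(gr)$meth / cov
}

#' Build the averaged control methylation profile
#'
#' Per-CpG mean of the per-control methylation percents (an unweighted mean
#' of sample percents, not a pooled-count estimate). With `requireAll`
#' (default), only CpGs covered at or above `minCoverage` in every control
#' enter the profile; otherwise CpGs covered in at least one control are kept
#' and the mean is taken over the covering controls.
#'
#' @param controls list of [Methylome-class] objects.
#' @param minCoverage minimum coverage per control per site (default 5).
#' @param requireAll require coverage in all controls (default TRUE).
#' @return a [ControlProfile-class].
#' @export
buildControlProfile <- function(controls, minCoverage = 5L,
                                requireAll = TRUE) {
  if (!length(controls)) stop("at least one control sample is required")
  ids <- vapply(controls, sampleId, "")
  grs <- lapply(controls, function(m) {
    s <- methSites(m)
    s[mcols(s)$meth + mcols(s)$unmeth >= minCoverage]
  })
  keys <- lapply(grs, siteKey)
  allkeys <- unique(unlist(keys))
  n <- length(allkeys)
  pct <- matrix(NA_real_, n, length(controls),
                dimnames = list(NULL, ids))
  cnt <- matrix(0L, n, 2L * length(controls))
  colnames(cnt) <- as.vector(rbind(paste0("meth.", ids),
                                   paste0("unmeth.", ids)))
  for (j in seq_along(grs)) {
    idx <- match(keys[[j]], allkeys)
    pct[idx, j] <- methPct(grs[[j]])
    cnt[idx, 2L * j - 1L] <- mcols(grs[[j]])$meth
    cnt[idx, 2L * j] <- mcols(grs[[j]])$unmeth
  }
  keep <- if (requireAll) rowSums(is.na(pct)) == 0L else
    rowSums(!is.na(pct)) >= 1L
  allkeys <- allkeys[keep]
  pct <- pct[keep, , drop = FALSE]
  cnt <- cnt[keep, , drop = FALSE]
  parts <- strsplit(allkeys, ":", fixed = TRUE)
  gr <- GRanges(vapply(parts, `[`, "", 1L),
                IRanges(as.integer(vapply(parts, `[`, "", 2L)), width = 1L),
                mean_meth = rowMeans(pct, na.rm = TRUE),
                n_controls = rowSums(!is.na(pct)))
  o <- GenomicRanges::order(gr)
  new("ControlProfile", sites = gr[o], pct = pct[o, , drop = FALSE],
      counts = cnt[o, , drop = FALSE], sampleIds = ids)
}

#' Classify CpGs as hypo-, hyper- or unmethylated relative to control
#'
#' On the intersection of the tumor sites and the control profile, each CpG
#' gets exactly one class: `hypo` when delta (tumor minus control mean, in
#' percentage points) is at or below `-deltaThreshold`, `hyper` at or above
#' `+deltaThreshold`, `unchanged` otherwise. Boundaries are inclusive
#' ("at least 10%" change).
#'
#' @param tumor a [Methylome-class].
#' @param profile a [ControlProfile-class].
#' @param deltaThreshold methylation-change threshold in percentage points
#'   (default 10).
#' @return list with `sites` (width-1 `GRanges` carrying `tumor_pct`,
#'   `control_pct`, `delta`, `class` and the profile row index `prow`) and
#'   `counts` (named vector hypo/hyper/unchanged).
#' @export
classifyCpgs <- function(tumor, profile, deltaThreshold = 10) {
  ts <- methSites(tumor)
  ps <- profileSites(profile)
  idx <- match(siteKey(ts), siteKey(ps))
  keep <- !is.na(idx)
  if (!any(keep)) stop("tumor and control profile share no CpG sites")
  ts <- ts[keep]
  idx <- idx[keep]
  tp <- methPct(ts)
  cp <- mcols(ps)$mean_meth[idx]
  delta <- tp - cp
  cls <- ifelse(delta <= -deltaThreshold, "hypo",
                ifelse(delta >= deltaThreshold, "hyper", "unchanged"))
  out <- granges(ts)
  mcols(out) <- DataFrame(meth = mcols(ts)$meth, unmeth = mcols(ts)$unmeth,
                          tumor_pct = tp, control_pct = cp, delta = delta,
                          class = cls, prow = idx)
  counts <- c(hypo = sum(cls == "hypo"), hyper = sum(cls == "hyper"),
              unchanged = sum(cls == "unchanged"))
  list(sites = out, counts = counts)
}

#' Call differentially methylated cytosines
#'
#' DMCs are the hypo/hyper CpGs from [classifyCpgs()]. With
#' `siteTest = "proportion"` a per-site Fisher exact test of the tumor's
#' (methylated, unmethylated) counts against the pooled control counts is
#' added, and only sites with p below `alpha` are kept. The default is no
#' per-site test: with one tumor against a handful of controls a per-site
#' rank test cannot reach p < 0.05, so the significance criterion belongs to
#' the region level (see [testDmr()]).
#'
#' @inheritParams classifyCpgs
#' @param siteTest `"none"` (default) or `"proportion"`.
#' @param alpha per-site significance level for the proportion test.
#' @return width-1 `GRanges` of DMCs with `tumor_pct`, `control_pct`,
#'   `delta`, `direction` and (for the proportion test) `p_value`.
#' @export
callDmcs <- function(tumor, profile, deltaThreshold = 10,
                     siteTest = c("none", "proportion"), alpha = 0.05) {
  siteTest <- match.arg(siteTest)
  cl <- classifyCpgs(tumor, profile, deltaThreshold)
  s <- cl$sites[mcols(cl$sites)$class != "unchanged"]
  mcols(s)$direction <- mcols(s)$class
  mcols(s)$class <- NULL
  if (siteTest == "proportion" && length(s)) {
    cnt <- profile@counts[mcols(s)$prow, , drop = FALSE]
    cm <- rowSums(cnt[, grepl("^meth\\.", colnames(cnt)), drop = FALSE])
    cu <- rowSums(cnt[, grepl("^unmeth\\.", colnames(cnt)), drop = FALSE])
    p <- vapply(seq_along(s), function(i) {
      stats::fisher.test(matrix(c(mcols(s)$meth[i], mcols(s)$unmeth[i],
                                  cm[i], cu[i]), nrow = 2L))$p.value
    }, 0)
    mcols(s)$p_value <- p
    s <- s[p < alpha]
  }
  s
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum U statistic for `x` against `y`, using midranks for ties. When
#' both group sizes are at or below `exactMax` the p-value is computed from
#' the full permutation distribution over all choose(nx+ny, nx) group
#' assignments of the observed (possibly tied) values; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. `alternative = "less"` tests whether `x` tends to be smaller.
#'
#' @param x,y numeric vectors.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param exactMax largest per-group size for the exact path (default 8).
#' @return list with elements `U`, `p.value` and `exact`.
#' @export
mwuTest <- function(x, y, alternative = c("less", "greater", "two.sided"),
                    exactMax = 8L) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (max(nx, ny) <= exactMax) {
    combos <- utils::combn(nx + ny, nx)
    Uall <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- switch(alternative,
      less = mean(Uall <= U),
      greater = mean(Uall >= U),
      two.sided = mean(abs(Uall - mu) >= abs(U - mu)))
    return(list(U = U, p.value = p, exact = TRUE))
  }
  N <- nx + ny
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  p <- if (sigma == 0) 1 else switch(alternative,
    less = stats::pnorm((U - mu + 0.5) / sigma),
    greater = stats::pnorm(-(U - mu - 0.5) / sigma),
    two.sided = min(1, 2 * min(stats::pnorm((U - mu + 0.5) / sigma),
                               stats::pnorm(-(U - mu - 0.5) / sigma))))
  list(U = U, p.value = p, exact = FALSE)
}

#' Segment DMCs into candidate regions
#'
#' Scans the position-sorted DMC sequence per chromosome and emits every
#' maximal run of same-direction DMCs in which each adjacent pair is at most
#' `maxGap` base pairs apart. A direction flip (including an intervening
#' opposite-direction DMC) or a larger gap terminates the run. Runs shorter
#' than `minCpgs` are dropped.
#'
#' @param dmcs width-1 `GRanges` of DMCs with a `direction` column, sorted.
#' @param minCpgs minimum DMCs per region (default 3).
#' @param maxGap maximum distance between consecutive member DMCs in bp
#'   (default 100).
#' @return `GRanges` of candidate regions spanning first to last member DMC,
#'   with `direction`, `n_cpgs` and a `members` IntegerList of the DMC
#'   indices into `dmcs`.
#' @export
segmentDmrs <- function(dmcs, minCpgs = 3L, maxGap = 100L) {
  empty <- GRanges(direction = character(), n_cpgs = integer())
  if (!length(dmcs)) {
    mcols(empty)$members <- IRanges::IntegerList()
    return(empty)
  }
  o <- GenomicRanges::order(dmcs)
  dmcs_o <- dmcs[o]
  chrom <- as.character(seqnames(dmcs_o))
  pos <- start(dmcs_o)
  dir <- mcols(dmcs_o)$direction
  n <- length(dmcs_o)
  newrun <- c(TRUE, chrom[-1L] != chrom[-n] | dir[-1L] != dir[-n] |
                (pos[-1L] - pos[-n]) > maxGap)
  runid <- cumsum(newrun)
  keep <- tabulate(runid)[runid] >= minCpgs
  if (!any(keep)) {
    mcols(empty)$members <- IRanges::IntegerList()
    return(empty)
  }
  idx <- split(o[keep], runid[keep])
  firsts <- vapply(split(which(keep), runid[keep]), min, 0L)
  out <- GRanges(chrom[firsts],
                 IRanges(vapply(split(pos[keep], runid[keep]), min, 0),
                         vapply(split(pos[keep], runid[keep]), max, 0)),
                 direction = dir[firsts],
                 n_cpgs = unname(lengths(idx)))
  mcols(out)$members <- IRanges::IntegerList(unname(idx))
  out
}

#' Test a candidate region with the Mann-Whitney U test
#'
#' Over the k member CpGs, the tumor per-CpG methylation percents are
#' compared against the control mean per-CpG percents with [mwuTest()],
#' one-sided in the candidate's direction by default. The region is accepted
#' when p is at or below `alpha` (inclusive, so the minimum 3-CpG region with
#' complete separation, exact p = 0.05, is callable).
#'
#' @param candidate one row of the [segmentDmrs()] output.
#' @param dmcs the DMC `GRanges` the candidate indexes into.
#' @param alpha region significance level (default 0.05).
#' @param sided `"one"` (default; in the candidate direction) or `"two"`.
#' @return `NULL` when rejected, else a one-row `GRanges` with `direction`,
#'   `n_cpgs`, `mean_delta`, `p_value`.
#' @export
testDmr <- function(candidate, dmcs, alpha = 0.05,
                    sided = c("one", "two")) {
  sided <- match.arg(sided)
  members <- mcols(candidate)$members[[1L]]
  m <- mcols(dmcs)[members, , drop = FALSE]
  alt <- if (sided == "two") "two.sided" else
    if (mcols(candidate)$direction == "hypo") "less" else "greater"
  tst <- mwuTest(m$tumor_pct, m$control_pct, alternative = alt)
  if (tst$p.value > alpha) return(NULL)
  out <- granges(candidate)
  mcols(out) <- DataFrame(direction = mcols(candidate)$direction,
                          n_cpgs = mcols(candidate)$n_cpgs,
                          mean_delta = mean(m$delta),
                          p_value = tst$p.value)
  out
}

#' Call DMRs for one tumor against the control profile
#'
#' Composition of [callDmcs()], [segmentDmrs()] and [testDmr()]: CpGs with a
#' methylation change of at least `deltaThreshold` percentage points relative
#' to the averaged control become DMCs; maximal runs of at least `minCpgs`
#' same-direction DMCs no more than `maxGap` bp apart become candidates; each
#' candidate is accepted when the region Mann-Whitney test reaches `alpha`.
#'
#' @inheritParams callDmcs
#' @inheritParams segmentDmrs
#' @param sided sidedness of the region test (default one-sided in the
#'   region's direction).
#' @param bhCorrect apply Benjamini-Hochberg correction across candidate
#'   regions before the `alpha` cut (default FALSE: raw p-values, as region
#'   counts are descriptive here).
#' @return `GRanges` of DMRs sorted by position, with `sample_id`,
#'   `direction`, `n_cpgs`, `mean_delta`, `p_value`.
#' @export
callSampleDmrs <- function(tumor, profile, minCoverage = 5L,
                           deltaThreshold = 10, minCpgs = 3L, maxGap = 100L,
                           alpha = 0.05, sided = c("one", "two"),
                           siteTest = c("none", "proportion"),
                           bhCorrect = FALSE) {
  sided <- match.arg(sided)
  siteTest <- match.arg(siteTest)
  dmcs <- callDmcs(tumor, profile, deltaThreshold, siteTest, alpha)
  cands <- segmentDmrs(dmcs, minCpgs, maxGap)
  empty <- GRanges(sample_id = character(), direction = character(),
                   n_cpgs = integer(), mean_delta = numeric(),
                   p_value = numeric())
  if (!length(cands)) return(empty)
  tested <- lapply(seq_along(cands),
                   function(i) testDmr(cands[i], dmcs, alpha = Inf,
                                       sided = sided))
  res <- do.call(c, tested)
  pv <- mcols(res)$p_value
  if (bhCorrect) pv <- stats::p.adjust(pv, "BH")
  res <- res[pv <= alpha]
  if (!length(res)) return(empty)
  mcols(res) <- DataFrame(sample_id = sampleId(tumor),
                          direction = mcols(res)$direction,
                          n_cpgs = mcols(res)$n_cpgs,
                          mean_delta = mcols(res)$mean_delta,
                          p_value = mcols(res)$p_value)
  GenomicRanges::sort(res, ignore.strand = TRUE)
}
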