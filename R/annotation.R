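#' Build strand-relative promoter windows around TSS records
#'
#' The promoter of a gene spans `upstream` bp before to `downstream` bp after
#' its transcription start site, strand-relative, with the TSS base itself
#' counted as the first downstream base (so the default window covers 2000
#' bp: -1500 to +500). Windows running off the chromosome start are clipped
#' at position 1.
#'
#' @param tss width-1 `GRanges` with explicit strand and a `gene_id` column.
#' @param upstream bp upstream of the TSS (default 1500).
#' @param downstream bp downstream including the TSS base (default 500).
#' @return `GRanges` of promoter windows keeping `gene_id` and strand.
#' @export
makePromoters <- function(tss, upstream = 1500L, downstream = 500L) {
  if (any(as.character(strand(tss)) == "*"))
    stop("TSS records must have '+' or '-' strand")
  p <- GenomicRanges::promoters(tss, upstream = upstream,
                                downstream = downstream)
  # clip at chromosome start; no genome lengths are assumed
  GenomicRanges::start(p) <- pmax(start(p), 1L)
  p
}

elementPriority <- c("promoter", "exon", "intron", "gene_body", "enhancer",
                     "repeat", "intergenic")

#' Annotate features with the genomic element classes they overlap
#'
#' Each feature (CpG or DMR) receives every element class it overlaps by at
#' least 1 bp; classes are not exclusive, matching bedtools-intersect
#' semantics, so a DMR can be e.g. both promoter and repeat. Features
#' overlapping nothing are `intergenic`. With `mode = "exclusive"` each
#' feature gets only its highest-priority class (promoter > exon > intron >
#' gene_body > enhancer > repeat > intergenic), for distribution-style
#' summaries.
#'
#' @param features `GRanges` of CpGs or DMRs (a `direction` column, if
#'   present, is used for the per-class counts).
#' @param annotation an [AnnotationSet-class].
#' @param mode `"multi"` (default) or `"exclusive"`.
#' @return list with `labels` (logical matrix, features x classes incl.
#'   `intergenic`) and `counts` (data.frame of per-class feature counts,
#'   split by direction when available).
#' @export
annotateFeatures <- function(features, annotation,
                             mode = c("multi", "exclusive")) {
  mode <- match.arg(mode)
  classes <- names(elementClasses(annotation))
  lab <- matrix(FALSE, length(features), length(classes) + 1L,
                dimnames = list(NULL, c(classes, "intergenic")))
  for (cl in classes) {
    hits <- GenomicRanges::countOverlaps(
      features, elementClasses(annotation)[[cl]], ignore.strand = TRUE)
    lab[, cl] <- hits > 0L
  }
  lab[, "intergenic"] <- rowSums(lab[, classes, drop = FALSE]) == 0L
  if (mode == "exclusive" && length(features)) {
    prio <- c(intersect(elementPriority, colnames(lab)),
              setdiff(colnames(lab), elementPriority))
    first <- apply(lab[, prio, drop = FALSE], 1L, function(z) prio[which(z)[1L]])
    lab[] <- FALSE
    lab[cbind(seq_len(nrow(lab)), match(first, colnames(lab)))] <- TRUE
  }
  dir <- mcols(features)$direction
  counts <- if (is.null(dir)) {
    data.frame(element_class = colnames(lab), n = colSums(lab))
  } else {
    do.call(rbind, lapply(colnames(lab), function(cl)
      data.frame(element_class = cl,
                 hypo = sum(lab[, cl] & dir == "hypo"),
                 hyper = sum(lab[, cl] & dir == "hyper"))))
  }
  rownames(counts) <- NULL
  list(labels = lab, counts = counts)
}

methBinLabels <- c("0-25", "26-50", "51-75", "76-100")

#' Bin methylation percents into the four canonical categories
#'
#' Continuous percents are binned as `[0,25]`, `(25,50]`, `(50,75]`,
#' `(75,100]`; a mean of exactly 25 falls in the lowest bin.
#'
#' @param values numeric percents in `[0, 100]`.
#' @return named integer vector of counts per bin, summing to
#'   `length(values)`.
#' @export
methBinCounts <- function(values) {
  stopifnot(all(values >= 0 & values <= 100))
  b <- cut(values, breaks = c(0, 25, 50, 75, 100), labels = methBinLabels,
           include.lowest = TRUE, right = TRUE)
  table(b) |> as.vector() |> setNames(methBinLabels)
}

methBin <- function(values) {
  cut(values, breaks = c(0, 25, 50, 75, 100), labels = methBinLabels,
      include.lowest = TRUE, right = TRUE) |> as.character()
}

#' Mean promoter methylation per gene
#'
#' Averages the methylation percents of all covered CpGs inside each gene's
#' promoter window (unweighted mean over CpGs). Genes with fewer than
#' `minCpgs` covered CpGs are absent from the output.
#'
#' @param sample a [Methylome-class] (already coverage-filtered on read).
#' @param promoters promoter `GRanges` from [makePromoters()].
#' @param minCpgs minimum covered CpGs per promoter (default 1).
#' @return data.frame with `gene_id`, `mean_meth_pct`, `n_cpgs`, `bin`.
#' @export
promoterMethylation <- function(sample, promoters, minCpgs = 1L) {
  s <- methSites(sample)
  hits <- GenomicRanges::findOverlaps(s, promoters, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(gene_id = character(), mean_meth_pct = numeric(),
                      n_cpgs = integer(), bin = character()))
  pct <- methPct(s)[queryHits(hits)]
  gene <- mcols(promoters)$gene_id[subjectHits(hits)]
  agg <- rowsum(pct, gene)
  n <- as.vector(table(gene)[rownames(agg)])
  mean_pct <- as.vector(agg[, 1L]) / n
  keep <- n >= minCpgs
  data.frame(gene_id = rownames(agg)[keep], mean_meth_pct = mean_pct[keep],
             n_cpgs = as.integer(n[keep]), bin = methBin(mean_pct[keep]),
             row.names = NULL)
}

#' Pairwise Pearson correlations between sample columns
#'
#' Standard Pearson R over the common feature set for every pair of columns;
#' rows with a missing value in either column of a pair are dropped for that
#' pair.
#'
#' @param m numeric matrix, features x samples (e.g. promoter means or
#'   per-CpG percents), possibly with NAs.
#' @return list with `r` (correlation matrix) and `n` (matrix of complete
#'   pair counts).
#' @export
pairwisePearson <- function(m) {
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] >= 2L) r[i, j] <- stats::cor(m[ok, i], m[ok, j])
  }
  list(r = r, n = n)
}

#' Expression by promoter-methylation bin
#'
#' Splits genes into the four promoter-methylation bins and reports per-bin
#' mean and SEM of expression plus all six pairwise two-tailed t-tests
#' (Welch by default). Bins with fewer than two genes yield NA for their
#' comparisons rather than an error.
#'
#' @param promMeth data.frame from [promoterMethylation()].
#' @param fpkm named numeric vector of per-gene expression (FPKM).
#' @param welch use Welch's unequal-variance t-test (default TRUE);
#'   FALSE gives the pooled-variance Student test.
#' @return list with `summary` (per-bin n, mean, sem), `tests` (pairwise
#'   bins, t, p), and `monotoneDecreasing` (does mean expression fall as the
#'   methylation bin rises).
#' @export
expressionByBin <- function(promMeth, fpkm, welch = TRUE) {
  common <- intersect(promMeth$gene_id, names(fpkm))
  pm <- promMeth[match(common, promMeth$gene_id), ]
  e <- fpkm[common]
  groups <- split(e, factor(pm$bin, levels = methBinLabels))
  summary <- data.frame(
    bin = methBinLabels,
    n = vapply(groups, length, 0L),
    mean_fpkm = vapply(groups, function(g) if (length(g)) mean(g) else NA_real_, 0),
    sem_fpkm = vapply(groups, function(g)
      if (length(g) >= 2L) stats::sd(g) / sqrt(length(g)) else NA_real_, 0),
    row.names = NULL)
  pairs <- utils::combn(methBinLabels, 2L)
  tests <- data.frame(bin1 = pairs[1L, ], bin2 = pairs[2L, ],
                      t = NA_real_, p_value = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    g1 <- groups[[pairs[1L, k]]]; g2 <- groups[[pairs[2L, k]]]
    if (length(g1) >= 2L && length(g2) >= 2L) {
      tt <- stats::t.test(g1, g2, var.equal = !welch)
      tests$t[k] <- unname(tt$statistic)
      tests$p_value[k] <- tt$p.value
    }
  }
  mu <- summary$mean_fpkm[!is.na(summary$mean_fpkm)]
  list(summary = summary, tests = tests,
       monotoneDecreasing = length(mu) >= 2L && all(diff(mu) < 0))
}
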