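singleLinkageClusters <- function(gr, reciprocalFrac = 0) {
  if (!length(gr)) return(integer())
  if (reciprocalFrac <= 0) {
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
    return(subjectHits(hits)[order(queryHits(hits))])
  }
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ov <- width(IRanges::pintersect(ranges(gr)[q], ranges(gr)[s]))
  keep <- ov >= reciprocalFrac * pmax(width(gr)[q], 1L) &
    ov >= reciprocalFrac * pmax(width(gr)[s], 1L)
  # union-find over qualifying overlap pairs
  parent <- seq_along(gr)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in which(keep)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(gr), find, 0L)
  match(roots, unique(roots))
}

#' @importFrom GenomicRanges ranges
#' @importFrom IRanges pintersect
NULL

#' Cross-tumor recurrent DMRs (core methylation signature)
#'
#' Same-direction DMRs from different tumors are clustered by single-linkage
#' with any 1-bp overlap (or, optionally, a reciprocal-overlap fraction);
#' each cluster supported by at least `nRequired` distinct tumors becomes one
#' merged signature region (the interval union of its members). At
#' `nRequired` equal to the number of tumors this is the signature of regions
#' recurrent in every tumor.
#'
#' @param dmrSets named list (one element per tumor) of DMR `GRanges` from
#'   [callSampleDmrs()].
#' @param nRequired minimum number of distinct supporting tumors (default:
#'   all tumors).
#' @param reciprocalFrac optional reciprocal-overlap fraction for cluster
#'   edges (default 0: plain 1-bp overlap).
#' @return `GRanges` of merged regions with `direction`, `support`
#'   (distinct-tumor count), a `tumors` CharacterList of supporting tumor
#'   ids, and a `delta` matrix column (regions x tumors, per-tumor mean
#'   methylation change, NA where unsupported).
#' @export
recurrentDmrs <- function(dmrSets, nRequired = length(dmrSets),
                          reciprocalFrac = 0) {
  if (length(dmrSets) < 2L) stop("at least two tumors are required")
  ids <- names(dmrSets)
  if (is.null(ids)) ids <- paste0("T", seq_along(dmrSets))
  out <- list()
  for (dir in c("hypo", "hyper")) {
    pool <- do.call(c, unname(lapply(seq_along(dmrSets), function(i) {
      g <- dmrSets[[i]][mcols(dmrSets[[i]])$direction == dir]
      mcols(g)$tumor <- if (length(g)) ids[i] else character()
      g
    })))
    if (!length(pool)) next
    cl <- singleLinkageClusters(pool, reciprocalFrac)
    regs <- unlist(range(GenomicRanges::split(pool, cl),
                         ignore.strand = TRUE))
    support <- unname(vapply(split(mcols(pool)$tumor, cl),
                             function(z) length(unique(z)), 0L))
    delta <- matrix(NA_real_, length(regs), length(ids),
                    dimnames = list(NULL, ids))
    dsplit <- split(seq_along(pool), cl)
    for (k in seq_along(dsplit)) {
      mm <- mcols(pool)[dsplit[[k]], , drop = FALSE]
      ag <- rowsum(mm$mean_delta, mm$tumor)
      delta[k, rownames(ag)] <- ag[, 1L] / as.vector(table(mm$tumor)[rownames(ag)])
    }
    keep <- support >= nRequired
    regs <- regs[keep]
    mcols(regs) <- DataFrame(
      direction = rep(dir, sum(keep)), support = support[keep],
      tumors = IRanges::CharacterList(lapply(split(mcols(pool)$tumor, cl),
                                             unique)[keep]))
    mcols(regs)$delta <- delta[keep, , drop = FALSE]
    out[[dir]] <- regs
  }
  res <- if (length(out)) do.call(c, unname(out)) else
    GRanges(direction = character(), support = integer())
  GenomicRanges::sort(res, ignore.strand = TRUE)
}

#' Per-gene, per-direction tumor counts of promoter DMR hits
#'
#' For each gene and each direction, counts the tumors having at least one
#' DMR of that direction overlapping the gene's promoter window; a tumor is
#' counted once regardless of how many of its DMRs hit.
#'
#' @param dmrSets named per-tumor list of DMR `GRanges`.
#' @param promoters promoter `GRanges` from [makePromoters()].
#' @return list with `counts` (data.frame `gene_id`, `hypo_count`,
#'   `hyper_count`), logical matrices `hypo` and `hyper` (genes x tumors),
#'   and `meanDelta` (genes x tumors mean promoter DMR methylation change,
#'   NA where no DMR hits).
#' @export
geneDmrFrequency <- function(dmrSets, promoters) {
  ids <- names(dmrSets)
  if (is.null(ids)) ids <- paste0("T", seq_along(dmrSets))
  genes <- mcols(promoters)$gene_id
  hypo <- matrix(FALSE, length(genes), length(ids),
                 dimnames = list(genes, ids))
  hyper <- hypo
  meanDelta <- matrix(NA_real_, length(genes), length(ids),
                      dimnames = list(genes, ids))
  for (i in seq_along(dmrSets)) {
    d <- dmrSets[[i]]
    hits <- GenomicRanges::findOverlaps(promoters, d, ignore.strand = TRUE)
    if (!length(hits)) next
    g <- queryHits(hits)
    dir <- mcols(d)$direction[subjectHits(hits)]
    hypo[unique(g[dir == "hypo"]), i] <- TRUE
    hyper[unique(g[dir == "hyper"]), i] <- TRUE
    dl <- mcols(d)$mean_delta[subjectHits(hits)]
    ag <- rowsum(dl, g)
    meanDelta[as.integer(rownames(ag)), i] <-
      ag[, 1L] / as.vector(table(g)[rownames(ag)])
  }
  list(counts = data.frame(gene_id = genes,
                           hypo_count = rowSums(hypo),
                           hyper_count = rowSums(hyper), row.names = NULL),
       hypo = hypo, hyper = hyper, meanDelta = meanDelta)
}

#' Core expression signature: genes deregulated in every tumor
#'
#' Up-genes have fold change at or above `fold` in at least `nRequired`
#' tumors; down-genes at or below `1/fold`. With the default `nRequired`
#' (all tumors) this is the signature of genes changed in every sample.
#'
#' @param fc fold-change matrix, genes x tumors.
#' @param fold fold-change cutoff (default 2).
#' @param nRequired minimum number of tumors (default all).
#' @return list with character vectors `up` and `down`.
#' @export
coreExpressionSignature <- function(fc, fold = 2, nRequired = ncol(fc)) {
  up <- rownames(fc)[rowSums(fc >= fold) >= nRequired]
  down <- rownames(fc)[rowSums(fc <= 1 / fold) >= nRequired]
  list(up = up, down = down)
}

#' Threshold profiles for methylation-expression integration
#'
#' `"fig5a"`: fold change at least 2, p < 0.05, promoter DMR in at least 6
#' of 7 tumors. `"text25"`: fold change at least 1.5, same recurrence. The
#' two profiles reflect the two threshold combinations used for the
#' integrated gene lists; both are plain parameter bundles for
#' [integrateMethExpr()].
#'
#' @param name profile name.
#' @return list of `fcThreshold`, `alpha`, `methMinTumors`.
#' @export
integrationProfile <- function(name = c("fig5a", "text25")) {
  name <- match.arg(name)
  switch(name,
    fig5a = list(fcThreshold = 2.0, alpha = 0.05, methMinTumors = 6L),
    text25 = list(fcThreshold = 1.5, alpha = 0.05, methMinTumors = 6L))
}

#' Integrate recurrent promoter methylation with expression change
#'
#' A gene is `hypo_up` when its promoter carries a hypomethylated DMR in at
#' least `methMinTumors` tumors and its expression is up (FC at or above
#' `fcThreshold`, p below `alpha`) in at least `exprMinTumors` tumors;
#' `hyper_down` is symmetric. The two recurrence knobs are independent; the
#' expression default is a majority of the expression-profiled tumors.
#'
#' @param geneFreq output of [geneDmrFrequency()].
#' @param de output of [deTable()].
#' @param methMinTumors minimum tumors with a promoter DMR (default 6).
#' @param fcThreshold fold-change cutoff (default 2).
#' @param alpha p-value cutoff (default 0.05).
#' @param exprMinTumors minimum tumors passing the expression rule
#'   (default: majority, `floor(n/2) + 1`).
#' @return data.frame per gene: `gene_id`, `hypo_promoter_count`,
#'   `hyper_promoter_count`, `up_count`, `down_count`, `class`.
#' @export
integrateMethExpr <- function(geneFreq, de, methMinTumors = 6L,
                              fcThreshold = 2, alpha = 0.05,
                              exprMinTumors = NULL) {
  freq <- geneFreq$counts
  common <- intersect(freq$gene_id, rownames(de$fc))
  if (length(common) < 0.5 * max(length(freq$gene_id), nrow(de$fc)))
    warning("fewer than half of the gene ids are shared between the ",
            "methylation and expression inputs")
  if (is.null(exprMinTumors)) exprMinTumors <- floor(ncol(de$fc) / 2) + 1L
  fc <- de$fc[common, , drop = FALSE]
  p <- de$p[common, , drop = FALSE]
  upc <- rowSums(fc >= fcThreshold & p < alpha, na.rm = TRUE)
  downc <- rowSums(fc <= 1 / fcThreshold & p < alpha, na.rm = TRUE)
  fr <- freq[match(common, freq$gene_id), ]
  hypoRule <- fr$hypo_count >= methMinTumors & upc >= exprMinTumors
  hyperRule <- fr$hyper_count >= methMinTumors & downc >= exprMinTumors
  class <- ifelse(hypoRule & hyperRule, "none",
                  ifelse(hypoRule, "hypo_up",
                         ifelse(hyperRule, "hyper_down", "none")))
  data.frame(gene_id = common,
             hypo_promoter_count = fr$hypo_count,
             hyper_promoter_count = fr$hyper_count,
             up_count = upc, down_count = downc, class = class,
             row.names = NULL)
}

#' Gene-effect lethality screen
#'
#' Counts, per gene, the cell lines in which the gene-effect score is at or
#' below `threshold` (lethal), split by lineage, and flags genes lethal in
#' at least `essentialFrac` of all lines as common-essential. The semantics
#' of the supplied score matrix (e.g. CRISPR knockout gene effect) are the
#' caller's responsibility; this is a plain threshold tabulation.
#'
#' @param effect numeric matrix, genes x cell lines.
#' @param lineage character vector per line, e.g. `"lymphoid"`, `"myeloid"`,
#'   `"other"`.
#' @param threshold lethality cutoff, inclusive (default -1).
#' @param essentialFrac common-essential fraction of all lines (default 0.9).
#' @return data.frame per gene with per-lineage lethal counts, `lethal_total`
#'   and `common_essential`.
#' @export
lethalityScreen <- function(effect, lineage, threshold = -1,
                            essentialFrac = 0.9) {
  stopifnot(length(lineage) == ncol(effect))
  lethal <- effect <= threshold
  lins <- unique(lineage)
  out <- data.frame(gene_id = rownames(effect), row.names = NULL)
  for (l in lins)
    out[[paste0("lethal_", l)]] <-
      rowSums(lethal[, lineage == l, drop = FALSE])
  out$lethal_total <- rowSums(lethal)
  out$common_essential <- out$lethal_total >= essentialFrac * ncol(effect)
  out
}
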