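#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end width
#'   strand mcols mcols<- sort findOverlaps countOverlaps reduce promoters
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame Rle
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom stats rbeta rbinom rnbinom rpois runif rnorm cor pnorm pt
#'   fisher.test p.adjust setNames sd t.test quantile
#' @importFrom utils read.table write.table combn
NULL

#' Single-specimen CpG methylome
#'
#' Holds the per-CpG methylated/unmethylated read counts for one bisulfite
#' sequencing specimen. Sites are width-1 [GenomicRanges::GRanges] at the
#' 1-based cytosine position (plus-strand position after symmetric-CpG
#' merging), carrying integer metadata columns `meth` and `unmeth`.
#'
#' @slot sampleId single character identifier.
#' @slot group `"control"` or `"tumor"`.
#' @slot sites `GRanges` of width-1 CpG positions, sorted, no duplicates,
#'   with `meth` and `unmeth` counts.
#' @exportClass Methylome
setClass("Methylome",
  slots = c(sampleId = "character", group = "character", sites = "GRanges"))

setValidity("Methylome", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (!object@group %in% c("control", "tumor"))
    msg <- c(msg, "group must be 'control' or 'tumor'")
  s <- object@sites
  mc <- mcols(s)
  if (!all(c("meth", "unmeth") %in% colnames(mc)))
    msg <- c(msg, "sites must carry 'meth' and 'unmeth' columns")
  else {
    if (any(mc$meth < 0) || any(mc$unmeth < 0))
      msg <- c(msg, "read counts must be non-negative")
  }
  if (length(s) && any(width(s) != 1L)) msg <- c(msg, "sites must have width 1")
  if (is.unsorted(order(as.integer(seqnames(s)), start(s))))
    msg <- c(msg, "sites must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(seqnames(s), start(s))))
    msg <- c(msg, "duplicate (chrom, pos) sites")
  if (length(msg)) msg else TRUE
})

#' Averaged control methylation profile
#'
#' Per-CpG mean methylation percent over a set of control methylomes, with the
#' per-control percents retained (needed for region-level rank tests). The
#' mean is the unweighted mean of per-sample percents, not a pooled-count
#' estimate.
#'
#' @slot sites width-1 `GRanges` with metadata column `mean_meth` (percent).
#' @slot pct numeric matrix, sites x controls, of per-control methylation
#'   percents (NA where a control lacks coverage).
#' @slot counts integer matrix, sites x (2*controls), pooled-count backing
#'   (`meth.<id>`, `unmeth.<id>` columns) used by the optional per-site
#'   proportion test.
#' @slot sampleIds control sample identifiers (column order of `pct`).
#' @exportClass ControlProfile
setClass("ControlProfile",
  slots = c(sites = "GRanges", pct = "matrix", counts = "matrix",
            sampleIds = "character"))

setValidity("ControlProfile", function(object) {
  msg <- character()
  if (nrow(object@pct) != length(object@sites))
    msg <- c(msg, "pct rows must match number of sites")
  if (ncol(object@pct) != length(object@sampleIds))
    msg <- c(msg, "pct columns must match sampleIds")
  mm <- mcols(object@sites)$mean_meth
  if (is.null(mm)) msg <- c(msg, "sites must carry 'mean_meth'")
  else if (length(mm) && (min(mm) < 0 || max(mm) > 100))
    msg <- c(msg, "mean_meth must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Genomic element annotation
#'
#' Strand-aware intervals grouped by element class, plus the TSS records the
#' promoter windows derive from. Intervals are ordinary 1-based `GRanges`
#' internally; BED input/output converts at the boundary.
#'
#' @slot elements named `GRangesList`, one element per class (e.g. promoter,
#'   gene_body, exon, intron, enhancer, repeat).
#' @slot tss width-1 `GRanges` of transcription start sites with metadata
#'   column `gene_id` and explicit strand.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  slots = c(elements = "GRangesList", tss = "GRanges"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (is.null(names(object@elements)) && length(object@elements))
    msg <- c(msg, "elements must be named by element class")
  if (length(object@tss)) {
    if (is.null(mcols(object@tss)$gene_id))
      msg <- c(msg, "tss must carry 'gene_id'")
    if (any(as.character(strand(object@tss)) == "*"))
      msg <- c(msg, "tss strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Methylome
#'
#' @param sampleId single character id.
#' @param group `"control"` or `"tumor"`.
#' @param sites width-1 `GRanges` with `meth`/`unmeth` counts; sorted on
#'   construction.
#' @return a [Methylome-class] object.
#' @export
Methylome <- function(sampleId, group, sites) {
  sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
  new("Methylome", sampleId = as.character(sampleId),
      group = as.character(group), sites = sites)
}

#' Construct an AnnotationSet
#'
#' @param elements named list or `GRangesList` of intervals per element class.
#' @param tss width-1 `GRanges` of TSS positions with `gene_id` and strand.
#' @return an [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(elements = GRangesList(), tss = GRanges()) {
  if (is.list(elements)) elements <- GRangesList(elements)
  new("AnnotationSet", elements = elements, tss = tss)
}
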