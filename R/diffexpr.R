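#' Compute FPKM from raw counts
#'
#' FPKM = count x 10^9 / (length_bp x library_size), with the library size
#' taken as the column sum of counts, so scaling a column's counts leaves its
#' FPKM unchanged.
#'
#' @param counts integer matrix, genes x samples (or a
#'   `SummarizedExperiment` with a `counts` assay and `rowData$length`).
#' @param geneLengths per-gene transcript lengths in bp (ignored when
#'   `counts` is a `SummarizedExperiment` carrying lengths).
#' @return numeric FPKM matrix with the same dimnames.
#' @export
computeFpkm <- function(counts, geneLengths = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    geneLengths <- SummarizedExperiment::rowData(counts)$length
    if (is.null(geneLengths))
      stop("SummarizedExperiment lacks rowData$length; FPKM needs lengths")
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(geneLengths)) stop("gene lengths are required for FPKM")
  stopifnot(length(geneLengths) == nrow(counts), all(geneLengths > 0))
  lib <- colSums(counts)
  sweep(counts * 1e9 / geneLengths, 2L, pmax(lib, 1), "/")
}

#' Per-tumor fold changes against the averaged controls
#'
#' FC = (tumor + eps) / (mean of controls + eps) per gene per tumor column,
#' with a small pseudocount preventing division by zero; FC = 1 when both
#' sides are zero.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param groups character vector (`"control"`/`"tumor"`) per column.
#' @param pseudocount pseudocount eps added to both sides (default 0.1).
#' @return list with `fc` and `log2fc` matrices (genes x tumor samples) and
#'   `controlMean` (per-gene mean control FPKM).
#' @export
foldChanges <- function(fpkm, groups, pseudocount = 0.1) {
  stopifnot(length(groups) == ncol(fpkm))
  ctrl <- fpkm[, groups == "control", drop = FALSE]
  tum <- fpkm[, groups == "tumor", drop = FALSE]
  if (!ncol(ctrl)) stop("at least one control column is required")
  cm <- rowMeans(ctrl)
  fc <- (tum + pseudocount) / (cm + pseudocount)
  list(fc = fc, log2fc = log2(fc), controlMean = cm)
}

#' Per-tumor differential-expression table
#'
#' Internal mode computes, per gene and tumor, a z-score of the tumor's
#' log2(FPKM + eps) against the distribution of the control replicates'
#' log2(FPKM + eps), with a two-sided normal-tail p-value. This is a simple
#' screening approximation for the single-tumor-versus-control-panel design,
#' not a count-model fit; for publication-grade inference an externally
#' produced table (e.g. from DESeq2) can be supplied via imported mode,
#' whose log2 fold changes and p-values are passed through unchanged while
#' FC is still computed from FPKM so both modes agree on it.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param groups `"control"`/`"tumor"` per column.
#' @param source `"internal"` (default) or `"imported"`.
#' @param imported for imported mode: data.frame with columns `gene`,
#'   `sample`, `p_value` (one row per gene per tumor).
#' @param pseudocount eps for the log2 transform and fold changes.
#' @param fcThreshold,alpha significance contract: a gene is significant in
#'   a tumor when p < `alpha` and FC >= `fcThreshold` or <= 1/`fcThreshold`.
#' @return list with matrices `fc`, `log2fc`, `p` and logical `significant`
#'   (all genes x tumors).
#' @export
deTable <- function(fpkm, groups, source = c("internal", "imported"),
                    imported = NULL, pseudocount = 0.1,
                    fcThreshold = 1.5, alpha = 0.05) {
  source <- match.arg(source)
  fcres <- foldChanges(fpkm, groups, pseudocount)
  fc <- fcres$fc
  if (source == "internal") {
    if (sum(groups == "control") < 2L)
      stop("internal mode needs at least two control replicates")
    lctrl <- log2(fpkm[, groups == "control", drop = FALSE] + pseudocount)
    ltum <- log2(fpkm[, groups == "tumor", drop = FALSE] + pseudocount)
    mu <- rowMeans(lctrl)
    sdv <- apply(lctrl, 1L, stats::sd)
    z <- (ltum - mu) / sdv
    p <- 2 * stats::pnorm(-abs(z))
    p[sdv == 0 & ltum == mu] <- 1
    p[sdv == 0 & ltum != mu] <- 0
  } else {
    if (is.null(imported)) stop("imported mode needs an imported table")
    p <- matrix(NA_real_, nrow(fc), ncol(fc), dimnames = dimnames(fc))
    idx <- cbind(match(imported$gene, rownames(p)),
                 match(imported$sample, colnames(p)))
    ok <- stats::complete.cases(idx)
    p[idx[ok, , drop = FALSE]] <- imported$p_value[ok]
    if (anyNA(p))
      warning(sum(rowSums(is.na(p)) > 0L),
              " gene(s) missing from the imported table; flags set NA")
  }
  sig <- p < alpha & (fc >= fcThreshold | fc <= 1 / fcThreshold)
  list(fc = fc, log2fc = fcres$log2fc, p = p, significant = sig)
}

#' Select highly expressed genes
#'
#' Genes whose mean FPKM over the designated columns is at or above the
#' threshold (inclusive).
#'
#' @param fpkm FPKM matrix.
#' @param columns columns to average over (default all).
#' @param threshold FPKM cutoff (default 5).
#' @return character vector of gene ids.
#' @export
selectExpressed <- function(fpkm, columns = seq_len(ncol(fpkm)),
                            threshold = 5) {
  mu <- rowMeans(fpkm[, columns, drop = FALSE])
  rownames(fpkm)[mu >= threshold]
}
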