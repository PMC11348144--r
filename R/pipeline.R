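#' Default pipeline parameters
#'
#' The thresholds of the analysis: 5x minimum CpG coverage, 10-percentage-
#' point methylation change, at least 3 consecutive DMCs no more than 100 bp
#' apart, region p at most 0.05 (one-sided), promoter window -1500/+500,
#' core-expression fold 2, integration profile thresholds, FPKM >= 5 for the
#' highly-expressed gene list, and gene-effect lethality at -1.
#'
#' @return named list of parameters.
#' @export
pipelineParams <- function() {
  list(minCoverage = 5L, deltaThreshold = 10, minCpgs = 3L, maxGap = 100L,
       alpha = 0.05, sided = "one", upstream = 1500L, downstream = 500L,
       coreFold = 2, fcThreshold = 2, intAlpha = 0.05, methMinTumors = 6L,
       fpkmThreshold = 5, pseudocount = 0.1, effectThreshold = -1)
}

#' Run the full analysis pipeline on a (possibly simulated) study
#'
#' Builds the averaged control profile, calls DMCs and DMRs per tumor,
#' annotates DMRs to genomic elements, computes FPKM, fold changes and the
#' differential-expression contract, derives the cross-tumor core
#' methylation and expression signatures, the per-gene promoter DMR
#' frequencies, and the methylation-expression integration. When `outDir`
#' is given, all stage outputs plus a run manifest are written as
#' tab-separated text; outputs are deterministic given the study and
#' parameters.
#'
#' @param study a study list as returned by [simulateStudy()] (or assembled
#'   from files: `controls`/`tumors` lists of [Methylome-class],
#'   `annotation` an [AnnotationSet-class], `expression` a
#'   `SummarizedExperiment`).
#' @param params parameter list, see [pipelineParams()].
#' @param outDir optional output directory.
#' @return list with `profile`, `dmcCounts`, `dmrs` (per-tumor `GRanges`),
#'   `dmrElementCounts`, `coreMethylation`, `geneFreq`, `fpkm`, `de`,
#'   `coreExpression`, `integrated`, `expressedGenes`, `params`.
#' @export
runPipeline <- function(study, params = pipelineParams(), outDir = NULL) {
  if (is.null(study$controls) || !length(study$controls))
    stop("study$controls is missing or empty")
  if (is.null(study$tumors) || !length(study$tumors))
    stop("study$tumors is missing or empty")
  prof <- buildControlProfile(study$controls,
                              minCoverage = params$minCoverage)
  promoters <- makePromoters(annotationTss(study$annotation),
                             upstream = params$upstream,
                             downstream = params$downstream)
  dmcCounts <- list()
  dmrs <- list()
  elemCounts <- list()
  for (tid in names(study$tumors)) {
    tum <- study$tumors[[tid]]
    dmcCounts[[tid]] <- classifyCpgs(tum, prof, params$deltaThreshold)$counts
    dmrs[[tid]] <- callSampleDmrs(
      tum, prof, minCoverage = params$minCoverage,
      deltaThreshold = params$deltaThreshold, minCpgs = params$minCpgs,
      maxGap = params$maxGap, alpha = params$alpha, sided = params$sided)
    elemCounts[[tid]] <- annotateFeatures(dmrs[[tid]],
                                          study$annotation)$counts
  }
  coreMeth <- recurrentDmrs(dmrs, nRequired = length(dmrs))
  geneFreq <- geneDmrFrequency(dmrs, promoters)
  se <- study$expression
  unit <- names(SummarizedExperiment::assays(se))[1L]
  fpkm <- if (unit == "fpkm") SummarizedExperiment::assay(se, "fpkm") else
    computeFpkm(se)
  groups <- SummarizedExperiment::colData(se)$group
  de <- deTable(fpkm, groups, pseudocount = params$pseudocount,
                fcThreshold = params$fcThreshold, alpha = params$intAlpha)
  coreExpr <- coreExpressionSignature(de$fc, fold = params$coreFold)
  integrated <- integrateMethExpr(geneFreq, de,
                                  methMinTumors = params$methMinTumors,
                                  fcThreshold = params$fcThreshold,
                                  alpha = params$intAlpha)
  expressed <- selectExpressed(fpkm, which(groups == "control"),
                               threshold = params$fpkmThreshold)
  res <- list(profile = prof, dmcCounts = dmcCounts, dmrs = dmrs,
              dmrElementCounts = elemCounts, coreMethylation = coreMeth,
              geneFreq = geneFreq, fpkm = fpkm, de = de,
              coreExpression = coreExpr, integrated = integrated,
              expressedGenes = expressed, params = params)
  if (!is.null(outDir)) writeRun(res, outDir)
  res
}

writeRun <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (tid in names(res$dmrs))
    writeDmrBed(res$dmrs[[tid]],
                file.path(outDir, paste0("dmrs_", tid, ".bed")))
  cm <- res$coreMethylation
  d <- data.frame(chrom = if (length(cm)) as.character(seqnames(cm)) else
                    character(),
                  start = if (length(cm)) start(cm) - 1L else integer(),
                  end = if (length(cm)) end(cm) else integer(),
                  direction = if (length(cm)) mcols(cm)$direction else
                    character(),
                  support = if (length(cm)) mcols(cm)$support else integer())
  utils::write.table(d, file.path(outDir, "core_methylation_signature.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$coreExpression$up,
             file.path(outDir, "core_expression_up.tsv"))
  writeLines(res$coreExpression$down,
             file.path(outDir, "core_expression_down.tsv"))
  utils::write.table(res$integrated,
                     file.path(outDir, "integrated_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(res$geneFreq$meanDelta),
               res$geneFreq$meanDelta, check.names = FALSE),
    file.path(outDir, "promoter_delta_matrix.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(res$de$log2fc), res$de$log2fc,
               check.names = FALSE),
    file.path(outDir, "log2fc_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  counts <- do.call(rbind, lapply(names(res$dmrElementCounts), function(t)
    cbind(tumor = t, res$dmrElementCounts[[t]])))
  utils::write.table(counts, file.path(outDir, "dmr_element_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dmc <- do.call(rbind, lapply(names(res$dmcCounts), function(t)
    data.frame(tumor = t, hypo = res$dmcCounts[[t]]["hypo"],
               hyper = res$dmcCounts[[t]]["hyper"],
               unchanged = res$dmcCounts[[t]]["unchanged"],
               row.names = NULL)))
  utils::write.table(dmc, file.path(outDir, "dmc_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(
    paste0("tool_version\t", dmrlinkVersion()),
    paste0("n_tumors\t", length(res$dmrs)),
    paste0("n_core_hypo\t",
           sum(if (length(cm)) mcols(cm)$direction == "hypo" else 0)),
    paste0("n_core_hyper\t",
           sum(if (length(cm)) mcols(cm)$direction == "hyper" else 0)),
    vapply(names(res$params), function(k)
      paste0("param_", k, "\t", res$params[[k]]), ""))
  writeLines(manifest, file.path(outDir, "manifest.tsv"))
  invisible(outDir)
}

#' Summarize a completed pipeline run directory
#'
#' Recomputes the headline numbers from the stage output files alone (no
#' state private to the run): per-tumor hypo/hyper DMR totals, per-element
#' counts, core signature sizes and integrated gene lists.
#'
#' @param runDir directory written by [runPipeline()].
#' @return list with `dmrCounts` (per tumor and direction),
#'   `elementCounts`, `coreSizes`, `integratedGenes`.
#' @export
summarizeRun <- function(runDir) {
  beds <- list.files(runDir, pattern = "^dmrs_.*\\.bed$", full.names = TRUE)
  dmrCounts <- do.call(rbind, lapply(beds, function(f) {
    g <- readDmrBed(f)
    data.frame(tumor = sub("^dmrs_(.*)\\.bed$", "\\1", basename(f)),
               hypo = sum(mcols(g)$direction == "hypo"),
               hyper = sum(mcols(g)$direction == "hyper"))
  }))
  core <- utils::read.table(
    file.path(runDir, "core_methylation_signature.bed"), sep = "\t",
    header = TRUE, stringsAsFactors = FALSE)
  integ <- utils::read.table(file.path(runDir, "integrated_genes.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  elem <- utils::read.table(file.path(runDir, "dmr_element_counts.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  list(dmrCounts = dmrCounts,
       elementCounts = elem,
       coreSizes = c(hypo = sum(core$direction == "hypo"),
                     hyper = sum(core$direction == "hyper")),
       integratedGenes = list(
         hypo_up = integ$gene_id[integ$class == "hypo_up"],
         hyper_down = integ$gene_id[integ$class == "hyper_down"]))
}
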