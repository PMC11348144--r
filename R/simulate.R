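#' Default planted-DMR specification
#'
#' Twenty hypomethylated blocks in repeats and ten hypermethylated blocks in
#' introns shared by all tumors (the core-signature backbone), plus twelve
#' promoter hypo blocks and eight promoter hyper blocks whose genes are
#' expression-coupled (hypo to up, hyper to down).
#'
#' @return data.frame with `element_class`, `direction`, `delta` (percentage
#'   points), `n_cpgs`, `presence` (`"all"`, `"kofn"` such as `"6of7"`, or a
#'   0/1 mask), `coupled`.
#' @export
defaultPlantedDmrs <- function() {
  rbind(
    data.frame(element_class = "repeat", direction = "hypo", delta = -30,
               n_cpgs = 6L, presence = "all", coupled = FALSE)[rep(1, 20), ],
    data.frame(element_class = "intron", direction = "hyper", delta = 30,
               n_cpgs = 6L, presence = "all", coupled = FALSE)[rep(1, 10), ],
    data.frame(element_class = "promoter", direction = "hypo", delta = -40,
               n_cpgs = 8L, presence = "all", coupled = TRUE)[rep(1, 12), ],
    data.frame(element_class = "promoter", direction = "hyper", delta = 40,
               n_cpgs = 8L, presence = "all", coupled = TRUE)[rep(1, 8), ],
    make.row.names = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: a miniature multi-chromosome
#' genome with a gene/element annotation, bimodal background CpG methylation
#' (most CpGs highly methylated), per-CpG binomial read sampling at
#' Poisson coverage (floored at 5x), planted hypo/hyper DMR blocks in chosen
#' genomic elements with per-tumor presence patterns, and negative-binomial
#' expression with a planted fold-change list plus genes whose expression
#' change is coupled to their planted promoter methylation change.
#'
#' @param seed RNG seed; the three generator stages use `seed`, `seed + 1`,
#'   `seed + 2` so each is independently reproducible.
#' @param nChroms,chromLength genome shape (default 2 x 300 kb).
#' @param cpgSpacing mean background CpG spacing in bp (exponential gaps).
#' @param islandSpacing CpG spacing inside promoter islands in bp.
#' @param nGenes number of genes (TSS records).
#' @param nControls,nTumors methylome sample counts.
#' @param coverageMean Poisson mean read coverage per CpG (min 5 enforced).
#' @param mixWeightHigh weight of the high-methylation Beta mode.
#' @param betaHigh,betaLow shape parameters of the two Beta modes.
#' @param jitterSd per-sample per-CpG logit-normal noise SD.
#' @param repeatFraction target fraction of the genome covered by repeats.
#' @param plantedDmrs planted-DMR data.frame (see [defaultPlantedDmrs()]).
#' @param exprControls expression control replicate count.
#' @param exprMeanLog,exprSdLog log-normal baseline expression parameters.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param coupledFcUp,coupledFcDown fold change applied to coupled genes in
#'   tumors carrying the planted promoter block.
#' @param nPlantedUp,nPlantedDown,plantedUpFc,plantedDownFc uncoupled
#'   universal differential-expression genes and their fold changes.
#' @param minPlantedBaseline minimum baseline mean for coupled and planted
#'   DE genes (truncated draw). Methylation-expression coupling is a
#'   property of expressed genes; planting fold changes on near-silent
#'   genes would simulate a signal the assay cannot carry.
#' @param noiseFree emit exact expected expression (FPKM units, no sampling)
#'   instead of negative-binomial counts.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L, nChroms = 2L, chromLength = 7.5e5L,
                      cpgSpacing = 100, islandSpacing = 30L, nGenes = 150L,
                      nControls = 5L, nTumors = 7L, coverageMean = 30,
                      mixWeightHigh = 0.7, betaHigh = c(8, 1),
                      betaLow = c(1, 8), jitterSd = 0.3,
                      repeatFraction = 0.2,
                      plantedDmrs = defaultPlantedDmrs(),
                      exprControls = 4L, exprMeanLog = log(100),
                      exprSdLog = 1, dispersion = 0.1,
                      coupledFcUp = 4, coupledFcDown = 0.25,
                      nPlantedUp = 15L, nPlantedDown = 5L,
                      plantedUpFc = 3, plantedDownFc = 1 / 3,
                      minPlantedBaseline = 50,
                      noiseFree = FALSE) {
  cfg <- as.list(environment())
  stopifnot(mixWeightHigh >= 0, mixWeightHigh <= 1, coverageMean > 0,
            nControls >= 1, nTumors >= 1)
  if (!is.null(plantedDmrs) && nrow(plantedDmrs)) {
    stopifnot(all(plantedDmrs$direction %in% c("hypo", "hyper")),
              all(abs(plantedDmrs$delta) <= 100))
  }
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate the genome annotation
#'
#' Lays out `nGenes` gene models (each with a TSS of random strand, a gene
#' body and 2-4 exons; introns are the body minus the exons), one enhancer
#' per inter-gene slot, and random 500-bp repeat intervals until the target
#' genome fraction is covered. Deterministic given the config seed.
#'
#' @param config a [simConfig()].
#' @return list with `annotation` (an [AnnotationSet-class] whose element
#'   classes are promoter, gene_body, exon, intron, enhancer, repeat) and
#'   `genes` (data.frame with `gene_id`, `chrom`, `tss_pos`, `strand`,
#'   `body_start`, `body_end`, `length_bp`).
#' @export
simulateAnnotation <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChroms))
  perChrom <- rep(config$nGenes %/% config$nChroms, config$nChroms)
  extra <- config$nGenes %% config$nChroms
  if (extra) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  genes <- NULL
  exons <- NULL
  enh <- NULL
  gid <- 0L
  for (ci in seq_along(chroms)) {
    g <- perChrom[ci]
    if (!g) next
    slotW <- config$chromLength %/% g
    maxBody <- min(7000L, slotW - 2600L)
    for (k in seq_len(g)) {
      gid <- gid + 1L
      bodyW <- round(stats::runif(1, 3000, maxBody))
      off <- 2000L + round(stats::runif(1, 0, slotW - bodyW - 2100L))
      bs <- (k - 1L) * slotW + off
      be <- bs + bodyW - 1L
      str <- sample(c("+", "-"), 1L)
      tss <- if (str == "+") bs else be
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("gene%03d", gid), chrom = chroms[ci],
        tss_pos = tss, strand = str, body_start = bs, body_end = be,
        length_bp = bodyW))
      nEx <- sample(2:4, 1L)
      chunk <- bodyW %/% nEx
      for (e in seq_len(nEx)) {
        es <- bs + (e - 1L) * chunk
        ew <- round(chunk * stats::runif(1, 0.3, 0.6))
        exons <- rbind(exons, data.frame(
          chrom = chroms[ci], start = es, end = es + ew - 1L,
          gene_id = sprintf("gene%03d", gid)))
      }
      enhS <- k * slotW - 800L
      if (enhS + 499L < config$chromLength)
        enh <- rbind(enh, data.frame(chrom = chroms[ci], start = enhS,
                                     end = enhS + 499L))
    }
  }
  # random non-overlapping 500 bp repeats up to the target genome fraction
  genomeBp <- as.numeric(config$nChroms) * config$chromLength
  target <- config$repeatFraction * genomeBp
  reps <- list()
  placed <- 0
  occ <- lapply(chroms, function(x) integer())
  names(occ) <- chroms
  tries <- 0L
  while (placed < target && tries < 1e5L) {
    tries <- tries + 1L
    cc <- sample(chroms, 1L)
    s <- sample.int(config$chromLength - 500L, 1L)
    bin <- s %/% 500L
    if (bin %in% occ[[cc]] || (bin + 1L) %in% occ[[cc]]) next
    occ[[cc]] <- c(occ[[cc]], bin, bin + 1L)
    reps[[length(reps) + 1L]] <- data.frame(chrom = cc, start = s,
                                            end = s + 499L)
    placed <- placed + 500
  }
  reps <- do.call(rbind, reps)
  tssGr <- GRanges(genes$chrom, IRanges(genes$tss_pos, width = 1L),
                   strand = genes$strand, gene_id = genes$gene_id)
  bodyGr <- GRanges(genes$chrom, IRanges(genes$body_start, genes$body_end),
                    strand = genes$strand, gene_id = genes$gene_id)
  exonGr <- GRanges(exons$chrom, IRanges(exons$start, exons$end),
                    gene_id = exons$gene_id)
  intronGr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(bodyGr, ignore.strand = TRUE),
    GenomicRanges::reduce(exonGr, ignore.strand = TRUE),
    ignore.strand = TRUE)
  promGr <- makePromoters(tssGr)
  mcols(promGr)$element_class <- NULL
  addClass <- function(gr, cl) { mcols(gr)$element_class <- cl; gr }
  ann <- AnnotationSet(
    elements = list(
      promoter = addClass(promGr, "promoter"),
      gene_body = addClass(bodyGr, "gene_body"),
      exon = addClass(exonGr, "exon"),
      intron = addClass(intronGr, "intron"),
      enhancer = addClass(GRanges(enh$chrom,
                                  IRanges(enh$start, enh$end)), "enhancer"),
      "repeat" = addClass(GRanges(reps$chrom,
                                  IRanges(reps$start, reps$end)), "repeat")),
    tss = tssGr)
  list(annotation = ann, genes = genes)
}

parsePresence <- function(presence, tumorIds) {
  n <- length(tumorIds)
  if (presence == "all") return(tumorIds)
  if (grepl("^[01]+$", presence)) {
    stopifnot(nchar(presence) == n)
    return(tumorIds[strsplit(presence, "")[[1]] == "1"])
  }
  m <- regmatches(presence, regexec("^([0-9]+)of([0-9]+)$", presence))[[1]]
  if (length(m) == 3L) {
    k <- as.integer(m[2L])
    stopifnot(as.integer(m[3L]) == n, k <= n)
    return(sample(tumorIds, k))
  }
  stop("unrecognized presence pattern: ", presence)
}

clampP <- function(p) pmin(pmax(p, 0.001), 0.999)

#' Simulate control and tumor methylomes with planted DMRs
#'
#' Background CpGs are laid down with exponential spacing plus dense CpG
#' islands inside promoter windows; each CpG gets a latent methylation level
#' from a two-component Beta mixture (high mode dominant, mirroring the
#' bimodal genome-wide distribution). Planted blocks override the latent
#' level to a regime that keeps the shifted value inside [0, 1] and are laid
#' at 40-bp CpG spacing inside their target element (DMRs are detectable
#' only where CpG density permits, so planted blocks sit in locally
#' CpG-dense segments). Every sample draws per-CpG logit-normal jitter;
#' tumors additionally shift by the planted delta where the block is present
#' in that tumor. Observed counts are Binomial(coverage, level) with
#' coverage Poisson(coverageMean) floored at 5.
#'
#' @param config a [simConfig()].
#' @param ann output of [simulateAnnotation()].
#' @return list with `controls` and `tumors` (lists of [Methylome-class]),
#'   and `truth` (data.frame per planted block: `chrom`, `start`, `end`,
#'   `direction`, `delta`, `element_class`, `gene_id`, `tumors`).
#' @export
simulateMethylomes <- function(config, ann) {
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$nChroms))
  tumorIds <- paste0("T", seq_len(config$nTumors))
  controlIds <- paste0("C", seq_len(config$nControls))
  # background CpG grid
  pos <- lapply(chroms, function(cc) {
    n <- ceiling(config$chromLength / max(config$cpgSpacing, 2) * 1.6)
    gaps <- pmax(2L, round(stats::rexp(n, 1 / config$cpgSpacing)))
    p <- cumsum(c(10L, gaps))
    p[p <= config$chromLength - 1L]
  })
  names(pos) <- chroms
  proms <- elementClasses(ann$annotation)[["promoter"]]
  for (i in seq_along(proms)) {
    cc <- as.character(seqnames(proms[i]))
    isl <- seq(start(proms[i]) + 5L, end(proms[i]), by = config$islandSpacing)
    pos[[cc]] <- c(pos[[cc]], isl)
  }
  # planted blocks: pick target intervals and densify CpGs inside them
  truth <- NULL
  planted <- config$plantedDmrs
  usedProm <- character()
  usedIv <- list()
  if (!is.null(planted) && nrow(planted)) {
    for (b in seq_len(nrow(planted))) {
      cl <- planted$element_class[b]
      k <- planted$n_cpgs[b]
      span <- 40L * (k - 1L)
      if (cl == "promoter") {
        avail <- setdiff(mcols(proms)$gene_id, usedProm)
        if (!length(avail)) stop("not enough promoters for planted blocks")
        gidx <- match(sample(avail, 1L), mcols(proms)$gene_id)
        usedProm <- c(usedProm, mcols(proms)$gene_id[gidx])
        iv <- proms[gidx]
        geneId <- mcols(proms)$gene_id[gidx]
      } else {
        ivs <- elementClasses(ann$annotation)[[cl]]
        wideEnough <- which(width(ivs) >= span + 20L)
        wideEnough <- setdiff(wideEnough, unlist(usedIv[[cl]]))
        if (!length(wideEnough))
          stop("no free ", cl, " interval wide enough for a planted block")
        pick <- sample(wideEnough, 1L)
        usedIv[[cl]] <- c(usedIv[[cl]], pick)
        iv <- ivs[pick]
        geneId <- NA_character_
      }
      cc <- as.character(seqnames(iv))
      bstart <- start(iv) + 10L
      bpos <- bstart + 40L * (0:(k - 1L))
      pos[[cc]] <- c(pos[[cc]], bpos)
      truth <- rbind(truth, data.frame(
        chrom = cc, start = min(bpos), end = max(bpos),
        direction = planted$direction[b], delta = planted$delta[b],
        n_cpgs = k, element_class = cl, gene_id = geneId,
        coupled = planted$coupled[b],
        tumors = paste(parsePresence(planted$presence[b], tumorIds),
                       collapse = ",")))
    }
  }
  pos <- lapply(pos, function(p) sort(unique(p)))
  allGr <- GRanges(rep(chroms, lengths(pos)),
                   IRanges(unlist(pos, use.names = FALSE), width = 1L))
  nC <- length(allGr)
  # latent background methylation: bimodal Beta mixture
  isHigh <- stats::runif(nC) < config$mixWeightHigh
  mu0 <- ifelse(isHigh,
                stats::rbeta(nC, config$betaHigh[1L], config$betaHigh[2L]),
                stats::rbeta(nC, config$betaLow[1L], config$betaLow[2L]))
  # planted CpGs get a baseline that keeps mu + delta inside [0, 1]
  shift <- rep(0, nC)
  inBlock <- rep(FALSE, nC)
  blockTumors <- vector("list", nC)
  if (!is.null(truth)) for (b in seq_len(nrow(truth))) {
    hit <- which(as.character(seqnames(allGr)) == truth$chrom[b] &
                   start(allGr) >= truth$start[b] &
                   start(allGr) <= truth$end[b])
    mu0[hit] <- if (truth$direction[b] == "hypo")
      stats::runif(length(hit), 0.65, 0.95) else
      stats::runif(length(hit), 0.05, 0.35)
    shift[hit] <- truth$delta[b] / 100
    inBlock[hit] <- TRUE
    tl <- strsplit(truth$tumors[b], ",")[[1L]]
    for (h in hit) blockTumors[[h]] <- tl
  }
  drawSample <- function(id, group, mu) {
    eps <- stats::rnorm(nC, 0, config$jitterSd)
    m <- stats::plogis(stats::qlogis(clampP(mu)) + eps)
    cov <- pmax(stats::rpois(nC, config$coverageMean), 5L)
    meth <- stats::rbinom(nC, cov, m)
    gr <- allGr
    mcols(gr) <- DataFrame(meth = meth, unmeth = cov - meth)
    Methylome(id, group, gr)
  }
  controls <- lapply(controlIds, drawSample, group = "control", mu = mu0)
  names(controls) <- controlIds
  tumors <- lapply(tumorIds, function(tid) {
    mu <- mu0
    if (any(inBlock)) {
      present <- vapply(blockTumors, function(z)
        !is.null(z) && tid %in% z, TRUE)
      idx <- inBlock & present
      mu[idx] <- clampP(mu0[idx] + shift[idx])
    }
    drawSample(tid, "tumor", mu)
  })
  names(tumors) <- tumorIds
  list(controls = controls, tumors = tumors, truth = truth)
}

#' Simulate the expression matrix with planted and coupled fold changes
#'
#' Baseline per-gene means are log-normal; control columns draw
#' NB(mean, dispersion) counts and tumor columns NB(mean x FC). Coupled
#' genes (those carrying a planted promoter DMR flagged `coupled`) receive
#' the configured up/down fold change exactly in the tumors where the block
#' is present, so the expression change tracks the methylation change gene
#' by gene. In noise-free mode the exact expected abundances are returned as
#' FPKM with no sampling.
#'
#' @param config a [simConfig()].
#' @param ann output of [simulateAnnotation()].
#' @param methTruth `truth` component of [simulateMethylomes()] (NULL for an
#'   uncoupled simulation).
#' @return list with `se` (`SummarizedExperiment`; assay `counts` with
#'   `rowData$length`, or assay `fpkm` in noise-free mode), `fcTruth`
#'   (genes x tumors matrix of true fold changes) and `deTruth` (data.frame
#'   of planted uncoupled DE genes with their class).
#' @export
simulateExpression <- function(config, ann, methTruth = NULL) {
  set.seed(config$seed + 2L)
  genes <- ann$genes
  nG <- nrow(genes)
  tumorIds <- paste0("T", seq_len(config$nTumors))
  ctrlIds <- paste0("EC", seq_len(config$exprControls))
  baseline <- stats::rlnorm(nG, config$exprMeanLog, config$exprSdLog)
  fc <- matrix(1, nG, length(tumorIds),
               dimnames = list(genes$gene_id, tumorIds))
  coupledGenes <- character()
  if (!is.null(methTruth)) {
    ct <- methTruth[methTruth$coupled & !is.na(methTruth$gene_id), ,
                    drop = FALSE]
    for (b in seq_len(nrow(ct))) {
      tl <- strsplit(ct$tumors[b], ",")[[1L]]
      f <- if (ct$direction[b] == "hypo") config$coupledFcUp else
        config$coupledFcDown
      fc[ct$gene_id[b], tl] <- f
      coupledGenes <- c(coupledGenes, ct$gene_id[b])
    }
  }
  free <- setdiff(genes$gene_id, coupledGenes)
  nUp <- min(config$nPlantedUp, length(free))
  upGenes <- if (nUp) sample(free, nUp) else character()
  free <- setdiff(free, upGenes)
  nDown <- min(config$nPlantedDown, length(free))
  downGenes <- if (nDown) sample(free, nDown) else character()
  fc[upGenes, ] <- config$plantedUpFc
  fc[downGenes, ] <- config$plantedDownFc
  # planted effects live on expressed genes: truncated baseline draw
  plantedIdx <- match(unique(c(coupledGenes, upGenes, downGenes)),
                      genes$gene_id)
  low <- plantedIdx[baseline[plantedIdx] < config$minPlantedBaseline]
  if (length(low)) {
    p0 <- stats::plnorm(config$minPlantedBaseline, config$exprMeanLog,
                        config$exprSdLog)
    baseline[low] <- if (p0 > 0.999) config$minPlantedBaseline else
      stats::qlnorm(stats::runif(length(low), p0, 1), config$exprMeanLog,
                    config$exprSdLog)
  }
  deTruth <- rbind(
    if (length(upGenes)) data.frame(gene_id = upGenes, class = "up",
                                    fc = config$plantedUpFc),
    if (length(downGenes)) data.frame(gene_id = downGenes, class = "down",
                                      fc = config$plantedDownFc))
  mu <- cbind(matrix(baseline, nG, length(ctrlIds),
                     dimnames = list(genes$gene_id, ctrlIds)),
              baseline * fc)
  grp <- c(rep("control", length(ctrlIds)), rep("tumor", length(tumorIds)))
  if (config$noiseFree) {
    se <- SummarizedExperiment(
      assays = list(fpkm = mu),
      colData = DataFrame(group = grp, row.names = colnames(mu)))
  } else {
    size <- 1 / config$dispersion
    cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = size),
                  nG, ncol(mu), dimnames = dimnames(mu))
    se <- SummarizedExperiment(
      assays = list(counts = cnt),
      colData = DataFrame(group = grp, row.names = colnames(mu)))
    SummarizedExperiment::rowData(se)$length <- genes$length_bp
  }
  list(se = se, fcTruth = fc, deTruth = deTruth)
}

#' Run the full synthetic study
#'
#' Annotation, methylomes and expression in sequence under one seed; when
#' `outDir` is given, all standard files (cytosine reports, annotation
#' TSV/BEDs, the counts table and the truth tables) are written there.
#'
#' @param config a [simConfig()].
#' @param outDir optional output directory.
#' @return list with `annotation`, `genes`, `controls`, `tumors`,
#'   `methTruth`, `expression` (the `SummarizedExperiment`), `fcTruth`,
#'   `deTruth`, and `config`.
#' @export
simulateStudy <- function(config = simConfig(), outDir = NULL) {
  ann <- simulateAnnotation(config)
  meth <- simulateMethylomes(config, ann)
  expr <- simulateExpression(config, ann, meth$truth)
  res <- list(annotation = ann$annotation, genes = ann$genes,
              controls = meth$controls, tumors = meth$tumors,
              methTruth = meth$truth, expression = expr$se,
              fcTruth = expr$fcTruth, deTruth = expr$deTruth,
              config = config)
  if (!is.null(outDir)) writeStudy(res, outDir)
  res
}

grToBed <- function(gr, path, name = NULL) {
  d <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                  end = end(gr),
                  name = if (is.null(name)) "." else name,
                  score = 0L,
                  strand = ifelse(as.character(strand(gr)) == "*", ".",
                                  as.character(strand(gr))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits Bismark-dialect cytosine reports per sample, a TSS table, one BED
#' per element class, the expression table and the truth tables.
#'
#' @param study output of [simulateStudy()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeStudy <- function(study, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (m in c(study$controls, study$tumors))
    writeCytosineReport(m, file.path(outDir,
                                     paste0(sampleId(m), ".CpG_report.txt")))
  tss <- annotationTss(study$annotation)
  utils::write.table(
    data.frame(gene_id = mcols(tss)$gene_id,
               chrom = as.character(seqnames(tss)), pos = start(tss),
               strand = as.character(strand(tss))),
    file.path(outDir, "tss.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  els <- elementClasses(study$annotation)
  for (cl in names(els))
    grToBed(els[[cl]], file.path(outDir, paste0(cl, ".bed")),
            name = if (!is.null(mcols(els[[cl]])$gene_id))
              mcols(els[[cl]])$gene_id else NULL)
  se <- study$expression
  unit <- names(SummarizedExperiment::assays(se))[1L]
  m <- SummarizedExperiment::assay(se, unit)
  d <- data.frame(gene_id = rownames(m), check.names = FALSE)
  if (!is.null(SummarizedExperiment::rowData(se)$length))
    d$length <- SummarizedExperiment::rowData(se)$length
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  utils::write.table(d, file.path(outDir, paste0(unit, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$methTruth))
    utils::write.table(study$methTruth,
                       file.path(outDir, "truth_dmrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(study$fcTruth), study$fcTruth,
               check.names = FALSE),
    file.path(outDir, "truth_fc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(outDir)
}
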