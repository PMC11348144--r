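dmrlinkVersion <- function() as.character(utils::packageVersion("dmrlink"))

outputHeader <- function(what, params = character()) {
  paste0("# dmrlink ", dmrlinkVersion(), " ", what,
         if (length(params)) paste0(" | ", paste(names(params), params,
                                                 sep = "=", collapse = " ")))
}

#' Read a per-CpG methylation call file
#'
#' Parses either a Bismark-style cytosine report (7 tab-separated columns:
#' chrom, 1-based position, strand, methylated count, unmethylated count,
#' context, trinucleotide) or a 6-column methylation bedGraph with counts
#' (chrom, 0-based start, end, percent, methylated count, unmethylated
#' count). The dialect is auto-detected from the column count. Only
#' CpG-context sites are kept; symmetric-CpG strand merging (on by default)
#' sums the plus-strand cytosine at position p with the minus-strand cytosine
#' at p+1 and reports the merged site at the plus-strand position. The
#' coverage filter is applied after merging when merging is on.
#'
#' @param path file path.
#' @param minCoverage minimum read coverage per retained site (default 5).
#' @param mergeStrands merge symmetric CpG strand pairs before filtering
#'   (default TRUE).
#' @param sampleId sample identifier; default the file base name.
#' @param group `"control"` or `"tumor"` (default `"tumor"`).
#' @return a [Methylome-class].
#' @export
readCytosineReport <- function(path, minCoverage = 5L, mergeStrands = TRUE,
                               sampleId = sub("\\.[^.]*$", "", basename(path)),
                               group = "tumor") {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  nf <- nf[!is.na(nf)]
  if (!length(nf)) stop("empty file: ", path)
  ncol <- nf[1L]
  bad <- which(nf != ncol)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path,
         ": expected ", ncol, " fields, found ", nf[bad[1L]])
  if (!ncol %in% c(6L, 7L))
    stop("unrecognized dialect in ", path, ": ", ncol,
         " columns (expected 7 for cytosine report, 6 for bedGraph+counts)")
  if (ncol == 7L) {
    d <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                           col.names = c("chrom", "pos", "strand", "meth",
                                         "unmeth", "context", "tri"),
                           colClasses = c("character", "integer", "character",
                                          "integer", "integer", "character",
                                          "character"))
    known <- d$context %in% c("CpG", "CG", "CHG", "CHH", "CN", "Unknown")
    if (any(!known))
      message(sum(!known), " line(s) with unknown context skipped")
    keep <- d$context %in% c("CpG", "CG") & known
    d <- d[keep, , drop = FALSE]
  } else {
    d <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                           col.names = c("chrom", "start", "end", "pct",
                                         "meth", "unmeth"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
    # bedGraph dialects are already strand-collapsed; positions 0-based
    d <- data.frame(chrom = d$chrom, pos = d$start + 1L, strand = "+",
                    meth = d$meth, unmeth = d$unmeth)
  }
  if (any(is.na(d$pos)) || any(is.na(d$meth)) || any(is.na(d$unmeth)))
    stop("malformed numeric field in ", path)
  if (mergeStrands) {
    # symmetric CpG: minus-strand C at p pairs with plus-strand C at p-1
    ppos <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
    key <- paste(d$chrom, ppos)
    meth <- rowsum(d$meth, key, reorder = FALSE)
    unmeth <- rowsum(d$unmeth, key, reorder = FALSE)
    first <- !duplicated(key)
    d <- data.frame(chrom = d$chrom[first], pos = ppos[first],
                    meth = as.integer(meth[, 1L]),
                    unmeth = as.integer(unmeth[, 1L]))
  }
  cov <- d$meth + d$unmeth
  d <- d[cov >= minCoverage, , drop = FALSE]
  if (is.unsorted(order(d$chrom, d$pos))) {
    warning("input positions not sorted; sorting internally")
  }
  gr <- GRanges(d$chrom, IRanges(d$pos, width = 1L),
                meth = d$meth, unmeth = d$unmeth)
  Methylome(sampleId, group, gr)
}

#' Write a Methylome as a Bismark-style cytosine report
#'
#' Emits the 7-column strand-merged dialect (strand `+`, context `CpG`)
#' that [readCytosineReport()] reads back.
#'
#' @param x a [Methylome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCytosineReport <- function(x, path) {
  s <- methSites(x)
  d <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                  strand = "+", meth = mcols(s)$meth,
                  unmeth = mcols(s)$unmeth, context = "CpG", tri = "CGN")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file as element intervals
#'
#' BED is 0-based half-open; intervals are converted to the 1-based inclusive
#' convention of `GRanges` at this boundary. BED3 lines get strand `*`.
#'
#' @param path file path.
#' @param elementClass element class label attached to every interval
#'   (e.g. `"promoter"`, `"repeat"`).
#' @return a `GRanges` with metadata columns `name` and `element_class`.
#' @export
readRegionBed <- function(path, elementClass) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  if (!length(nf)) {
    return(GRanges(name = character(), element_class = character()))
  }
  ncol <- min(nf)
  d <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                         fill = TRUE, stringsAsFactors = FALSE)
  if (ncol < 3L) stop("BED file needs at least 3 columns: ", path)
  starts <- suppressWarnings(as.integer(d[[2L]]))
  ends <- suppressWarnings(as.integer(d[[3L]]))
  if (any(is.na(starts)) || any(is.na(ends)))
    stop("malformed coordinate at line ",
         which(is.na(starts) | is.na(ends))[1L], " in ", path)
  bad <- which(starts >= ends)
  if (length(bad))
    stop("empty or inverted interval at line ", bad[1L], " in ", path,
         " (start >= end)")
  nm <- if (ncol(d) >= 4L) as.character(d[[4L]]) else
    paste0(elementClass, "_", seq_len(nrow(d)))
  str <- if (ncol(d) >= 6L) ifelse(d[[6L]] %in% c("+", "-"),
                                   as.character(d[[6L]]), "*") else "*"
  GRanges(d[[1L]], IRanges(starts + 1L, ends), strand = str,
          name = nm, element_class = elementClass)
}

#' Read an expression table
#'
#' Tab-separated with a header; first column gene id; an optional `length`
#' column gives transcript lengths in bp. Remaining columns are samples.
#'
#' @param path file path.
#' @param groups named character vector mapping sample name to
#'   `"control"`/`"tumor"`; samples absent from the map are an error.
#' @param unit `"counts"` or `"fpkm"`.
#' @return a `SummarizedExperiment` with one assay named after `unit`,
#'   `colData$group`, and `rowData$length` when lengths are present.
#' @export
readExpressionTable <- function(path, groups, unit = c("counts", "fpkm")) {
  unit <- match.arg(unit)
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  gene <- as.character(d[[1L]])
  dup <- gene[duplicated(gene)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  d <- d[, -1L, drop = FALSE]
  lens <- NULL
  if ("length" %in% names(d)) {
    lens <- as.numeric(d[["length"]])
    d <- d[, names(d) != "length", drop = FALSE]
    if (any(is.na(lens)) || any(lens <= 0))
      stop("gene lengths must be positive")
  }
  m <- as.matrix(d)
  if (any(is.na(m))) stop("missing expression values are not allowed")
  if (any(m < 0)) stop("negative expression values are not allowed")
  rownames(m) <- gene
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  grp <- unname(groups[colnames(m)])
  if (!all(grp %in% c("control", "tumor")))
    stop("groups must be 'control' or 'tumor'")
  rd <- if (is.null(lens)) NULL else DataFrame(length = lens)
  se <- SummarizedExperiment(
    assays = setNames(list(m), unit),
    colData = DataFrame(group = grp, row.names = colnames(m)))
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  se
}

#' Write DMRs as BED6+3
#'
#' Columns: chrom, 0-based start, half-open end, `sample:direction`,
#' `round(|mean delta|)` score, strand `.`, then `n_cpgs`, `mean_delta`,
#' `p_value`. Rows are ordered by (chrom, start). A commented header line
#' records the tool version.
#'
#' @param dmrs a `GRanges` as returned by [callSampleDmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader("DMR BED",
                          c(columns = "chrom,start,end,name,score,strand,n_cpgs,mean_delta,p_value")),
             con)
  if (length(dmrs)) {
    o <- order(as.character(seqnames(dmrs)), start(dmrs))
    dmrs <- dmrs[o]
    mc <- mcols(dmrs)
    d <- data.frame(chrom = as.character(seqnames(dmrs)),
                    start = start(dmrs) - 1L, end = end(dmrs),
                    name = paste0(mc$sample_id, ":", mc$direction),
                    score = round(abs(mc$mean_delta)), strand = ".",
                    n_cpgs = mc$n_cpgs, mean_delta = mc$mean_delta,
                    p_value = mc$p_value)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read DMRs written by [writeDmrBed()]
#'
#' @param path file path.
#' @return a `GRanges` with `sample_id`, `direction`, `n_cpgs`, `mean_delta`,
#'   `p_value`.
#' @export
readDmrBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(GRanges(sample_id = character(), direction = character(),
                   n_cpgs = integer(), mean_delta = numeric(),
                   p_value = numeric()))
  d <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  nm <- strsplit(d[[4L]], ":", fixed = TRUE)
  GRanges(d[[1L]], IRanges(d[[2L]] + 1L, d[[3L]]),
          sample_id = vapply(nm, `[`, "", 1L),
          direction = vapply(nm, `[`, "", 2L),
          n_cpgs = as.integer(d[[7L]]), mean_delta = as.numeric(d[[8L]]),
          p_value = as.numeric(d[[9L]]))
}
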