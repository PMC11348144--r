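#' Accessors for dmrlink classes
#'
#' `sampleId()`, `sampleGroup()` and `methSites()` extract the identifier,
#' group label and CpG site ranges of a [Methylome-class]. `profileSites()`,
#' `controlPct()` and `controlIds()` access a [ControlProfile-class].
#' `elementClasses()` and `annotationTss()` access an [AnnotationSet-class].
#'
#' @param object a dmrlink S4 object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("sampleGroup", function(object) standardGeneric("sampleGroup"))
#' @rdname accessors
#' @export
setGeneric("methSites", function(object) standardGeneric("methSites"))
#' @rdname accessors
#' @export
setGeneric("profileSites", function(object) standardGeneric("profileSites"))
#' @rdname accessors
#' @export
setGeneric("controlPct", function(object) standardGeneric("controlPct"))
#' @rdname accessors
#' @export
setGeneric("controlIds", function(object) standardGeneric("controlIds"))
#' @rdname accessors
#' @export
setGeneric("elementClasses", function(object) standardGeneric("elementClasses"))
#' @rdname accessors
#' @export
setGeneric("annotationTss", function(object) standardGeneric("annotationTss"))

#' @rdname accessors
setMethod("sampleId", "Methylome", function(object) object@sampleId)
#' @rdname accessors
setMethod("sampleGroup", "Methylome", function(object) object@group)
#' @rdname accessors
setMethod("methSites", "Methylome", function(object) object@sites)
#' @rdname accessors
setMethod("profileSites", "ControlProfile", function(object) object@sites)
#' @rdname accessors
setMethod("controlPct", "ControlProfile", function(object) object@pct)
#' @rdname accessors
setMethod("controlIds", "ControlProfile", function(object) object@sampleIds)
#' @rdname accessors
setMethod("elementClasses", "AnnotationSet", function(object) object@elements)
#' @rdname accessors
setMethod("annotationTss", "AnnotationSet", function(object) object@tss)

setMethod("show", "Methylome", function(object) {
  s <- object@sites
  cov <- mcols(s)$meth + mcols(s)$unmeth
  cat("Methylome '", object@sampleId, "' (", object@group, ")\n", sep = "")
  cat("  ", length(s), " CpG sites on ",
      length(unique(as.character(seqnames(s)))), " chromosome(s)\n", sep = "")
  if (length(s))
    cat("  median coverage ", stats::median(cov), ", mean methylation ",
        round(mean(100 * mcols(s)$meth / pmax(cov, 1L)), 1), "%\n", sep = "")
})

setMethod("show", "ControlProfile", function(object) {
  cat("ControlProfile over ", length(object@sampleIds), " control(s): ",
      paste(object@sampleIds, collapse = ", "), "\n", sep = "")
  cat("  ", length(object@sites), " CpG sites", sep = "")
  if (length(object@sites))
    cat(", mean methylation ",
        round(mean(mcols(object@sites)$mean_meth), 1), "%", sep = "")
  cat("\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@tss), "TSS records\n")
  for (cl in names(object@elements))
    cat("  ", cl, ": ", length(object@elements[[cl]]), " intervals\n",
        sep = "")
})
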