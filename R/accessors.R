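#' @name accessors
#' @title Accessors for gbsmap classes
#'
#' @description Small accessor family: `tags()`, `tagMeta()`,
#' `exclusions()` for [ReferenceTagSet-class]; `sampleNames()` for pileups
#' and SNP records; `snpInfo()`, `refDepth()`, `altDepth()` for
#' [SnpRecords-class]; `calls()`, `markerNames()`, `markerQuality()` for
#' [GenotypeMatrix-class]; `mapTable()` for [GeneticMap-class];
#' `scanTable()` for [QtlScan-class].
#'
#' @param x An object of the documented class.
#' @return The slot contents named by each accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("tags", function(x) standardGeneric("tags"))
#' @rdname accessors
#' @export
setMethod("tags", "ReferenceTagSet", function(x) x@tags)

#' @rdname accessors
#' @export
setGeneric("tagMeta", function(x) standardGeneric("tagMeta"))
#' @rdname accessors
#' @export
setMethod("tagMeta", "ReferenceTagSet", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setMethod("exclusions", "ReferenceTagSet", function(x) x@exclusions)

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setMethod("sampleNames", "GbsPileup", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleNames", "SnpRecords", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setMethod("snpInfo", "SnpRecords", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))
#' @rdname accessors
#' @export
setMethod("refDepth", "SnpRecords", function(x) x@refDepth)

#' @rdname accessors
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))
#' @rdname accessors
#' @export
setMethod("altDepth", "SnpRecords", function(x) x@altDepth)

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname accessors
#' @export
setMethod("calls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setMethod("markerNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setGeneric("markerQuality", function(x) standardGeneric("markerQuality"))
#' @rdname accessors
#' @export
setMethod("markerQuality", "GenotypeMatrix", function(x) x@quality)

#' @rdname accessors
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))
#' @rdname accessors
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
#' @rdname accessors
#' @export
setMethod("scanTable", "QtlScan", function(x) x@table)

setMethod("show", "ReferenceTagSet", function(object) {
  cat(sprintf(
    "ReferenceTagSet: %d tags of %s bp (overhang %s), %d exclusions\n",
    length(object@tags),
    if (length(object@tags)) Biostrings::width(object@tags)[1L] else "?",
    object@overhang, nrow(object@exclusions)))
  src <- table(object@meta$source)
  if (length(src))
    cat("  sources:", paste(sprintf("%s=%d", names(src), src),
                            collapse = ", "), "\n")
})

setMethod("show", "TagIndex", function(object) {
  cat(sprintf("TagIndex: %d tags (%d bp), %d distinct sequences\n",
              length(object@tagIds), object@tagLen, nrow(object@seqTable)))
})

setMethod("show", "GbsPileup", function(object) {
  cat(sprintf(
    "GbsPileup: %d tags x %d samples, %.0f mapped reads, %d mismatch events\n",
    length(object@tagIds), length(object@samples), sum(object@reads),
    nrow(object@mismatches)))
})

setMethod("show", "SnpRecords", function(object) {
  pass <- if (nrow(object@info)) sum(object@info$filter == "") else 0L
  cat(sprintf("SnpRecords: %d candidate sites x %d samples (%d pass filters)\n",
              nrow(object@info), length(object@samples), pass))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cl <- object@calls
  cat(sprintf("GenotypeMatrix: %d markers x %d progeny (parents %s/%s)\n",
              nrow(cl), ncol(cl), object@parentA, object@parentB))
  if (length(cl))
    cat(sprintf("  missing %.1f%%, het %.2f%%\n",
                100 * mean(is.na(cl)), 100 * mean(cl == "h", na.rm = TRUE)))
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneticMap: %d markers in %d groups, %d isolated\n",
              nrow(tb), length(unique(tb$group)), length(object@isolated)))
  if (nrow(tb)) {
    len <- tapply(tb$cM, tb$group, max)
    cat(sprintf("  total length %.1f cM\n", sum(len)))
  }
})

setMethod("show", "QtlScan", function(object) {
  tb <- object@table
  cat(sprintf("QtlScan (%s): %d positions, max LOD %.2f", object@kind,
              nrow(tb), if (nrow(tb)) max(tb$lod) else NA_real_))
  if (length(object@threshold) && !is.na(object@threshold))
    cat(sprintf(" (threshold %.2f)", object@threshold))
  cat("\n")
})
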