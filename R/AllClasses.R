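#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet vmatchPattern subseq width
#' @importFrom S4Vectors DataFrame
#' @importFrom data.table data.table setkey setkeyv := as.data.table rbindlist
#'   setnames
#' @importFrom stats pbinom pchisq quantile lm lm.fit anova rbinom rpois
#'   rmultinom runif rnorm setNames coef complete.cases cor median qlnorm
#'   sd var
#' @importFrom utils head read.table write.table tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib gbsmap, .registration = TRUE
NULL

setOldClass("data.table")

#' Reference tag set
#'
#' Fixed-length restriction-site flanking sequences ("tags") extracted from
#' one or more genome assemblies, the unit that GBS reads are mapped to.
#' Each tag is a strand-resolved flank of a restriction site (default PstI,
#' CTGCAG) beginning with the enzyme's 5' overhang (TGCAG), so tags are
#' directly comparable to barcode-stripped reads.
#'
#' @slot tags A [Biostrings::DNAStringSet] of equal-width tag sequences,
#'   named by tag id (`contig:position:direction`).
#' @slot meta A `data.frame` with one row per tag: `tag_id`, `contig`,
#'   `position` (0-based offset of the recognition motif), `direction`
#'   ("F"/"R") and `source` (assembly name).
#' @slot exclusions A `data.frame` of flanks that could not be emitted:
#'   `tag_id`, `reason` ("edge" or "ambiguous-base").
#' @slot overhang Single character string, the expected tag prefix.
#'
#' @seealso [buildReferenceTags()], [extractFlankTags()],
#'   [mergeAssemblies()], [screenChloroplast()]
#' @exportClass ReferenceTagSet
setClass("ReferenceTagSet",
  representation(
    tags = "DNAStringSet",
    meta = "data.frame",
    exclusions = "data.frame",
    overhang = "character"
  )
)

setValidity("ReferenceTagSet", function(object) {
  msg <- character()
  n <- length(object@tags)
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per tag")
  if (n > 0L) {
    if (anyDuplicated(names(object@tags)))
      msg <- c(msg, "tag ids must be unique")
    w <- unique(Biostrings::width(object@tags))
    if (length(w) > 1L)
      msg <- c(msg, "all tags must have the same length")
    oh <- object@overhang
    if (nchar(oh) > 0L) {
      pref <- substr(as.character(object@tags), 1L, nchar(oh))
      if (!all(pref == oh))
        msg <- c(msg, sprintf("every tag must begin with %s", oh))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Read-mapping index over a reference tag set
#'
#' Supports exact and single-mismatch end-to-end queries for fixed-length
#' reads via a pigeonhole split of each tag into two halves: a read with at
#' most one substitution matches at least one half exactly.
#'
#' @slot tagIds Character vector of tag ids.
#' @slot tagSeqs Character vector of tag sequences, parallel to `tagIds`.
#' @slot tagLen Integer tag length.
#' @slot seqTable `data.table` keyed by sequence: columns `seq`, `nIds`
#'   (number of tag ids sharing the sequence), `firstIdx`.
#' @slot halfTables List of two `data.table`s keyed by half-sequence,
#'   mapping each tag half to tag indices.
#'
#' @seealso [buildTagIndex()], [mapReads()]
#' @exportClass TagIndex
setClass("TagIndex",
  representation(
    tagIds = "character",
    tagSeqs = "character",
    tagLen = "integer",
    seqTable = "data.table",
    halfTables = "list"
  )
)

#' Per-sample allele pileup over reference tags
#'
#' Compact pileup for ungapped end-to-end mapping: because every mapped
#' read covers all positions of its tag, per-sample depth at every offset
#' equals the per-sample read count on the tag; only non-reference base
#' observations (at most one per read under the one-mismatch contract) are
#' stored explicitly.
#'
#' @slot samples Character vector of sample ids (column order).
#' @slot tagIds Character vector of tag ids (row order).
#' @slot tagSeqs Character vector of tag sequences, parallel to `tagIds`.
#' @slot reads Integer matrix (tags x samples) of mapped read counts.
#' @slot posQual Numeric matrix (tags x tag length) of summed base
#'   qualities over all mapped reads, all samples.
#' @slot mismatches `data.frame` of non-reference observations: `tag_id`,
#'   `offset` (0-based), `base`, `sample`, `count`, `qualsum`.
#'
#' @seealso [accumulatePileup()], [callCandidateSnps()]
#' @exportClass GbsPileup
setClass("GbsPileup",
  representation(
    samples = "character",
    tagIds = "character",
    tagSeqs = "character",
    reads = "matrix",
    posQual = "matrix",
    mismatches = "data.frame"
  )
)

#' Candidate SNP records with per-sample allele depths
#'
#' One row per biallelic candidate site on a reference tag, with parallel
#' per-sample reference/alternative depth matrices, population base-quality
#' summaries, a Phred-scaled site quality and the ordered filter ledger
#' flags accumulated by [applyFilterCascade()].
#'
#' @slot info `data.frame`: `tag_id`, `offset` (0-based within tag),
#'   `ref`, `alt`, `quality`, `multiallelic`, `mean_ref_baseq`,
#'   `mean_alt_baseq`, `filter` (semicolon-joined failed stages, "" = pass).
#' @slot refDepth,altDepth Integer matrices (sites x samples).
#' @slot altQualSum Numeric matrix (sites x samples) of summed alternative
#'   base qualities (per-sample mean alt quality = altQualSum/altDepth).
#' @slot samples Character vector of sample ids.
#'
#' @seealso [callCandidateSnps()], [applyFilterCascade()], [exportVcf()]
#' @exportClass SnpRecords
setClass("SnpRecords",
  representation(
    info = "data.frame",
    refDepth = "matrix",
    altDepth = "matrix",
    altQualSum = "matrix",
    samples = "character"
  )
)

setValidity("SnpRecords", function(object) {
  msg <- character()
  n <- nrow(object@info)
  for (s in c("refDepth", "altDepth", "altQualSum")) {
    m <- slot(object, s)
    if (nrow(m) != n || ncol(m) != length(object@samples))
      msg <- c(msg, sprintf("%s must be sites x samples", s))
  }
  if (n > 0L) {
    if (any(object@info$ref == object@info$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (any(object@refDepth < 0L) || any(object@altDepth < 0L))
      msg <- c(msg, "depths must be non-negative")
    if (any(object@info$quality < 0))
      msg <- c(msg, "site quality must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Parental-coded genotype matrix
#'
#' Markers x progeny matrix in biparental coding: `"a"` (parent-A
#' homozygote), `"b"` (parent-B homozygote), `"h"` (heterozygote) and `NA`
#' (missing). Parents themselves are not columns; by construction every
#' retained marker is `a` in parent A and `b` in parent B.
#'
#' @slot calls Character matrix (markers x progeny) over {"a","b","h",NA}.
#' @slot quality Numeric vector of per-marker quality scores.
#' @slot parentA,parentB Sample ids of the two parents.
#' @slot info `data.frame` of per-marker annotation (tag id, offset, ...).
#'
#' @seealso [recodeParental()], [buildGeneticMap()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    calls = "matrix",
    quality = "numeric",
    parentA = "character",
    parentB = "character",
    info = "data.frame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cl <- object@calls
  if (!is.character(cl)) msg <- c(msg, "calls must be a character matrix")
  bad <- !(cl %in% c("a", "b", "h") | is.na(cl))
  if (any(bad)) msg <- c(msg, "calls must be a/b/h or NA")
  if (length(object@quality) != nrow(cl))
    msg <- c(msg, "one quality per marker required")
  if (is.null(rownames(cl))) msg <- c(msg, "markers must be named")
  if (length(msg)) msg else TRUE
})

#' Genetic linkage map
#'
#' Ordered markers with cumulative centimorgan positions per linkage
#' group, together with the bookkeeping produced during map construction:
#' redundancy (co-segregation) groups, isolated markers, poor-fit
#' removals and a per-group summary ledger.
#'
#' @slot table `data.frame`: `group`, `marker`, `cM` (non-decreasing
#'   within group, starting at 0).
#' @slot redundancy Named list: representative marker -> character vector
#'   of collapsed co-segregating markers (possibly empty).
#' @slot isolated Character vector of markers in singleton groups.
#' @slot dropped `data.frame`: `marker`, `reason` for markers removed
#'   before or during mapping.
#' @slot ledger `data.frame` per-group summary (markers clustered, mapped,
#'   co-segregating), plus totals.
#'
#' @seealso [buildGeneticMap()], [assignCm()]
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(
    table = "data.frame",
    redundancy = "list",
    isolated = "character",
    dropped = "data.frame",
    ledger = "data.frame"
  )
)

setValidity("GeneticMap", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb)) {
    if (!all(c("group", "marker", "cM") %in% names(tb)))
      msg <- c(msg, "table needs group/marker/cM columns")
    else {
      dec <- tapply(tb$cM, tb$group, function(x) any(diff(x) < 0))
      if (any(unlist(dec)))
        msg <- c(msg, "cM must be non-decreasing within each group")
    }
  }
  if (length(msg)) msg else TRUE
})

#' QTL scan result
#'
#' LOD profile over a cM grid with per-position variance explained and
#' additive effect (b-class minus a-class mean difference) with its
#' standard error.
#'
#' @slot table `data.frame`: `group`, `cM`, `lod`, `varexp`, `effect`,
#'   `se`, `degenerate` (logical flag for zero-residual fits).
#' @slot threshold Numeric genome-wide LOD threshold used (NA if unset).
#' @slot n Integer number of lines used in the scan.
#' @slot kind Character label ("interval", "rmqm").
#'
#' @seealso [intervalScan()], [rmqmScan()], [permutationThreshold()],
#'   [supportInterval()]
#' @exportClass QtlScan
setClass("QtlScan",
  representation(
    table = "data.frame",
    threshold = "numeric",
    n = "integer",
    kind = "character"
  )
)
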