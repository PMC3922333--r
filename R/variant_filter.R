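#' Discover candidate biallelic SNPs from a pileup
#'
#' Scans every (tag, offset) where at least two base classes are observed
#' across the population. The reference allele is the tag base; the
#' alternative allele is the most frequent non-reference base
#' population-wide (ties broken alphabetically for determinism). A
#' candidate is emitted when the alternative allele is supported by at
#' least `min_alt_reads` reads in total; sites with more than two
#' observed alleles keep the top alternative and are flagged
#' multiallelic. The site quality is the Phred-scaled binomial tail
#' probability that all alternative-supporting reads arise from per-base
#' sequencing error at the rate implied by their mean base quality,
#' capped at 3000.
#'
#' @param pileup A [GbsPileup-class].
#' @param min_alt_reads Minimum population-wide alternative-allele read
#'   count (default 4, i.e. "greater than 3").
#' @return A [SnpRecords-class].
#' @export
callCandidateSnps <- function(pileup, min_alt_reads = 4L) {
  stopifnot(is(pileup, "GbsPileup"))
  samples <- pileup@samples
  empty <- new("SnpRecords",
               info = data.frame(tag_id = character(), offset = integer(),
                                 ref = character(), alt = character(),
                                 quality = numeric(), multiallelic = logical(),
                                 mean_ref_baseq = numeric(),
                                 mean_alt_baseq = numeric(),
                                 filter = character()),
               refDepth = matrix(0L, 0L, length(samples)),
               altDepth = matrix(0L, 0L, length(samples)),
               altQualSum = matrix(0, 0L, length(samples)),
               samples = samples)
  mm <- as.data.table(pileup@mismatches)
  if (!nrow(mm)) return(empty)

  tagTotal <- rowSums(pileup@reads)
  names(tagTotal) <- pileup@tagIds

  byBase <- mm[, list(n = sum(count), qs = sum(qualsum)),
               by = c("tag_id", "offset", "base")]
  bySite <- byBase[order(tag_id, offset, -n, base)][,
    list(nonref_total = sum(n), nonref_qs = sum(qs),
         alt = base[1L], alt_n = n[1L], alt_qs = qs[1L],
         n_bases = .N),
    by = c("tag_id", "offset")]
  bySite[, tag_total := tagTotal[tag_id]]
  bySite[, ref_total := tag_total - nonref_total]
  # at least two observed base classes and enough alt support
  bySite <- bySite[(ref_total > 0L) + n_bases >= 2L & alt_n >= min_alt_reads]
  if (!nrow(bySite)) return(empty)
  setkeyv(bySite, c("tag_id", "offset"))

  tagRow <- match(bySite$tag_id, pileup@tagIds)
  ref <- substr(pileup@tagSeqs[tagRow], bySite$offset + 1L, bySite$offset + 1L)
  posQ <- pileup@posQual[cbind(tagRow, bySite$offset + 1L)]
  mean_alt_q <- bySite$alt_qs / bySite$alt_n
  mean_ref_q <- ifelse(bySite$ref_total > 0,
                       (posQ - bySite$nonref_qs) / bySite$ref_total, NA)
  err <- 10^(-mean_alt_q / 10)
  logp <- pbinom(bySite$alt_n - 1L, bySite$tag_total, err,
                 lower.tail = FALSE, log.p = TRUE)
  quality <- pmin(-10 * logp / log(10), 3000)
  quality[!is.finite(quality)] <- 3000

  ns <- length(samples)
  key <- paste(bySite$tag_id, bySite$offset)
  siteRow <- match(paste(mm$tag_id, mm$offset), key)
  sampCol <- match(mm$sample, samples)
  inSite <- !is.na(siteRow)

  altDepth <- matrix(0L, nrow(bySite), ns)
  altQualSum <- matrix(0, nrow(bySite), ns)
  nonrefDepth <- matrix(0L, nrow(bySite), ns)
  isAlt <- inSite & mm$base == bySite$alt[siteRow]
  .acc <- function(m, rows, vals) {
    idx <- cbind(siteRow[rows], sampCol[rows])
    agg <- rowsum(vals, group = paste(idx[, 1L], idx[, 2L]))
    ij <- do.call(rbind, strsplit(rownames(agg), " "))
    m[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] <-
      m[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] + agg[, 1L]
    m
  }
  if (any(isAlt)) {
    altDepth <- .acc(altDepth, which(isAlt), mm$count[isAlt])
    altQualSum <- .acc(altQualSum, which(isAlt), mm$qualsum[isAlt])
  }
  if (any(inSite)) {
    nonrefDepth <- .acc(nonrefDepth, which(inSite), mm$count[inSite])
  }
  perSampleReads <- pileup@reads[tagRow, , drop = FALSE]
  colnames(perSampleReads) <- samples
  refDepth <- perSampleReads - nonrefDepth
  storage.mode(refDepth) <- "integer"
  storage.mode(altDepth) <- "integer"
  colnames(altDepth) <- colnames(altQualSum) <- samples

  info <- data.frame(
    tag_id = bySite$tag_id, offset = bySite$offset, ref = ref,
    alt = bySite$alt, quality = quality,
    multiallelic = (bySite$n_bases + (bySite$ref_total > 0L)) > 2L,
    mean_ref_baseq = mean_ref_q, mean_alt_baseq = mean_alt_q,
    filter = "", stringsAsFactors = FALSE)
  rownames(info) <- NULL
  new("SnpRecords", info = info, refDepth = refDepth, altDepth = altDepth,
      altQualSum = altQualSum, samples = samples)
}

#' @describeIn SnpRecords-class Subset sites by index.
#' @param x,i,j,...,drop Subsetting arguments (only `i` is used).
#' @export
setMethod("[", "SnpRecords", function(x, i, j, ..., drop = FALSE) {
  initialize(x, info = x@info[i, , drop = FALSE],
             refDepth = x@refDepth[i, , drop = FALSE],
             altDepth = x@altDepth[i, , drop = FALSE],
             altQualSum = x@altQualSum[i, , drop = FALSE],
             samples = x@samples)
})

.filterStages <- c("alt-fraction", "baseq-diff", "snp-quality", "coverage",
                   "het-percent", "alt-ref-ratio", "dominant",
                   "parent-missing")

#' Default filter-cascade thresholds
#'
#' @return Named list of the default thresholds applied by
#'   [applyFilterCascade()]: minimum population alternative-allele read
#'   fraction 0.1; maximum base-quality percentage difference 5; minimum
#'   site quality 20; minimum mean per-sample depth 5; maximum
#'   heterozygous-sample percentage 2; minimum alternative/reference
#'   ratio 0.5.
#' @export
defaultFilterThresholds <- function() {
  list(`alt-fraction` = 0.1, `baseq-diff` = 5, `snp-quality` = 20,
       `coverage` = 5, `het-percent` = 2, `alt-ref-ratio` = 0.5)
}

#' Apply the staged SNP filter cascade
#'
#' Stages, in order: (1) population alternative-allele read fraction at
#' least 0.1; (2) percentage difference between mean reference and
#' alternative base qualities at most 5, computed as
#' `|q_ref - q_alt| / max(q_ref, q_alt) * 100`; (3) site quality at least
#' 20; (4) total read coverage at least `coverage x n_samples` (mean of 5
#' reads per sample); (5) heterozygous samples at most 2% of the
#' population (provisional proportion-rule genotypes); (6) population
#' alternative/reference read-count ratio at least 0.5 (or alt:ref
#' homozygous sample-count ratio with `ratio_mode = "samples"`); (7)
#' dominant-marker removal: sites on tags where either parent has no
#' mapped reads at all; (8) sites where either parent's provisional
#' genotype is missing. Every stage is a pure predicate on the full
#' record set, so the surviving set is order-independent; only the
#' intermediate ledger counts depend on stage order.
#'
#' @param snps A [SnpRecords-class].
#' @param parent_a,parent_b Parent sample ids (required for stages 7-8;
#'   if `NULL` those stages pass everything).
#' @param tag_reads Optional tags x samples read-count matrix (rownames =
#'   tag ids) for the dominant stage; defaults from `pileup`.
#' @param pileup Optional [GbsPileup-class] supplying `tag_reads`.
#' @param thresholds Named list overriding [defaultFilterThresholds()];
#'   unknown stage names are a configuration error.
#' @param n_samples Population size used by the coverage and
#'   heterozygosity percentages (default: progeny count, i.e. samples
#'   minus parents).
#' @param ratio_mode `"reads"` (default) or `"samples"` for stage 6.
#' @return A list: `passed` ([SnpRecords-class] surviving all stages),
#'   `records` (all records, `filter` column updated with failed-stage
#'   labels), and `ledger` (`data.frame`: `stage`, `survivors`, starting
#'   from the candidate count).
#' @export
applyFilterCascade <- function(snps, parent_a = NULL, parent_b = NULL,
                               tag_reads = NULL, pileup = NULL,
                               thresholds = list(), n_samples = NULL,
                               ratio_mode = c("reads", "samples")) {
  stopifnot(is(snps, "SnpRecords"))
  ratio_mode <- match.arg(ratio_mode)
  th <- defaultFilterThresholds()
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown))
    stop("unknown filter stage in thresholds: ",
         paste(unknown, collapse = ", "))
  th[names(thresholds)] <- thresholds
  if (is.null(tag_reads) && !is.null(pileup)) {
    tag_reads <- pileup@reads
  }
  n <- nrow(snps@info)
  if (is.null(n_samples))
    n_samples <- length(setdiff(snps@samples, c(parent_a, parent_b)))

  popRef <- rowSums(snps@refDepth)
  popAlt <- rowSums(snps@altDepth)
  total <- popRef + popAlt
  states <- callGenotypes(snps)
  prog <- setdiff(snps@samples, c(parent_a, parent_b))

  fail <- list()
  fail[["alt-fraction"]] <- popAlt / pmax(total, 1L) < th[["alt-fraction"]]
  q_ref <- snps@info$mean_ref_baseq
  q_alt <- snps@info$mean_alt_baseq
  pdiff <- abs(q_ref - q_alt) / pmax(q_ref, q_alt) * 100
  fail[["baseq-diff"]] <- !is.na(pdiff) & pdiff > th[["baseq-diff"]]
  fail[["snp-quality"]] <- snps@info$quality < th[["snp-quality"]]
  fail[["coverage"]] <- total < th[["coverage"]] * n_samples
  hetn <- rowSums(states[, prog, drop = FALSE] == "het")
  fail[["het-percent"]] <- 100 * hetn / n_samples > th[["het-percent"]]
  if (ratio_mode == "reads") {
    fail[["alt-ref-ratio"]] <- popAlt / pmax(popRef, 1L) <
      th[["alt-ref-ratio"]]
  } else {
    nA <- rowSums(states == "hom_alt")
    nR <- rowSums(states == "hom_ref")
    fail[["alt-ref-ratio"]] <- nA / pmax(nR, 1L) < th[["alt-ref-ratio"]]
  }
  if (!is.null(parent_a) && !is.null(parent_b) && !is.null(tag_reads)) {
    pnull <- tag_reads[, parent_a] == 0L | tag_reads[, parent_b] == 0L
    fail[["dominant"]] <- pnull[match(snps@info$tag_id, rownames(tag_reads))]
  } else {
    fail[["dominant"]] <- rep(FALSE, n)
  }
  if (!is.null(parent_a) && !is.null(parent_b)) {
    fail[["parent-missing"]] <- states[, parent_a] == "missing" |
      states[, parent_b] == "missing"
  } else {
    fail[["parent-missing"]] <- rep(FALSE, n)
  }

  alive <- rep(TRUE, n)
  surv <- integer(length(.filterStages))
  flags <- rep("", n)
  for (k in seq_along(.filterStages)) {
    st <- .filterStages[k]
    f <- fail[[st]]
    flags <- ifelse(f, ifelse(nzchar(flags), paste(flags, st, sep = ";"), st),
                    flags)
    alive <- alive & !f
    surv[k] <- sum(alive)
  }
  records <- snps
  records@info$filter <- flags
  ledger <- data.frame(stage = c("candidates", .filterStages),
                       survivors = c(n, surv), stringsAsFactors = FALSE)
  list(passed = records[which(alive)], records = records, ledger = ledger)
}

#' Export SNP records as VCF
#'
#' Tag-relative coordinates: `CHROM` is the tag id and `POS` is the
#' 1-based offset within the tag. Sample columns carry `GT:AD` with the
#' proportion-rule genotype and ref,alt depths; failed cascade stages go
#' in `FILTER`.
#'
#' @param snps A [SnpRecords-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportVcf <- function(snps, file) {
  stopifnot(is(snps, "SnpRecords"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gbsmap",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=MA,Number=0,Type=Flag,Description=\"Multiallelic site (top alternative kept)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", snps@samples), collapse = "\t"))
  n <- nrow(snps@info)
  if (!n) {
    writeLines(hdr, file)
    return(invisible(file))
  }
  states <- callGenotypes(snps)
  gt <- matrix("./.", n, length(snps@samples))
  gt[states == "hom_ref"] <- "0/0"
  gt[states == "hom_alt"] <- "1/1"
  gt[states == "het"] <- "0/1"
  ad <- matrix(paste0(snps@refDepth, ",", snps@altDepth), n)
  cells <- matrix(paste0(gt, ":", ad), n)
  info <- snps@info
  rows <- paste(info$tag_id, info$offset + 1L, ".", info$ref, info$alt,
                sprintf("%.6g", info$quality),
                ifelse(nzchar(info$filter), info$filter, "PASS"),
                paste0("DP=", rowSums(snps@refDepth) + rowSums(snps@altDepth),
                       ifelse(info$multiallelic, ";MA", "")),
                "GT:AD", sep = "\t")
  rows <- paste(rows, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Import a gbsmap VCF back into SnpRecords
#'
#' Reads the VCF written by [exportVcf()]; allele depths round-trip
#' exactly. Base-quality summaries are not stored in the VCF and come
#' back as `NA`.
#'
#' @param file VCF path.
#' @return A [SnpRecords-class].
#' @export
importVcf <- function(file) {
  x <- readLines(file)
  hdr <- x[startsWith(x, "#CHROM")]
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  body <- x[!startsWith(x, "#")]
  ns <- length(samples)
  if (!length(body)) {
    return(new("SnpRecords",
               info = data.frame(tag_id = character(), offset = integer(),
                                 ref = character(), alt = character(),
                                 quality = numeric(), multiallelic = logical(),
                                 mean_ref_baseq = numeric(),
                                 mean_alt_baseq = numeric(),
                                 filter = character()),
               refDepth = matrix(0L, 0L, ns), altDepth = matrix(0L, 0L, ns),
               altQualSum = matrix(0, 0L, ns), samples = samples))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  n <- nrow(f)
  ads <- sub("^[^:]*:", "", f[, 10:(9 + ns), drop = FALSE])
  refDepth <- matrix(as.integer(sub(",.*", "", ads)), n)
  altDepth <- matrix(as.integer(sub(".*,", "", ads)), n)
  colnames(refDepth) <- colnames(altDepth) <- samples
  info <- data.frame(
    tag_id = f[, 1L], offset = as.integer(f[, 2L]) - 1L,
    ref = f[, 4L], alt = f[, 5L], quality = as.numeric(f[, 6L]),
    multiallelic = grepl("(^|;)MA($|;)", f[, 8L]),
    mean_ref_baseq = NA_real_, mean_alt_baseq = NA_real_,
    filter = ifelse(f[, 7L] == "PASS", "", f[, 7L]),
    stringsAsFactors = FALSE)
  new("SnpRecords", info = info, refDepth = refDepth, altDepth = altDepth,
      altQualSum = matrix(0, n, ns, dimnames = list(NULL, samples)),
      samples = samples)
}
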