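#' Build a mapping index over reference tags
#'
#' Indexes full tag sequences for exact lookup and the two tag halves for
#' single-mismatch lookup (pigeonhole: a read with at most one
#' substitution matches at least one half exactly). Tags sharing an
#' identical sequence form an ambiguity class: any read matching them is
#' inherently multi-mapped.
#'
#' @param tags A [ReferenceTagSet-class], [Biostrings::DNAStringSet] or
#'   named character vector of equal-length tags.
#' @return A [TagIndex-class].
#' @export
buildTagIndex <- function(tags) {
  if (is(tags, "ReferenceTagSet")) tags <- tags@tags
  ids <- names(tags)
  seqs <- as.character(tags)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  names(seqs) <- ids
  if (!length(seqs)) stop("no tags to index")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("all tags must have the same length")
  len <- lens[1L]
  st <- data.table(seq = seqs, idx = seq_along(seqs))
  seqTable <- st[, list(nIds = .N, firstIdx = idx[1L]), by = "seq"]
  setkey(seqTable, seq)
  half <- len %/% 2L
  h1 <- data.table(kmer = substr(seqs, 1L, half), idx = seq_along(seqs))
  h2 <- data.table(kmer = substr(seqs, half + 1L, len), idx = seq_along(seqs))
  setkey(h1, kmer); setkey(h2, kmer)
  new("TagIndex", tagIds = ids, tagSeqs = unname(seqs), tagLen = len,
      seqTable = seqTable, halfTables = list(h1, h2))
}

#' Map standardised reads to reference tags
#'
#' End-to-end ungapped mapping under the best-stratum, unique,
#' at-most-one-mismatch contract: an exact hit is returned only when it
#' is unique (one-mismatch hits never compete with an exact hit); when no
#' exact hit exists, the read maps only if exactly one tag lies at
#' Hamming distance one, otherwise it is `ambiguous` (several) or
#' `unmapped` (none). Ties are never broken.
#'
#' @param seqs Character vector of reads, all of the index tag length.
#' @param index A [TagIndex-class].
#' @return A `data.table` with one row per read: `read` (index), `status`
#'   (`"mapped"`/`"ambiguous"`/`"unmapped"`), `tag_idx`, `tag_id`,
#'   `mismatch` (0 or 1) and `offset` (0-based mismatch position, NA for
#'   exact hits).
#' @export
mapReads <- function(seqs, index) {
  stopifnot(is(index, "TagIndex"))
  n <- length(seqs)
  if (n && any(nchar(seqs) != index@tagLen))
    stop("reads must have the index tag length")
  status <- rep("unmapped", n)
  tag_idx <- rep(NA_integer_, n)
  mismatch <- rep(NA_integer_, n)
  offset <- rep(NA_integer_, n)

  hit <- index@seqTable[data.table(seq = seqs), on = "seq",
                        c("nIds", "firstIdx")]
  exact <- !is.na(hit$firstIdx)
  uniq <- exact & hit$nIds == 1L
  status[uniq] <- "mapped"
  tag_idx[uniq] <- hit$firstIdx[uniq]
  mismatch[uniq] <- 0L
  status[exact & !uniq] <- "ambiguous"

  rest <- which(!exact)
  if (length(rest)) {
    half <- index@tagLen %/% 2L
    rdt1 <- data.table(kmer = substr(seqs[rest], 1L, half),
                       r = rest)
    rdt2 <- data.table(kmer = substr(seqs[rest], half + 1L, index@tagLen),
                       r = rest)
    cand <- unique(rbind(
      merge(rdt1, index@halfTables[[1L]], by = "kmer",
            allow.cartesian = TRUE)[, c("r", "idx")],
      merge(rdt2, index@halfTables[[2L]], by = "kmer",
            allow.cartesian = TRUE)[, c("r", "idx")]))
    if (nrow(cand)) {
      cand[, dist := hamming_pairs(seqs[r], index@tagSeqs[idx], max_mm = 1L)]
      cand <- cand[dist == 1L]
      if (nrow(cand)) {
        hits <- cand[, list(nhit = .N, tag = idx[1L]), by = "r"]
        one <- hits[nhit == 1L]
        many <- hits[nhit > 1L]
        status[one$r] <- "mapped"
        tag_idx[one$r] <- one$tag
        mismatch[one$r] <- 1L
        offset[one$r] <- first_mismatch_pairs(seqs[one$r],
                                              index@tagSeqs[one$tag])
        status[many$r] <- "ambiguous"
      }
    }
  }
  data.table(read = seq_len(n), status = status, tag_idx = tag_idx,
             tag_id = ifelse(is.na(tag_idx), NA_character_,
                             index@tagIds[tag_idx]),
             mismatch = mismatch, offset = offset)
}

#' @rdname mapReads
#' @param seq A single read sequence.
#' @export
mapRead <- function(seq, index) mapReads(seq, index)

#' Accumulate a per-sample allele pileup from mapped reads
#'
#' Every mapped read contributes depth at all positions of its tag;
#' non-reference bases (at most one per read under the one-mismatch
#' contract) are recorded individually with their base quality.
#'
#' @param demux Assigned reads: `data.table`/list with `sample_id`,
#'   `seq`, `qual` (as produced by [demultiplexReads()]`$assigned`).
#' @param mapres Result of [mapReads()] on `demux$seq`.
#' @param index The [TagIndex-class] used for mapping.
#' @param samples Optional character vector fixing the sample set and
#'   column order (defaults to sorted unique sample ids present).
#' @return A [GbsPileup-class].
#' @export
accumulatePileup <- function(demux, mapres, index, samples = NULL) {
  stopifnot(is(index, "TagIndex"))
  if (is.null(samples)) samples <- sort(unique(demux$sample_id))
  nT <- length(index@tagIds)
  nS <- length(samples)
  ok <- which(mapres$status == "mapped")
  sidx <- match(demux$sample_id[ok], samples)
  if (anyNA(sidx)) stop("sample ids outside the declared sample set")
  tidx <- mapres$tag_idx[ok]

  reads <- matrix(0L, nT, nS, dimnames = list(index@tagIds, samples))
  if (length(ok)) {
    cnt <- data.table(t = tidx, s = sidx)[, list(n = .N), by = c("t", "s")]
    reads[cbind(cnt$t, cnt$s)] <- cnt$n
  }
  posQual <- position_qual_sums(tidx, demux$qual[ok], nT, index@tagLen)
  rownames(posQual) <- index@tagIds

  mm <- which(mapres$status == "mapped" & mapres$mismatch == 1L)
  mismatches <- if (length(mm)) {
    off <- mapres$offset[mm]
    base <- substr(demux$seq[mm], off + 1L, off + 1L)
    qch <- substr(demux$qual[mm], off + 1L, off + 1L)
    q <- as.integer(charToRaw(paste(qch, collapse = ""))) - 33L
    dt <- data.table(tag_id = index@tagIds[mapres$tag_idx[mm]],
                     offset = off, base = base,
                     sample = demux$sample_id[mm], q = q)
    as.data.frame(dt[, list(count = .N, qualsum = sum(q)),
                     by = c("tag_id", "offset", "base", "sample")])
  } else {
    data.frame(tag_id = character(), offset = integer(), base = character(),
               sample = character(), count = integer(), qualsum = numeric())
  }
  new("GbsPileup", samples = samples, tagIds = index@tagIds,
      tagSeqs = index@tagSeqs, reads = reads, posQual = posQual,
      mismatches = mismatches)
}
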