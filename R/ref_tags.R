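#' Find restriction sites on the forward strand
#'
#' Scans each contig for exact occurrences of the recognition motif.
#' The default PstI motif (CTGCAG) is its own reverse complement, so a
#' forward-strand scan finds every site on either strand; for
#' non-palindromic motifs a warning is issued because reverse-strand
#' sites would need a separate scan.
#'
#' @param contigs A [Biostrings::DNAStringSet] (named) or named character
#'   vector of contig sequences.
#' @param motif Recognition motif (default `"CTGCAG"`, PstI). Must be
#'   plain A/C/G/T.
#' @return A `data.frame` with columns `contig`, `position` (0-based
#'   offset of the first motif base) and `motif`, ordered by contig then
#'   coordinate.
#' @examples
#' findRestrictionSites(c(c1 = "AAACTGCAGAAA"))
#' @export
findRestrictionSites <- function(contigs, motif = "CTGCAG") {
  if (!nzchar(motif)) stop("motif must be non-empty")
  .checkDna(motif, "motif", allow_n = FALSE)
  if (!is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)))
    stop("contigs must be named")
  if (.revcomp(motif) != motif)
    warning("motif is not palindromic; only forward-strand sites reported")
  hits <- Biostrings::vmatchPattern(motif, contigs, fixed = TRUE)
  starts <- lapply(hits, function(h) IRanges::start(h) - 1L)
  n <- lengths(starts)
  pos <- unlist(starts, use.names = FALSE)
  data.frame(
    contig = rep(names(contigs), n),
    position = if (length(pos)) pos else integer(),
    motif = rep(motif, length(pos)),
    stringsAsFactors = FALSE
  )
}

#' Extract fixed-length flanking tags around restriction sites
#'
#' For every site at 0-based motif offset `p`, the forward tag is the
#' `flank_len` bases starting one base into the motif (so it begins with
#' the enzyme overhang, TGCAG for PstI) and the reverse tag is the
#' reverse complement of the `flank_len` bases ending at `p + 5`. A flank
#' is emitted only when it lies fully within the contig and contains no
#' ambiguous base; otherwise an exclusion record with reason `"edge"` or
#' `"ambiguous-base"` is produced, so that
#' `tags emitted + exclusions == 2 * sites` always holds.
#'
#' @param contigs Named [Biostrings::DNAStringSet] or character vector.
#' @param sites `data.frame` as returned by [findRestrictionSites()].
#' @param flank_len Tag length in bases (default 64; must be > 5).
#' @param source Assembly label stored with each tag.
#' @return A [ReferenceTagSet-class].
#' @examples
#' ctg <- c(c1 = paste(rep("A", 130), collapse = ""))
#' substr(ctg, 61, 66) <- "CTGCAG"
#' sites <- findRestrictionSites(ctg)
#' extractFlankTags(ctg, sites)
#' @export
extractFlankTags <- function(contigs, sites, flank_len = 64L,
                             source = "assembly") {
  flank_len <- as.integer(flank_len)
  if (flank_len < 6L) stop("flank_len must be at least 6")
  if (!is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs))) stop("contigs must be named")
  overhang <- if (nrow(sites) && !is.na(sites$motif[1L])) {
    substring(sites$motif[1L], 2L)
  } else "TGCAG"
  if (!nrow(sites)) {
    return(new("ReferenceTagSet",
               tags = Biostrings::DNAStringSet(),
               meta = data.frame(tag_id = character(), contig = character(),
                                 position = integer(), direction = character(),
                                 source = character()),
               exclusions = data.frame(tag_id = character(),
                                       reason = character()),
               overhang = overhang))
  }
  cidx <- match(sites$contig, names(contigs))
  clen <- Biostrings::width(contigs)[cidx]
  x <- contigs[cidx]   # XStringSet views share data: cheap to replicate
  p <- as.integer(sites$position)

  # forward flank: 0-based [p+1, p+1+flank_len)
  fwd_ok <- (p + 1L + flank_len) <= clen
  fwd_seq <- rep(NA_character_, length(p))
  if (any(fwd_ok))
    fwd_seq[fwd_ok] <- as.character(Biostrings::subseq(
      x[fwd_ok], start = p[fwd_ok] + 2L, width = flank_len))
  # reverse flank: revcomp of 0-based [p+5-flank_len, p+5)
  rev_ok <- p >= (flank_len - 5L)
  rev_seq <- rep(NA_character_, length(p))
  if (any(rev_ok))
    rev_seq[rev_ok] <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(x[rev_ok], start = p[rev_ok] + 6L - flank_len,
                         width = flank_len)))

  build <- function(seq, ok, dir) {
    id <- paste(sites$contig, p, dir, sep = ":")
    hasN <- !is.na(seq) & grepl("N", seq, fixed = TRUE)
    emit <- ok & !hasN
    reason <- ifelse(!ok, "edge", ifelse(hasN, "ambiguous-base", NA))
    list(id = id, seq = seq, emit = emit, reason = reason)
  }
  f <- build(fwd_seq, fwd_ok, "F")
  r <- build(rev_seq, rev_ok, "R")

  emit_id <- c(f$id[f$emit], r$id[r$emit])
  emit_seq <- c(f$seq[f$emit], r$seq[r$emit])
  meta <- data.frame(
    tag_id = emit_id,
    contig = c(sites$contig[f$emit], sites$contig[r$emit]),
    position = c(p[f$emit], p[r$emit]),
    direction = c(rep("F", sum(f$emit)), rep("R", sum(r$emit))),
    source = rep(source, length(emit_id)),
    stringsAsFactors = FALSE
  )
  excl <- data.frame(
    tag_id = c(f$id[!f$emit], r$id[!r$emit]),
    reason = c(f$reason[!f$emit], r$reason[!r$emit]),
    stringsAsFactors = FALSE
  )
  tags <- Biostrings::DNAStringSet(emit_seq)
  names(tags) <- emit_id
  new("ReferenceTagSet", tags = tags, meta = meta, exclusions = excl,
      overhang = overhang)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Construct a reference tag set from bare sequences
#'
#' Low-level constructor for tag sets that do not come from
#' [extractFlankTags()] (e.g. externally supplied or constructed tag
#' collections). Ids default to `seq1`, `seq2`, ...
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of
#'   equal-length tag sequences (optionally named).
#' @param source Assembly label.
#' @param overhang Expected prefix (default the PstI overhang TGCAG;
#'   `""` disables the check).
#' @return A [ReferenceTagSet-class].
#' @export
ReferenceTagSet <- function(seqs, source = "assembly", overhang = "TGCAG") {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  meta <- data.frame(tag_id = names(seqs), contig = NA_character_,
                     position = NA_integer_, direction = NA_character_,
                     source = source, stringsAsFactors = FALSE)
  new("ReferenceTagSet", tags = seqs, meta = meta,
      exclusions = data.frame(tag_id = character(), reason = character()),
      overhang = overhang)
}

#' Build a reference tag set from an assembly
#'
#' Convenience wrapper: [findRestrictionSites()] followed by
#' [extractFlankTags()].
#'
#' @inheritParams findRestrictionSites
#' @inheritParams extractFlankTags
#' @return A [ReferenceTagSet-class].
#' @export
buildReferenceTags <- function(contigs, motif = "CTGCAG", flank_len = 64L,
                               source = "assembly") {
  sites <- findRestrictionSites(contigs, motif)
  extractFlankTags(contigs, sites, flank_len = flank_len, source = source)
}

#' Merge tags from additional assemblies into a primary reference set
#'
#' A secondary tag is added when its best full-length ungapped match
#' against the primary set has at least `min_mismatches` substitutions
#' (so that the one-mismatch read mapper cannot cross-map reads between
#' near-identical merged tags), and optionally when it has no primary
#' match at all within `max_hit_mm` mismatches. Identical sequences
#' within the added set are collapsed to a single representative.
#'
#' @param primary,other [ReferenceTagSet-class] objects with equal tag
#'   length.
#' @param min_mismatches Minimum distance to the nearest primary tag for
#'   a matched secondary tag to be added (default 2).
#' @param add_no_hit Add secondary tags with no primary match within
#'   `max_hit_mm` mismatches (default `TRUE`).
#' @param max_hit_mm Largest distance still counted as a "match" when
#'   deciding no-hit status (default 6, i.e. 90% identity for 64 bp).
#' @return The merged [ReferenceTagSet-class]; the attribute
#'   `"mergeStats"` carries counts of added / rejected secondary tags.
#' @export
mergeAssemblies <- function(primary, other, min_mismatches = 2L,
                            add_no_hit = TRUE, max_hit_mm = 6L) {
  stopifnot(is(primary, "ReferenceTagSet"), is(other, "ReferenceTagSet"))
  pseq <- as.character(primary@tags)
  oseq <- as.character(other@tags)
  if (!length(oseq)) return(primary)
  if (length(pseq) && nchar(pseq[1L]) != nchar(oseq[1L]))
    stop("primary and other tag lengths differ")

  min_mismatches <- as.integer(min_mismatches)
  probe_mm <- max(min_mismatches - 1L, if (add_no_hit) 0L else max_hit_mm)
  pairs <- .pigeonholePairs(oseq, pseq, probe_mm)
  best <- rep(NA_integer_, length(oseq))
  if (nrow(pairs)) {
    bq <- pairs[, list(d = min(dist)), by = "q"]
    best[bq$q] <- bq$d
  }
  matched_far <- !is.na(best) & best >= min_mismatches
  keep <- matched_far | (if (add_no_hit) is.na(best) else FALSE)

  # collapse duplicate sequences within the added set; drop sequences
  # already present verbatim in the primary set (best == 0 covers them,
  # but guard the degenerate min_mismatches = 0 case too)
  keep[keep][duplicated(oseq[keep])] <- FALSE
  stats <- c(candidates = length(oseq), added = sum(keep),
             too_similar = sum(!is.na(best) & best < min_mismatches),
             no_hit_dropped = sum(is.na(best) & !add_no_hit),
             duplicate = length(oseq) - sum(keep) -
               sum(!is.na(best) & best < min_mismatches) -
               sum(is.na(best) & !add_no_hit))

  addTags <- other@tags[keep]
  merged <- new("ReferenceTagSet",
                tags = c(primary@tags, addTags),
                meta = rbind(primary@meta, other@meta[keep, , drop = FALSE]),
                exclusions = primary@exclusions,
                overhang = primary@overhang)
  attr(merged, "mergeStats") <- stats
  merged
}

#' Screen reference tags against a chloroplast genome
#'
#' A tag is removed when it has an ungapped full-length alignment to
#' either strand of the chloroplast genome with identity at least
#' `min_identity` over at least `min_align_len` bases; for 64 bp tags and
#' the defaults this is a Hamming distance of at most 6 at some window.
#' Matching uses a pigeonhole chunk prefilter with exact verification.
#'
#' @param x A [ReferenceTagSet-class].
#' @param cp_genome Chloroplast genome: single sequence as character, or
#'   [Biostrings::DNAStringSet] (concatenated if multiple).
#' @param min_identity Minimum identity fraction (default 0.90).
#' @param min_align_len Minimum alignment length (default 64).
#' @return `list(kept=, removed=)`, both [ReferenceTagSet-class].
#' @export
screenChloroplast <- function(x, cp_genome, min_identity = 0.90,
                              min_align_len = 64L) {
  stopifnot(is(x, "ReferenceTagSet"))
  if (is(cp_genome, "DNAStringSet"))
    cp_genome <- paste(as.character(cp_genome), collapse = "")
  cp_genome <- as.character(cp_genome)
  if (!nzchar(cp_genome)) stop("cp_genome must be non-empty")
  tseq <- as.character(x@tags)
  n <- length(tseq)
  if (!n) return(list(kept = x, removed = x))
  len <- nchar(tseq[1L])
  removed <- rep(FALSE, n)
  if (min_align_len <= len && nchar(cp_genome) >= len) {
    max_mm <- floor(len * (1 - min_identity))
    L <- nchar(cp_genome)
    starts <- seq_len(L - len + 1L)
    win <- substring(cp_genome, starts, starts + len - 1L)
    win <- c(win, .revcomp(win))
    pairs <- .pigeonholePairs(tseq, win, max_mm)
    if (nrow(pairs)) removed[unique(pairs$q)] <- TRUE
  }
  list(kept = x[which(!removed)], removed = x[which(removed)])
}

#' @describeIn ReferenceTagSet-class Subset by integer index or tag id.
#' @param x,i,j,...,drop Subsetting arguments (only `i` is used).
#' @export
setMethod("[", "ReferenceTagSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@tags))
  initialize(x, tags = x@tags[i], meta = x@meta[i, , drop = FALSE],
             exclusions = x@exclusions, overhang = x@overhang)
})

#' Write / read a reference tag set
#'
#' Tags are stored as FASTA with header `tag_id source=<s> direction=<d>`
#' and the exclusion ledger as a two-column TSV alongside (same path with
#' extension `.exclusions.tsv`) when there are exclusion records.
#'
#' @param x A [ReferenceTagSet-class].
#' @param file FASTA path.
#' @return `writeReferenceTags` returns `file` invisibly;
#'   `readReferenceTags` returns a [ReferenceTagSet-class].
#' @export
writeReferenceTags <- function(x, file) {
  out <- x@tags
  names(out) <- sprintf("%s source=%s direction=%s", x@meta$tag_id,
                        x@meta$source, x@meta$direction)
  Biostrings::writeXStringSet(out, file)
  if (nrow(x@exclusions)) {
    write.table(x@exclusions, paste0(file, ".exclusions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname writeReferenceTags
#' @export
readReferenceTags <- function(file) {
  tags <- Biostrings::readDNAStringSet(file)
  hdr <- strsplit(names(tags), " ", fixed = TRUE)
  id <- vapply(hdr, `[`, "", 1L)
  field <- function(k) {
    vapply(hdr, function(h) {
      v <- grep(paste0("^", k, "="), h, value = TRUE)
      if (length(v)) sub(paste0("^", k, "="), "", v[1L]) else NA_character_
    }, "")
  }
  names(tags) <- id
  parts <- strsplit(id, ":", fixed = TRUE)
  meta <- data.frame(
    tag_id = id,
    contig = vapply(parts, function(p) paste(head(p, -2L), collapse = ":"), ""),
    position = as.integer(vapply(parts, function(p) p[length(p) - 1L], "")),
    direction = field("direction"),
    source = field("source"),
    stringsAsFactors = FALSE
  )
  exf <- paste0(file, ".exclusions.tsv")
  excl <- if (file.exists(exf)) {
    read.table(exf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    data.frame(tag_id = character(), reason = character())
  }
  new("ReferenceTagSet", tags = tags, meta = meta, exclusions = excl,
      overhang = substr(as.character(tags[[1L]]), 1L, 5L))
}
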