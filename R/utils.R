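# Internal helpers shared across modules.

.revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.checkDna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, x)))
    stop(sprintf("%s contains characters outside %s", what,
                 if (allow_n) "A/C/G/T/N" else "A/C/G/T"), call. = FALSE)
  invisible(TRUE)
}

# Evenly split 1..len into k chunks; returns list(start, end) (1-based).
.chunkBounds <- function(len, k) {
  b <- floor(seq(0L, len, length.out = k + 1L))
  list(start = b[-(k + 1L)] + 1L, end = b[-1L])
}

#' All query/subject pairs within a Hamming-distance bound
#'
#' Pigeonhole search between two sets of equal-length sequences: each
#' sequence is split into `max_mm + 1` chunks, so any pair within the
#' distance bound shares at least one chunk exactly. Candidate pairs found
#' by chunk hashing are verified by full Hamming distance.
#'
#' @param query,subject Character vectors of equal-length sequences.
#' @param max_mm Maximum Hamming distance reported.
#' @return A `data.table` with columns `q`, `s` (1-based indices into
#'   `query` and `subject`) and `dist`, one row per pair with
#'   `dist <= max_mm`.
#' @keywords internal
#' @noRd
.pigeonholePairs <- function(query, subject, max_mm) {
  stopifnot(max_mm >= 0L)
  nq <- length(query)
  ns <- length(subject)
  empty <- data.table(q = integer(), s = integer(), dist = integer())
  if (!nq || !ns) return(empty)
  len <- nchar(query[1L])
  k <- max_mm + 1L
  cb <- .chunkBounds(len, k)
  pieces <- vector("list", k)
  for (c in seq_len(k)) {
    sdt <- data.table(kmer = substr(subject, cb$start[c], cb$end[c]),
                      s = seq_len(ns))
    qdt <- data.table(kmer = substr(query, cb$start[c], cb$end[c]),
                      q = seq_len(nq))
    pieces[[c]] <- merge(qdt, sdt, by = "kmer",
                         allow.cartesian = TRUE)[, c("q", "s")]
  }
  cand <- unique(rbindlist(pieces))
  if (!nrow(cand)) return(empty)
  cand[, dist := hamming_pairs(query[q], subject[s], max_mm = max_mm)]
  cand[dist <= max_mm]
}

# Deterministic child seed derived from a master seed and a stage label.
.childSeed <- function(seed, salt) {
  s <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + s) %% 2147483647)
}

# Random DNA with every occurrence of `motif` destroyed (one base of each
# occurrence is substituted until none remain). Used by the simulator.
.randomDnaNoMotif <- function(n, motif = "CTGCAG") {
  x <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    hits <- gregexpr(motif, x, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) break
    for (h in hits) {
      repl <- sample(setdiff(c("A", "C", "G", "T"),
                             substr(motif, 1L, 1L)), 1L)
      substr(x, h, h) <- repl
    }
  }
  x
}
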