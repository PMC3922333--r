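#' Load and validate an inline-barcode table
#'
#' Barcodes are 4-8 nt sequences ligated 5' of the enzyme overhang.
#' Validation rejects duplicate barcodes and any pair where one
#' barcode + overhang is a prefix of another barcode + overhang, which is
#' the exact condition under which longest-match-first assignment would
#' be ambiguous.
#'
#' @param barcodes `data.frame` with columns `sample_id` and `barcode`,
#'   or a TSV path with those columns.
#' @param overhang Enzyme overhang expected after the barcode.
#' @return The validated `data.frame` (invisibly ordered as given).
#' @export
readBarcodeTable <- function(barcodes, overhang = "TGCAG") {
  if (is.character(barcodes) && length(barcodes) == 1L)
    barcodes <- read.table(barcodes, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "barcode") %in% names(barcodes)))
  if (!nrow(barcodes)) stop("barcode set is empty")
  bc <- toupper(barcodes$barcode)
  .checkDna(bc, "barcode", allow_n = FALSE)
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode set")
  if (anyDuplicated(barcodes$sample_id))
    stop("duplicate sample ids in barcode set")
  full <- paste0(bc, overhang)
  ord <- order(nchar(full))
  for (i in seq_along(ord)) {
    fi <- full[ord[i]]
    rest <- full[ord[-seq_len(i)]]
    if (any(startsWith(rest, fi)))
      stop(sprintf("barcode set ambiguous: %s+%s is a prefix of another entry",
                   bc[ord[i]], overhang))
  }
  barcodes$barcode <- bc
  barcodes
}

#' Assign reads to samples by inline barcode
#'
#' A read is assigned when some barcode matches its 5' end exactly, the
#' bases immediately following equal the enzyme overhang, and the
#' barcode-stripped read contains no undetermined base (N). Ties across
#' barcode lengths are impossible for a validated set; matching is
#' longest-barcode-first. The barcode is removed, the overhang retained.
#'
#' @param seqs Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (parallel).
#' @param barcodes Validated barcode table ([readBarcodeTable()]).
#' @param overhang Expected overhang (default `"TGCAG"`).
#' @param n_check Where the N filter applies: `"stripped"` (default,
#'   whole barcode-stripped read) or `"retained"` (defer to the final
#'   standardised bases, applied by [trimAndStandardise()]).
#' @return A list with `sample` (sample id or `NA`), `seq`, `qual`
#'   (barcode-stripped, `NA` where rejected) and `reason`
#'   (`NA` for assigned reads, else `"no-barcode"`, `"bad-overhang"` or
#'   `"contains-N"`).
#' @export
assignReads <- function(seqs, quals, barcodes, overhang = "TGCAG",
                        n_check = c("stripped", "retained")) {
  n_check <- match.arg(n_check)
  if (is.null(barcodes) || !nrow(barcodes)) stop("barcode set is empty")
  n <- length(seqs)
  bclen <- nchar(barcodes$barcode)
  full <- paste0(barcodes$barcode, overhang)
  sample <- rep(NA_character_, n)
  usedLen <- rep(NA_integer_, n)
  bcOnly <- rep(FALSE, n)
  for (L in sort(unique(bclen), decreasing = TRUE)) {
    idx <- which(bclen == L)
    open <- which(is.na(sample))
    if (!length(open)) break
    hitFull <- match(substr(seqs[open], 1L, L + nchar(overhang)), full[idx])
    got <- !is.na(hitFull)
    sample[open[got]] <- barcodes$sample_id[idx[hitFull[got]]]
    usedLen[open[got]] <- L
    # barcode matches but overhang does not: remember for classification
    miss <- open[!got]
    if (length(miss)) {
      hitBc <- match(substr(seqs[miss], 1L, L), barcodes$barcode[idx])
      bcOnly[miss[!is.na(hitBc)]] <- TRUE
    }
  }
  assigned <- !is.na(sample)
  stripped <- ifelse(assigned, substr(seqs, usedLen + 1L, nchar(seqs)), NA)
  squal <- ifelse(assigned, substr(quals, usedLen + 1L, nchar(quals)), NA)
  reason <- ifelse(assigned, NA_character_,
                   ifelse(bcOnly, "bad-overhang", "no-barcode"))
  if (n_check == "stripped") {
    hasN <- assigned & grepl("N", stripped, fixed = TRUE)
    reason[hasN] <- "contains-N"
    sample[hasN] <- NA_character_
    stripped[hasN] <- NA_character_
    squal[hasN] <- NA_character_
  }
  list(sample = sample, seq = stripped, qual = squal, reason = reason)
}

#' Quality-trim and standardise barcode-stripped reads
#'
#' Removes the maximal 3' suffix whose bases all have quality below
#' `min_q` (trailing-run trimming), then truncates to `out_len` bases
#' from the 5' end; reads left shorter than `out_len` are rejected.
#'
#' @param seqs,quals Barcode-stripped sequences and Phred+33 qualities.
#' @param min_q Minimum Phred quality retained at the 3' end (default 20).
#' @param out_len Standard output length (default 64).
#' @param check_n Also reject reads whose retained `out_len` bases
#'   contain an N (used when the N filter is deferred).
#' @return A list with `seq`, `qual` (length-`out_len`, `NA` where
#'   rejected) and `reason` (`NA`, `"too-short"` or `"contains-N"`).
#' @export
trimAndStandardise <- function(seqs, quals, min_q = 20L, out_len = 64L,
                               check_n = FALSE) {
  keep <- trailing_keep_len(quals, as.integer(min_q))
  ok <- !is.na(seqs) & keep >= out_len
  oseq <- ifelse(ok, substr(seqs, 1L, out_len), NA)
  oqual <- ifelse(ok, substr(quals, 1L, out_len), NA)
  reason <- ifelse(ok, NA_character_, "too-short")
  if (check_n) {
    hasN <- ok & grepl("N", oseq, fixed = TRUE)
    reason[hasN] <- "contains-N"
    oseq[hasN] <- NA_character_
    oqual[hasN] <- NA_character_
  }
  reason[is.na(seqs)] <- NA_character_  # already rejected upstream
  list(seq = oseq, qual = oqual, reason = reason)
}

#' Demultiplex a set of raw GBS reads
#'
#' Full deconvolution: barcode assignment ([assignReads()]) followed by
#' quality trimming and length standardisation ([trimAndStandardise()]).
#' Every input read ends up either assigned or in exactly one rejection
#' class.
#'
#' @param reads A list with `id`, `seq`, `qual` (see [readFastq()]), or a
#'   FASTQ path.
#' @inheritParams assignReads
#' @inheritParams trimAndStandardise
#' @return A list with `assigned` (`data.table`: `read_id`, `sample_id`,
#'   `seq`, `qual`), `rejects` (`data.table`: `read_id`, `reason`) and
#'   `stats` (see [demuxStats()]).
#' @export
demultiplexReads <- function(reads, barcodes, overhang = "TGCAG",
                             min_q = 20L, out_len = 64L,
                             n_check = c("stripped", "retained")) {
  n_check <- match.arg(n_check)
  if (is.character(reads) && length(reads) == 1L) reads <- readFastq(reads)
  barcodes <- readBarcodeTable(barcodes, overhang)
  asg <- assignReads(reads$seq, reads$qual, barcodes, overhang, n_check)
  trm <- trimAndStandardise(asg$seq, asg$qual, min_q = min_q,
                            out_len = out_len,
                            check_n = (n_check == "retained"))
  reason <- ifelse(!is.na(asg$reason), asg$reason, trm$reason)
  ok <- is.na(reason)
  assigned <- data.table(read_id = reads$id[ok], sample_id = asg$sample[ok],
                         seq = trm$seq[ok], qual = trm$qual[ok])
  rejects <- data.table(read_id = reads$id[!ok], reason = reason[!ok])
  out <- list(assigned = assigned, rejects = rejects)
  out$stats <- demuxStats(out)
  out
}

#' Demultiplexing summary statistics
#'
#' @param demux Result of [demultiplexReads()].
#' @return A list with `per_sample` (read counts), `reasons` (rejection
#'   histogram), `total`, and `categorised_fraction` (assigned / total).
#' @export
demuxStats <- function(demux) {
  total <- nrow(demux$assigned) + nrow(demux$rejects)
  per_sample <- if (nrow(demux$assigned)) {
    tab <- table(demux$assigned$sample_id)
    setNames(as.integer(tab), names(tab))
  } else integer()
  reasons <- if (nrow(demux$rejects)) {
    tab <- table(demux$rejects$reason)
    setNames(as.integer(tab), names(tab))
  } else integer()
  list(per_sample = per_sample, reasons = reasons, total = total,
       categorised_fraction = if (total) nrow(demux$assigned) / total else NA)
}

#' Minimal FASTQ input/output
#'
#' `readFastq` reads a (optionally gzipped) FASTQ file into parallel
#' character vectors; `writeFastq` writes one.
#'
#' @param file FASTQ path (gzipped if ending in `.gz`).
#' @param reads List with `id`, `seq`, `qual`.
#' @return `readFastq`: list with `id`, `seq`, `qual`; `writeFastq`:
#'   `file`, invisibly.
#' @export
readFastq <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  x <- readLines(con)
  if (length(x) %% 4L != 0L) stop("truncated FASTQ: ", file)
  i <- seq(1L, length(x), by = 4L)
  list(id = sub("^@", "", sub(" .*", "", x[i])),
       seq = toupper(x[i + 1L]), qual = x[i + 3L])
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  n <- length(reads$id)
  out <- character(4L * n)
  out[seq(1L, 4L * n, 4L)] <- paste0("@", reads$id)
  out[seq(2L, 4L * n, 4L)] <- reads$seq
  out[seq(3L, 4L * n, 4L)] <- "+"
  out[seq(4L, 4L * n, 4L)] <- reads$qual
  writeLines(out, con)
  invisible(file)
}
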