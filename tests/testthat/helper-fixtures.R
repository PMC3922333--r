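# Shared fixtures (built once per run) and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small read-level experiment: exercises the full read pipeline quickly.
smallSimConfig <- function(...) {
  defaults <- list(n_markers = 60L, n_lines = 30L,
                   chrom_cM = c(60, 70, 80, 50, 90, 60, 70),
                   depth_range = c(1500, 3000),
                   depth_meanlog = log(2000), depth_sdlog = 0.3)
  do.call(simConfig, utils::modifyList(defaults, list(...),
                                       keep.null = TRUE))
}

smallSim <- function() {
  .cached("smallSim", simulateGbsExperiment(smallSimConfig(), seed = 11L))
}

# Genotype-level experiment at the full study scale (no reads).
scaleSim <- function() {
  .cached("scaleSim", {
    cfg <- simConfig()
    gen <- makeParentalGenomes(cfg, seed = 5L)
    ril <- simulateRilPopulation(gen, cfg, seed = 5L)
    pheno <- simulatePhenotypes(ril, cfg, seed = 5L)
    list(config = cfg, genomes = gen, ril = ril, phenotypes = pheno)
  })
}

randomDna <- function(n, len, seed = 1L, prefix = "TGCAG") {
  set.seed(seed)
  body <- len - nchar(prefix)
  vapply(seq_len(n), function(i)
    paste0(prefix, paste(sample(c("A", "C", "G", "T"), body,
                                replace = TRUE), collapse = "")), "")
}

# Brute-force site finder: scan every offset.
naiveFindSites <- function(seq, motif) {
  L <- nchar(seq)
  m <- nchar(motif)
  which(vapply(seq_len(L - m + 1L),
               function(i) substr(seq, i, i + m - 1L) == motif,
               TRUE)) - 1L
}

# Plain-R Hamming distance between two equal-length strings.
naiveHamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Brute-force best-stratum unique mapper (the oracle for mapReads).
naiveMap <- function(read, tagseqs) {
  d <- vapply(tagseqs, naiveHamming, 0, a = read)
  exact <- which(d == 0L)
  if (length(exact) == 1L) return(list(status = "mapped", tag = exact,
                                       mismatch = 0L))
  if (length(exact) > 1L) return(list(status = "ambiguous"))
  one <- which(d == 1L)
  if (length(one) == 1L) return(list(status = "mapped", tag = one,
                                     mismatch = 1L))
  if (length(one) > 1L) return(list(status = "ambiguous"))
  list(status = "unmapped")
}

# Construct a SnpRecords object directly from depth matrices.
makeSnps <- function(refDepth, altDepth, quality = NULL,
                     mean_ref_baseq = 38, mean_alt_baseq = 38,
                     tag_id = NULL, offset = NULL) {
  n <- nrow(refDepth)
  samples <- colnames(refDepth)
  if (is.null(quality)) quality <- rep(100, n)
  if (is.null(tag_id)) tag_id <- sprintf("tag%04d", seq_len(n))
  if (is.null(offset)) offset <- rep(10L, n)
  info <- data.frame(tag_id = tag_id, offset = rep(offset, length.out = n),
                     ref = rep("A", n), alt = rep("G", n),
                     quality = rep(quality, length.out = n),
                     multiallelic = rep(FALSE, n),
                     mean_ref_baseq = rep(mean_ref_baseq, length.out = n),
                     mean_alt_baseq = rep(mean_alt_baseq, length.out = n),
                     filter = rep("", n), stringsAsFactors = FALSE)
  new("SnpRecords", info = info,
      refDepth = refDepth, altDepth = altDepth,
      altQualSum = altDepth * info$mean_alt_baseq,
      samples = samples)
}

# Construct a GenotypeMatrix from a character matrix.
makeGm <- function(calls, quality = NULL) {
  if (is.null(quality)) quality <- rep(30, nrow(calls))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("m%04d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  new("GenotypeMatrix", calls = calls, quality = quality,
      parentA = "PA", parentB = "PB",
      info = data.frame(row.names = rownames(calls)))
}
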