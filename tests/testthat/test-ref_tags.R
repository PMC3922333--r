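test_that("restriction sites are found at every forward-strand occurrence", {
  expect_equal(findRestrictionSites(c(c1 = "AAACTGCAGAAA"))$position, 3L)
  expect_equal(nrow(findRestrictionSites(c(c1 = "AAATTTAAA"))), 0L)
  expect_equal(findRestrictionSites(c(c1 = "CTGCAGCTGCAG"))$position,
               c(0L, 6L))
  expect_error(findRestrictionSites(c(c1 = "ACGT"), motif = "CTGNAG"),
               "motif")
  expect_error(findRestrictionSites(c(c1 = "ACGT"), motif = ""), "motif")
  # brute-force agreement on random contigs
  set.seed(42)
  for (i in 1:10) {
    ctg <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
    got <- findRestrictionSites(setNames(ctg, "c"))$position
    expect_identical(got, naiveFindSites(ctg, "CTGCAG"))
  }
})

test_that("flank extraction matches coordinate arithmetic and brute force", {
  set.seed(7)
  ctg <- c(c1 = paste(sample(c("A", "C", "G", "T"), 130, replace = TRUE),
                      collapse = ""))
  substr(ctg, 61, 66) <- "CTGCAG"
  sites <- findRestrictionSites(ctg)
  sites <- sites[sites$position == 60L, ]
  rt <- extractFlankTags(ctg, sites)
  expect_equal(length(tags(rt)), 2L)
  seqs <- as.character(tags(rt))
  expect_true(all(nchar(seqs) == 64L))
  expect_true(all(startsWith(seqs, "TGCAG")))
  # brute-force substring oracle (0-based p = 60)
  fwd <- substr(ctg, 62, 125)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ctg, 2, 65))))
  expect_setequal(unname(seqs), c(fwd, rev))
})

test_that("near-edge sites yield partial tags plus exclusion records", {
  set.seed(8)
  mk <- function(len, p) {
    x <- paste(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
    substr(x, p + 1L, p + 6L) <- "CTGCAG"
    setNames(x, "c")
  }
  ctg <- mk(200L, 10L)          # forward fits, reverse needs p >= 59
  rt <- extractFlankTags(ctg, findRestrictionSites(ctg))
  expect_equal(length(tags(rt)), 1L)
  expect_equal(tagMeta(rt)$direction, "F")
  expect_equal(exclusions(rt)$reason, "edge")

  ctg2 <- mk(20L, 3L)           # both flanks exceed the contig
  rt2 <- extractFlankTags(ctg2, findRestrictionSites(ctg2))
  expect_equal(length(tags(rt2)), 0L)
  expect_equal(exclusions(rt2)$reason, rep("edge", 2L))

  # ambiguous-base exclusion
  ctg3 <- mk(200L, 80L)
  substr(ctg3, 95, 95) <- "N"   # inside the forward flank
  rt3 <- extractFlankTags(ctg3, findRestrictionSites(ctg3))
  expect_equal(tagMeta(rt3)$direction, "R")
  expect_equal(exclusions(rt3)$reason, "ambiguous-base")
})

test_that("flank accounting conserves: tags + exclusions = 2 x sites", {
  set.seed(9)
  for (i in 1:8) {
    len <- sample(80:4000, 1L)
    ctg <- paste(sample(c("A", "C", "G", "T", "N"), len,
                        replace = TRUE, prob = c(rep(0.2475, 4), 0.01)),
                 collapse = "")
    ctg <- setNames(ctg, "c")
    sites <- findRestrictionSites(ctg)
    rt <- extractFlankTags(ctg, sites)
    expect_equal(length(tags(rt)) + nrow(exclusions(rt)), 2L * nrow(sites))
    if (length(tags(rt))) {
      expect_true(all(Biostrings::width(tags(rt)) == 64L))
      expect_true(all(startsWith(as.character(tags(rt)), "TGCAG")))
    }
  }
})

test_that("assembly merge keeps only sufficiently diverged tags", {
  prim <- ReferenceTagSet(randomDna(30, 64, seed = 21), source = "morex")
  ps <- as.character(tags(prim))
  mut <- function(s, k) {
    for (p in k) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- if (cur == "A") "C" else "A"
    }
    s
  }
  other <- ReferenceTagSet(
    c(o1 = unname(ps[1L]),            # identical -> not added
      o2 = mut(unname(ps[2L]), 40L),  # 1 mismatch -> not added
      o3 = mut(unname(ps[3L]), c(30L, 50L)),  # 2 mismatches -> added
      o4 = randomDna(1, 64, seed = 99)),      # no hit -> added by default
    source = "bowman")
  merged <- mergeAssemblies(prim, other)
  expect_equal(length(tags(merged)), 32L)
  expect_setequal(tagMeta(merged)$tag_id[31:32], c("o3", "o4"))
  # no-hit tags dropped when disabled
  merged2 <- mergeAssemblies(prim, other, add_no_hit = FALSE)
  expect_equal(tagMeta(merged2)$tag_id[31L], "o3")
  expect_equal(length(tags(merged2)), 31L)
  # brute-force confirmation of the distance classes
  d2 <- min(vapply(ps, naiveHamming, 0, b = mut(unname(ps[3L]),
                                                c(30L, 50L))))
  d1 <- min(vapply(ps, naiveHamming, 0, b = mut(unname(ps[2L]), 40L)))
  expect_equal(c(d1, d2), c(1, 2))
})

test_that("assembly merge is idempotent and collapses duplicates", {
  prim <- ReferenceTagSet(randomDna(25, 64, seed = 31))
  self <- mergeAssemblies(prim, ReferenceTagSet(
    setNames(as.character(tags(prim)), paste0("dup", 1:25))))
  expect_equal(length(tags(self)), 25L)
  # two identical diverged candidates collapse to one
  s <- as.character(tags(prim))[1L]
  substr(s, 30, 30) <- "N"  # placeholder, replaced below
  s <- sub("N", if (substr(as.character(tags(prim))[1L], 30, 30) == "A")
    "C" else "A", s)
  substr(s, 40, 40) <- if (substr(s, 40, 40) == "A") "C" else "A"
  dup <- ReferenceTagSet(c(x1 = s, x2 = s))
  merged <- mergeAssemblies(prim, dup)
  expect_equal(length(tags(merged)), 26L)
})

test_that("chloroplast screen removes tags at >= 90% identity", {
  tagset <- ReferenceTagSet(randomDna(20, 64, seed = 41))
  seqs <- as.character(tags(tagset))
  flip <- function(s, k) {
    for (p in k) substr(s, p, p) <- if (substr(s, p, p) == "A") "C" else "A"
    s
  }
  # cp genome embeds tag 1 verbatim, tag 2 with 6 flips, tag 3 with 7
  emb <- c(seqs[1L], flip(seqs[2L], 10:15), flip(seqs[3L], 10:16))
  set.seed(5)
  sp <- function() paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                         collapse = "")
  cp <- paste0(sp(), emb[1L], sp(), emb[2L], sp(), emb[3L], sp())
  scr <- screenChloroplast(tagset, cp)
  removed <- tagMeta(scr$removed)$tag_id
  expect_setequal(removed, c("seq1", "seq2"))     # 0 and 6 mismatches
  expect_true("seq3" %in% tagMeta(scr$kept)$tag_id)  # 7 mismatches kept
  expect_equal(length(tags(scr$kept)) + length(tags(scr$removed)), 20L)
  # brute-force sliding-window identity confirms the boundary
  best <- function(tag) {
    w <- vapply(seq_len(nchar(cp) - 63L),
                function(i) naiveHamming(tag, substr(cp, i, i + 63L)), 0)
    min(w)
  }
  expect_equal(best(seqs[2L]), 6)
  expect_equal(best(seqs[3L]), 7)
})

test_that("reverse-strand chloroplast matches are detected", {
  tagset <- ReferenceTagSet(randomDna(3, 64, seed = 51))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as.character(tags(tagset))[2L])))
  cp <- paste0(strrep("AC", 30), rc, strrep("GA", 30))
  scr <- screenChloroplast(tagset, cp)
  expect_equal(tagMeta(scr$removed)$tag_id, "seq2")
})

test_that("tag sets round-trip through FASTA with their ledger", {
  ctg <- smallSim()$genomes$parentA
  rt <- buildReferenceTags(ctg, source = "parentA")
  f <- tempfile(fileext = ".fa")
  writeReferenceTags(rt, f)
  back <- readReferenceTags(f)
  expect_identical(as.character(tags(back)), as.character(tags(rt)))
  expect_identical(tagMeta(back)$direction, tagMeta(rt)$direction)
  expect_identical(tagMeta(back)$source, tagMeta(rt)$source)
  expect_equal(nrow(exclusions(back)), nrow(exclusions(rt)))
})
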