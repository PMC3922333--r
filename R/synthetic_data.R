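#' Simulation configuration for a GBS RIL experiment
#'
#' Defaults emulate a barley-style two-enzyme (PstI/MseI) GBS experiment
#' on an F11 single-seed-descent RIL population: seven chromosomes
#' totalling 1,200 cM, ~1,300 polymorphic marker tags, 138 lines, plant
#' height controlled by a major 5H-style QTL plus a 3H-style QTL and a
#' row-type locus measured over two correlated year replicates, 100 bp
#' barcoded single-end reads at desk scale (per-sample read counts are
#' the published 0.5-6.5 M range scaled down ~100x).
#'
#' @param n_chromosomes Number of chromosomes (default 7).
#' @param chrom_cM Genetic lengths per chromosome (default sums to 1200).
#' @param n_markers Target number of polymorphic marker tags (default 1300).
#' @param n_lines RIL population size (default 138).
#' @param selfing_gens Selfing meioses past the F1 (default 10, i.e. F11).
#' @param qtl List of QTLs: each `list(chr=, cM=, effect=)` with one
#'   additive effect (b minus a class difference, cm) per year.
#' @param rowtype Row-type locus spec `list(chr=, cM=, effect=)`; lines
#'   homozygous for the parent-B allele are six-rowed and `effect` is the
#'   six-row minus two-row height difference per year.
#' @param baseline Height of the all-a genotype, cm (default 80).
#' @param sd_line Line-specific (year-shared) residual SD, cm (default 7.9).
#' @param sd_year Year-specific residual SD, cm (default 5.5).
#' @param n_years Number of year replicates (default 2).
#' @param read_len Raw read length (default 100).
#' @param tag_len Reference tag length (default 64).
#' @param error_rate Per-base substitution error rate at plateau quality
#'   (default 0.002; plateau Phred = -10 log10(rate)).
#' @param n_rate Per-base rate of undetermined (N) bases (default 5e-4).
#' @param depth_range Per-sample read-count range, desk scale
#'   (default c(5204, 65549)).
#' @param depth_meanlog,depth_sdlog Log-normal read-count parameters.
#' @param depth_scale Multiplier on per-sample read counts (default 1;
#'   set 100 for full published scale).
#' @param dominant_fraction Fraction of sites whose PstI site is lost in
#'   parent B, creating presence/absence (dominant) tags (default 0.05).
#' @param extra_site_fraction Monomorphic sites as a fraction of
#'   `n_markers` (default 0.3).
#' @param marker_gap `list(chr=, from=, to=)` marker-free region
#'   adjacent to the major QTL (default chr 5, 31-47 cM; `NULL` disables).
#' @param fragment_window PstI-MseI size-selection window, bp
#'   (default c(200, 500)).
#' @param motif,mse_motif Rare- and common-cutter motifs.
#' @param seed Master seed (mandatory for generation functions).
#' @return A classed list (`"SimConfig"`) of validated settings.
#' @export
simConfig <- function(n_chromosomes = 7L,
                      chrom_cM = c(160, 185, 170, 140, 190, 160, 195),
                      n_markers = 1300L, n_lines = 138L, selfing_gens = 10L,
                      qtl = list(
                        list(chr = 5L, cM = 29.7, effect = c(27.5, 24.8)),
                        list(chr = 3L, cM = 51.6, effect = c(9.7, 8.9))),
                      rowtype = list(chr = 2L, cM = 80.5,
                                     effect = c(-10.1, -6.8)),
                      baseline = 80, sd_line = 7.9, sd_year = 5.5,
                      n_years = 2L, read_len = 100L, tag_len = 64L,
                      error_rate = 0.002, n_rate = 5e-4,
                      depth_range = c(5204, 65549),
                      depth_meanlog = log(15000), depth_sdlog = 0.6,
                      depth_scale = 1, dominant_fraction = 0.05,
                      extra_site_fraction = 0.3,
                      marker_gap = list(chr = 5L, from = 31, to = 47),
                      fragment_window = c(200L, 500L),
                      motif = "CTGCAG", mse_motif = "TTAA", seed = NULL) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_cM = chrom_cM, n_markers = as.integer(n_markers),
              n_lines = as.integer(n_lines),
              selfing_gens = as.integer(selfing_gens), qtl = qtl,
              rowtype = rowtype, baseline = baseline, sd_line = sd_line,
              sd_year = sd_year, n_years = as.integer(n_years),
              read_len = as.integer(read_len), tag_len = as.integer(tag_len),
              error_rate = error_rate, n_rate = n_rate,
              depth_range = depth_range, depth_meanlog = depth_meanlog,
              depth_sdlog = depth_sdlog, depth_scale = depth_scale,
              dominant_fraction = dominant_fraction,
              extra_site_fraction = extra_site_fraction,
              marker_gap = marker_gap, fragment_window = fragment_window,
              motif = motif, mse_motif = mse_motif, seed = seed)
  stopifnot(length(cfg$chrom_cM) == cfg$n_chromosomes,
            all(cfg$chrom_cM > 0), cfg$n_markers > 0, cfg$n_lines > 0,
            cfg$selfing_gens >= 1, cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$n_rate >= 0, cfg$n_rate < 1,
            cfg$dominant_fraction >= 0, cfg$dominant_fraction < 1,
            cfg$read_len > cfg$tag_len, cfg$tag_len > 5)
  class(cfg) <- "SimConfig"
  cfg
}

# Scrubbed random filler: no rare-cutter site, no common-cutter site.
.fillerStrings <- function(lengths, motifs) {
  total <- sum(lengths)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  big <- paste(chars, collapse = "")
  out <- substring(big, cumsum(lengths) - lengths + 1L, cumsum(lengths))
  repeat {
    dirty <- FALSE
    for (m in motifs) {
      hits <- gregexpr(m, out, fixed = TRUE)
      for (i in seq_along(out)) {
        h <- hits[[i]]
        if (h[1L] == -1L) next
        dirty <- TRUE
        for (p in h) {
          substr(out[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 substr(m, 1L, 1L)), 1L)
        }
      }
    }
    if (!dirty) break
  }
  out
}

#' Generate a validated inline barcode set
#'
#' Random 4-8 nt barcodes, regenerated until unique and unambiguous
#' (no barcode + overhang is a prefix of another; see
#' [readBarcodeTable()]).
#'
#' @param sample_ids Character vector of sample ids.
#' @param overhang Enzyme overhang (default `"TGCAG"`).
#' @param seed Integer seed.
#' @return `data.frame` with `sample_id`, `barcode`.
#' @export
makeBarcodeSet <- function(sample_ids, overhang = "TGCAG", seed = 1L) {
  n <- length(sample_ids)
  .withSeed(seed, {
    for (attempt in 1:100) {
      lens <- rep(4:8, length.out = n)
      bc <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), "")
      tab <- data.frame(sample_id = sample_ids, barcode = bc,
                        stringsAsFactors = FALSE)
      ok <- tryCatch({ readBarcodeTable(tab, overhang); TRUE },
                     error = function(e) FALSE)
      if (ok) return(tab)
    }
    stop("could not generate an unambiguous barcode set")
  })
}

#' Generate the two parental genomes with planted tag structure
#'
#' Builds one contig per chromosome in which every site unit carries a
#' PstI motif whose two PstI-MseI fragments fall inside the
#' size-selection window. Marker sites differ between the parents by one
#' substitution in one 64 bp flank; dominant sites have the PstI motif
#' destroyed in parent B; extra sites are monomorphic. Fillers contain
#' no stray PstI or MseI motif, so fragment structure is fully
#' controlled. A small chloroplast contig embedding copies of two
#' monomorphic tags is included to exercise chloroplast screening.
#'
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#' @return A list: `parentA`, `parentB` ([Biostrings::DNAStringSet]),
#'   `cp_genome` (character), `sites` (per-site truth `data.frame`:
#'   chr, cM, site_pos, type, snp_dir, snp_offset, ref, alt, locus),
#'   `markers` (polymorphic-marker subset with `marker_id`), `loci`
#'   (segregating loci for meiosis: locus, chr, cM, kind), `templates`
#'   (read templates keyed `site:dir:parent`).
#' @export
makeParentalGenomes <- function(config, seed) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(.childSeed(seed, "genomes"), {
    tagL <- config$tag_len
    readL <- config$read_len
    tmplL <- readL - 4L  # longest needed after the shortest barcode
    motif <- config$motif
    mse <- config$mse_motif
    mlen <- nchar(motif)

    # marker placement on the genetic map
    prop <- config$chrom_cM / sum(config$chrom_cM)
    nm <- round(config$n_markers * prop)
    site_list <- list()
    for (ch in seq_len(config$n_chromosomes)) {
      len <- config$chrom_cM[ch]
      pos <- sort(runif(nm[ch], 0, len))
      gap <- config$marker_gap
      if (!is.null(gap) && gap$chr == ch)
        pos <- pos[pos < gap$from | pos > gap$to]
      forced <- numeric()
      for (q in config$qtl) if (q$chr == ch) forced <- c(forced, q$cM)
      if (!is.null(config$rowtype) && config$rowtype$chr == ch)
        forced <- c(forced, rep(config$rowtype$cM, 2L))  # co-segregating pair
      pos <- sort(c(pos, forced))
      site_list[[ch]] <- data.frame(chr = ch, cM = pos, type = "marker")
    }
    sites <- do.call(rbind, site_list)
    n_marker <- nrow(sites)
    n_dom <- round(config$dominant_fraction * n_marker)
    n_extra <- round(config$extra_site_fraction * n_marker)
    aux <- data.frame(
      chr = sample(config$n_chromosomes, n_dom + n_extra, replace = TRUE,
                   prob = prop),
      cM = NA_real_,
      type = rep(c("dominant", "extra"), c(n_dom, n_extra)))
    aux$cM <- runif(nrow(aux), 0, config$chrom_cM[aux$chr])
    sites <- rbind(sites, aux)
    sites <- sites[order(sites$chr, sites$cM), ]
    rownames(sites) <- NULL
    ns <- nrow(sites)

    # physical layout: per site [TTAA gapL MOTIF gapR TTAA] + pad
    gapL <- sample(210:430, ns, replace = TRUE)
    gapR <- sample(210:430, ns, replace = TRUE)
    pad <- sample(40:80, ns, replace = TRUE)
    fills <- .fillerStrings(c(gapL, gapR, pad), c(motif, mse))
    fL <- fills[seq_len(ns)]
    fR <- fills[ns + seq_len(ns)]
    fP <- fills[2L * ns + seq_len(ns)]

    sites$snp_dir <- ifelse(sites$type == "marker",
                            sample(c("F", "R"), ns, replace = TRUE), NA)
    sites$snp_offset <- ifelse(sites$type == "marker",
                               sample(5:(tagL - 1L), ns, replace = TRUE),
                               NA_integer_)

    contigsA <- character(config$n_chromosomes)
    site_pos <- integer(ns)
    for (ch in seq_len(config$n_chromosomes)) {
      idx <- which(sites$chr == ch)
      units <- paste0(mse, fL[idx], motif, fR[idx], mse, fP[idx])
      offs <- cumsum(c(0L, head(nchar(units), -1L)))
      site_pos[idx] <- offs + nchar(mse) + gapL[idx]  # 0-based motif start
      contigsA[ch] <- paste(units, collapse = "")
    }
    sites$site_pos <- site_pos
    chrNames <- paste0("chr", seq_len(config$n_chromosomes))

    # parent B: SNP substitutions + dominant-site motif loss
    contigsB <- contigsA
    ref <- alt <- rep(NA_character_, ns)
    for (i in which(sites$type == "marker")) {
      ch <- sites$chr[i]
      p <- sites$site_pos[i]
      o <- sites$snp_offset[i]
      if (sites$snp_dir[i] == "F") {
        gpos <- p + 1L + o + 1L            # 1-based genome position
        ref[i] <- substr(contigsA[ch], gpos, gpos)
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
        substr(contigsB[ch], gpos, gpos) <- alt[i]
      } else {
        gpos <- p + 5L - o                  # 1-based: tag offset o = p+4-o 0-based
        base_a <- substr(contigsA[ch], gpos, gpos)
        sub_b <- sample(setdiff(c("A", "C", "G", "T"), base_a), 1L)
        substr(contigsB[ch], gpos, gpos) <- sub_b
        ref[i] <- .revcomp(base_a)          # alleles in tag orientation
        alt[i] <- .revcomp(sub_b)
      }
    }
    for (i in which(sites$type == "dominant")) {
      ch <- sites$chr[i]
      gpos <- sites$site_pos[i] + 1L
      substr(contigsB[ch], gpos, gpos) <- "A"  # destroys CTGCAG in parent B
    }
    sites$ref <- ref
    sites$alt <- alt

    # read templates (overhang + downstream context, both directions)
    tmpl <- list()
    for (par in c("A", "B")) {
      ctg <- if (par == "A") contigsA else contigsB
      for (i in seq_len(ns)) {
        if (par == "B" && sites$type[i] == "dominant") next
        ch <- sites$chr[i]
        p <- sites$site_pos[i]
        tmpl[[paste(i, "F", par, sep = ":")]] <-
          substr(ctg[ch], p + 2L, p + 1L + tmplL)
        tmpl[[paste(i, "R", par, sep = ":")]] <-
          .revcomp(substr(ctg[ch], p + 6L - tmplL, p + 5L))
      }
    }
    templates <- unlist(tmpl)

    sites$locus <- NA_integer_
    seg <- sites$type %in% c("marker", "dominant")
    sites$locus[seg] <- seq_len(sum(seg))
    sites$marker_id <- ifelse(
      sites$type == "marker",
      paste(chrNames[sites$chr], sites$site_pos, sites$snp_dir, sep = ":"),
      NA)
    loci <- data.frame(locus = sites$locus[seg], chr = sites$chr[seg],
                       cM = sites$cM[seg],
                       kind = sites$type[seg], stringsAsFactors = FALSE)
    for (q in config$qtl) {
      loci <- rbind(loci, data.frame(locus = nrow(loci) + 1L, chr = q$chr,
                                     cM = q$cM, kind = "qtl"))
    }
    if (!is.null(config$rowtype))
      loci <- rbind(loci, data.frame(locus = nrow(loci) + 1L,
                                     chr = config$rowtype$chr,
                                     cM = config$rowtype$cM,
                                     kind = "rowtype"))
    loci <- loci[order(loci$chr, loci$cM, loci$locus), ]
    rownames(loci) <- NULL

    parentA <- Biostrings::DNAStringSet(setNames(contigsA, chrNames))
    parentB <- Biostrings::DNAStringSet(setNames(contigsB, chrNames))
    # chloroplast contig embedding two monomorphic tags verbatim
    extra <- which(sites$type == "extra")
    cp_parts <- .fillerStrings(c(900L, 300L, 900L), c(motif, mse))
    if (length(extra) >= 2L) {
      emb <- vapply(extra[1:2], function(i) {
        p <- sites$site_pos[i]
        substr(contigsA[sites$chr[i]], p + 2L, p + 1L + tagL)
      }, "")
      cp <- paste0(cp_parts[1L], emb[1L], cp_parts[2L], emb[2L],
                   cp_parts[3L])
    } else cp <- paste(cp_parts, collapse = "")

    list(parentA = parentA, parentB = parentB, cp_genome = cp,
         sites = sites, markers = sites[sites$type == "marker", ],
         loci = loci, templates = templates,
         chrom_cM = config$chrom_cM)
  })
}

# One meiosis of a diploid plant: list of two haplotype matrices
# (loci x 1 vectors). Haldane model: Poisson crossovers, no interference.
.meiosis <- function(hap1, hap2, loci, chrom_cM) {
  gam <- integer(length(hap1))
  for (ch in unique(loci$chr)) {
    idx <- which(loci$chr == ch)
    L <- chrom_cM[ch]
    k <- rpois(1L, L / 100)
    xo <- if (k > 0L) sort(runif(k, 0, L)) else numeric()
    phase <- (findInterval(loci$cM[idx], xo) +
                sample(0:1, 1L)) %% 2L
    gam[idx] <- ifelse(phase == 0L, hap1[idx], hap2[idx])
  }
  gam
}

#' Simulate an F11 single-seed-descent RIL population
#'
#' Starting from the F1 heterozygote, each line is selfed for
#' `selfing_gens` generations (single seed each generation); crossovers
#' follow the Haldane no-interference model on the true cM map, so the
#' residual per-locus heterozygosity has expectation `(1/2)^gens`.
#'
#' @param genomes Result of [makeParentalGenomes()] (uses `loci` and
#'   `chrom_cM`), or a list with those two elements.
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#' @return A list: `G` (loci x lines integer matrix: 0 = AA, 1 = AB,
#'   2 = BB), `loci`, `lines` (line ids).
#' @export
simulateRilPopulation <- function(genomes, config, seed) {
  loci <- genomes$loci
  chrom_cM <- genomes$chrom_cM %||% config$chrom_cM
  nl <- nrow(loci)
  lines <- sprintf("RIL%03d", seq_len(config$n_lines))
  .withSeed(.childSeed(seed, "ril"), {
    G <- matrix(0L, nl, config$n_lines, dimnames = list(NULL, lines))
    for (j in seq_len(config$n_lines)) {
      h1 <- rep(0L, nl)
      h2 <- rep(1L, nl)
      for (gen in seq_len(config$selfing_gens)) {
        g1 <- .meiosis(h1, h2, loci, chrom_cM)
        g2 <- .meiosis(h1, h2, loci, chrom_cM)
        h1 <- g1
        h2 <- g2
      }
      G[, j] <- h1 + h2
    }
    list(G = G, loci = loci, lines = lines)
  })
}

#' Simulate two-year heights and row type
#'
#' Height is baseline + additive QTL effects (per-year effect sizes) +
#' a line-specific deviation shared across years + independent
#' year-specific noise; the default variance components make the major
#' QTL explain ~55-62% of the variance and the between-year
#' correlation ~0.89. Row type is determined by the row-type locus:
#' parent-B homozygotes are six-rowed (the allele acts recessively, so
#' heterozygotes are two-rowed); the six-row class has the configured
#' (negative) height effect.
#'
#' @param ril Result of [simulateRilPopulation()].
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#' @return A `data.frame`: `line`, `height_y1` ... `height_y<n>`,
#'   `row_type` ("two"/"six").
#' @export
simulatePhenotypes <- function(ril, config, seed) {
  loci <- ril$loci
  G <- ril$G
  n <- ncol(G)
  .withSeed(.childSeed(seed, "pheno"), {
    genetic <- matrix(0, n, config$n_years)
    for (q in config$qtl) {
      li <- which(loci$kind == "qtl" & loci$chr == q$chr &
                    abs(loci$cM - q$cM) < 1e-9)[1L]
      dose <- G[li, ] / 2
      genetic <- genetic + outer(dose, q$effect[seq_len(config$n_years)])
    }
    row_type <- rep("two", n)
    if (!is.null(config$rowtype)) {
      li <- which(loci$kind == "rowtype")[1L]
      six <- G[li, ] == 2L
      row_type[six] <- "six"
      genetic <- genetic +
        outer(as.numeric(six),
              config$rowtype$effect[seq_len(config$n_years)])
    }
    dev <- rnorm(n, 0, config$sd_line)
    heights <- config$baseline + genetic + dev +
      matrix(rnorm(n * config$n_years, 0, config$sd_year), n)
    out <- data.frame(line = ril$lines, stringsAsFactors = FALSE)
    for (y in seq_len(config$n_years)) out[[paste0("height_y", y)]] <-
      heights[, y]
    out$row_type <- row_type
    out
  })
}

#' Simulate barcoded GBS reads with a per-read truth table
#'
#' Per-sample read counts are drawn from a clipped log-normal (parents
#' get the top of the range, emulating repeat sequencing); reads are
#' distributed over the sequenceable PstI-MseI fragments of each line's
#' haplotypes, composed as barcode + overhang + genomic context clipped
#' to the read length, given plateau qualities with occasional
#' low-quality 3' tails, and mutated with quality-consistent
#' substitution errors and a small N rate.
#'
#' @param genomes Result of [makeParentalGenomes()].
#' @param ril Result of [simulateRilPopulation()].
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#' @return A list: `reads` (list `id`, `seq`, `qual`), `barcodes`
#'   (`data.frame`), `truth` (`data.table`: read_id, sample, site, dir,
#'   hap), `depths` (per-sample read counts).
#' @export
simulateGbsReads <- function(genomes, ril, config, seed) {
  sites <- genomes$sites
  ns <- nrow(sites)
  samples <- c("parentA", "parentB", ril$lines)
  barcodes <- makeBarcodeSet(samples, seed = .childSeed(seed, "barcodes"))
  .withSeed(.childSeed(seed, "reads"), {
    q0 <- max(2L, min(40L, round(-10 * log10(max(config$error_rate,
                                                 1e-4)))))
    nsamp <- length(samples)
    depths <- round(config$depth_scale * pmin(pmax(
      exp(rnorm(nsamp, config$depth_meanlog, config$depth_sdlog)),
      config$depth_range[1L]), config$depth_range[2L]))
    depths[1:2] <- round(config$depth_scale * config$depth_range[2L])
    names(depths) <- samples

    # genotype at each site's locus, per sample (parents fixed 0/2)
    Gs <- matrix(0L, ns, nsamp, dimnames = list(NULL, samples))
    seg <- !is.na(sites$locus)
    rowOf <- match(sites$locus[seg], ril$loci$locus)
    Gs[seg, ril$lines] <- ril$G[rowOf, , drop = FALSE]
    Gs[, "parentB"] <- ifelse(is.na(sites$locus), 0L, 2L)
    Gs[sites$type == "extra", "parentB"] <- 0L

    pieces <- vector("list", nsamp)
    for (s in seq_len(nsamp)) {
      g <- Gs[, s]
      # fragment weight: dominant site lost on the B haplotype
      w <- rep(1, ns)
      dom <- sites$type == "dominant"
      w[dom & g == 2L] <- 0
      w[dom & g == 1L] <- 0.5
      w2 <- rep(w, 2L)  # F and R fragments
      nr <- depths[s]
      cnt <- as.integer(rmultinom(1L, nr, prob = w2 / sum(w2)))
      site_i <- rep(rep(seq_len(ns), 2L), cnt)
      dir_i <- rep(rep(c("F", "R"), each = ns), cnt)
      # haplotype per read: het loci emit both alleles 50/50
      g_i <- g[site_i]
      hap <- ifelse(g_i == 0L, "A", ifelse(g_i == 2L, "B", NA))
      het <- is.na(hap)
      if (any(het)) {
        hap[het] <- c("A", "B")[1L + rbinom(sum(het), 1L, 0.5)]
        # a het read from the lost-site haplotype of a dominant tag
        # cannot exist; those fragments only carry the A haplotype
        hap[het & dom[site_i]] <- "A"
      }
      pieces[[s]] <- data.table(sample = samples[s], site = site_i,
                                dir = dir_i, hap = hap)
    }
    truth <- rbindlist(pieces)
    nreads <- nrow(truth)
    truth <- truth[sample.int(nreads)]  # shuffle lanes
    truth[, read_id := sprintf("r%07d", seq_len(nreads))]

    bc <- barcodes$barcode[match(truth$sample, barcodes$sample_id)]
    tkey <- paste(truth$site, truth$dir, truth$hap, sep = ":")
    tm <- genomes$templates[tkey]
    seqs <- paste0(bc, substr(tm, 1L, config$read_len - nchar(bc)))

    tail_len <- rbinom(nreads, 12L, 0.15)
    qc <- intToUtf8(q0 + 33L, multiple = FALSE)
    ql <- intToUtf8(10L + 33L, multiple = FALSE)
    quals <- paste0(strrep(qc, config$read_len - tail_len),
                    strrep(ql, tail_len))
    if (config$error_rate > 0) {
      seqs <- mutate_reads(seqs, quals, config$n_rate)
    } else if (config$n_rate > 0) {
      # error-free mode: plant only Ns, with an effectively perfect quality
      seqs <- mutate_reads(seqs,
                           rep(strrep("~", config$read_len), nreads),
                           config$n_rate)
    }
    list(reads = list(id = truth$read_id, seq = seqs, qual = quals),
         barcodes = barcodes,
         truth = as.data.frame(truth), depths = depths)
  })
}

#' Truth-table views of a simulated experiment
#'
#' `truthGenotypeMatrix` returns the planted marker genotypes as a
#' [GenotypeMatrix-class] (0/1/2 copies of the parent-B allele coded
#' a/h/b); `truthGeneticMap` returns the true marker order and cM
#' positions as a [GeneticMap-class]. Both operate on the output of
#' [makeParentalGenomes()] + [simulateRilPopulation()] (or the full
#' [simulateGbsExperiment()] list).
#'
#' @param genomes Result of [makeParentalGenomes()] (or a list with
#'   `genomes` and `ril`, as returned by [simulateGbsExperiment()]).
#' @param ril Result of [simulateRilPopulation()]; ignored when
#'   `genomes` already bundles it.
#' @return A [GenotypeMatrix-class] or [GeneticMap-class].
#' @export
truthGenotypeMatrix <- function(genomes, ril = NULL) {
  if (!is.null(genomes$genomes)) {
    ril <- genomes$ril
    genomes <- genomes$genomes
  }
  mk <- genomes$sites[genomes$sites$type == "marker", ]
  rows <- match(mk$locus, ril$loci$locus)
  G <- ril$G[rows, , drop = FALSE]
  calls <- matrix(NA_character_, nrow(G), ncol(G),
                  dimnames = list(mk$marker_id, ril$lines))
  calls[G == 0L] <- "a"
  calls[G == 1L] <- "h"
  calls[G == 2L] <- "b"
  new("GenotypeMatrix", calls = calls, quality = rep(40, nrow(G)),
      parentA = "parentA", parentB = "parentB",
      info = data.frame(chr = mk$chr, cM = mk$cM,
                        row.names = mk$marker_id))
}

#' @rdname truthGenotypeMatrix
#' @export
truthGeneticMap <- function(genomes, ril = NULL) {
  if (!is.null(genomes$genomes)) genomes <- genomes$genomes
  mk <- genomes$sites[genomes$sites$type == "marker", ]
  mk <- mk[order(mk$chr, mk$cM), ]
  tab <- data.frame(group = paste0("chr", mk$chr), marker = mk$marker_id,
                    cM = mk$cM, stringsAsFactors = FALSE)
  # per-group positions re-anchored at the first marker
  tab$cM <- tab$cM - stats::ave(tab$cM, tab$group, FUN = min)
  new("GeneticMap", table = tab,
      redundancy = setNames(vector("list", 0L), character()),
      isolated = character(),
      dropped = data.frame(marker = character(), reason = character()),
      ledger = makeMapLedger(data.frame(
        group = unique(tab$group),
        clustered = as.integer(table(tab$group)[unique(tab$group)]),
        mapped = as.integer(table(tab$group)[unique(tab$group)]),
        cosegregating = 0L)))
}

#' Run the full simulator and (optionally) write a run directory
#'
#' Generates parental genomes, the RIL population, phenotypes and raw
#' reads under one master seed, returning everything in memory and,
#' when `dir` is given, writing the standard text artifacts: parental
#' FASTAs, chloroplast FASTA, pooled FASTQ, barcode TSV, phenotype TSV
#' and truth TSVs. Fully deterministic: a fixed seed gives
#' byte-identical output.
#'
#' @param config A [simConfig()] object.
#' @param seed Integer master seed.
#' @param dir Optional output directory.
#' @return A list: `config`, `genomes`, `ril`, `phenotypes`, `gbs`.
#' @export
simulateGbsExperiment <- function(config = simConfig(), seed, dir = NULL) {
  if (missing(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required")
  genomes <- makeParentalGenomes(config, seed)
  ril <- simulateRilPopulation(genomes, config, seed)
  pheno <- simulatePhenotypes(ril, config, seed)
  gbs <- simulateGbsReads(genomes, ril, config, seed)
  out <- list(config = config, genomes = genomes, ril = ril,
              phenotypes = pheno, gbs = gbs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(genomes$parentA,
                                file.path(dir, "parentA.fa"))
    Biostrings::writeXStringSet(genomes$parentB,
                                file.path(dir, "parentB.fa"))
    writeLines(c(">chloroplast", genomes$cp_genome),
               file.path(dir, "chloroplast.fa"))
    writeFastq(gbs$reads, file.path(dir, "reads.fastq"))
    write.table(gbs$barcodes, file.path(dir, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pheno, file.path(dir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(genomes$sites, file.path(dir, "truth_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    geno <- cbind(ril$loci, as.data.frame(ril$G))
    write.table(geno, file.path(dir, "truth_genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gbs$truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                             TRUE)],
                     file.path(dir, "config.yaml"))
  }
  out
}
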