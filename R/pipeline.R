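.pipelineDefaults <- function() {
  list(
    simulate = list(),                     # simConfig() overrides
    ref_tags = list(motif = "CTGCAG", flank_len = 64L,
                    screen_chloroplast = TRUE,
                    cp_min_identity = 0.90, cp_min_align_len = 64L),
    demux = list(min_q = 20L, out_len = 64L, n_check = "stripped"),
    filters = as.list(defaultFilterThresholds()),
    call = list(min_alt_reads = 4L),
    genotype = list(hi = 0.8, lo = 0.2, min_hom_depth = 3L,
                    min_het_depth = 6L),
    map = list(lod_threshold = 6, max_missing = 0.2, min_overlap = 0.5,
               n_starts = 10L, map_fun = "haldane", max_dxo = 3L),
    qtl = list(step_cm = 1, n_perm = 1000L, alpha = 0.05,
               window_cm = 10, lod_drop = 1),
    seed = NULL
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults for every stage, rejects unknown keys (naming the
#' offender) and requires a seed, since simulation, marker ordering and
#' the permutation test are all seeded.
#'
#' @param config Nested list of per-stage settings, or a YAML file path.
#' @return The normalised configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  def <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration section: ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (sec %in% c("seed", "simulate")) next
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  out <- def
  for (sec in setdiff(names(config), "seed"))
    out[[sec]][names(config[[sec]])] <- config[[sec]]
  out$seed <- config$seed
  if (is.null(out$seed))
    stop("config$seed is required (simulation, ordering and permutations)")
  if (!is.null(config$simulate)) {
    ok <- names(formals(simConfig))
    bad <- setdiff(names(config$simulate), ok)
    if (length(bad))
      stop("unknown key in section 'simulate': ",
           paste(bad, collapse = ", "))
  }
  out
}

#' Run the full GBS pipeline end-to-end on simulated data
#'
#' simulate -> reference tags -> demultiplex -> map -> pileup -> SNP
#' calling and filter cascade -> genotype recoding -> linkage map ->
#' QTL scans (per-year interval scans with 1,000-permutation
#' thresholds, a cofactor-adjusted scan, the row-type association and
#' the joint three-locus model). Every stage appends to a run ledger
#' whose counts conserve (inputs = outputs + rejections). Text
#' artifacts are written to `dir` when given, so a failed run leaves
#' the completed stages on disk.
#'
#' @param config A configuration list (see [validateConfig()]).
#' @param dir Optional run directory for text artifacts.
#' @param quiet Suppress progress messages.
#' @return A list with every stage result (`sim`, `tags`, `demux`,
#'   `mapres`, `pileup`, `snps`, `cascade`, `genotypes`, `map`,
#'   `probs`, `scans`, `thresholds`, `rmqm`, `rowtype_assoc`, `joint`,
#'   `ledger`).
#' @export
runPipeline <- function(config = list(), dir = NULL, quiet = FALSE) {
  cfg <- validateConfig(config)
  seed <- cfg$seed
  say <- function(...) if (!quiet) message(...)
  ledger <- list()
  note <- function(stage, input, output, detail = "") {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, input = input, output = output, detail = detail,
      stringsAsFactors = FALSE)
  }

  say("simulate: generating GBS experiment (seed ", seed, ")")
  scfg <- do.call(simConfig, cfg$simulate)
  sim <- simulateGbsExperiment(scfg, seed = seed,
                               dir = if (!is.null(dir))
                                 file.path(dir, "sim") else NULL)
  note("simulate", NA, length(sim$gbs$reads$id),
       sprintf("%d lines, %d sites", scfg$n_lines, nrow(sim$genomes$sites)))

  say("ref-tags: extracting reference tags from parent A assembly")
  tags <- buildReferenceTags(sim$genomes$parentA,
                             motif = cfg$ref_tags$motif,
                             flank_len = cfg$ref_tags$flank_len,
                             source = "parentA")
  n_raw <- length(tags@tags)
  note("ref-tags", 2L * (n_raw + nrow(tags@exclusions)) / 2L, n_raw,
       sprintf("%d flank exclusions", nrow(tags@exclusions)))
  if (isTRUE(cfg$ref_tags$screen_chloroplast)) {
    scr <- screenChloroplast(tags, sim$genomes$cp_genome,
                             min_identity = cfg$ref_tags$cp_min_identity,
                             min_align_len = cfg$ref_tags$cp_min_align_len)
    note("chloroplast-screen", n_raw, length(scr$kept@tags),
         sprintf("%d removed", length(scr$removed@tags)))
    tags <- scr$kept
  }
  if (!is.null(dir)) writeReferenceTags(tags, file.path(dir, "tags.fa"))

  say("demux: assigning ", length(sim$gbs$reads$id), " reads")
  demux <- demultiplexReads(sim$gbs$reads, sim$gbs$barcodes,
                            min_q = cfg$demux$min_q,
                            out_len = cfg$demux$out_len,
                            n_check = cfg$demux$n_check)
  stopifnot(nrow(demux$assigned) + nrow(demux$rejects) ==
              length(sim$gbs$reads$id))
  note("demux", length(sim$gbs$reads$id), nrow(demux$assigned),
       paste(sprintf("%s=%d", names(demux$stats$reasons),
                     demux$stats$reasons), collapse = ","))

  say("map: mapping to ", length(tags@tags), " tags")
  index <- buildTagIndex(tags)
  mapres <- mapReads(demux$assigned$seq, index)
  tb <- table(factor(mapres$status,
                     levels = c("mapped", "ambiguous", "unmapped")))
  stopifnot(sum(tb) == nrow(demux$assigned))
  note("map", nrow(demux$assigned), tb[["mapped"]],
       sprintf("ambiguous=%d,unmapped=%d", tb[["ambiguous"]],
               tb[["unmapped"]]))
  samples <- c("parentA", "parentB", sim$ril$lines)
  pileup <- accumulatePileup(demux$assigned, mapres, index,
                             samples = samples)

  say("call: SNP discovery and filter cascade")
  snps <- callCandidateSnps(pileup,
                            min_alt_reads = cfg$call$min_alt_reads)
  casc <- applyFilterCascade(snps, parent_a = "parentA",
                             parent_b = "parentB", pileup = pileup,
                             thresholds = cfg$filters)
  for (k in seq_len(nrow(casc$ledger)))
    note(paste0("filter:", casc$ledger$stage[k]),
         if (k == 1L) nrow(snps@info) else casc$ledger$survivors[k - 1L],
         casc$ledger$survivors[k])
  if (!is.null(dir)) exportVcf(casc$records, file.path(dir, "snps.vcf"))

  say("genotype: proportion-rule calls and parental recoding")
  states <- callGenotypes(casc$passed, hi = cfg$genotype$hi,
                          lo = cfg$genotype$lo,
                          min_hom_depth = cfg$genotype$min_hom_depth,
                          min_het_depth = cfg$genotype$min_het_depth)
  rownames(states) <- casc$passed@info$tag_id
  rec <- recodeParental(states, "parentA", "parentB",
                        quality = casc$passed@info$quality,
                        info = casc$passed@info)
  note("recode", nrow(states), nrow(rec$genotypes@calls),
       paste(sprintf("%s=%d", names(table(rec$dropped$reason)),
                     table(rec$dropped$reason)), collapse = ","))
  gm <- rec$genotypes
  if (!is.null(dir)) {
    gtab <- cbind(marker = rownames(gm@calls),
                  as.data.frame(ifelse(is.na(gm@calls), "-", gm@calls)))
    write.table(gtab, file.path(dir, "genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  say("mapbuild: linkage map from ", nrow(gm@calls), " markers")
  gmap <- buildGeneticMap(gm, lod_threshold = cfg$map$lod_threshold,
                          max_missing = cfg$map$max_missing,
                          min_overlap = cfg$map$min_overlap,
                          seed = .childSeed(seed, "order"),
                          n_starts = cfg$map$n_starts,
                          map_fun = cfg$map$map_fun,
                          max_dxo = cfg$map$max_dxo)
  note("mapbuild", nrow(gm@calls), nrow(gmap@table),
       sprintf("groups=%d,isolated=%d", length(unique(gmap@table$group)),
               length(gmap@isolated)))
  if (!is.null(dir)) {
    writeGeneticMap(gmap, file.path(dir, "map.tsv"))
    write.table(gmap@ledger, file.path(dir, "map_ledger.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  say("qtl: interval scans, thresholds, cofactor scan, joint model")
  probs <- genotypeProbabilities(gmap, gm, step_cm = cfg$qtl$step_cm)
  years <- grep("^height_y", names(sim$phenotypes), value = TRUE)
  scans <- list()
  thresholds <- list()
  for (y in years) {
    trait <- setNames(sim$phenotypes[[y]], sim$phenotypes$line)
    sc <- intervalScan(trait, probs)
    thr <- permutationThreshold(trait, probs, n_perm = cfg$qtl$n_perm,
                                alpha = cfg$qtl$alpha,
                                seed = .childSeed(seed, paste0("perm", y)))
    sc@threshold <- as.numeric(thr)
    scans[[y]] <- sc
    thresholds[[y]] <- thr
  }
  trait1 <- setNames(sim$phenotypes[[years[1L]]], sim$phenotypes$line)
  peak <- scans[[1L]]@table[which.max(scans[[1L]]@table$lod), ]
  cof_mk <- {
    mt <- gmap@table
    cand <- mt[mt$group == peak$group, ]
    cand$marker[which.min(abs(cand$cM - peak$cM))]
  }
  rmqm <- rmqmScan(trait1, probs, cofactors = cof_mk,
                   window_cm = cfg$qtl$window_cm)
  rowtype <- setNames(sim$phenotypes$row_type, sim$phenotypes$line)
  assoc <- binaryAssociation(gm, rowtype)
  loci <- data.frame(
    major = as.numeric(gm@calls[cof_mk, ] == "b"),
    row.names = colnames(gm@calls))
  minor_pk <- {
    tb2 <- rmqm@table[rmqm@table$group != peak$group, ]
    p2 <- tb2[which.max(tb2$lod), ]
    cand <- gmap@table[gmap@table$group == p2$group, ]
    cand$marker[which.min(abs(cand$cM - p2$cM))]
  }
  loci$minor <- as.numeric(gm@calls[minor_pk, ] == "b")
  loci$sixrow <- as.numeric(rowtype[rownames(loci)] == "six")
  joint <- jointModel(trait1, loci)
  note("qtl", nrow(gmap@table), nrow(scans[[1L]]@table),
       sprintf("thresholds=%s",
               paste(sprintf("%.2f", unlist(thresholds)), collapse = "/")))

  ledger <- do.call(rbind, ledger)
  if (!is.null(dir)) {
    write.table(ledger, file.path(dir, "run_ledger.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (y in years)
      write.table(scans[[y]]@table,
                  file.path(dir, sprintf("scan_%s.tsv", y)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  list(config = cfg, sim = sim, tags = tags, demux = demux,
       mapres = mapres, pileup = pileup, snps = snps, cascade = casc,
       genotypes = gm, map = gmap, probs = probs, scans = scans,
       thresholds = thresholds, rmqm = rmqm, rowtype_assoc = assoc,
       joint = joint, ledger = ledger)
}
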