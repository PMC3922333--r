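.encodeCalls <- function(calls) {
  m <- matrix(0L, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  m[calls == "a"] <- 1L
  m[calls == "b"] <- 2L
  m[calls == "h"] <- 3L
  m
}

# restore RNG state on exit so seeded internals do not perturb callers
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Collapse markers with identical segregation patterns
#'
#' Markers whose non-missing calls agree at every progeny called in both
#' and that share at least `min_overlap` of the progeny are grouped; the
#' highest-quality member represents each group, so lower-quality
#' co-segregating markers are the ones dropped.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param min_overlap Minimum shared-call fraction of progeny
#'   (default 0.5).
#' @param exact_only If `TRUE`, collapse only markers with identical
#'   complete patterns (no missing-tolerant matching).
#' @return A list: `genotypes` (reduced [GenotypeMatrix-class]) and
#'   `redundancy` (named list, representative -> collapsed markers).
#' @export
collapseIdentical <- function(gm, min_overlap = 0.5, exact_only = FALSE) {
  stopifnot(is(gm, "GenotypeMatrix"))
  cl <- gm@calls
  n <- ncol(cl)
  ord <- order(-gm@quality, rownames(cl))  # quality desc, stable
  enc <- .encodeCalls(cl)[ord, , drop = FALSE]
  min_shared <- if (exact_only) n else as.integer(ceiling(min_overlap * n))
  if (exact_only) {
    # exact mode: only complete identical patterns collapse
    key <- apply(enc, 1L, paste, collapse = "")
    complete <- !grepl("0", key, fixed = TRUE)
    rep_idx <- seq_len(nrow(enc))
    idx_c <- which(complete)
    rep_idx[idx_c] <- idx_c[match(key[idx_c], key[idx_c])]
  } else {
    rep_idx <- collapse_groups(enc, min_shared)
  }
  mk <- rownames(enc)
  reps <- unique(rep_idx)
  redundancy <- lapply(reps, function(r) mk[rep_idx == r & seq_along(mk) != r])
  names(redundancy) <- mk[reps]
  keep_names <- mk[reps]
  keep <- match(keep_names, rownames(cl))
  out <- new("GenotypeMatrix", calls = cl[keep, , drop = FALSE],
             quality = gm@quality[keep], parentA = gm@parentA,
             parentB = gm@parentB,
             info = gm@info[keep, , drop = FALSE])
  list(genotypes = out, redundancy = redundancy)
}

#' Drop markers with excessive missing data
#'
#' A marker is kept when its missing fraction across progeny is at most
#' `max_missing` (strictly greater is excluded).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param max_missing Maximum missing fraction (default 0.2).
#' @return A list: `genotypes` (reduced matrix) and `dropped` (character
#'   vector of excluded markers).
#' @export
filterMissing <- function(gm, max_missing = 0.2) {
  stopifnot(is(gm, "GenotypeMatrix"))
  miss <- rowMeans(is.na(gm@calls))
  keep <- miss <= max_missing
  out <- new("GenotypeMatrix", calls = gm@calls[keep, , drop = FALSE],
             quality = gm@quality[keep], parentA = gm@parentA,
             parentB = gm@parentB, info = gm@info[keep, , drop = FALSE])
  list(genotypes = out, dropped = rownames(gm@calls)[!keep])
}

#' Pairwise recombination fractions and independence LOD scores
#'
#' Heterozygous calls are treated as missing (negligible information in
#' a late-generation RIL). For each marker pair, `R` is the recombinant
#' fraction over progeny informative for both, and the independence LOD
#' is the log10 likelihood ratio of the observed parental/recombinant
#' split under the estimated `R` (capped at 0.5) versus independent
#' assortment (`R = 0.5`).
#'
#' @param gm A [GenotypeMatrix-class] (or character call matrix).
#' @return A list of markers x markers matrices: `R`, `lod`, `ninf`
#'   (informative progeny counts). Pairs with no informative progeny
#'   have `R = NA`, `lod = NA`.
#' @export
pairwiseLinkage <- function(gm) {
  cl <- if (is(gm, "GenotypeMatrix")) gm@calls else gm
  A <- (cl == "a") & !is.na(cl)
  B <- (cl == "b") & !is.na(cl)
  storage.mode(A) <- "numeric"
  storage.mode(B) <- "numeric"
  naa <- tcrossprod(A)
  nbb <- tcrossprod(B)
  nab <- A %*% t(B)
  par <- naa + nbb
  rec <- nab + t(nab)
  ninf <- par + rec
  R <- ifelse(ninf > 0, rec / ninf, NA)
  Rc <- pmin(R, 0.5)
  lod <- ifelse(par > 0, par * log10(2 * (1 - Rc)), 0) +
    ifelse(rec > 0, rec * log10(2 * Rc), 0)
  lod[ninf == 0] <- NA
  list(R = R, lod = lod, ninf = ninf)
}

#' Cluster markers into linkage groups by independence LOD
#'
#' Single-linkage transitive closure over marker pairs whose
#' independence LOD reaches the threshold; singleton components are
#' reported as isolated markers.
#'
#' @param pairs Result of [pairwiseLinkage()].
#' @param lod_threshold Grouping LOD (default 6).
#' @return A list: `groups` (list of marker-name vectors, largest
#'   first) and `isolated` (character vector).
#' @export
groupMarkers <- function(pairs, lod_threshold = 6) {
  lod <- pairs$lod
  adj <- !is.na(lod) & lod >= lod_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  mk <- rownames(lod)
  groups <- split(mk, comp$membership)
  sizes <- lengths(groups)
  isolated <- unlist(groups[sizes == 1L], use.names = FALSE)
  groups <- groups[sizes > 1L]
  groups <- groups[order(-lengths(groups))]
  # paste0 recycles zero-length to "", so guard the empty case
  names(groups) <- if (length(groups)) paste0("LG", seq_along(groups))
                   else character()
  list(groups = groups,
       isolated = if (is.null(isolated)) character() else
         as.character(isolated))
}

.sarf <- function(R, ord) sum(R[cbind(ord[-length(ord)], ord[-1L])])

#' Order markers within a linkage group
#'
#' Seeded multi-start heuristic minimising the sum of adjacent
#' recombination fractions: greedy chain extension from several start
#' markers followed by 2-opt segment-reversal polishing. Deterministic
#' given the seed; the achieved objective is attached as attribute
#' `"objective"`.
#'
#' @param R Recombination-fraction matrix restricted to the group
#'   (dimnames = marker names); `NA` entries are treated as 0.5.
#' @param seed Integer seed.
#' @param n_starts Number of greedy starts (default 10).
#' @return Character vector of ordered marker names.
#' @export
orderGroup <- function(R, seed = 1L, n_starts = 10L) {
  n <- nrow(R)
  mk <- rownames(R)
  if (n <= 2L) {
    out <- mk
    attr(out, "objective") <- if (n == 2L) R[1L, 2L] else 0
    return(out)
  }
  R[is.na(R)] <- 0.5
  .withSeed(seed, {
    starts <- unique(c(which.min(apply(R, 1L, function(x) sort(x)[2L])),
                       sample.int(n, min(n, n_starts))))[
                         seq_len(min(n, n_starts))]
    best <- NULL
    bestObj <- Inf
    for (s in starts) {
      ord <- .greedyChain(R, s)
      ord <- .twoOpt(R, ord)
      obj <- .sarf(R, ord)
      if (obj < bestObj - 1e-12) {
        bestObj <- obj
        best <- ord
      }
    }
    out <- mk[best]
    attr(out, "objective") <- bestObj
    out
  })
}

.greedyChain <- function(R, start) {
  n <- nrow(R)
  used <- rep(FALSE, n)
  chain <- c(start)
  used[start] <- TRUE
  while (length(chain) < n) {
    free <- which(!used)
    dl <- R[chain[1L], free]
    dr <- R[chain[length(chain)], free]
    if (min(dl) <= min(dr)) {
      pick <- free[which.min(dl)]
      chain <- c(pick, chain)
    } else {
      pick <- free[which.min(dr)]
      chain <- c(chain, pick)
    }
    used[pick] <- TRUE
  }
  chain
}

.twoOpt <- function(R, ord, max_sweeps = 60L) {
  n <- length(ord)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        before <- (if (i > 1L) R[ord[i - 1L], ord[i]] else 0) +
          (if (j < n) R[ord[j], ord[j + 1L]] else 0)
        after <- (if (i > 1L) R[ord[i - 1L], ord[j]] else 0) +
          (if (j < n) R[ord[i], ord[j + 1L]] else 0)
        if (after < before - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

#' Convert observed RIL recombinant fractions to map distances
#'
#' Adjacent observed fractions are first corrected for repeated selfing
#' by the Haldane-Waddington inverse `r = R / (2 (1 - R))` and then
#' converted to centimorgans with the Haldane map function
#' `d = -50 ln(1 - 2 r)` (Kosambi selectable). Fractions at or above 0.5
#' are capped at `max_gap` with a warning.
#'
#' @param R_adj Numeric vector of adjacent observed recombinant
#'   fractions (length = markers - 1).
#' @param map_fun `"haldane"` (default) or `"kosambi"`.
#' @param max_gap Distance cap in cM for unlinked-looking adjacencies
#'   (default 50).
#' @return Numeric vector of cumulative cM positions starting at 0.
#' @export
assignCm <- function(R_adj, map_fun = c("haldane", "kosambi"),
                     max_gap = 50) {
  map_fun <- match.arg(map_fun)
  if (!length(R_adj)) return(0)
  bad <- !is.na(R_adj) & R_adj >= 0.5
  r <- ifelse(bad, NA, R_adj / (2 * (1 - R_adj)))
  d <- if (map_fun == "haldane") -50 * log(1 - 2 * r)
       else 25 * log((1 + 2 * r) / (1 - 2 * r))
  d[bad | is.na(d) | d > max_gap] <- max_gap
  if (any(bad)) warning(sum(bad), " adjacent fraction(s) >= 0.5 capped at ",
                        max_gap, " cM")
  cumsum(c(0, d))
}

#' Remove markers that fit their neighbours poorly
#'
#' A marker showing apparent double crossovers (its call differs from
#' two agreeing immediate neighbours) in more than `max_dxo` progeny is
#' removed; this is a singleton-switch heuristic for the "poor fit"
#' criterion and is labelled as such in the map ledger.
#'
#' @param ordered Character vector of ordered markers in one group.
#' @param calls Character call matrix (markers x progeny).
#' @param max_dxo Maximum tolerated double-crossover progeny (default 3).
#' @return Character vector of markers to remove.
#' @export
dropPoorFit <- function(ordered, calls, max_dxo = 3L) {
  n <- length(ordered)
  if (n < 3L) return(character())
  cl <- calls[ordered, , drop = FALSE]
  ab <- cl %in% c("a", "b")
  dim(ab) <- dim(cl)
  dxo <- integer(n)
  for (j in 2:(n - 1L)) {
    ok <- ab[j - 1L, ] & ab[j, ] & ab[j + 1L, ]
    dxo[j] <- sum(ok & cl[j - 1L, ] == cl[j + 1L, ] &
                    cl[j, ] != cl[j - 1L, ])
  }
  ordered[dxo > max_dxo]
}

#' Build a genetic linkage map from a genotype matrix
#'
#' Full map construction: collapse co-segregating markers (keeping the
#' higher-quality member), drop high-missingness markers, group by
#' independence LOD, order each group by seeded multi-start seriation,
#' assign Haldane-Waddington-corrected cM positions, remove poor-fit
#' markers and re-order once. The per-group ledger accounts for every
#' input marker: mapped + co-segregating + missing-filtered + isolated +
#' poor-fit = input.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param lod_threshold Grouping LOD (default 6).
#' @param max_missing Missing-fraction cut (default 0.2).
#' @param min_overlap Shared-call fraction for the co-segregation
#'   collapse (default 0.5).
#' @param seed Integer seed for ordering.
#' @param n_starts Ordering starts per group (default 10).
#' @param map_fun Map function, `"haldane"` or `"kosambi"`.
#' @param max_dxo Poor-fit double-crossover tolerance (default 3).
#' @return A [GeneticMap-class].
#' @export
buildGeneticMap <- function(gm, lod_threshold = 6, max_missing = 0.2,
                            min_overlap = 0.5, seed = 1L, n_starts = 10L,
                            map_fun = "haldane", max_dxo = 3L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  n_in <- nrow(gm@calls)
  col <- collapseIdentical(gm, min_overlap = min_overlap)
  red <- col$redundancy
  fil <- filterMissing(col$genotypes, max_missing = max_missing)
  g2 <- fil$genotypes
  pr <- pairwiseLinkage(g2)
  grp <- groupMarkers(pr, lod_threshold = lod_threshold)

  dropped <- data.frame(marker = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (length(fil$dropped))
    dropped <- rbind(dropped, data.frame(marker = fil$dropped,
                                         reason = "missing-filtered"))
  coseg <- unlist(red, use.names = FALSE)
  if (length(coseg))
    dropped <- rbind(dropped, data.frame(marker = coseg,
                                         reason = "co-segregating"))

  rows <- list()
  ledger <- list()
  poor_all <- character()
  for (gname in names(grp$groups)) {
    mks <- grp$groups[[gname]]
    Rsub <- pr$R[mks, mks, drop = FALSE]
    ord <- orderGroup(Rsub, seed = .childSeed(seed, gname),
                      n_starts = n_starts)
    poor <- dropPoorFit(as.character(ord), g2@calls, max_dxo = max_dxo)
    n_clustered <- length(mks)
    if (length(poor)) {
      mks <- setdiff(mks, poor)
      poor_all <- c(poor_all, poor)
      Rsub <- pr$R[mks, mks, drop = FALSE]
      ord <- orderGroup(Rsub, seed = .childSeed(seed, paste0(gname, "b")),
                        n_starts = n_starts)
    }
    ordv <- as.character(ord)
    adjR <- if (length(ordv) > 1L)
      pr$R[cbind(ordv[-length(ordv)], ordv[-1L])] else numeric()
    cm <- assignCm(adjR, map_fun = map_fun)
    rows[[gname]] <- data.frame(group = gname, marker = ordv, cM = cm,
                                stringsAsFactors = FALSE)
    n_coseg <- sum(lengths(red[ordv]))
    ledger[[gname]] <- data.frame(group = gname, clustered = n_clustered,
                                  mapped = length(ordv),
                                  cosegregating = n_coseg,
                                  stringsAsFactors = FALSE)
  }
  if (length(poor_all))
    dropped <- rbind(dropped, data.frame(marker = poor_all,
                                         reason = "poor-fit"))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), marker = character(), cM = numeric())
  rownames(tab) <- NULL
  led <- makeMapLedger(if (length(ledger)) do.call(rbind, ledger) else
    data.frame(group = character(), clustered = integer(),
               mapped = integer(), cosegregating = integer()))
  new("GeneticMap", table = tab, redundancy = red,
      isolated = grp$isolated, dropped = dropped, ledger = led)
}

#' Per-group map ledger with totals
#'
#' Appends a `Total` row to a per-group summary of markers clustered,
#' mapped and co-segregating, the same accounting used in published GBS
#' map summaries.
#'
#' @param per_group `data.frame` with columns `group`, `clustered`,
#'   `mapped` and (optionally) `cosegregating`.
#' @return The ledger `data.frame` with a totals row.
#' @export
makeMapLedger <- function(per_group) {
  stopifnot(all(c("group", "clustered", "mapped") %in% names(per_group)))
  num <- setdiff(names(per_group), "group")
  tot <- c(group = "Total",
           lapply(per_group[num], function(x) sum(x)))
  rbind(per_group, as.data.frame(tot, stringsAsFactors = FALSE))
}

#' Write a genetic map as TSV
#'
#' @param map A [GeneticMap-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeGeneticMap <- function(map, file) {
  tb <- map@table
  tb$redundancy <- lengths(map@redundancy[tb$marker])
  write.table(tb, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
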