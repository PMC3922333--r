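# Observed RIL recombinant fraction across a map distance d (cM):
# Haldane per-meiosis fraction, then Haldane-Waddington accumulation
# over repeated selfing.
.rilR <- function(d) {
  r <- (1 - exp(-2 * d / 100)) / 2
  2 * r / (1 + 2 * r)
}

#' Conditional genotype probabilities on a cM grid
#'
#' For every line and every grid position, the probability of carrying
#' the parent-B allele given the nearest informative flanking markers
#' (heterozygous and missing calls are uninformative). At a marker the
#' probability is 0/1 for called lines; between markers it follows the
#' two-flank conditional with Haldane recombination accumulated to the
#' RIL scale; lines with no informative marker in a group get 0.5.
#' Marker positions are merged into the grid so marker columns are
#' always present.
#'
#' @param map A [GeneticMap-class].
#' @param gm A [GenotypeMatrix-class] on the mapped markers.
#' @param step_cm Grid step in cM (default 1).
#' @return A list with `groups` (per linkage group: `cM` grid and `pb`,
#'   a lines x positions matrix of P(b)), `lines`, and `markers` (the
#'   map table).
#' @export
genotypeProbabilities <- function(map, gm, step_cm = 1) {
  stopifnot(is(map, "GeneticMap"), is(gm, "GenotypeMatrix"))
  tb <- map@table
  lines <- colnames(gm@calls)
  out <- list()
  for (g in unique(tb$group)) {
    sub <- tb[tb$group == g, ]
    mks <- intersect(sub$marker, rownames(gm@calls))
    if (!length(mks)) {
      warning("group ", g, " has no markers in the genotype matrix; skipped")
      next
    }
    sub <- sub[sub$marker %in% mks, ]
    grid <- sort(unique(c(seq(0, max(sub$cM), by = step_cm), sub$cM)))
    pb <- matrix(0.5, length(lines), length(grid),
                 dimnames = list(lines, NULL))
    cl <- gm@calls[sub$marker, , drop = FALSE]
    for (i in seq_along(lines)) {
      inf <- which(cl[, i] %in% c("a", "b"))
      if (!length(inf)) next
      pm <- sub$cM[inf]
      sv <- as.numeric(cl[inf, i] == "b")
      k <- findInterval(grid, pm)
      hasL <- k >= 1L
      hasR <- k < length(pm)
      p <- numeric(length(grid))
      # both flanks
      b2 <- hasL & hasR
      if (any(b2)) {
        RL <- .rilR(grid[b2] - pm[k[b2]])
        RR <- .rilR(pm[k[b2] + 1L] - grid[b2])
        sL <- sv[k[b2]]
        sR <- sv[k[b2] + 1L]
        same <- sL == sR
        pSame <- (1 - RL) * (1 - RR) / ((1 - RL) * (1 - RR) + RL * RR)
        pLeft <- (1 - RL) * RR / ((1 - RL) * RR + RL * (1 - RR))
        pB <- ifelse(same, ifelse(sL == 1, pSame, 1 - pSame),
                     ifelse(sL == 1, pLeft, 1 - pLeft))
        p[b2] <- pB
      }
      onlyL <- hasL & !hasR
      if (any(onlyL)) {
        RL <- .rilR(grid[onlyL] - pm[k[onlyL]])
        sL <- sv[k[onlyL]]
        p[onlyL] <- ifelse(sL == 1, 1 - RL, RL)
      }
      onlyR <- !hasL
      if (any(onlyR)) {
        RR <- .rilR(pm[1L] - grid[onlyR])
        sR <- sv[1L]
        p[onlyR] <- ifelse(sR == 1, 1 - RR, RR)
      }
      pb[i, ] <- p
    }
    out[[g]] <- list(cM = grid, pb = pb)
  }
  list(groups = out, lines = lines, markers = tb)
}

# Single-predictor Haley-Knott statistics for one dosage matrix.
.hkStats <- function(y, X, lod_cap = 300) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Xc <- sweep(X, 2L, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), 0)
  degen <- r2 >= 1 - 1e-12
  lod <- ifelse(degen, lod_cap, -(n / 2) * log10(pmax(1 - r2, 1e-300)))
  lod <- pmin(lod, lod_cap)
  effect <- ifelse(sxx > 0, sxy / sxx, 0)
  rss1 <- pmax(syy - ifelse(sxx > 0, sxy^2 / sxx, 0), 0)
  se <- ifelse(sxx > 0 & !degen, sqrt(rss1 / ((n - 2) * sxx)), NA)
  list(lod = lod, varexp = 100 * r2, effect = effect, se = se,
       degenerate = degen)
}

#' Haley-Knott interval mapping scan
#'
#' At each grid position the trait is regressed on the expected
#' parent-B dosage; `LOD = (n/2) log10(RSS0/RSS1)`, variance explained
#' is `100 (1 - RSS1/RSS0)` and the effect is the fitted b-minus-a
#' class-mean difference with its standard error. Zero-residual fits are
#' flagged degenerate and capped.
#'
#' @param trait Named numeric vector of per-line trait values (missing
#'   allowed; lines matched by name to the probability object).
#' @param probs Result of [genotypeProbabilities()].
#' @param min_lines Minimum number of phenotyped, genotyped lines
#'   (default 20).
#' @return A [QtlScan-class].
#' @export
intervalScan <- function(trait, probs, min_lines = 20L) {
  use <- names(trait)[!is.na(trait)]
  use <- intersect(use, probs$lines)
  if (length(use) < min_lines)
    stop("fewer than ", min_lines, " lines with trait and genotypes")
  y <- trait[use]
  rows <- lapply(names(probs$groups), function(g) {
    gr <- probs$groups[[g]]
    st <- .hkStats(y, gr$pb[use, , drop = FALSE])
    data.frame(group = g, cM = gr$cM, lod = st$lod, varexp = st$varexp,
               effect = st$effect, se = st$se, degenerate = st$degenerate,
               stringsAsFactors = FALSE)
  })
  new("QtlScan", table = do.call(rbind, rows), threshold = NA_real_,
      n = length(use), kind = "interval")
}

#' Genome-wide permutation LOD threshold
#'
#' Trait values are permuted across whole lines (preserving the marker
#' correlation structure) `n_perm` times with a fixed seed; the
#' genome-wide maximum LOD of each permutation is recorded and the
#' `1 - alpha` quantile returned.
#'
#' @inheritParams intervalScan
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   draws a warning).
#' @param alpha Genome-wide type-I error (default 0.05).
#' @param seed Integer seed (mandatory).
#' @return The LOD threshold; the permutation maxima are attached as
#'   attribute `"max_lods"`.
#' @export
permutationThreshold <- function(trait, probs, n_perm = 1000L,
                                 alpha = 0.05, seed) {
  if (missing(seed)) stop("seed is required for the permutation test")
  if (n_perm < 100L) warning("n_perm < 100 gives an unstable threshold")
  use <- intersect(names(trait)[!is.na(trait)], probs$lines)
  y <- trait[use]
  D <- do.call(cbind, lapply(probs$groups,
                             function(gr) gr$pb[use, , drop = FALSE]))
  n <- length(y)
  Dc <- sweep(D, 2L, colMeans(D))
  sxx <- colSums(Dc^2)
  keep <- sxx > 0
  Dc <- Dc[, keep, drop = FALSE]
  sxx <- sxx[keep]
  Y <- .withSeed(seed,
                 vapply(seq_len(n_perm), function(i) sample(y), numeric(n)))
  Yc <- sweep(Y, 2L, colMeans(Y))
  syy <- colSums(Yc^2)
  num <- crossprod(Dc, Yc)          # positions x permutations
  r2 <- sweep(num^2, 1L, sxx, "/")
  r2 <- sweep(r2, 2L, syy, "/")
  maxr2 <- apply(r2, 2L, max)
  lods <- -(n / 2) * log10(pmax(1 - maxr2, 1e-300))
  thr <- unname(quantile(lods, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- lods
  thr
}

#' Cofactor-adjusted (restricted MQM style) scan
#'
#' At each grid position the regression includes the supplied cofactor
#' markers as covariates, excluding any cofactor within `window_cm` of
#' the test position (same group); the LOD compares against the
#' cofactor-only null at that position.
#'
#' @inheritParams intervalScan
#' @param cofactors Character vector of mapped marker names.
#' @param window_cm Exclusion window around the test position
#'   (default 10).
#' @return A [QtlScan-class].
#' @export
rmqmScan <- function(trait, probs, cofactors, window_cm = 10,
                     min_lines = 20L) {
  if (!length(cofactors)) return(intervalScan(trait, probs,
                                              min_lines = min_lines))
  mk <- probs$markers
  bad <- setdiff(cofactors, mk$marker)
  if (length(bad)) stop("cofactors not on the map: ",
                        paste(bad, collapse = ", "))
  use <- intersect(names(trait)[!is.na(trait)], probs$lines)
  if (length(use) < min_lines)
    stop("fewer than ", min_lines, " lines with trait and genotypes")
  y <- trait[use]
  n <- length(y)
  cof <- mk[match(cofactors, mk$marker), ]
  cofX <- sapply(seq_len(nrow(cof)), function(i) {
    gr <- probs$groups[[cof$group[i]]]
    gr$pb[use, match(cof$cM[i], gr$cM)]
  })
  cofX <- matrix(cofX, ncol = nrow(cof))
  rows <- list()
  for (g in names(probs$groups)) {
    gr <- probs$groups[[g]]
    pb <- gr$pb[use, , drop = FALSE]
    m <- length(gr$cM)
    lod <- varexp <- effect <- se <- numeric(m)
    degen <- logical(m)
    for (j in seq_len(m)) {
      far <- !(cof$group == g & abs(cof$cM - gr$cM[j]) < window_cm)
      X0 <- cbind(1, cofX[, far, drop = FALSE])
      x <- pb[, j]
      X1 <- cbind(X0, x = x)
      f0 <- lm.fit(X0, y)
      f1 <- lm.fit(X1, y)
      rss0 <- sum(f0$residuals^2)
      rss1 <- sum(f1$residuals^2)
      b <- coef(f1)["x"]
      if (rss1 <= 1e-12 * max(rss0, 1)) {
        degen[j] <- TRUE
        lod[j] <- 300
        varexp[j] <- 100
        effect[j] <- if (is.na(b)) 0 else b
        se[j] <- NA
      } else {
        lod[j] <- (n / 2) * log10(rss0 / rss1)
        varexp[j] <- 100 * (1 - rss1 / rss0)
        if (is.na(b)) { effect[j] <- 0; se[j] <- NA } else {
          effect[j] <- b
          v <- tryCatch(solve(crossprod(X1))[ncol(X1), ncol(X1)],
                        error = function(e) NA_real_)
          se[j] <- sqrt(rss1 / (n - f1$rank) * v)
        }
      }
    }
    rows[[g]] <- data.frame(group = g, cM = gr$cM, lod = lod,
                            varexp = varexp, effect = effect, se = se,
                            degenerate = degen, stringsAsFactors = FALSE)
  }
  new("QtlScan", table = do.call(rbind, rows), threshold = NA_real_,
      n = n, kind = "rmqm")
}

#' LOD support interval around the scan peak
#'
#' The widest contiguous interval around the peak position whose LOD
#' stays within `drop` of the peak, in the peak's linkage group.
#'
#' @param scan A [QtlScan-class].
#' @param drop LOD drop (1 for one-LOD, 2 for two-LOD intervals).
#' @param threshold Optional significance threshold; `NULL` (no check)
#'   by default. If given and the peak is below it, `NULL` is returned.
#' @return `list(group=, peak_cM=, left=, right=)`, or `NULL`.
#' @export
supportInterval <- function(scan, drop = 1, threshold = NULL) {
  tb <- scan@table
  pk <- which.max(tb$lod)
  if (!is.null(threshold) && tb$lod[pk] < threshold) return(NULL)
  g <- tb$group[pk]
  sub <- tb[tb$group == g, ]
  i <- which(sub$cM == tb$cM[pk] & sub$lod == tb$lod[pk])[1L]
  ok <- sub$lod >= tb$lod[pk] - drop
  l <- i
  while (l > 1L && ok[l - 1L]) l <- l - 1L
  r <- i
  while (r < nrow(sub) && ok[r + 1L]) r <- r + 1L
  list(group = g, peak_cM = sub$cM[i], left = sub$cM[l], right = sub$cM[r])
}

#' Joint additive multi-locus model with interaction test
#'
#' Fits the trait on additive locus terms, reports the joint variance
#' explained, per-locus effects with standard errors, and an F-test of
#' all pairwise interactions against the additive model.
#'
#' @param trait Named numeric per-line trait vector.
#' @param loci Named list or data.frame of per-line locus codings
#'   (numeric dosages or 0/1 indicators), names matching `trait`.
#' @return A list: `fit` (the additive `lm`), `varexp` (percent),
#'   `effects` (`data.frame`: term, effect, se), `interaction_F`,
#'   `interaction_p`, `dropped_collinear`.
#' @export
jointModel <- function(trait, loci) {
  df <- as.data.frame(loci)
  stopifnot(!is.null(names(trait)))
  df <- df[names(trait), , drop = FALSE]
  df$.y <- unname(trait)
  df <- df[complete.cases(df), , drop = FALSE]
  add <- lm(.y ~ ., data = df)
  dropped <- names(which(is.na(coef(add))))
  if (length(dropped)) {
    warning("collinear loci dropped: ", paste(dropped, collapse = ", "))
    df <- df[, !(names(df) %in% dropped), drop = FALSE]
    add <- lm(.y ~ ., data = df)
  }
  full <- lm(.y ~ (.)^2, data = df)
  an <- anova(add, full)
  sm <- summary(add)$coefficients
  eff <- data.frame(term = rownames(sm)[-1L], effect = sm[-1L, 1L],
                    se = sm[-1L, 2L], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(fit = add, varexp = 100 * summary(add)$r.squared, effects = eff,
       interaction_F = an$F[2L], interaction_p = an$`Pr(>F)`[2L],
       dropped_collinear = dropped)
}

#' Marker-by-marker association with a binary trait
#'
#' Pearson chi-square statistics (no continuity correction) of the
#' 2 x 2 table of a/b calls against the two trait classes, per marker;
#' tables with an empty margin return statistic 0 and are flagged, and
#' perfect co-segregation (no recombinants) is flagged.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param binary Named per-line factor/vector with exactly two levels.
#' @return A `data.frame` ordered by decreasing statistic: `marker`,
#'   `chisq`, `p`, `n`, `perfect`, `degenerate`.
#' @export
binaryAssociation <- function(gm, binary) {
  stopifnot(is(gm, "GenotypeMatrix"))
  cl <- gm@calls
  use <- intersect(colnames(cl), names(binary)[!is.na(binary)])
  bt <- factor(binary[use])
  if (nlevels(bt) != 2L) stop("binary trait must have exactly two levels")
  t1 <- bt == levels(bt)[1L]
  cl <- cl[, use, drop = FALSE]
  a <- rowSums(cl == "a" & rep(t1, each = nrow(cl)), na.rm = TRUE)
  b <- rowSums(cl == "a" & rep(!t1, each = nrow(cl)), na.rm = TRUE)
  c_ <- rowSums(cl == "b" & rep(t1, each = nrow(cl)), na.rm = TRUE)
  d <- rowSums(cl == "b" & rep(!t1, each = nrow(cl)), na.rm = TRUE)
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chisq <- ifelse(den > 0, n * (a * d - b * c_)^2 / den, 0)
  perfect <- den > 0 & ((b == 0 & c_ == 0) | (a == 0 & d == 0))
  out <- data.frame(marker = rownames(cl), chisq = chisq,
                    p = ifelse(den > 0, pchisq(chisq, 1L,
                                               lower.tail = FALSE), NA),
                    n = n, perfect = perfect, degenerate = den == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$chisq), ]
}
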