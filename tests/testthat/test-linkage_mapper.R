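test_that("co-segregating markers collapse onto the higher-quality one", {
  pat <- rep(c("a", "b"), length.out = 20L)
  cl <- rbind(m1 = pat, m2 = pat, m3 = replace(pat, 3L, "b"))
  gm <- makeGm(cl, quality = c(30, 40, 10))
  res <- collapseIdentical(gm)
  expect_setequal(markerNames(res$genotypes), c("m2", "m3"))
  expect_equal(res$redundancy[["m2"]], "m1")   # quality 40 beats 30
  # patterns differing at one progeny stay separate
  expect_true("m3" %in% markerNames(res$genotypes))
})

test_that("missing-tolerant collapse honours the overlap floor", {
  pat <- rep(c("a", "b"), length.out = 20L)
  part <- replace(pat, 1:8, NA)    # agrees on 12/20 shared (60%)
  few <- replace(pat, 1:12, NA)    # only 8/20 shared (40%)
  gm <- makeGm(rbind(m1 = pat, m2 = part, m3 = few),
               quality = c(50, 10, 10))
  res <- collapseIdentical(gm)
  expect_equal(res$redundancy[["m1"]], "m2")   # 60% overlap collapses
  expect_true("m3" %in% markerNames(res$genotypes))  # 40% does not
  # exact mode keeps partially-missing markers apart
  res2 <- collapseIdentical(gm, exact_only = TRUE)
  expect_equal(length(markerNames(res2$genotypes)), 3L)
})

test_that("missing-fraction filter uses a strict 20% boundary", {
  n <- 138L
  mk <- function(nmiss) replace(rep(c("a", "b"), length.out = n),
                                seq_len(nmiss), NA)
  gm <- makeGm(rbind(m27 = mk(27L), m28 = mk(28L), m0 = mk(0L)))
  res <- filterMissing(gm)
  expect_setequal(markerNames(res$genotypes), c("m27", "m0"))  # 19.6% kept
  expect_equal(res$dropped, "m28")                             # 20.3% out
})

test_that("pairwise recombination and independence LOD match closed forms", {
  # counts (aa:40, ab:10, ba:10, bb:40) -> R = 0.2, LOD ~ 8.37
  cl <- rbind(
    m1 = c(rep("a", 50L), rep("b", 50L)),
    m2 = c(rep("a", 40L), rep("b", 10L), rep("a", 10L), rep("b", 40L)))
  pr <- pairwiseLinkage(makeGm(cl))
  expect_equal(pr$R[1L, 2L], 0.2)
  expect_equal(pr$lod[1L, 2L],
               80 * log10(1.6) + 20 * log10(0.4), tolerance = 1e-10)
  # perfect co-segregation over n = 100: LOD = n log10(2)
  pr2 <- pairwiseLinkage(makeGm(rbind(m1 = cl[1L, ], m2 = cl[1L, ])))
  expect_equal(pr2$lod[1L, 2L], 100 * log10(2))
  expect_equal(pr2$R[1L, 2L], 0)
  # balanced table: independence
  cl3 <- rbind(m1 = rep(c("a", "b"), each = 50L),
               m2 = rep(c("a", "b", "a", "b"), each = 25L))
  pr3 <- pairwiseLinkage(makeGm(cl3))
  expect_equal(pr3$R[1L, 2L], 0.5)
  expect_equal(pr3$lod[1L, 2L], 0)
  # het calls are uninformative for pair statistics
  cl4 <- cl
  cl4[2L, 1:10] <- "h"
  expect_equal(pairwiseLinkage(makeGm(cl4))$ninf[1L, 2L], 90)
})

test_that("single-linkage grouping is transitive and reports isolates", {
  lod <- matrix(0, 4L, 4L, dimnames = list(paste0("m", 1:4),
                                           paste0("m", 1:4)))
  lod["m1", "m2"] <- lod["m2", "m1"] <- 7
  lod["m2", "m3"] <- lod["m3", "m2"] <- 7
  lod["m1", "m3"] <- lod["m3", "m1"] <- 2
  grp <- groupMarkers(list(lod = lod), lod_threshold = 6)
  expect_equal(length(grp$groups), 1L)
  expect_setequal(grp$groups[[1L]], c("m1", "m2", "m3"))
  expect_equal(grp$isolated, "m4")
  # nothing linked: everything isolated
  grp2 <- groupMarkers(list(lod = matrix(0, 3L, 3L,
                                         dimnames = list(paste0("m", 1:3),
                                                         paste0("m", 1:3)))))
  expect_equal(length(grp2$groups), 0L)
  expect_equal(length(grp2$isolated), 3L)
})

test_that("ordering recovers the optimum found by exhaustive search", {
  # three markers with R(A,B) = R(B,C) = 0.05, R(A,C) = 0.10
  R <- matrix(c(0, .05, .10, .05, 0, .05, .10, .05, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ord <- orderGroup(R, seed = 1L)
  expect_true(paste(ord, collapse = "") %in% c("ABC", "CBA"))
  # up to 8 markers: objective equals the exhaustive-permutation optimum
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(4:8, 1L)
    pos <- sort(runif(n, 0, 60))
    R <- outer(pos, pos, function(a, b) (1 - exp(-2 * abs(a - b) / 100)) / 2)
    R <- R + matrix(runif(n * n, 0, 0.02), n)  # noise, symmetrised
    R <- (R + t(R)) / 2
    diag(R) <- 0
    dimnames(R) <- list(paste0("m", 1:n), paste0("m", 1:n))
    perms <- gtools_permutations <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    allp <- perms(seq_len(n))
    best <- min(vapply(allp, function(p)
      sum(R[cbind(p[-n], p[-1L])]), 0))
    ord <- orderGroup(R, seed = rep, n_starts = 10L)
    expect_equal(attr(ord, "objective"), best, tolerance = 1e-9)
  }
  # determinism under a fixed seed
  R2 <- R
  expect_identical(orderGroup(R2, seed = 4L), orderGroup(R2, seed = 4L))
})

test_that("map distances follow the RIL-corrected Haldane function", {
  expect_equal(assignCm(numeric()), 0)
  expect_equal(assignCm(0), c(0, 0))
  # R = 0.25 -> r = 1/6 -> d = -50 ln(2/3) ~ 20.27
  expect_equal(assignCm(0.25)[2L], -50 * log(1 - 2 * (0.25 / 1.5)),
               tolerance = 1e-12)
  expect_equal(assignCm(0.25)[2L], 20.27, tolerance = 1e-2)
  # unlinked-looking adjacency is capped with a warning
  expect_warning(d <- assignCm(c(0.1, 0.55)), "capped")
  expect_equal(d[3L] - d[2L], 50)
  # Kosambi option gives shorter distances for the same R
  expect_lt(assignCm(0.25, map_fun = "kosambi")[2L], assignCm(0.25)[2L])
})

test_that("poor-fit markers are flagged by double-crossover counts", {
  n <- 40L
  base <- rep(c("a", "b"), each = n / 2L)
  good <- rbind(mA = base, mB = base, mC = base)
  expect_equal(dropPoorFit(c("mA", "mB", "mC"), good), character())
  # middle marker with 5 singleton switches between agreeing flanks
  bad <- base
  bad[c(3L, 7L, 11L, 30L, 35L)] <- ifelse(
    base[c(3L, 7L, 11L, 30L, 35L)] == "a", "b", "a")
  cl <- rbind(mA = base, mB = bad, mC = base)
  expect_equal(dropPoorFit(c("mA", "mB", "mC"), cl), "mB")
  expect_equal(dropPoorFit(c("mA", "mB", "mC"), cl, max_dxo = 5L),
               character())
})

test_that("map reversal leaves adjacent distances unchanged", {
  sim <- scaleSim()
  gm <- truthGenotypeMatrix(sim$genomes, sim$ril)
  sub <- makeGm(calls(gm)[1:30, ], quality = markerQuality(gm)[1:30])
  pr <- pairwiseLinkage(sub)
  ord <- orderGroup(pr$R, seed = 2L)
  fwd <- assignCm(pr$R[cbind(ord[-30L], ord[-1L])])
  rev_ord <- rev(as.character(ord))
  bwd <- assignCm(pr$R[cbind(rev_ord[-30L], rev_ord[-1L])])
  expect_equal(diff(fwd), rev(diff(bwd)), tolerance = 1e-12)
})

test_that("a full-scale map recovers seven groups and the true order", {
  sim <- scaleSim()
  gm <- truthGenotypeMatrix(sim$genomes, sim$ril)
  map <- buildGeneticMap(gm, seed = 3L)
  expect_equal(length(unique(mapTable(map)$group)), 7L)
  truth <- truthGeneticMap(sim$genomes)
  tt <- mapTable(truth)
  for (g in unique(mapTable(map)$group)) {
    mk <- mapTable(map)$marker[mapTable(map)$group == g]
    tr <- tt[match(mk, tt$marker), ]
    expect_equal(length(unique(tr$group)), 1L)   # no chimeric groups
    rho <- abs(cor(seq_along(mk), tr$cM, method = "spearman"))
    expect_gte(rho, 0.99)
  }
  # accounting identity: every input marker lands in exactly one class
  n_acc <- nrow(mapTable(map)) + length(map@isolated) +
    nrow(map@dropped)
  expect_equal(n_acc, nrow(calls(gm)))
  # ledger totals row sums the per-group counts
  led <- map@ledger
  tot <- led[led$group == "Total", ]
  per <- led[led$group != "Total", ]
  expect_equal(tot$clustered, sum(per$clustered))
  expect_equal(tot$mapped, sum(per$mapped))
})
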