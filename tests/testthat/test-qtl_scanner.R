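# A small deterministic map + genotype set for scan tests.
toyMapAndGeno <- function(n_lines = 60L, seed = 101L) {
  set.seed(seed)
  pos <- c(0, 10, 20, 30, 40, 50)
  mk <- sprintf("m%02d", seq_along(pos))
  tab <- data.frame(group = "LG1", marker = mk, cM = pos)
  map <- new("GeneticMap", table = tab, redundancy = list(),
             isolated = character(),
             dropped = data.frame(marker = character(),
                                  reason = character()),
             ledger = makeMapLedger(data.frame(group = "LG1",
                                               clustered = 6L,
                                               mapped = 6L,
                                               cosegregating = 0L)))
  calls <- matrix(sample(c("a", "b"), length(pos) * n_lines, TRUE),
                  length(pos), n_lines,
                  dimnames = list(mk, sprintf("L%03d", seq_len(n_lines))))
  # make neighbouring markers strongly correlated for realism
  for (i in 2:length(pos)) {
    keep <- runif(n_lines) < 0.85
    calls[i, keep] <- calls[i - 1L, keep]
  }
  list(map = map, gm = makeGm(calls))
}

test_that("conditional genotype probabilities behave at and off markers", {
  toy <- toyMapAndGeno()
  pr <- genotypeProbabilities(toy$map, toy$gm, step_cm = 1)
  g <- pr$groups[["LG1"]]
  # at a marker, a called line has probability 0/1
  j <- match(0, g$cM)
  expect_equal(unname(g$pb[, j]),
               as.numeric(calls(toy$gm)["m01", ] == "b"))
  # midpoint of a 20 cM interval with both flanks 'a': P(a) > 0.95
  cl <- rbind(mL = rep("a", 10L), mR = rep("a", 10L))
  colnames(cl) <- sprintf("L%03d", 1:10)
  tab <- data.frame(group = "LG1", marker = c("mL", "mR"), cM = c(0, 20))
  map2 <- new("GeneticMap", table = tab, redundancy = list(),
              isolated = character(),
              dropped = data.frame(marker = character(),
                                   reason = character()),
              ledger = data.frame())
  pr2 <- genotypeProbabilities(map2, makeGm(cl))
  mid <- match(10, pr2$groups[["LG1"]]$cM)
  expect_true(all(1 - pr2$groups[["LG1"]]$pb[, mid] > 0.95))
  # discordant flanks at equal distance: exactly 0.5
  cl2 <- rbind(mL = rep("a", 5L), mR = rep("b", 5L))
  colnames(cl2) <- sprintf("L%03d", 1:5)
  pr3 <- genotypeProbabilities(map2, makeGm(cl2))
  expect_equal(unname(pr3$groups[["LG1"]]$pb[, mid]), rep(0.5, 5L))
  # heterozygous/missing lines fall back to 0.5 with no information
  cl3 <- rbind(mL = rep("h", 5L), mR = rep(NA_character_, 5L))
  colnames(cl3) <- sprintf("L%03d", 1:5)
  pr4 <- genotypeProbabilities(map2, makeGm(cl3))
  expect_true(all(pr4$groups[["LG1"]]$pb == 0.5))
})

test_that("interval scan reduces to single-marker regression at markers", {
  toy <- toyMapAndGeno()
  pr <- genotypeProbabilities(toy$map, toy$gm)
  set.seed(102)
  x <- as.numeric(calls(toy$gm)["m03", ] == "b")
  y <- 10 * x + rnorm(ncol(calls(toy$gm)), 0, 3)
  names(y) <- colnames(calls(toy$gm))
  sc <- intervalScan(y, pr)
  tb <- scanTable(sc)
  at <- tb[tb$cM == 20, ]
  f <- lm(y ~ x)
  r2 <- summary(f)$r.squared
  n <- length(y)
  expect_equal(at$lod, -(n / 2) * log10(1 - r2), tolerance = 1e-9)
  expect_equal(at$varexp, 100 * r2, tolerance = 1e-9)
  expect_equal(at$effect, unname(coef(f)[2L]), tolerance = 1e-9)
  expect_equal(at$se, summary(f)$coefficients[2L, 2L], tolerance = 1e-9)
  # LOD is invariant to affine transformation of the trait
  sc2 <- intervalScan(3 * y + 100, pr)
  expect_equal(scanTable(sc2)$lod, tb$lod, tolerance = 1e-9)
  # trait orthogonal to every dosage column: LOD 0 everywhere
  y0 <- setNames(rep(c(-1, 1), length.out = n), names(y))
  D <- do.call(cbind, lapply(pr$groups, function(g) g$pb))
  y0 <- setNames(residuals(lm(y0 ~ D)), names(y))
  sc0 <- intervalScan(y0, pr)
  expect_lt(max(scanTable(sc0)$lod), 1e-6)
  # trait exactly equal to a dosage column: degenerate flag
  yd <- setNames(as.numeric(calls(toy$gm)["m01", ] == "b"), names(y))
  scd <- intervalScan(yd, pr)
  expect_true(any(scanTable(scd)$degenerate))
  expect_error(intervalScan(y[1:5], pr), "fewer than")
})

test_that("permutation thresholds are seeded, monotone in alpha", {
  toy <- toyMapAndGeno()
  pr <- genotypeProbabilities(toy$map, toy$gm)
  set.seed(103)
  y <- setNames(rnorm(ncol(calls(toy$gm))), colnames(calls(toy$gm)))
  t1 <- permutationThreshold(y, pr, n_perm = 200L, seed = 7L)
  t2 <- permutationThreshold(y, pr, n_perm = 200L, seed = 7L)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_error(permutationThreshold(y, pr, n_perm = 200L), "seed")
  expect_warning(permutationThreshold(y, pr, n_perm = 50L, seed = 1L),
                 "unstable")
  # alpha = 1 returns the smallest permutation maximum
  tmin <- permutationThreshold(y, pr, n_perm = 200L, alpha = 1, seed = 7L)
  expect_equal(as.numeric(tmin), min(attr(t1, "max_lods")))
  expect_lte(as.numeric(tmin), as.numeric(t1))
})

test_that("cofactor-adjusted scans unmask a minor linked QTL", {
  sim <- scaleSim()
  gm <- truthGenotypeMatrix(sim$genomes, sim$ril)
  map <- truthGeneticMap(sim$genomes)
  pr <- genotypeProbabilities(map, gm)
  y <- setNames(sim$phenotypes$height_y1, sim$phenotypes$line)
  plain <- intervalScan(y, pr)
  # no cofactors: identical to the plain scan
  expect_identical(scanTable(rmqmScan(y, pr, character())),
                   scanTable(plain))
  # cofactor at the major peak raises the 3H-analogue QTL's peak LOD
  tbl <- scanTable(plain)
  pk <- tbl[which.max(tbl$lod), ]
  cof <- {
    mt <- mapTable(map)
    cand <- mt[mt$group == pk$group, ]
    cand$marker[which.min(abs(cand$cM - pk$cM))]
  }
  adj <- rmqmScan(y, pr, cofactors = cof)
  minor_group <- "chr3"
  lod_plain <- max(tbl$lod[tbl$group == minor_group])
  lod_adj <- max(scanTable(adj)$lod[scanTable(adj)$group == minor_group])
  expect_gt(lod_adj, lod_plain)
  # the cofactor's own neighbourhood is excluded, not nulled genome-wide
  expect_gt(max(scanTable(adj)$lod[scanTable(adj)$group == pk$group]), 0)
})

test_that("support intervals follow the LOD-drop geometry", {
  prof <- data.frame(group = "LG1", cM = 0:60,
                     lod = pmax(0, 10 - abs(30 - (0:60))),
                     varexp = 0, effect = 0, se = 0, degenerate = FALSE)
  sc <- new("QtlScan", table = prof, threshold = 3, n = 100L,
            kind = "interval")
  si <- supportInterval(sc, drop = 1)
  expect_equal(c(si$left, si$right), c(29, 31))
  expect_equal(si$peak_cM, 30)
  expect_equal(supportInterval(sc, drop = 0)$left, 30)
  # plateau: the whole plateau is returned
  prof2 <- prof
  prof2$lod[prof2$cM %in% 25:35] <- 10
  sc2 <- new("QtlScan", table = prof2, threshold = 3, n = 100L,
             kind = "interval")
  si2 <- supportInterval(sc2, drop = 0.5)
  expect_equal(c(si2$left, si2$right), c(25, 35))
  # below-threshold peak: nothing
  expect_null(supportInterval(sc, drop = 1, threshold = 99))
})

test_that("the joint additive model reproduces per-locus regressions", {
  set.seed(104)
  n <- 120L
  g1 <- rbinom(n, 1L, 0.5)
  g2 <- rbinom(n, 1L, 0.5)
  y <- 20 * g1 + 8 * g2 + rnorm(n, 0, 6)
  names(y) <- sprintf("L%03d", seq_len(n))
  loci <- data.frame(q1 = g1, q2 = g2, row.names = names(y))
  jm <- jointModel(y, loci)
  full <- lm(y ~ g1 + g2)
  expect_equal(jm$varexp, 100 * summary(full)$r.squared, tolerance = 1e-9)
  expect_equal(jm$effects$effect, unname(coef(full)[2:3]),
               tolerance = 1e-9)
  # single locus reduces to marker regression
  jm1 <- jointModel(y, loci["q1"])
  expect_equal(jm1$varexp, 100 * summary(lm(y ~ g1))$r.squared,
               tolerance = 1e-9)
  # additive truth: interaction test rarely significant
  expect_gt(jm$interaction_p, 0.001)
  # planted interaction is detected
  y2 <- y + 25 * g1 * g2
  jm2 <- jointModel(setNames(y2, names(y)), loci)
  expect_lt(jm2$interaction_p, 0.05)
  # collinear locus is dropped with a warning
  loci3 <- cbind(loci, q3 = g1)
  expect_warning(jm3 <- jointModel(y, loci3), "collinear")
  expect_equal(nrow(jm3$effects), 2L)
})

test_that("binary association ranks markers by the 2x2 chi-square", {
  # perfect co-segregation, 56 two-rowed vs 80 six-rowed
  n2 <- 56L; n6 <- 80L
  trait <- setNames(rep(c("two", "six"), c(n2, n6)),
                    sprintf("L%03d", seq_len(n2 + n6)))
  perfect <- rep(c("a", "b"), c(n2, n6))
  balanced <- rep(c("a", "b"), length.out = n2 + n6)
  flat <- rep("a", n2 + n6)
  cl <- rbind(mPerfect = perfect, mBalanced = balanced, mFlat = flat)
  colnames(cl) <- names(trait)
  res <- binaryAssociation(makeGm(cl), trait)
  expect_equal(res$marker[1L], "mPerfect")
  expect_true(res$perfect[res$marker == "mPerfect"])
  expect_equal(res$chisq[res$marker == "mPerfect"], n2 + n6)
  expect_true(res$degenerate[res$marker == "mFlat"])
  expect_equal(res$chisq[res$marker == "mFlat"], 0)
  # 2x2 with identical margins: statistic 0
  half <- setNames(rep(c("two", "six"), 60L), sprintf("L%03d", 1:120))
  # period-4 calls give the balanced table (30,30;30,30)
  cl2 <- rbind(m = rep(c("a", "a", "b", "b"), 30L))
  colnames(cl2) <- names(half)
  expect_equal(binaryAssociation(makeGm(cl2), half)$chisq, 0)
})
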