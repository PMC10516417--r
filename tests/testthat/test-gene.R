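test_that("one-sided KS prior follows the exact D+ distribution", {
  # n = 1: D+ = 0.5 and P(D+ >= 0.5) = 0.5 exactly; the two-sided D
  # statistic is always >= 0.5 for n = 1, so its p-value is 1
  expect_equal(ksPriorPvalue(0.5), 0.5, tolerance = 1e-12)
  expect_equal(ksPriorPvalue(0.5, twoSided = TRUE), 1)
  # best-fit case: p-values at uniform quantiles give D+ = 0.5/n, p near 1
  n <- 20
  p <- ((1:n) - 0.5) / n
  expect_gt(ksPriorPvalue(p), 0.9)
  # an extreme excess of small p-values: only the all-below-1/n event
  # remains, P = (max p)^n by direct enumeration
  expect_equal(ksPriorPvalue(c(0.001, 0.002, 0.003)), 0.003^3,
               tolerance = 1e-9)
  expect_error(ksPriorPvalue(numeric()), "at least one")
  expect_error(ksPriorPvalue(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("KS prior p-values are uniform under the null (simulation)", {
  set.seed(3)
  pks <- replicate(4000, ksPriorPvalue(runif(25)))
  expect_gt(ks.test(pks, "punif")$p.value, 0.01)
  # asymptotic branch stays sane for larger genes
  pbig <- replicate(2000, ksPriorPvalue(runif(80)))
  expect_lt(abs(mean(pbig <= 0.05) - 0.05), 0.02)
})

test_that("chi-square mixture tail matches closed forms and Monte Carlo", {
  expect_equal(as.numeric(chisqMixturePvalue(1, qchisq(0.95, 1))), 0.05,
               tolerance = 1e-6)
  expect_equal(as.numeric(chisqMixturePvalue(c(1, 1), qchisq(0.95, 2))), 0.05,
               tolerance = 1e-6)
  for (k in c(3, 7)) {
    q <- qchisq(0.99, k)
    expect_equal(as.numeric(chisqMixturePvalue(rep(1, k), q)), 0.01,
                 tolerance = 1e-6)
    # scale invariance
    expect_equal(as.numeric(chisqMixturePvalue(rep(2.5, k), 2.5 * q)), 0.01,
                 tolerance = 1e-6)
  }
  set.seed(4)
  B <- 2e6
  mc <- mean(2 * rchisq(B, 1) + rchisq(B, 1) > 8)
  p <- as.numeric(chisqMixturePvalue(c(2, 1), 8))
  expect_lt(abs(p - mc), 3 * sqrt(mc * (1 - mc) / B))
  expect_error(chisqMixturePvalue(c(1, 2), -1), "non-negative")
  expect_error(chisqMixturePvalue(c(0, 0), 1), "not all be zero")
  expect_equal(as.numeric(chisqMixturePvalue(1, 0)), 1)
})

test_that("SKAT reduces to the score test for one variant", {
  set.seed(9)
  n <- 500
  y <- rep(c(1, 0), each = n / 2)
  g <- rbinom(n, 2, 0.2)
  expect_equal(skatPvalue(matrix(g), y, weights = 1,
                          nullDist = "asymptotic"),
               as.numeric(scoreTestPvalue(g, y)), tolerance = 1e-6)
  # duplicated columns behave as one column at four-fold weight
  G2 <- cbind(g, g)
  expect_equal(skatPvalue(G2, y, weights = c(1, 1), nullDist = "asymptotic"),
               skatPvalue(matrix(g), y, weights = 2, nullDist = "asymptotic"),
               tolerance = 1e-8)
  expect_error(skatPvalue(matrix(0, n, 2), y), "polymorphic")
})

test_that("small-cohort SKAT agrees with a phenotype-permutation oracle", {
  set.seed(14)
  n <- 60
  y <- rep(c(1, 0), each = 30)
  G <- matrix(rbinom(n * 5, 2, rep(c(0.15, 0.2, 0.25, 0.3, 0.1), each = n)),
              n, 5)
  p <- skatPvalue(G, y, weights = rep(1, 5))          # auto -> resampling
  r0 <- y - mean(y)
  Q0 <- sum(drop(crossprod(G, r0))^2)
  Qs <- replicate(20000, sum(drop(crossprod(G, sample(r0)))^2))
  pPerm <- mean(Qs >= Q0)
  se <- sqrt(pPerm * (1 - pPerm) / 20000)
  expect_lt(abs(as.numeric(p) - pPerm), 3 * se)
  # deterministic despite internal resampling
  expect_identical(as.numeric(p),
                   as.numeric(skatPvalue(G, y, weights = rep(1, 5))))
})

test_that("burden evidence matches the 2x2 G-test and is monotone", {
  y <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  b <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  lr <- burdenBF(matrix(b), y)
  O <- matrix(c(30, 10, 70, 90), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(as.numeric(lr), 2 * sum(O * log(O / E)), tolerance = 1e-6)
  # all case-carriers maximizes the statistic over same-margin tables
  yy <- rep(c(1, 0), each = 50)
  allCase <- c(rep(1, 10), rep(0, 90))
  lrMax <- burdenBF(matrix(allCase), yy)
  for (k in c(2, 5, 8)) {
    shifted <- c(rep(1, 10 - k), rep(0, 40 + k), rep(1, k), rep(0, 50 - k))
    expect_lt(as.numeric(burdenBF(matrix(shifted), yy)), as.numeric(lrMax))
  }
  degen <- burdenBF(matrix(1, 100, 1), yy)
  expect_equal(as.numeric(degen), 0)
  expect_true(isTRUE(attr(degen, "degenerate")))
})

test_that("burden statistic is chi-square(1) under the null", {
  set.seed(21)
  n <- 400
  y <- rep(c(1, 0), each = n / 2)
  Bm <- matrix(rbinom(n * 2000, 4, 0.05), n, 2000)
  lr <- rvbf:::.burdenLrtVec(Bm, y)
  expect_lt(abs(mean(lr) - 1), 0.1)
  expect_lt(abs(mean(pchisq(lr, 1, lower.tail = FALSE) <= 0.05) - 0.05),
            0.015)
})

test_that("the beta-binomial backend rises with case-control imbalance", {
  y <- rep(c(1, 0), each = 100)
  G <- matrix(c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)), ncol = 1)
  strong <- burdenBF(G, y, backend = "betabinom")
  Gnull <- matrix(c(rep(1, 20), rep(0, 80), rep(1, 20), rep(0, 80)), ncol = 1)
  weak <- burdenBF(Gnull, y, backend = "betabinom")
  expect_gt(as.numeric(strong), as.numeric(weak))
  expect_error(burdenBF(G, y, X = cbind(1, rnorm(200)),
                        backend = "betabinom"), "covariates")
})

test_that("the gene test composes burden and prior into a chi-square(3) tail", {
  # degenerate burden + uninformative prior sits exactly at the null point
  y <- rep(c(1, 0), each = 20)
  r0 <- geneBFTest(matrix(1, 40, 1), y, variantP = NULL, prior = "ks")
  # with a constant gene, burden is 0; feed prior p = 1 via variantP
  expect_equal(r0$bf2log, 0)
  # analytic composition: prior 0.05 and no burden evidence
  T <- -2 * log(0.05)
  expect_equal(pchisq(T, 3, lower.tail = FALSE),
               1 - pchisq(5.991465, 3), tolerance = 1e-6)
  # stronger prior or larger burden strictly reduces the gene p
  set.seed(2)
  g <- rbinom(400, 2, 0.05)
  yy <- rep(c(1, 0), each = 200)
  res1 <- geneBFTest(matrix(g), yy, variantP = 0.5, prior = "ks")
  res2 <- geneBFTest(matrix(g), yy, variantP = 0.01, prior = "ks")
  expect_lt(res2$p, res1$p)
  expect_equal(res2$T - res1$T,
               -2 * log(ksPriorPvalue(0.01)) + 2 * log(ksPriorPvalue(0.5)),
               tolerance = 1e-10)
})

test_that("genome scans find the causal gene and respect sample order", {
  set.seed(33)
  causal <- data.frame(gene = 2L, arch = "sparse", logOR = log(6),
                       fracCausal = 0.15)
  cfg <- simulationConfig(nCases = 400, nControls = 400, nGenes = 12,
                          sitesPerGene = 25, mafSpectrum = rareSpectrum(),
                          causalGenes = causal,
                          qualityModel = list(enabled = FALSE), seed = 61)
  co <- simulateCohort(cfg)
  gm <- geneMapOf(co)
  scan <- genomeScan(co, gm, prior = "ks")
  expect_equal(scan$gene[1], "G2")
  # permutation equivariance: shuffling sample order leaves results intact
  perm <- sample(ncol(co))
  scanP <- genomeScan(co[, perm], gm, prior = "ks")
  expect_equal(scanP$p, scan$p, tolerance = 1e-12)
  # determinism
  expect_identical(scan$p, genomeScan(co, gm, prior = "ks")$p)
})

test_that("genes dropped by the site-count rule appear in the log only", {
  co <- nullCohort(100, 100, 4, sitesPerGene = 25, seed = 71)
  regions <- buildGeneRegions(meta(co)$genes)
  gm <- assignVariantsToGenes(co, regions, minSites = 20)
  gm$members[["G1"]] <- gm$members[["G1"]][1:10]   # force a small gene
  gm$members <- gm$members[c("G2", "G3", "G4")]
  gm$dropped <- data.frame(gene = "G1", n_sites = 10L)
  scan <- genomeScan(co, gm, prior = "ks")
  expect_false("G1" %in% scan$gene)
  expect_equal(attr(scan, "dropped")$gene, "G1")
})

test_that("the vectorized permutation path reproduces genomeScan exactly", {
  co <- nullCohort(150, 150, 30, sitesPerGene = 22, seed = 81)
  gm <- geneMapOf(co)
  fac <- geneTestFactory(co, gm)
  fast <- fac(co)
  slow <- genomeScan(co, gm, prior = "ks")
  expect_equal(unname(fast[slow$gene]), slow$p, tolerance = 1e-10)
})

test_that("the priors respond to different signal architectures", {
  # The KS prior reacts to the COUNT of small within-gene p-values (an
  # excess relative to uniform), while the SKAT prior reacts to their
  # MAGNITUDE: an ECDF statistic moves by at most 1/m for a single
  # variant however extreme, a quadratic form is dominated by it.
  nullRest <- (seq_len(15) - 0.5) / 15 * 0.7 + 0.28
  manyModerate <- c(rep(0.005, 5), nullRest)
  oneExtreme <- c(1e-12, (seq_len(19) - 0.5) / 19)
  expect_lt(ksPriorPvalue(manyModerate), ksPriorPvalue(oneExtreme))
  set.seed(15)
  run <- function(mode, reps = 40, n = 700, m = 20, maf = 0.008) {
    sapply(seq_len(reps), function(r) {
      y <- rep(c(1, 0), each = n / 2)
      G <- matrix(rbinom(n * m, 2, maf), n, m)
      if (mode == "one") {
        G[y == 1, 1] <- rbinom(n / 2, 2, plogis(qlogis(maf) + 2.5))
      } else {
        for (j in 1:5)
          G[y == 1, j] <- rbinom(n / 2, 2, plogis(qlogis(maf) + 0.9))
      }
      pv <- scoreTestPvalues(G, y)
      c(ks = ksPriorPvalue(pv),
        skat = skatPvalue(G, y, nullDist = "asymptotic"))
    })
  }
  one <- run("one"); many <- run("many")
  # KS gains power from an excess of small p-values, not a single outlier
  expect_lt(median(many["ks", ]), median(one["ks", ]))
  # SKAT is the stronger prior for a single large-effect variant
  expect_lt(median(one["skat", ]), median(one["ks", ]))
  # the KS prior's relative standing improves under the distributed signal
  relOne <- median(one["ks", ]) / median(one["skat", ])
  relMany <- median(many["ks", ]) / median(many["skat", ])
  expect_lt(relMany, relOne)
})
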