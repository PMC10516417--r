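test_that("identical config and seed give byte-identical cohorts", {
  c1 <- nullCohort(50, 50, 3, 10, seed = 9)
  c2 <- nullCohort(50, 50, 3, 10, seed = 9)
  expect_identical(dosages(c1), dosages(c2))
  expect_identical(cdata(c1), cdata(c2))
  c3 <- nullCohort(50, 50, 3, 10, seed = 10)
  expect_false(identical(dosages(c1), dosages(c3)))
})

test_that("simulateCohort returns exactly the requested case/control counts", {
  co <- nullCohort(37, 21, 2, 5, seed = 3)
  expect_equal(sum(phenotype(co) == 1), 37)
  expect_equal(sum(phenotype(co) == 0), 21)
})

test_that("an unattainable case count names the population cap", {
  cfg <- simulationConfig(nCases = 5000, nControls = 10, nGenes = 1,
                          sitesPerGene = 2, popMultiplier = 2,
                          prevalenceIntercept = -8, seed = 1)
  expect_error(simulateCohort(cfg), "population cap")
})

test_that("null cohorts show no systematic case-control frequency difference", {
  co <- nullCohort(400, 400, 8, 25, seed = 21)
  d <- dosages(co)
  y <- phenotype(co)
  diffs <- rowMeans(d[, y == 1]) / 2 - rowMeans(d[, y == 0]) / 2
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("default MAF spectrum reproduces the rare-dominated bin weights", {
  maf <- drawSiteMafs(10000, defaultMafSpectrum(), seed = 5)
  frac <- mean(maf > 0 & maf < 0.01)
  expect_lt(abs(frac - 0.7579), 0.02)
  expect_lt(abs(mean(maf == 0) - 0.1012), 0.02)
  expect_true(all(maf >= 0 & maf < 0.5))
})

test_that("an injected per-allele OR of 2 is recovered from carrier tables", {
  causal <- data.frame(gene = 1L, arch = "sparse", logOR = log(2),
                       fracCausal = NA_real_)
  logOrs <- vapply(1:40, function(r) {
    cfg <- simulationConfig(
      nCases = 5000, nControls = 5000, nGenes = 1, sitesPerGene = 21,
      mafSpectrum = defaultMafSpectrum(
        weights = c(mono = 0, rare = 1, low = 0, common = 0),
        rareRange = c(0.005, 0.00501)),
      causalGenes = causal, popMultiplier = 8, seed = 1000 + r,
      qualityModel = list(enabled = FALSE))
    co <- simulateCohort(cfg)
    cv <- meta(co)$causalVariants
    g <- dosages(co)[cv$variant[1], ]
    y <- phenotype(co)
    a <- sum(g[y == 1] >= 1); b <- sum(y == 1) - a
    c_ <- sum(g[y == 0] >= 1); d_ <- sum(y == 0) - c_
    log((a + 0.5) * (d_ + 0.5) / ((b + 0.5) * (c_ + 0.5)))
  }, 0)
  ciHalf <- 2 * sd(logOrs) / sqrt(length(logOrs))
  expect_lt(abs(mean(logOrs) - log(2)), ciHalf + 0.05)
})

test_that("smoking is generated confounded with case status", {
  co <- nullCohort(500, 500, 2, 5, seed = 4)
  cd <- cdata(co)
  everRate <- tapply(cd$smoking_ever, cd$status, mean)
  expect_gt(everRate["1"], everRate["0"] + 0.05)
})

test_that("phenotype permutation conserves totals and is uniform", {
  co <- nullCohort(2, 2, 1, 2, seed = 8)
  expect_error(permutePhenotype(co[, 1]), "at least 2")
  perm <- permutePhenotype(co, seed = 1)
  expect_equal(sum(phenotype(perm)), sum(phenotype(co)))
  # 4 samples, 2 cases: each of the 6 case-position patterns ~ 1/6
  pats <- replicate(3000, paste(phenotype(permutePhenotype(co)),
                                collapse = ""))
  tab <- table(pats)
  expect_equal(length(tab), 6)
  expect_true(all(abs(tab / 3000 - 1 / 6) < 4 * sqrt((1 / 6) * (5 / 6) / 3000)))
})

test_that("all-case cohorts permute to themselves in multiset terms", {
  co <- tinyCohort(matrix(0, 2, 4), status = rep(1L, 4))
  expect_equal(sort(phenotype(permutePhenotype(co, seed = 1))),
               sort(phenotype(co)))
})

test_that("zero corruption rates violate no site-level rule except MAF", {
  co <- simulateCohort(simulationConfig(
    nCases = 100, nControls = 100, nGenes = 3, sitesPerGene = 20, seed = 31))
  qc <- qcConfig("ilcco")
  res <- applySiteFilters(maskGenotypes(co, qc), qc)
  rc <- res$report@ruleCounts
  expect_equal(sum(rc[setdiff(names(rc), "maf")]), 0)
  expect_equal(nrow(meta(co)$qualityLedger), 0)
})

test_that("full QUAL corruption pushes every site under the preset floor", {
  qm <- .rvbfDefaultQuality()
  qm$corruption$site_qual <- 1
  co <- simulateCohort(simulationConfig(
    nCases = 30, nControls = 30, nGenes = 2, sitesPerGene = 10,
    qualityModel = qm, seed = 13))
  expect_true(all(vmeta(co)$QUAL < 100))
  expect_error(simulateCohort(simulationConfig(
    nCases = 5, nControls = 5, nGenes = 1, sitesPerGene = 2,
    qualityModel = modifyList(qm, list(corruption = list(genotype = 1.5))),
    seed = 1)), "corruption")
})

test_that("genotype corruption honors its rate and is ledgered", {
  qm <- .rvbfDefaultQuality()
  qm$corruption$genotype <- 0.10
  co <- simulateCohort(simulationConfig(
    nCases = 10, nControls = 10, nGenes = 5, sitesPerGene = 10,
    qualityModel = qm, seed = 17))
  led <- meta(co)$qualityLedger
  nGt <- nrow(co) * ncol(co)          # 1,000 genotypes
  hits <- sum(led$kind == "genotype")
  expect_lt(abs(hits - 0.10 * nGt), 4 * sqrt(nGt * 0.1 * 0.9))
  # ledgered genotypes actually fail the ilcco mask
  gq <- genotypeQuality(co)
  bad <- led[led$kind == "genotype", ]
  expect_true(all(gq[cbind(bad$variant, bad$sample)] < 30))
})
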