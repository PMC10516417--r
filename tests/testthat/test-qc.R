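test_that("genotype masking applies strict GQ/DP thresholds per preset", {
  d <- matrix(1, 1, 4)
  gq <- matrix(c(29, 30, 25, 99), 1, 4)
  dp <- matrix(c(50, 10, 9, 50), 1, 4)
  co <- tinyCohort(d, gq = gq, dp = dp)
  ilcco <- dosages(maskGenotypes(co, qcConfig("ilcco")))
  # GQ=29 fails GQ<30; GQ=30,DP=10 sits on both boundaries and survives;
  # GQ=25 fails; GQ=99/DP=50 clean
  expect_equal(as.vector(ilcco), c(NA, 1, NA, 1))
  ukb <- dosages(maskGenotypes(co, qcConfig("ukbiobank")))
  # ukbiobank masks DP<10 or GQ<20: GQ=25 passes GQ but DP=9 fails
  expect_equal(as.vector(ukb), c(1, 1, NA, 1))
  # absent GQ/DP fails the mask
  gq[1, 4] <- NA
  co2 <- tinyCohort(d, gq = gq, dp = dp)
  expect_true(is.na(dosages(maskGenotypes(co2, qcConfig("ilcco")))[1, 4]))
})

test_that("computeMaf counts alleles, folds, and excludes missing", {
  expect_equal(computeMaf(c(0, 0, 1)), 1 / 6)
  expect_equal(computeMaf(c(2, 2, 1)), 1 / 6)
  expect_equal(computeMaf(c(0, NA, 1)), 1 / 4)
  expect_error(computeMaf(c(NA, NA)), "missing")
  # 14 heterozygous carriers among 173,494 individuals
  maf <- computeMaf(c(rep(1, 14), rep(0, 173480)))
  expect_equal(signif(maf, 2), 4.0e-5)
})

test_that("HWE exact test matches its stated special cases", {
  expect_equal(hweExactTest(100, 0, 0), 1)
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)
  expect_lt(hweExactTest(50, 0, 50), 1e-7)
})

test_that("HWE exact test equals full enumeration on small configurations", {
  for (n in c(3, 7, 12)) {
    for (minor in 0:n) {
      for (het in seq(minor %% 2, minor, by = 2)) {
        naa <- (minor - het) / 2
        nAA <- n - het - naa
        expect_equal(hweExactTest(nAA, het, naa), hweOracle(nAA, het, naa),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Ts/Tv classifies transitions and flags the degenerate cases", {
  expect_equal(tstvRatio(c("A", "A"), c("G", "C")), 1.0)
  expect_warning(r <- tstvRatio(c("A", "G", "C", "T"), c("G", "A", "T", "C")),
                 "transversions")
  expect_equal(as.numeric(r), Inf)
  expect_error(tstvRatio(character(), character()), "SNV")
  # independent classification oracle on random sites
  set.seed(2)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 100, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  pur <- c("A", "G")
  isTs <- (ref %in% pur) == (alt %in% pur)
  expect_equal(tstvRatio(ref, alt), sum(isTs) / sum(!isTs))
})

test_that("sample QC removes high-missingness and low-heterozygosity samples", {
  d <- matrix(rep(c(1, 0), 10), 20, 6)
  d[1:3, 2] <- NA                        # 15% missing > 10%
  co <- tinyCohort(d)
  out <- sampleQC(co, qcConfig("ilcco"))
  removedMiss <- out$removals$sample[out$removals$reason == "missing_rate"]
  expect_equal(removedMiss, colnames(dosages(co))[2])
  expect_equal(ncol(dosages(out$cohort)), 5)
  # identical heterozygosity leaves everyone in place (SD = 0 convention)
  co2 <- tinyCohort(matrix(1, 5, 4))
  out2 <- sampleQC(co2)
  expect_equal(nrow(out2$removals), 0)
})

test_that("an engineered heterozygosity outlier is removed", {
  # enough sites that per-sample heterozygosity is tight around its mean,
  # enough samples that one outlier cannot inflate the SD past its own
  # deviation: the zero-heterozygosity sample sits ~10 SDs low
  set.seed(6)
  d <- matrix(rbinom(2000 * 100, 1, 0.5), 2000, 100)
  d[, 100] <- 0
  co <- tinyCohort(d)
  out <- sampleQC(co, qcConfig("ilcco", hetSdMult = 6))
  expect_true(colnames(dosages(co))[100] %in% out$removals$sample)
  expect_equal(out$removals$reason, "low_heterozygosity")
})

test_that("gene regions are flanked inclusively and assignment multi-maps", {
  ann <- data.frame(gene = c("A", "B"), chrom = c("1", "1"),
                    start = c(5000, 6500), end = c(6000, 7000))
  regions <- buildGeneRegions(ann, flank = 1000)
  expect_equal(GenomicRanges::start(regions)[1], 4000)
  expect_equal(GenomicRanges::end(regions)[1], 7000)
  d <- matrix(rep(c(0, 1), 12), 3, 8)
  co <- tinyCohort(d, pos = c(4000, 6800, 7500))
  gm <- assignVariantsToGenes(co, regions, minSites = 1)
  expect_equal(gm$members$A, c(1L, 2L))       # 4000 inclusive; 6800 in both
  expect_equal(gm$members$B, c(2L, 3L))       # 7500 only in B's flank
  # malformed rows are skipped with a message
  bad <- rbind(ann, data.frame(gene = "C", chrom = NA, start = 1, end = 2))
  expect_message(r2 <- buildGeneRegions(bad), "skipped 1")
  expect_equal(length(r2), 2)
})

test_that("genes below the 20-site rule drop from the analyzable map", {
  ann <- data.frame(gene = "A", chrom = "1", start = 1000, end = 5000)
  regions <- buildGeneRegions(ann)
  d <- matrix(rep(c(0, 1), 19 * 2), 19, 4)
  co <- tinyCohort(d, pos = seq(1000, length.out = 19, by = 10))
  gm <- assignVariantsToGenes(co, regions, minSites = 20)
  expect_equal(length(gm$members), 0)
  expect_equal(gm$dropped$gene, "A")
  expect_equal(gm$dropped$n_sites, 19L)
})

test_that("the site cascade is idempotent and conserves attribution", {
  co <- simulateCohort(simulationConfig(
    nCases = 80, nControls = 80, nGenes = 3, sitesPerGene = 15,
    mafSpectrum = defaultMafSpectrum(), seed = 55,
    qualityModel = modifyList(.rvbfDefaultQuality(),
                              list(corruption = list(site_qual = 0.2,
                                                     site_mean_gq = 0.1,
                                                     genotype = 0.02)))))
  qc <- qcConfig("ilcco")
  masked <- maskGenotypes(co, qc)
  r1 <- applySiteFilters(masked, qc)
  # conservation: PASS + one first-failing bucket each
  expect_equal(r1$report@nIn,
               r1$report@nPass + sum(r1$report@ruleCounts))
  expect_equal(length(meta(r1$cohort)$failedRules),
               r1$report@nIn - r1$report@nPass)
  # idempotence on the passing set
  r2 <- applySiteFilters(r1$cohort, qc)
  expect_equal(r2$report@nPass, r1$report@nPass)
  expect_equal(sum(r2$report@ruleCounts), 0)
  expect_equal(unname(dosages(r2$cohort)), unname(dosages(r1$cohort)))
  # PASS set carries no mass above MAF 0.01
  hist <- r1$report@mafHistogram
  expect_equal(unname(hist["[0.01,0.05)"] + hist["[0.05,0.5]"]), 0)
})

test_that("boundary sites survive: MAF at exactly 1%, singleton at GQ50/DP20", {
  # 100 samples, 2 het carriers: MAF exactly 2/200 = 0.01; not a singleton
  d <- matrix(0, 1, 100); d[1, 1:2] <- 1
  co <- tinyCohort(d)
  r <- applySiteFilters(co, qcConfig("ilcco"))
  expect_equal(r$report@nPass, 1L)
  # good-quality singleton survives at the exact thresholds
  d2 <- matrix(0, 1, 100); d2[1, 1] <- 1
  gq <- matrix(99, 1, 100); gq[1, 1] <- 50
  dp <- matrix(50, 1, 100); dp[1, 1] <- 20
  co2 <- tinyCohort(d2, gq = gq, dp = dp)
  r2 <- applySiteFilters(co2, qcConfig("ilcco"))
  expect_equal(r2$report@nPass, 1L)
  # one notch below either threshold excludes it
  gq[1, 1] <- 49
  r3 <- applySiteFilters(tinyCohort(d2, gq = gq, dp = dp), qcConfig("ilcco"))
  expect_equal(unname(r3$report@ruleCounts["singleton_quality"]), 1L)
})

test_that("the engineered 8-site panel attributes one exclusion per rule", {
  qc <- qcConfig("ilcco")
  pan <- maskGenotypes(exampleQCPanel(), qc)
  res <- applySiteFilters(pan, qc)
  expected <- meta(exampleQCPanel())$expectedVerdicts
  expect_equal(res$report@nPass, 1L)
  expect_equal(rownames(res$cohort), "clean")
  fails <- meta(res$cohort)$failedRules
  expect_equal(fails[names(expected)[expected != "PASS"]],
               expected[expected != "PASS"])
  expect_true(all(res$report@ruleCounts[unique(unname(expected[expected != "PASS"]))] == 1))
})
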