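# Shared fixtures, built in code.

cdata <- function(co) as.data.frame(SummarizedExperiment::colData(co))
vmeta <- function(co) S4Vectors::mcols(SummarizedExperiment::rowRanges(co))
meta <- function(co) S4Vectors::metadata(co)
.rvbfDefaultQuality <- function() rvbf:::.defaultQualityModel()

# a tiny hand-specified cohort: explicit dosages, GQ/DP, phenotype
tinyCohort <- function(dosage, status = NULL, gq = NULL, dp = NULL,
                       chrom = rep("1", nrow(dosage)),
                       pos = seq(100, by = 100, length.out = nrow(dosage)),
                       qual = rep(500, nrow(dosage))) {
  n <- ncol(dosage)
  if (is.null(status)) status <- rep(c(1L, 0L), length.out = n)
  if (is.null(gq)) gq <- matrix(99, nrow(dosage), n)
  if (is.null(dp)) dp <- matrix(50, nrow(dosage), n)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               ref = rep("A", nrow(dosage)),
                               alt = rep("G", nrow(dosage)),
                               QUAL = qual, gene = rep("G1", nrow(dosage)))
  RVCohort(dosage, gr, S4Vectors::DataFrame(status = status),
           GQ = gq, DP = dp)
}

# null case-control cohort for statistics tests (no quality fields)
nullCohort <- function(nCases, nControls, nGenes, sitesPerGene = 25,
                       seed = 1, spectrum = rareSpectrum()) {
  qm <- list(enabled = FALSE)
  simulateCohort(simulationConfig(nCases = nCases, nControls = nControls,
                                  nGenes = nGenes,
                                  sitesPerGene = sitesPerGene,
                                  mafSpectrum = spectrum,
                                  qualityModel = qm, seed = seed))
}

geneMapOf <- function(cohort, minSites = 20) {
  regions <- buildGeneRegions(S4Vectors::metadata(cohort)$genes)
  assignVariantsToGenes(cohort, regions, minSites = minSites)
}

# independent penalized-likelihood evaluator used by Firth oracles
penLoglikOracle <- function(y, X) {
  function(beta) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(crossprod(X * w, X), logarithm = TRUE)$modulus
  }
}

# direct-factorial HWE enumeration oracle (independent of the package's
# recurrence-free implementation path)
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  minor <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (minor == 0) return(1)
  hets <- seq(minor %% 2, minor, by = 2)
  probs <- vapply(hets, function(h) {
    ha <- (minor - h) / 2
    hA <- n - h - ha
    factorial(n) / (factorial(hA) * factorial(h) * factorial(ha)) * 2^h
  }, 0)
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hets)]
  sum(probs[probs <= pObs * (1 + 1e-12)])
}
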