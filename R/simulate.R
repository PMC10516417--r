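# Synthetic case-control exome cohorts.
#
# The generator draws a super-population, assigns disease by a logistic
# model over causal rare-variant dosages and covariates, then samples the
# requested numbers of cases and controls retrospectively — the sampling
# design of a case-control sequencing study. A single master seed fans out
# to named substreams so each stage (spectrum, covariates, phenotype,
# genotypes, quality fields) is independently reproducible.

.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 44488 * 48271 + h * 9973) %% 2147483647L)
}

#' Default minor-allele-frequency spectrum
#'
#' A four-component mixture over population MAF matching the bin make-up of
#' a rare-variant-dominated exome call set: weights 10.12% monomorphic,
#' 75.79% in (0, 0.01), 4.47% in [0.01, 0.05) and 9.62% in [0.05, 0.5),
#' drawn log-uniformly within each polymorphic bin. Pass different weights
#' or bounds to reshape the spectrum (e.g. \code{rareSpectrum()} for
#' polymorphic-rare-only simulations).
#'
#' @param weights named non-negative weights for components
#'   \code{mono}, \code{rare}, \code{low}, \code{common}.
#' @param rareRange,lowRange,commonRange numeric length-2 MAF bounds.
#' @return a spectrum list understood by \code{\link{drawSiteMafs}}.
#' @export
defaultMafSpectrum <- function(weights = c(mono = 0.1012, rare = 0.7579,
                                           low = 0.0447, common = 0.0962),
                               rareRange = c(1e-4, 0.01),
                               lowRange = c(0.01, 0.05),
                               commonRange = c(0.05, 0.5)) {
  list(weights = weights,
       ranges = list(mono = c(0, 0), rare = rareRange,
                     low = lowRange, common = commonRange))
}

#' @rdname defaultMafSpectrum
#' @param minMaf,maxMaf bounds of the single rare component.
#' @export
rareSpectrum <- function(minMaf = 0.002, maxMaf = 0.01)
  defaultMafSpectrum(weights = c(mono = 0, rare = 1, low = 0, common = 0),
                     rareRange = c(minMaf, maxMaf))

#' Draw per-site population minor allele frequencies
#'
#' @param n number of sites.
#' @param spectrum a spectrum list (see \code{\link{defaultMafSpectrum}}).
#' @param seed optional integer seed.
#' @return numeric vector of MAFs (0 for the monomorphic component).
#' @export
drawSiteMafs <- function(n, spectrum = defaultMafSpectrum(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- spectrum$weights
  comp <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
  maf <- numeric(n)
  for (k in names(w)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    r <- spectrum$ranges[[k]]
    if (r[2] <= 0) maf[idx] <- 0
    else maf[idx] <- exp(runif(length(idx), log(r[1]), log(r[2])))
  }
  maf
}

.defaultCovariateModel <- function(nPCs = 5L) {
  list(age = list(mean = 60, sd = 10, beta = 0.02),
       sex = list(pMale = 0.5, beta = 0.2),
       smoking = list(p = c(never = 0.45, former = 0.35, current = 0.20),
                      beta = c(never = 0, former = 1.0, current = 1.6)),
       pcs = list(sd = 1, beta = rep(0, nPCs)))
}

.defaultQualityModel <- function() {
  list(enabled = TRUE,
       qual = list(shift = 100, shape = 2, scale = 200),
       gq = list(base = 50, lambda = 20),
       dp = list(base = 20, lambda = 30),
       corruption = list(site_qual = 0, site_mean_gq = 0, genotype = 0),
       targetPreset = "ilcco")
}

#' Build a simulation recipe
#'
#' @param nCases,nControls cohort sizes to sample retrospectively.
#' @param nGenes,sitesPerGene gene layout; \code{sitesPerGene} may be a
#'   single count or a length-2 range.
#' @param mafSpectrum see \code{\link{defaultMafSpectrum}}.
#' @param causalGenes data.frame with columns \code{gene} (index),
#'   \code{arch} ("sparse" or "distributed"), \code{logOR} (per-allele
#'   log odds ratio) and \code{fracCausal} (fraction of the gene's sites
#'   carrying the effect).
#' @param covariateModel effect sizes and generating distributions for
#'   age/sex/smoking/PC terms; smoking is generated with a strong disease
#'   effect so adjusted and unadjusted analyses differ measurably.
#' @param prevalenceIntercept baseline log-odds of disease for a
#'   never-smoking female of mean age at PC = 0.
#' @param qualityModel QUAL/GQ/DP distributions plus named corruption rates
#'   (\code{site_qual}, \code{site_mean_gq}, \code{genotype}).
#' @param popMultiplier super-population size as a multiple of
#'   \code{nCases + nControls}.
#' @param nPCs number of principal-component covariates.
#' @param seed master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nCases, nControls, nGenes = 10L,
                             sitesPerGene = 25L,
                             mafSpectrum = defaultMafSpectrum(),
                             causalGenes = data.frame(gene = integer(),
                                                      arch = character(),
                                                      logOR = numeric(),
                                                      fracCausal = numeric()),
                             covariateModel = .defaultCovariateModel(nPCs),
                             prevalenceIntercept = -3,
                             qualityModel = .defaultQualityModel(),
                             popMultiplier = 25, nPCs = 5L, seed = 1L) {
  new("SimulationConfig", nCases = as.integer(nCases),
      nControls = as.integer(nControls), nGenes = as.integer(nGenes),
      sitesPerGene = as.integer(sitesPerGene), mafSpectrum = mafSpectrum,
      causalGenes = causalGenes, covariateModel = covariateModel,
      prevalenceIntercept = prevalenceIntercept, qualityModel = qualityModel,
      popMultiplier = popMultiplier, nPCs = as.integer(nPCs),
      seed = as.integer(seed))
}

.geneLayout <- function(config) {
  set.seed(.substreamSeed(config@seed, "layout"))
  nG <- config@nGenes
  spg <- config@sitesPerGene
  m <- if (length(spg) == 2L) sample(spg[1]:spg[2], nG, replace = TRUE)
       else rep(spg, nG)
  chrom <- as.character((seq_len(nG) - 1L) %% 22L + 1L)
  start <- 10000L + ((seq_len(nG) - 1L) %/% 22L) * 50000L
  span <- 30000L
  genes <- data.frame(gene = paste0("G", seq_len(nG)), chrom = chrom,
                      start = start, end = start + span - 1L,
                      stringsAsFactors = FALSE)
  pos <- unlist(lapply(seq_len(nG), function(g)
    sort(sample(seq(genes$start[g], genes$end[g]), m[g]))))
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  nS <- sum(m)
  ref <- sample(bases, nS, replace = TRUE)
  isTs <- runif(nS) < 2 / 3
  alt <- ifelse(isTs, transition[ref],
                vapply(ref, function(b) {
                  tv <- setdiff(bases, c(b, transition[[b]]))
                  tv[sample.int(2, 1)]
                }, ""))
  list(genes = genes, siteGene = rep(genes$gene, m),
       chrom = rep(chrom, m), pos = pos, ref = ref, alt = unname(alt),
       sitesPerGene = m)
}

#' Simulate a case-control cohort
#'
#' Draws Hardy-Weinberg genotypes at spectrum frequencies, assigns disease
#' by \eqn{\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum_v \beta_v G_v +
#' \gamma' X}, samples cases and controls retrospectively, and attaches
#' QUAL/GQ/DP quality fields (see \code{\link{injectQualityFields}}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return an \linkS4class{RVCohort}; \code{metadata()} carries the gene
#'   annotation table (\code{genes}), the causal-variant table
#'   (\code{causalVariants}) and the quality-corruption ledger
#'   (\code{qualityLedger}).
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  lay <- .geneLayout(config)
  nS <- length(lay$pos)

  maf <- drawSiteMafs(nS, config@mafSpectrum,
                      seed = .substreamSeed(config@seed, "spectrum"))

  # causal-variant table
  set.seed(.substreamSeed(config@seed, "causal"))
  beta <- numeric(nS)
  cg <- config@causalGenes
  if (nrow(cg)) for (i in seq_len(nrow(cg))) {
    gid <- paste0("G", cg$gene[i])
    idx <- which(lay$siteGene == gid & maf > 0)
    frac <- if (!is.null(cg$fracCausal) && is.finite(cg$fracCausal[i]))
      cg$fracCausal[i] else if (identical(cg$arch[i], "sparse")) 0.1 else 1
    k <- max(1L, round(frac * length(idx)))
    pick <- if (length(idx) > k) sort(sample(idx, k)) else idx
    beta[pick] <- cg$logOR[i]
  }
  causalIdx <- which(beta != 0)

  # super-population covariates and linear predictor
  n <- config@nCases + config@nControls
  N <- ceiling(config@popMultiplier * n)
  cm <- config@covariateModel
  set.seed(.substreamSeed(config@seed, "covariates"))
  age <- rnorm(N, cm$age$mean, cm$age$sd)
  sex <- rbinom(N, 1, cm$sex$pMale)
  smoking <- sample(names(cm$smoking$p), N, replace = TRUE, prob = cm$smoking$p)
  pcs <- matrix(rnorm(N * config@nPCs, 0, cm$pcs$sd), N, config@nPCs)
  lp <- config@prevalenceIntercept + cm$age$beta * (age - cm$age$mean) +
    cm$sex$beta * sex + unname(cm$smoking$beta[smoking]) +
    drop(pcs %*% cm$pcs$beta)

  # causal genotypes are drawn for the whole population (they shape disease);
  # neutral sites only for the sampled individuals (independent of phenotype)
  set.seed(.substreamSeed(config@seed, "causalgeno"))
  Gc <- NULL
  if (length(causalIdx)) {
    Gc <- matrix(rbinom(N * length(causalIdx), 2,
                        rep(maf[causalIdx], each = N)), N)
    lp <- lp + drop(Gc %*% beta[causalIdx])
  }

  set.seed(.substreamSeed(config@seed, "phenotype"))
  y <- rbinom(N, 1, 1 / (1 + exp(-lp)))
  if (sum(y) < config@nCases)
    stop("population cap exceeded: N = ", N, " produced ", sum(y),
         " cases but ", config@nCases, " were requested; raise",
         " popMultiplier or prevalenceIntercept")
  if (sum(1 - y) < config@nControls)
    stop("population cap exceeded: N = ", N, " produced ", sum(1 - y),
         " controls but ", config@nControls, " were requested")

  set.seed(.substreamSeed(config@seed, "sampling"))
  pick <- c(sample(which(y == 1), config@nCases),
            sample(which(y == 0), config@nControls))

  set.seed(.substreamSeed(config@seed, "genotypes"))
  dosage <- matrix(rbinom(nS * n, 2, rep(maf, times = n)), nrow = nS)
  if (length(causalIdx)) dosage[causalIdx, ] <- t(Gc[pick, , drop = FALSE])

  samples <- DataFrame(status = y[pick], age = age[pick], sex = sex[pick],
                       smoking = smoking[pick],
                       smoking_ever = as.integer(smoking[pick] != "never"))
  for (k in seq_len(config@nPCs)) samples[[paste0("PC", k)]] <- pcs[pick, k]
  rownames(dosage) <- paste0("v", seq_len(nS))
  colnames(dosage) <- rownames(samples) <- paste0("S", seq_len(n))

  gr <- GRanges(lay$chrom, IRanges(lay$pos, lay$pos), ref = lay$ref,
                alt = lay$alt, QUAL = rep(NA_real_, nS), gene = lay$siteGene,
                popMaf = maf)
  cohort <- RVCohort(dosage, gr, samples)
  metadata(cohort)$genes <- lay$genes
  metadata(cohort)$causalVariants <-
    data.frame(variant = rownames(dosage)[causalIdx],
               gene = lay$siteGene[causalIdx], logOR = beta[causalIdx])
  injectQualityFields(cohort, config)
}

#' Attach QUAL/GQ/DP quality fields to a cohort
#'
#' Every site receives a QUAL value and every genotype a GQ and DP, drawn
#' from \code{config@qualityModel}. With all corruption rates at zero the
#' defaults violate no site- or genotype-level filter rule of either QC
#' preset. Corruption rates engineer violations in expectation: a corrupted
#' site's QUAL drops below the target preset's floor, a corrupted
#' \code{site_mean_gq} site has all its GQ values pulled below the mean-GQ
#' threshold, and a corrupted genotype gets GQ below the mask threshold.
#' Engineered violations are recorded in
#' \code{metadata(cohort)$qualityLedger}.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return the cohort with \code{QUAL} filled in and \code{GQ}/\code{DP}
#'   assays added.
#' @export
injectQualityFields <- function(cohort, config) {
  qm <- config@qualityModel
  if (isFALSE(qm$enabled)) return(cohort)
  cr <- qm$corruption
  if (any(unlist(cr) < 0) || any(unlist(cr) > 1))
    stop("corruption rates must be in [0, 1]")
  preset <- qcConfig(if (is.null(qm$targetPreset)) "ilcco" else qm$targetPreset)
  nS <- nrow(cohort); n <- ncol(cohort)
  set.seed(.substreamSeed(config@seed, "quality"))
  qual <- qm$qual$shift + rgamma(nS, shape = qm$qual$shape,
                                 scale = qm$qual$scale)
  gq <- matrix(qm$gq$base + pmin(49, rpois(nS * n, qm$gq$lambda)), nS, n)
  dp <- matrix(qm$dp$base + rpois(nS * n, qm$dp$lambda), nS, n)

  ledger <- data.frame(kind = character(), variant = integer(),
                       sample = integer())
  badQ <- which(runif(nS) < (cr$site_qual %||% 0))
  if (length(badQ)) {
    qual[badQ] <- runif(length(badQ), 0, preset@minQual)
    ledger <- rbind(ledger, data.frame(kind = "site_qual", variant = badQ,
                                       sample = NA_integer_))
  }
  badG <- which(runif(nS) < (cr$site_mean_gq %||% 0))
  badG <- setdiff(badG, badQ)      # one engineered site-level fault per site
  if (length(badG)) {
    gq[badG, ] <- matrix(round(runif(length(badG) * n, 0,
                                     preset@minMeanGQ - 1)),
                         length(badG), n)
    ledger <- rbind(ledger, data.frame(kind = "site_mean_gq", variant = badG,
                                       sample = NA_integer_))
  }
  badGt <- which(runif(nS * n) < (cr$genotype %||% 0))
  if (length(badGt)) {
    gq[badGt] <- round(runif(length(badGt), 0, preset@maskGQ - 1))
    ledger <- rbind(ledger,
                    data.frame(kind = "genotype",
                               variant = (badGt - 1L) %% nS + 1L,
                               sample = (badGt - 1L) %/% nS + 1L))
  }
  mcols(rowRanges(cohort))$QUAL <- qual
  dimnames(gq) <- dimnames(dp) <- dimnames(dosages(cohort))
  assays(cohort)$GQ <- gq
  assays(cohort)$DP <- dp
  metadata(cohort)$qualityLedger <- ledger
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permute the phenotype of a cohort
#'
#' Uniform random permutation of the case/control labels; genotypes and
#' covariates are untouched, so case and control totals are conserved.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param seed optional integer seed.
#' @return the cohort with permuted \code{status}.
#' @export
permutePhenotype <- function(cohort, seed = NULL) {
  if (ncol(cohort) < 2L) stop("need at least 2 samples to permute")
  if (!is.null(seed)) set.seed(seed)
  colData(cohort)$status <- sample(phenotype(cohort))
  cohort
}
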