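#' RVCohort: a case-control rare-variant cohort
#'
#' An S4 container for a genotyped case-control cohort, extending
#' \linkS4class{RangedSummarizedExperiment}. Rows are bi-allelic variant
#' sites (a \link[GenomicRanges]{GRanges} with \code{ref}, \code{alt},
#' \code{QUAL} and a \code{gene} hint in \code{mcols}); columns are samples.
#' Assays:
#' \describe{
#'   \item{\code{dosage}}{minor/alt-allele dosage in \{0,1,2\}, \code{NA} =
#'     missing genotype.}
#'   \item{\code{GQ}, \code{DP}}{per-genotype quality and depth (optional
#'     until quality fields are injected or read from a VCF).}
#' }
#' \code{colData} carries \code{status} (1 = case, 0 = control) and any
#' covariates (\code{age}, \code{sex}, \code{smoking}, \code{smoking_ever},
#' \code{PC1..PCk}).
#'
#' @aliases RVCohort-class
#' @exportClass RVCohort
setClass("RVCohort", contains = "RangedSummarizedExperiment")

.validRVCohort <- function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (!"status" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'status'")
  else {
    s <- colData(object)$status
    if (!all(s %in% c(0, 1)))
      msg <- c(msg, "status must be binary (1 = case, 0 = control)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RVCohort", .validRVCohort)

#' Construct an RVCohort
#'
#' @param dosage variants x samples integer/numeric matrix in \{0,1,2,NA\}.
#' @param variants \code{GRanges} (one range per row of \code{dosage}) with
#'   metadata columns \code{ref}, \code{alt}, \code{QUAL}; or a data.frame
#'   with \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{QUAL}.
#' @param samples \code{data.frame}/\code{DataFrame} of per-sample phenotype
#'   and covariates; must contain \code{status}.
#' @param GQ,DP optional matrices matching \code{dosage}.
#' @return an \linkS4class{RVCohort}.
#' @export
RVCohort <- function(dosage, variants, samples, GQ = NULL, DP = NULL) {
  if (is.data.frame(variants)) {
    variants <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos),
                        ref = variants$ref, alt = variants$alt,
                        QUAL = variants$QUAL)
  }
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("v", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  names(variants) <- rownames(dosage)
  al <- list(dosage = dosage)
  if (!is.null(GQ)) { dimnames(GQ) <- dimnames(dosage); al$GQ <- GQ }
  if (!is.null(DP)) { dimnames(DP) <- dimnames(dosage); al$DP <- DP }
  se <- SummarizedExperiment(assays = al, rowRanges = variants,
                             colData = DataFrame(samples))
  new("RVCohort", se)
}

#' Quality-control configuration
#'
#' Thresholds for the site/genotype/sample filter cascade. All comparisons
#' are strict inequalities exactly as the rules are usually stated
#' (e.g. "exclude QUAL < 100"); boundary values survive. \code{NA} disables
#' a rule. See \code{\link{qcConfig}} for the two built-in presets.
#'
#' @slot preset name of the preset ("ilcco", "ukbiobank" or "custom").
#' @slot minQual minimum site QUAL.
#' @slot minMeanGQ minimum mean genotype quality across called genotypes.
#' @slot singletonGQ,singletonDP singleton sites are excluded when the
#'   minor-allele carrier's GQ or DP falls below these.
#' @slot biallelicOnly,excludeSexChrom structural exclusions.
#' @slot hweFloor Hardy-Weinberg exact-test p-value floor (controls only).
#' @slot maxMissing maximum post-mask genotype missing rate per site.
#' @slot maxMaf maximum minor allele frequency (rare-variant definition).
#' @slot maskGQ,maskDP genotype-level mask: set missing when GQ < maskGQ or
#'   DP < maskDP.
#' @slot sampleMaxMissing per-sample genotype missing-rate ceiling.
#' @slot hetSdMult samples more than this many SDs below mean
#'   heterozygosity are dropped.
#' @aliases QCConfig-class
#' @exportClass QCConfig
setClass("QCConfig", representation(
  preset = "character",
  minQual = "numeric", minMeanGQ = "numeric",
  singletonGQ = "numeric", singletonDP = "numeric",
  biallelicOnly = "logical", excludeSexChrom = "logical",
  hweFloor = "numeric", maxMissing = "numeric", maxMaf = "numeric",
  maskGQ = "numeric", maskDP = "numeric",
  sampleMaxMissing = "numeric", hetSdMult = "numeric"))

setValidity("QCConfig", function(object) {
  msg <- character()
  for (sl in c("minQual", "minMeanGQ", "singletonGQ", "singletonDP",
               "hweFloor", "maxMissing", "maxMaf", "maskGQ", "maskDP",
               "sampleMaxMissing", "hetSdMult"))
    if (length(slot(object, sl)) != 1L)
      msg <- c(msg, paste0("'", sl, "' must be length 1 (NA to disable)"))
  if (!is.na(object@maxMaf) && (object@maxMaf <= 0 || object@maxMaf > 0.5))
    msg <- c(msg, "maxMaf must be in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Simulation recipe for a synthetic case-control exome cohort
#'
#' Full description of a synthetic cohort: cohort sizes, gene/site layout,
#' minor-allele-frequency spectrum, causal-gene architectures, covariate
#' disease model, genotype-quality model and the master seed. Identical
#' config + seed gives byte-identical cohorts. Build with
#' \code{\link{simulationConfig}}.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nCases = "integer", nControls = "integer",
  nGenes = "integer", sitesPerGene = "integer",
  mafSpectrum = "list", causalGenes = "data.frame",
  covariateModel = "list", prevalenceIntercept = "numeric",
  qualityModel = "list", popMultiplier = "numeric",
  nPCs = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "nCases and nControls must be >= 1")
  if (object@nGenes < 1L || any(object@sitesPerGene < 1L))
    msg <- c(msg, "nGenes and sitesPerGene must be >= 1")
  cg <- object@causalGenes
  if (nrow(cg)) {
    if (any(cg$gene < 1L | cg$gene > object@nGenes))
      msg <- c(msg, "every causal gene index must be in [1, nGenes]")
    if (any(!is.finite(cg$logOR)))
      msg <- c(msg, "causal log-odds-ratios must be finite")
  }
  w <- object@mafSpectrum$weights
  if (is.null(w) || any(w < 0) || sum(w) <= 0)
    msg <- c(msg, "mafSpectrum$weights must be non-negative, not all zero")
  cr <- object@qualityModel$corruption
  if (length(cr) && (any(unlist(cr) < 0) || any(unlist(cr) > 1)))
    msg <- c(msg, "corruption rates must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Quality-control report
#'
#' Per-rule exclusion tallies for one pass of the site-filter cascade, with
#' conservation: every input site is either PASS or attributed to exactly
#' one first-failing rule.
#'
#' @slot ruleCounts named integer vector of first-failing-rule exclusions.
#' @slot nIn,nPass sites in/out.
#' @slot genotypesMasked number of genotypes set missing by the GQ/DP mask.
#' @slot samplesRemoved data.frame(sample, reason).
#' @slot tstvBefore,tstvAfter transition/transversion ratio over SNVs.
#' @slot mafHistogram site counts in MAF bins 0, (0,0.01), [0.01,0.05),
#'   [0.05,0.5].
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport", representation(
  ruleCounts = "integer", nIn = "integer", nPass = "integer",
  genotypesMasked = "integer", samplesRemoved = "data.frame",
  tstvBefore = "numeric", tstvAfter = "numeric",
  mafHistogram = "numeric"))

setValidity("QCReport", function(object) {
  if (any(object@ruleCounts < 0)) return("rule counts must be non-negative")
  if (object@nIn != object@nPass + sum(object@ruleCounts))
    return("sites in must equal sites out plus per-rule exclusions")
  TRUE
})
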