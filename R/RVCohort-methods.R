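#' @describeIn RVCohort-class minor-allele dosage matrix (variants x samples).
#' @param x,object an \code{RVCohort}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname RVCohort-class
#' @export
setMethod("dosages", "RVCohort", function(x) assay(x, "dosage"))

#' @describeIn RVCohort-class binary phenotype vector (1 = case).
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname RVCohort-class
#' @export
setMethod("phenotype", "RVCohort", function(x) colData(x)$status)

#' @describeIn RVCohort-class per-genotype quality matrix (or NULL).
#' @export
setGeneric("genotypeQuality", function(x) standardGeneric("genotypeQuality"))

#' @rdname RVCohort-class
#' @export
setMethod("genotypeQuality", "RVCohort", function(x)
  if ("GQ" %in% names(assays(x))) assay(x, "GQ") else NULL)

#' @describeIn RVCohort-class per-genotype read-depth matrix (or NULL).
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname RVCohort-class
#' @export
setMethod("readDepth", "RVCohort", function(x)
  if ("DP" %in% names(assays(x))) assay(x, "DP") else NULL)

#' Design matrix of adjustment covariates
#'
#' Assembles an intercept-plus-covariates design from \code{colData}. The
#' default term set mirrors a standard epidemiological adjustment: age, sex,
#' ever/never smoking and the top five principal components (terms absent
#' from \code{colData} are skipped with a message).
#'
#' @param x an \code{RVCohort}.
#' @param terms character vector of colData columns; NULL for intercept-only.
#' @return numeric matrix with an \code{(Intercept)} column.
#' @export
covariateMatrix <- function(x, terms = c("age", "sex", "smoking_ever",
                                         paste0("PC", 1:5))) {
  cd <- as.data.frame(colData(x))
  keep <- intersect(terms, colnames(cd))
  miss <- setdiff(terms, keep)
  if (length(miss) && !is.null(terms))
    message("covariateMatrix: skipping absent terms: ",
            paste(miss, collapse = ", "))
  X <- matrix(1, nrow(cd), 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in keep) X <- cbind(X, setNames(data.frame(as.numeric(cd[[tm]])), tm))
  as.matrix(X)
}

setMethod("show", "RVCohort", function(object) {
  s <- phenotype(object)
  cat("RVCohort:", nrow(object), "variant sites x", ncol(object), "samples\n")
  cat("  cases:", sum(s == 1), " controls:", sum(s == 0), "\n")
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
  cv <- setdiff(colnames(colData(object)), "status")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
})

setMethod("show", "QCConfig", function(object) {
  cat("QCConfig preset:", object@preset, "\n")
  cat(sprintf("  site: QUAL<%s, meanGQ<%s, singleton GQ<%s/DP<%s, HWE p<%s,\n",
              object@minQual, object@minMeanGQ, object@singletonGQ,
              object@singletonDP, object@hweFloor))
  cat(sprintf("        missing>%s, MAF>%s; biallelic-only=%s, drop sex chrom=%s\n",
              object@maxMissing, object@maxMaf, object@biallelicOnly,
              object@excludeSexChrom))
  cat(sprintf("  genotype mask: GQ<%s or DP<%s\n", object@maskGQ, object@maskDP))
  cat(sprintf("  sample: missing>%s, heterozygosity < mean - %s SD\n",
              object@sampleMaxMissing, object@hetSdMult))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nIn, "sites in,", object@nPass, "PASS\n")
  rc <- object@ruleCounts[object@ruleCounts > 0]
  if (length(rc))
    for (r in names(rc)) cat(sprintf("  excluded by %-18s %d\n", r, rc[[r]]))
  cat("  genotypes masked:", object@genotypesMasked, "\n")
  if (nrow(object@samplesRemoved))
    cat("  samples removed:", nrow(object@samplesRemoved), "\n")
  if (is.finite(object@tstvBefore) || is.finite(object@tstvAfter))
    cat(sprintf("  Ts/Tv before/after: %.3f / %.3f\n",
                object@tstvBefore, object@tstvAfter))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCases, "cases +", object@nControls,
      "controls;", object@nGenes, "genes x",
      paste(unique(object@sitesPerGene), collapse = "-"), "sites\n")
  if (nrow(object@causalGenes))
    cat("  causal genes:", nrow(object@causalGenes), "\n")
  cat("  seed:", object@seed, "\n")
})
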