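# Variant, genotype and sample quality control.
#
# The cascade order is fixed: genotype masking first (missingness and MAF
# are computed from masked data), then site rules in the order
# site-quality -> structure (biallelic / sex chromosome) -> singleton ->
# HWE-in-controls -> missing rate -> MAF, with first-failure attribution so
# every excluded site lands in exactly one report bucket.

#' QC presets
#'
#' Two built-in filter cascades for case-control exome data plus a custom
#' constructor. All thresholds are strict inequalities; boundary values
#' survive.
#'
#' \describe{
#' \item{\code{"ilcco"}}{site QUAL < 100 or mean GQ < 50 excluded; singleton
#'   whose minor-allele carrier has GQ < 50 or DP < 20 excluded;
#'   non-bi-allelic and sex-chromosome sites excluded; Hardy-Weinberg exact
#'   p < 1e-7 in controls excluded; genotypes masked at GQ < 30 or DP < 10;
#'   MAF > 1\% excluded.}
#' \item{\code{"ukbiobank"}}{non-bi-allelic or QUAL < 10 excluded; mean
#'   GQ < 30 excluded; singleton with DP < 20 or GQ < 40 excluded; genotypes
#'   masked at DP < 10 or GQ < 20; post-mask missing rate > 10\% excluded;
#'   MAF > 1\% excluded. No HWE or sex-chromosome rule.}
#' }
#'
#' @param preset "ilcco", "ukbiobank" or "custom".
#' @param ... for \code{preset = "custom"}, slot overrides (see
#'   \linkS4class{QCConfig}).
#' @return a \linkS4class{QCConfig}.
#' @export
qcConfig <- function(preset = c("ilcco", "ukbiobank", "custom"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ilcco = list(minQual = 100, minMeanGQ = 50, singletonGQ = 50,
                 singletonDP = 20, biallelicOnly = TRUE,
                 excludeSexChrom = TRUE, hweFloor = 1e-7,
                 maxMissing = NA_real_, maxMaf = 0.01,
                 maskGQ = 30, maskDP = 10),
    ukbiobank = list(minQual = 10, minMeanGQ = 30, singletonGQ = 40,
                     singletonDP = 20, biallelicOnly = TRUE,
                     excludeSexChrom = FALSE, hweFloor = NA_real_,
                     maxMissing = 0.10, maxMaf = 0.01,
                     maskGQ = 20, maskDP = 10),
    custom = list(minQual = NA_real_, minMeanGQ = NA_real_,
                  singletonGQ = NA_real_, singletonDP = NA_real_,
                  biallelicOnly = TRUE, excludeSexChrom = FALSE,
                  hweFloor = NA_real_, maxMissing = NA_real_, maxMaf = 0.01,
                  maskGQ = NA_real_, maskDP = NA_real_))
  args <- utils::modifyList(c(base, list(sampleMaxMissing = 0.10,
                                         hetSdMult = 6)),
                            list(...))
  do.call(new, c(list("QCConfig", preset = preset), args))
}

#' Minor allele frequency of a dosage vector
#'
#' Alt-allele frequency over non-missing genotypes, folded to \eqn{\le} 0.5.
#'
#' @param dosages numeric vector in \{0,1,2,NA\}.
#' @return the folded MAF.
#' @export
computeMaf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("cannot compute MAF: all genotypes missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

.mafVector <- function(d) {
  nOk <- rowSums(!is.na(d))
  f <- rowSums(d, na.rm = TRUE) / (2 * nOk)
  ifelse(nOk == 0, NA_real_, pmin(f, 1 - f))
}

#' Mask low-confidence genotypes
#'
#' Sets a genotype missing when its GQ or DP falls below the configured
#' thresholds (strict inequalities). A genotype with absent GQ/DP fails the
#' mask. Masking happens before missing-rate and MAF computation.
#'
#' @param cohort an \linkS4class{RVCohort} with GQ/DP assays.
#' @param qc a \linkS4class{QCConfig}.
#' @return the cohort with offending dosages set to NA;
#'   \code{metadata()$genotypesMasked} counts newly masked genotypes.
#' @export
maskGenotypes <- function(cohort, qc) {
  gq <- genotypeQuality(cohort)
  dp <- readDepth(cohort)
  if (is.null(gq) || is.null(dp))
    stop("maskGenotypes requires GQ and DP assays")
  d <- dosages(cohort)
  bad <- matrix(FALSE, nrow(d), ncol(d))
  if (!is.na(qc@maskGQ)) bad <- bad | is.na(gq) | gq < qc@maskGQ
  if (!is.na(qc@maskDP)) bad <- bad | is.na(dp) | dp < qc@maskDP
  newly <- bad & !is.na(d)
  d[bad] <- NA_real_
  assays(cohort)$dosage <- d
  metadata(cohort)$genotypesMasked <-
    (metadata(cohort)$genotypesMasked %||% 0L) + sum(newly)
  cohort
}

.isSNV <- function(ref, alt)
  ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

.isTransition <- function(ref, alt)
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")

#' Transition/transversion ratio
#'
#' @param ref,alt character vectors of alleles (SNVs).
#' @return Ts/Tv over SNV sites; +Inf with attribute \code{warning} when no
#'   transversions are present.
#' @export
tstvRatio <- function(ref, alt) {
  snv <- .isSNV(ref, alt) & ref != alt
  if (!any(snv)) stop("no SNVs: Ts/Tv undefined")
  ts <- sum(.isTransition(ref[snv], alt[snv]))
  tv <- sum(snv) - ts
  if (tv == 0) {
    r <- Inf
    attr(r, "warning") <- "no transversions"
    warning("Ts/Tv: no transversions among SNVs")
    return(r)
  }
  ts / tv
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: all heterozygote counts compatible with the
#' observed minor-allele count are enumerated, each weighted by the
#' conditional distribution of heterozygotes given allele counts, and the
#' p-value sums the probabilities no larger than that of the observed
#' configuration.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygous major, Aa het, aa
#'   homozygous minor).
#' @return the exact p-value (1 for a monomorphic site).
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("no genotypes")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  minor <- min(nA, na)
  if (minor == 0) return(1)
  # conditional distribution of the het count h given (n, minor count):
  # P(h) proportional to n! / (nMajorHom! h! nMinorHom!) * 2^h
  hets <- seq(minor %% 2, minor, by = 2)
  haa <- (minor - hets) / 2
  hAA <- n - hets - haa
  logp <- lgamma(n + 1) - lgamma(hAA + 1) - lgamma(hets + 1) -
    lgamma(haa + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pObs <- p[match(nAa, hets)]
  sum(p[p <= pObs * (1 + 1e-12)])
}

#' Assemble a site table with derived per-site QC quantities
#' @keywords internal
.siteStats <- function(cohort, controls) {
  d <- dosages(cohort)
  gr <- rowRanges(cohort)
  gq <- genotypeQuality(cohort)
  maf <- .mafVector(d)
  missRate <- rowMeans(is.na(d))
  nOk <- rowSums(!is.na(d))
  altCount <- rowSums(d, na.rm = TRUE)
  minorCount <- pmin(altCount, 2 * nOk - altCount)
  list(maf = maf, missRate = missRate, minorCount = minorCount,
       altCount = altCount, nOk = nOk,
       meanGQ = if (is.null(gq)) rep(NA_real_, nrow(d)) else
         rowMeans(gq, na.rm = TRUE),
       qual = mcols(gr)$QUAL,
       chrom = as.character(seqnames(gr)),
       ref = mcols(gr)$ref, alt = mcols(gr)$alt)
}

.sexChroms <- c("X", "Y", "chrX", "chrY")

#' Apply the site-filter cascade
#'
#' Genotype masking must already have been applied (\code{maskGenotypes});
#' rules are evaluated in the declared order with first-failure attribution.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param qc a \linkS4class{QCConfig}.
#' @param controls logical/index vector of control samples for the HWE rule;
#'   defaults to \code{phenotype(cohort) == 0}.
#' @return \code{list(cohort = passing subset, report = \linkS4class{QCReport})}.
#' @export
applySiteFilters <- function(cohort, qc, controls = phenotype(cohort) == 0) {
  nS <- nrow(cohort)
  rules <- c("low_qual", "low_mean_gq", "not_biallelic", "sex_chromosome",
             "singleton_quality", "hwe", "missing_rate", "maf")
  counts <- setNames(integer(length(rules)), rules)
  if (nS == 0L) {
    report <- new("QCReport", ruleCounts = counts, nIn = 0L, nPass = 0L,
                  genotypesMasked = as.integer(metadata(cohort)$genotypesMasked %||% 0L),
                  samplesRemoved = data.frame(), tstvBefore = NA_real_,
                  tstvAfter = NA_real_, mafHistogram = mafBinCounts(numeric()))
    return(list(cohort = cohort, report = report))
  }
  st <- .siteStats(cohort, controls)
  d <- dosages(cohort)
  gq <- genotypeQuality(cohort)
  dp <- readDepth(cohort)
  fail <- rep(NA_character_, nS)
  mark <- function(idx, rule) {
    idx <- idx & is.na(fail)
    fail[idx] <<- rule
  }
  if (!is.na(qc@minQual)) mark(!is.na(st$qual) & st$qual < qc@minQual,
                               "low_qual")
  if (!is.na(qc@minMeanGQ)) mark(!is.na(st$meanGQ) & st$meanGQ < qc@minMeanGQ,
                                 "low_mean_gq")
  if (qc@biallelicOnly) mark(grepl(",", st$alt), "not_biallelic")
  if (qc@excludeSexChrom) mark(st$chrom %in% .sexChroms, "sex_chromosome")
  if (!is.na(qc@singletonGQ) || !is.na(qc@singletonDP)) {
    singleton <- which(st$minorCount == 1 & is.na(fail))
    for (i in singleton) {
      row <- d[i, ]
      # one minor allele implies exactly one heterozygous carrier,
      # whichever allele is minor
      carrier <- which(!is.na(row) & row == 1)[1]
      bad <- FALSE
      if (!is.na(qc@singletonGQ))
        bad <- bad || is.null(gq) || is.na(gq[i, carrier]) ||
          gq[i, carrier] < qc@singletonGQ
      if (!is.na(qc@singletonDP))
        bad <- bad || is.null(dp) || is.na(dp[i, carrier]) ||
          dp[i, carrier] < qc@singletonDP
      if (bad) fail[i] <- "singleton_quality"
    }
  }
  if (!is.na(qc@hweFloor)) {
    cand <- which(is.na(fail))
    for (i in cand) {
      row <- d[i, controls]
      row <- row[!is.na(row)]
      if (!length(row)) next
      p <- hweExactTest(sum(row == 0), sum(row == 1), sum(row == 2))
      if (p < qc@hweFloor) fail[i] <- "hwe"
    }
  }
  if (!is.na(qc@maxMissing)) mark(st$missRate > qc@maxMissing, "missing_rate")
  if (!is.na(qc@maxMaf)) mark(!is.na(st$maf) & st$maf > qc@maxMaf, "maf")

  pass <- is.na(fail)
  tab <- table(factor(fail, levels = rules))
  counts[rules] <- as.integer(tab[rules])
  snv <- .isSNV(st$ref, st$alt) & st$ref != st$alt
  tstvB <- if (any(snv)) suppressWarnings(
    as.numeric(tstvRatio(st$ref[snv], st$alt[snv]))) else NA_real_
  tstvA <- if (any(snv & pass)) suppressWarnings(
    as.numeric(tstvRatio(st$ref[snv & pass], st$alt[snv & pass]))) else NA_real_
  report <- new("QCReport", ruleCounts = counts, nIn = nS,
                nPass = sum(pass),
                genotypesMasked = as.integer(metadata(cohort)$genotypesMasked %||% 0L),
                samplesRemoved = data.frame(),
                tstvBefore = tstvB, tstvAfter = tstvA,
                mafHistogram = mafBinCounts(st$maf[pass]))
  out <- cohort[pass, ]
  mcols(rowRanges(out))$maf <- st$maf[pass]
  metadata(out)$failedRules <- setNames(fail[!pass], rownames(cohort)[!pass])
  list(cohort = out, report = report)
}

#' Site counts in standard MAF bins
#'
#' Bins are 0, (0, 0.01), [0.01, 0.05), [0.05, 0.5].
#'
#' @param maf numeric vector of folded MAFs.
#' @return named counts.
#' @export
mafBinCounts <- function(maf) {
  maf <- maf[!is.na(maf)]
  c(`0` = sum(maf == 0),
    `(0,0.01)` = sum(maf > 0 & maf < 0.01),
    `[0.01,0.05)` = sum(maf >= 0.01 & maf < 0.05),
    `[0.05,0.5]` = sum(maf >= 0.05))
}

#' Sample-level QC
#'
#' Drops samples with genotype missing rate above \code{qc@sampleMaxMissing}
#' (strict), then samples whose heterozygosity (fraction of non-missing
#' genotypes that are heterozygous) lies more than \code{qc@hetSdMult}
#' standard deviations below the mean of the remaining samples. A zero SD
#' means no heterozygosity outliers.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param qc a \linkS4class{QCConfig}.
#' @return \code{list(cohort = kept samples, removals = data.frame(sample,
#'   reason))}.
#' @export
sampleQC <- function(cohort, qc = qcConfig("ilcco")) {
  d <- dosages(cohort)
  missRate <- colMeans(is.na(d))
  removeMiss <- missRate > qc@sampleMaxMissing
  het <- colSums(d == 1, na.rm = TRUE) / pmax(colSums(!is.na(d)), 1)
  hetKeep <- het[!removeMiss]
  s <- sd(hetKeep)
  removeHet <- rep(FALSE, ncol(d))
  if (is.finite(s) && s > 0)
    removeHet <- !removeMiss & het < mean(hetKeep) - qc@hetSdMult * s
  removals <- data.frame(
    sample = colnames(d)[removeMiss | removeHet],
    reason = c(rep("missing_rate", sum(removeMiss)),
               rep("low_heterozygosity", sum(removeHet))))
  keep <- !(removeMiss | removeHet)
  if (sum(keep) < 2L) stop("sample QC would leave fewer than 2 samples")
  list(cohort = cohort[, keep], removals = removals)
}

#' Build flanked gene analysis regions
#'
#' Each annotated gene span is extended by \code{flank} bp on both sides
#' (start floored at 1); coordinates are 1-based inclusive and the
#' variant-containment test is inclusive on both ends.
#'
#' @param annotations data.frame with \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param flank flank size in bp (default 1000).
#' @return a \code{GRanges} keyed by \code{gene}; malformed rows are skipped
#'   and counted in \code{metadata()$skipped}.
#' @export
buildGeneRegions <- function(annotations, flank = 1000) {
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% colnames(annotations)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  ok <- !is.na(annotations$start) & !is.na(annotations$end) &
    !is.na(annotations$chrom) & annotations$start <= annotations$end &
    annotations$start >= 1
  skipped <- sum(!ok)
  if (skipped) message("buildGeneRegions: skipped ", skipped,
                       " malformed annotation rows")
  a <- annotations[ok, ]
  gr <- GRanges(a$chrom, IRanges(pmax(1, a$start - flank), a$end + flank),
                gene = a$gene)
  names(gr) <- a$gene
  metadata(gr)$skipped <- skipped
  gr
}

#' Assign variants to gene regions
#'
#' A variant may belong to several overlapping genes. Genes with fewer than
#' \code{minSites} member variants are excluded from the analyzable map
#' (the \eqn{\ge} 20-rare-variant inclusion rule), applied per cohort.
#'
#' @param cohort an \linkS4class{RVCohort} of QC-passed rare variants.
#' @param regions output of \code{\link{buildGeneRegions}}.
#' @param minSites minimum member count (default 20).
#' @return \code{list(members = named list of variant indices for analyzable
#'   genes, dropped = data.frame(gene, n_sites) for genes under the rule)}.
#' @export
assignVariantsToGenes <- function(cohort, regions, minSites = 20) {
  hits <- findOverlaps(rowRanges(cohort), regions)
  members <- split(S4Vectors::queryHits(hits),
                   names(regions)[S4Vectors::subjectHits(hits)])
  nSites <- lengths(members)
  keep <- nSites >= minSites
  list(members = members[keep],
       dropped = data.frame(gene = names(members)[!keep],
                            n_sites = as.integer(nSites[!keep])))
}

#' An engineered 8-site QC demonstration panel (synthetic)
#'
#' A hand-constructed cohort of 60 samples (30 cases, 30 controls) and 8
#' bi-allelic sites in which exactly one site violates each rule of the
#' "ilcco" cascade — low QUAL, low mean GQ, non-bi-allelic, sex chromosome,
#' singleton with poor carrier quality, Hardy-Weinberg failure in controls,
#' common (MAF > 1\%) — plus one clean PASS site. The expected first-failing
#' rule per site is recorded in \code{metadata()$expectedVerdicts}.
#'
#' @return an \linkS4class{RVCohort}.
#' @export
exampleQCPanel <- function() {
  n <- 60L
  status <- rep(c(1L, 0L), each = 30)
  mk <- function(x) rep(x, length.out = n)
  # one heterozygote carrier in most rows keeps sites polymorphic & rare
  base <- c(1, rep(0, n - 1))
  dosage <- rbind(
    qual_fail      = base,
    mean_gq_fail   = base,
    multi_allelic  = base,
    sex_chrom      = base,
    bad_singleton  = base,
    hwe_fail       = mk(c(2, 0)),            # homozygote-only: het deficit
    common_maf     = mk(c(1, 1, 0, 0)),      # MAF 0.25 > 1%
    clean          = base)                   # good-quality singleton, rare
  gq <- matrix(60, nrow(dosage), n, dimnames = list(rownames(dosage), NULL))
  dp <- matrix(40, nrow(dosage), n, dimnames = list(rownames(dosage), NULL))
  gq["mean_gq_fail", ] <- 40                 # mean GQ 40 < 50
  gq["bad_singleton", 1] <- 45               # carrier GQ 45 < 50
  qual <- rep(500, nrow(dosage))
  names(qual) <- rownames(dosage)
  qual["qual_fail"] <- 50
  gr <- GRanges(
    c("1", "1", "1", "X", "1", "1", "1", "1"),
    IRanges(seq(1000, by = 100, length.out = 8), width = 1),
    ref = rep("A", 8), alt = c("G", "G", "G,T", "G", "G", "G", "G", "G"),
    QUAL = unname(qual), gene = rep("DEMO", 8))
  cohort <- RVCohort(dosage, gr, DataFrame(status = status), GQ = gq, DP = dp)
  metadata(cohort)$expectedVerdicts <- c(
    qual_fail = "low_qual", mean_gq_fail = "low_mean_gq",
    multi_allelic = "not_biallelic", sex_chrom = "sex_chromosome",
    bad_singleton = "singleton_quality", hwe_fail = "hwe",
    common_maf = "maf", clean = "PASS")
  cohort
}
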