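# Two-stage discovery/replication significance: permutation calibration of
# the joint thresholds (gamma, lambda) controlling the family-wise error
# rate FWER = Pr(V >= 1), replication selection, and Fisher's method.

#' Fisher's method for two p-values
#'
#' \eqn{X = -2(\ln p_d + \ln p_r)} referred to chi-square(4); the closed
#' form is \eqn{p = e^{-X/2}(1 + X/2)}.
#'
#' @param pd,pr p-values in (0, 1] (vectorized).
#' @return combined p-values.
#' @export
fisherCombine <- function(pd, pr) {
  if (any(is.na(pd) | is.na(pr)) || any(pd <= 0 | pr <= 0) ||
      any(pd > 1 | pr > 1))
    stop("p-values must be in (0, 1]")
  X <- -2 * (log(pd) + log(pr))
  pchisq(X, df = 4, lower.tail = FALSE)
}

#' Calibrate joint discovery/replication thresholds by permutation
#'
#' For b = 1..B the phenotype of each cohort is permuted and all gene
#' p-values recomputed in both; for each grid pair (gamma, lambda) the
#' event \{at least one gene with \eqn{P_d \le \gamma} and
#' \eqn{P_r \le \lambda}\} is recorded. The least stringent pair whose
#' event count is \eqn{\le B\alpha} is returned (ties broken toward larger
#' gamma, then larger lambda), together with the full event-count grid.
#' With \code{criterion = "total"} the admissibility count is the total
#' number of hits across replicates instead of replicates-with-any-hit.
#'
#' @param discoveryTest,replicationTest functions mapping a (permuted)
#'   \linkS4class{RVCohort} to a named vector of gene p-values; the two
#'   cohorts must share the gene universe.
#' @param discoveryCohort,replicationCohort the two cohorts.
#' @param B number of permutation replicates (default 100).
#' @param alpha target FWER (default 0.05).
#' @param gammaGrid,lambdaGrid candidate thresholds in (0, 1).
#' @param seed permutation seed.
#' @param criterion "any" (replicates with at least one hit; the empirical
#'   version of Pr(V >= 1)) or "total".
#' @return list(gamma, lambda, eventCount (at the returned pair),
#'   eventCounts (the full gamma x lambda audit grid), B, alpha).
#' @export
calibrateThresholds <- function(discoveryTest, replicationTest,
                                discoveryCohort, replicationCohort,
                                B = 100, alpha = 0.05,
                                gammaGrid = c(1e-3, 5e-4, 1e-4, 5e-5),
                                lambdaGrid = c(0.05, 0.01),
                                seed = 1L, criterion = c("any", "total")) {
  criterion <- match.arg(criterion)
  stopifnot(B >= 1, alpha > 0, alpha < 1, length(gammaGrid) >= 1,
            length(lambdaGrid) >= 1)
  gammaGrid <- sort(gammaGrid, decreasing = TRUE)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  counts <- matrix(0L, length(gammaGrid), length(lambdaGrid),
                   dimnames = list(gamma = format(gammaGrid, trim = TRUE),
                                   lambda = format(lambdaGrid, trim = TRUE)))
  for (b in seq_len(B)) {
    pd <- discoveryTest(permutePhenotype(discoveryCohort,
                                         seed = .substreamSeed(seed, paste0("d", b))))
    pr <- replicationTest(permutePhenotype(replicationCohort,
                                           seed = .substreamSeed(seed, paste0("r", b))))
    shared <- intersect(names(pd), names(pr))
    if (!length(shared)) stop("cohorts share no genes")
    pd <- pd[shared]; pr <- pr[shared]
    for (i in seq_along(gammaGrid)) for (j in seq_along(lambdaGrid)) {
      v <- sum(pd <= gammaGrid[i] & pr <= lambdaGrid[j], na.rm = TRUE)
      counts[i, j] <- counts[i, j] +
        if (criterion == "any") as.integer(v >= 1) else v
    }
  }
  admissible <- counts <= B * alpha
  if (!any(admissible))
    stop("no grid pair satisfies the FWER constraint; best achieved count ",
         min(counts), " over B = ", B, " (bound ", B * alpha, ")")
  # least stringent admissible pair: largest gamma first, then largest lambda
  idx <- which(admissible, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pick <- idx[1, ]
  list(gamma = gammaGrid[pick[1]], lambda = lambdaGrid[pick[2]],
       eventCount = counts[pick[1], pick[2]], eventCounts = counts,
       B = B, alpha = alpha)
}

#' Two-stage replication selection with Fisher combination
#'
#' Genes with discovery p \eqn{\le \gamma} enter the replication set; those
#' additionally with replication p \eqn{\le \lambda} are flagged
#' replicated. Fisher-combined p-values are computed for every gene in the
#' replication set; genes untestable in replication carry NA.
#'
#' @param discovery,replication data.frames with columns \code{gene} and
#'   \code{p} (use \code{\link{genomeScan}} output).
#' @param gamma,lambda thresholds in (0, 1).
#' @return data.frame: gene, Pd, Pr, replicated, combined_p; attribute
#'   \code{V} is the replicated-gene count.
#' @export
twoStageSelect <- function(discovery, replication, gamma = 5e-4,
                           lambda = 0.05) {
  stopifnot(gamma > 0, gamma < 1, lambda >= 0, lambda < 1)
  sel <- discovery[!is.na(discovery$p) & discovery$p <= gamma, ]
  pr <- replication$p[match(sel$gene, replication$gene)]
  replicated <- !is.na(pr) & pr <= lambda
  combined <- rep(NA_real_, nrow(sel))
  ok <- !is.na(pr)
  if (any(ok)) combined[ok] <- fisherCombine(sel$p[ok], pr[ok])
  out <- data.frame(gene = sel$gene, Pd = sel$p, Pr = pr,
                    replicated = replicated, combined_p = combined,
                    stringsAsFactors = FALSE)
  out <- out[order(out$Pd), ]
  rownames(out) <- NULL
  attr(out, "V") <- sum(replicated)
  out
}
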