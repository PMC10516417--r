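# Vectorized unadjusted BF_KS gene scans.
#
# Permutation calibration re-tests every gene hundreds of times, so the
# unadjusted path is vectorized: score statistics for all variants come
# from one cross-product against the centered phenotype, and the burden
# likelihood-ratio statistics for all genes are fitted simultaneously by
# damped Newton iterations on the two-parameter (intercept + burden)
# logistic models. Results agree with genomeScan() to numerical precision;
# a test asserts it.

# 2 log LR for y ~ 1 + b, all burden columns at once
.burdenLrtVec <- function(Bm, y, maxit = 40, tol = 1e-10) {
  n <- length(y)
  nG <- ncol(Bm)
  mu0 <- mean(y)
  devNull <- -2 * (sum(y) * log(mu0) + (n - sum(y)) * log(1 - mu0))
  b0 <- rep(log(mu0 / (1 - mu0)), nG)
  b1 <- numeric(nG)
  active <- which(matrixStats_colVars(Bm) > 0)
  for (it in seq_len(maxit)) {
    if (!length(active)) break
    Ba <- Bm[, active, drop = FALSE]
    eta <- sweep(Ba * rep(b1[active], each = n), 2, b0[active], `+`)
    mu <- 1 / (1 + exp(-eta))
    res <- y - mu
    w <- mu * (1 - mu)
    g0 <- colSums(res)
    g1 <- colSums(Ba * res)
    I00 <- colSums(w)
    I01 <- colSums(Ba * w)
    I11 <- colSums(Ba * Ba * w)
    det <- pmax(I00 * I11 - I01^2, 1e-300)
    d0 <- (I11 * g0 - I01 * g1) / det
    d1 <- (I00 * g1 - I01 * g0) / det
    # dampen occasional large steps (burdens are sparse counts)
    sc <- pmax(1, pmax(abs(d0), abs(d1)) / 5)
    b0[active] <- b0[active] + d0 / sc
    b1[active] <- b1[active] + d1 / sc
    conv <- pmax(abs(g0), abs(g1)) < tol
    active <- active[!conv]
  }
  eta <- sweep(Bm * rep(b1, each = n), 2, b0, `+`)
  dev <- -2 * colSums(y * eta - log1p(exp(eta)))
  lr <- devNull - dev
  lr[matrixStats_colVars(Bm) == 0] <- 0
  pmax(lr, 0)
}

matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - colSums(x)^2 / n) / (n - 1)
}

# ---- exact conditional KS prior ------------------------------------------
#
# Per-variant p-values of rare variants are discrete (a site with k minor
# alleles admits only k+1 case/control splits), so the Birnbaum-Tingey
# distribution of D+ — derived for continuous uniforms — is miscalibrated
# as a prior: -2 log p_KS is then not chi-square(2) and the gene statistic
# drifts off chi-square(3). The exact prior instead (i) scores each variant
# by the mid-p of its hypergeometric case-allele count, and (ii) refers the
# gene's D+ to a Monte-Carlo sample of its own conditional null, generated
# once per gene from the allele counts (which phenotype permutation leaves
# unchanged) under a fixed internal stream. The prior p-value is then
# uniform to Monte-Carlo resolution by construction.

.dplus <- function(p) {
  m <- length(p)
  max(seq_len(m) / m - sort(p))
}

.midpTable <- function(pr) {
  midp <- vapply(seq_along(pr), function(i)
    sum(pr[pr < pr[i] * (1 - 1e-9)]) +
      0.5 * sum(pr[abs(pr - pr[i]) <= pr[i] * 1e-9]), 0)
  pmin(pmax(midp, 1e-300), 1)
}

.ksExactSetup <- function(counts, nCaseAlleles, nControlAlleles, B = 2000L,
                          seed = 20240601L) {
  atoms <- lapply(counts, function(k) {
    pr <- dhyper(0:k, nCaseAlleles, nControlAlleles, k)
    list(pr = pr, midp = .midpTable(pr))
  })
  m <- length(counts)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  P <- matrix(0, m, B)
  for (j in seq_len(m)) {
    x <- sample.int(length(atoms[[j]]$pr), B, replace = TRUE,
                    prob = atoms[[j]]$pr)
    P[j, ] <- atoms[[j]]$midp[x]
  }
  nullD <- sort(apply(P, 2, .dplus))
  list(atoms = atoms, nullD = nullD, B = B)
}

.ksExactP <- function(setup, xObs) {
  pobs <- vapply(seq_along(xObs),
                 function(j) setup$atoms[[j]]$midp[xObs[j] + 1L], 0)
  d <- .dplus(pobs)
  nd <- setup$nullD
  gt <- setup$B - findInterval(d + 1e-12, nd)
  eq <- findInterval(d + 1e-12, nd) - findInterval(d - 1e-12, nd)
  (gt + 0.5 * eq + 0.5) / (setup$B + 1)
}

#' Build a fast gene-level test function for permutation analysis
#'
#' Precomputes per-gene structures of a cohort and returns a closure that
#' maps a (possibly phenotype-permuted) copy of the same cohort to the
#' named vector of unadjusted BF_KS gene p-values. Intended as the
#' \code{discoveryTest}/\code{replicationTest} argument of
#' \code{\link{calibrateThresholds}}, where the same genes are re-tested
#' for every permutation replicate.
#'
#' With complete integer dosages the KS prior is computed against its exact
#' conditional null (see the notes above); with missingness it falls back
#' to score-test p-values referred to the Birnbaum-Tingey distribution.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param geneMap output of \code{\link{assignVariantsToGenes}}.
#' @param priorB Monte-Carlo size of the per-gene exact prior null.
#' @return function(cohort) -> named vector of gene p-values.
#' @export
geneTestFactory <- function(cohort, geneMap, priorB = 2000L) {
  members <- if (!is.null(geneMap$members)) geneMap$members else geneMap
  D <- t(dosages(cohort))                       # samples x variants
  exact <- !anyNA(D) && all(D == round(D))
  if (!exact) {
    mns <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D))
    D[idx] <- mns[(idx - 1L) %/% nrow(D) + 1L]
  }
  n <- nrow(D)
  cs <- colSums(D)
  cs2 <- colSums(D^2)
  Bm <- vapply(members, function(ix)
    rowSums(D[, ix, drop = FALSE]), numeric(n))
  genes <- names(members)
  y0 <- phenotype(cohort)
  n1 <- sum(y0 == 1)
  setups <- NULL
  fold <- NULL
  if (exact) {
    alt <- cs
    fold <- alt > n                 # minor allele is REF at these sites
    counts <- ifelse(fold, 2 * n - alt, alt)
    setups <- lapply(members, function(ix)
      .ksExactSetup(counts[ix], 2 * n1, 2 * (n - n1), B = priorB,
                    seed = .substreamSeed(20240601L,
                                          paste(counts[ix],
                                                collapse = ","))))
  }
  function(cohortPerm) {
    y <- phenotype(cohortPerm)
    lr <- .burdenLrtVec(Bm, y)
    if (exact) {
      u <- drop(crossprod(D, y))
      xObs <- ifelse(fold, 2 * sum(y) - u, u)
      pks <- vapply(seq_along(members), function(g)
        .ksExactP(setups[[g]], xObs[members[[g]]]), 0)
    } else {
      mu <- mean(y)
      U <- drop(crossprod(D, y - mu))
      V <- mu * (1 - mu) * (cs2 - cs^2 / n)
      pv <- ifelse(V > 1e-12, pchisq(U^2 / V, 1, lower.tail = FALSE), 1)
      pks <- vapply(members, function(ix) ksPriorPvalue(pv[ix]), 0)
    }
    setNames(pchisq(lr - 2 * log(pks), df = 3, lower.tail = FALSE), genes)
  }
}
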