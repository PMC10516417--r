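# Gene-level Bayes-factor association tests.
#
# The statistic combines burden evidence with an informative prior p-value:
#   T = 2 log BF = 2 log BF0 - 2 log p_prior,
# where 2 log BF0 is the likelihood-ratio statistic for adding the
# per-sample rare-allele burden to the null logistic model (chi-square(1)
# under the null) and p_prior is either a one-sided Kolmogorov-Smirnov
# p-value over the gene's single-variant p-values or a SKAT
# variance-component p-value (each approximately Uniform(0,1) under the
# null, so -2 log p_prior is chi-square(2)). T is referred to the upper
# tail of chi-square(3). The burden backend is isolated so an alternative
# Bayes-factor algebra can replace it without touching callers.

#' One-sided Kolmogorov-Smirnov prior p-value
#'
#' Tests the within-gene single-variant p-values against Uniform(0,1),
#' oriented to detect an excess of small p-values (the \eqn{D^+}
#' statistic). The exact Birnbaum-Tingey distribution is used for
#' \eqn{n \le} \code{exactMax}, the asymptotic tail
#' \eqn{e^{-2 n d^2}} beyond.
#'
#' @param p vector of p-values in (0, 1].
#' @param twoSided use the two-sided D statistic instead.
#' @param exactMax largest n for which the exact distribution is used.
#' @return the KS prior p-value.
#' @export
ksPriorPvalue <- function(p, twoSided = FALSE, exactMax = 50) {
  if (!length(p)) stop("need at least one p-value")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must be in (0, 1]")
  n <- length(p)
  ps <- sort(p)
  dPlus <- max(seq_len(n) / n - ps)
  if (!twoSided) return(.ksOneSidedTail(dPlus, n, exactMax))
  dMinus <- max(ps - (seq_len(n) - 1) / n)
  d <- max(dPlus, dMinus)
  if (n <= exactMax) {
    # two-sided exact via the one-sample KS CDF
    1 - .ksTwoSidedCdf(d, n)
  } else {
    min(1, 2 * exp(-2 * n * d^2))
  }
}

# P(D+ >= d): Birnbaum-Tingey closed form (exact), else asymptotic
.ksOneSidedTail <- function(d, n, exactMax = 50) {
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  if (n <= exactMax) {
    j <- 0:floor(n * (1 - d))
    lt <- lchoose(n, j) + (j - 1) * log(d + j / n) +
      (n - j) * log1p(-(d + j / n))
    min(1, d * sum(exp(lt)))
  } else {
    exp(-2 * n * d^2)
  }
}

# Marsaglia-Tsang-Wang style evaluation via the recursion-free
# Durbin matrix method (adequate for the small n used here)
.ksTwoSidedCdf <- function(d, n) {
  # P(D_n < d) by Durbin's matrix power method
  k <- ceiling(n * d)
  h <- k - n * d
  m <- 2 * k - 1
  H <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) if (i - j + 1 >= 0) H[i, j] <- 1
  for (i in 1:m) {
    H[i, 1] <- H[i, 1] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1)
  }
  H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in 1:m) for (j in 1:m) if (i - j + 1 > 0)
    H[i, j] <- H[i, j] / factorial(i - j + 1)
  Hn <- diag(m)
  for (r in seq_len(n)) Hn <- Hn %*% H
  s <- Hn[k, k]
  for (r in seq_len(n)) s <- s * r / n
  max(0, min(1, s))
}

#' Tail probability of a weighted mixture of chi-square(1) variables
#'
#' \eqn{P(\sum_k \lambda_k \chi^2_{1,k} > q)} by Imhof's
#' characteristic-function inversion, with a Liu-type moment-matching
#' fallback (flagged via attribute \code{method}) when the numerical
#' integration does not reach the requested accuracy.
#'
#' @param lambda non-negative eigenvalues, not all zero.
#' @param q quantile (\eqn{\ge 0}).
#' @param absTol target absolute accuracy of the inversion.
#' @return the tail probability.
#' @export
chisqMixturePvalue <- function(lambda, q, absTol = 1e-6) {
  if (q < 0) stop("q must be non-negative")
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("eigenvalues must not all be zero")
  if (q == 0) return(1)
  m <- length(lambda)
  # exact whenever all eigenvalues coincide (includes the chi-square(k)
  # closed forms); also the single-eigenvalue case
  if (max(lambda) - min(lambda) < 1e-12 * max(lambda))
    return(structure(pchisq(q / lambda[1], df = m, lower.tail = FALSE),
                     method = "exact"))
  # the tail probability is invariant to a common rescaling; normalizing by
  # the largest eigenvalue keeps the oscillatory integrand well-scaled
  q <- q / max(lambda)
  lambda <- lambda / max(lambda)
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    ifelse(u == 0, 0.5 * (sum(lambda) - q), sin(theta) / (u * rho))
  }
  # finite truncation with an explicit oscillatory-tail envelope bound:
  # |integrand| <= u^{-(m/2+1)} prod(lambda)^{-1/2}, phase rate -> q/2
  tailBound <- function(U)
    4 * U^(-(m / 2 + 1)) / (prod(lambda)^0.5 * pi * q)
  U <- 2000
  while (tailBound(U) > absTol / 2 && U < 1e7) U <- U * 10
  res <- try(integrate(imhof, 0, U, rel.tol = 1e-12, abs.tol = absTol / 10,
                       subdivisions = 50000L, stop.on.error = FALSE),
             silent = TRUE)
  pLiu <- .liuPvalue(lambda, q)
  if (inherits(res, "try-error") || res$message != "OK" ||
      res$abs.error + tailBound(U) > absTol) {
    return(structure(pLiu, method = "liu"))
  }
  p <- 0.5 + res$value / pi
  structure(max(min(p, 1), 0), method = "imhof")
}

# Liu-Tang-Zhang moment-matched non-central chi-square approximation
.liuPvalue <- function(lambda, q) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  muX <- l + delta; sigmaX <- sqrt(2) * a
  pchisq((q - muQ) / sigmaQ * sigmaX + muX, df = l, ncp = delta,
         lower.tail = FALSE)
}

#' Beta-density MAF weights for SKAT
#'
#' @param maf per-variant minor allele frequencies.
#' @param a,b Beta shape parameters (field-standard 1 and 25).
#' @return weight vector \eqn{w_j = \mathrm{Beta}(maf_j; a, b)}.
#' @export
betaMafWeights <- function(maf, a = 1, b = 25) dbeta(pmin(maf, 0.5), a, b)

#' SKAT variance-component p-value for a gene
#'
#' Score statistic \eqn{Q = (y - \hat y)' G W G' (y - \hat y)} with
#' \eqn{\hat y} from the covariates-only logistic fit and
#' \eqn{W = \mathrm{diag}(w_j^2)}; the p-value is the tail of the implied
#' mixture of chi-square(1) variables at Q
#' (\code{\link{chisqMixturePvalue}}).
#'
#' In large cohorts the mixture-of-chi-squares tail is evaluated by
#' characteristic-function inversion. In small cohorts that asymptotic null
#' is visibly miscalibrated for a binary trait (the score residuals take
#' two values, so the quadratic form's permutation distribution deviates
#' from the Gaussian-based mixture by far more than Monte-Carlo error), so
#' with \code{nullDist = "auto"} cohorts of at most 200 samples are
#' referred to a high-resolution residual-permutation null instead; the
#' internal resampling stream is fixed, so results stay deterministic.
#'
#' @param G dosage matrix, samples x variants (missing mean-imputed).
#' @param y binary response.
#' @param X covariate design with intercept; NULL = intercept only.
#' @param weights per-variant weights; default Beta(MAF; 1, 25) at the
#'   sample MAF.
#' @param nullDist "auto" (resampling when n <= 200, asymptotic otherwise),
#'   "asymptotic" or "resampling".
#' @param B resampling replicates for the small-sample null.
#' @return the SKAT p-value.
#' @export
skatPvalue <- function(G, y, X = NULL, weights = NULL,
                       nullDist = c("auto", "asymptotic", "resampling"),
                       B = 200000L) {
  nullDist <- match.arg(nullDist)
  n <- length(y)
  G <- as.matrix(G)
  if (anyNA(G)) {
    mns <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    G[idx] <- mns[(idx - 1L) %/% n + 1L]
  }
  poly <- apply(G, 2, var) > 0
  if (!any(poly)) stop("gene has no polymorphic sites")
  G <- G[, poly, drop = FALSE]
  if (is.null(weights)) {
    f <- colMeans(G) / 2
    weights <- betaMafWeights(pmin(f, 1 - f))
  } else weights <- weights[poly]
  if (is.null(X)) X <- matrix(1, n, 1)
  mu <- if (ncol(X) == 1L) rep(mean(y), n)
        else glm.fit(X, y, family = binomial())$fitted.values
  r <- y - mu
  w <- mu * (1 - mu)
  Gw <- sweep(G, 2, weights, `*`)
  Q <- sum(drop(crossprod(Gw, r))^2)
  if (nullDist == "resampling" || (nullDist == "auto" && n <= 200))
    return(.skatResamplingP(Gw, r, Q, B))
  # eigenvalues of Gw' P Gw with P = V - VX(X'VX)^{-1}X'V
  VG <- Gw * w
  XtVG <- crossprod(X * w, Gw)
  A <- solve(crossprod(X * w, X))
  M <- crossprod(Gw, VG) - crossprod(XtVG, A %*% XtVG)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev))))
    stop("kernel matrix has substantially negative eigenvalues")
  ev <- ev[ev > 1e-12 * max(ev)]
  as.numeric(chisqMixturePvalue(ev, Q))
}

# residual-permutation null for small cohorts; exact (up to Monte-Carlo
# resolution) for the intercept-only model, Freedman-Lane-style with
# covariates. A fixed internal stream keeps the result deterministic
# without disturbing the caller's RNG.
.skatResamplingP <- function(Gw, r, Q, B) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(20231107L)
  n <- length(r)
  hits <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    R <- matrix(r[vapply(seq_len(nb), function(i) sample.int(n), integer(n))],
                n, nb)
    Qs <- colSums(crossprod(Gw, R)^2)
    hits <- hits + sum(Qs >= Q * (1 - 1e-12))
    done <- done + nb
  }
  structure(hits / B, method = "resampling", B = B)
}

#' Burden Bayes-factor evidence for a gene
#'
#' Default backend ("lrt"): the per-sample burden \eqn{b_i = \sum_v G_{iv}}
#' is added to the null logistic model and \eqn{2\log BF_0} is the
#' likelihood-ratio statistic (chi-square(1) under the null); covariates
#' enter both models. Alternate backend ("betabinom", no covariates): a
#' conjugate beta-binomial marginal-likelihood ratio of separate vs. common
#' minor-allele rates in cases and controls with Beta(0.5, 0.5) priors.
#'
#' @param G dosage matrix, samples x variants.
#' @param y binary response.
#' @param X covariate design with intercept; NULL = intercept only.
#' @param backend "lrt" or "betabinom".
#' @return \code{2 log BF0}; attribute \code{degenerate} when the burden is
#'   constant.
#' @export
burdenBF <- function(G, y, X = NULL, backend = c("lrt", "betabinom")) {
  backend <- match.arg(backend)
  G <- as.matrix(G)
  if (anyNA(G)) {
    n <- length(y)
    mns <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    G[idx] <- mns[(idx - 1L) %/% n + 1L]
  }
  b <- rowSums(G)
  if (var(b) == 0) return(structure(0, degenerate = TRUE))
  if (backend == "betabinom") {
    if (!is.null(X) && ncol(X) > 1)
      stop("the beta-binomial backend does not support covariates")
    k1 <- sum(G[y == 1, ]); n1 <- 2 * sum(y == 1) * ncol(G)
    k0 <- sum(G[y == 0, ]); n0 <- 2 * sum(y == 0) * ncol(G)
    lbf <- lbeta(k1 + 0.5, n1 - k1 + 0.5) + lbeta(k0 + 0.5, n0 - k0 + 0.5) +
      lbeta(0.5, 0.5) - lbeta(0.5, 0.5) - lbeta(0.5, 0.5) -
      lbeta(k1 + k0 + 0.5, n1 + n0 - k1 - k0 + 0.5)
    return(2 * lbf)
  }
  if (is.null(X)) X <- matrix(1, length(y), 1)
  null <- glm.fit(X, y, family = binomial())
  full <- glm.fit(cbind(X, b), y, family = binomial())
  max(0, null$deviance - full$deviance)
}

#' Gene-level Bayes-factor test
#'
#' \eqn{T = 2\log BF_0 - 2\log p_{prior}} referred to the upper tail of
#' chi-square(3). The prior is the one-sided KS p-value over the gene's
#' single-variant score-test p-values (covariate-adjusted when \code{X} is
#' given), or the SKAT p-value.
#'
#' For the KS prior on complete integer dosages without covariates, the
#' prior p-value is computed against the exact conditional null of
#' \eqn{D^+} given the gene's minor-allele counts (hypergeometric mid-p
#' per variant, fixed-stream Monte-Carlo null of size \code{priorB}); the
#' discreteness of rare-variant p-values otherwise distorts the
#' Birnbaum-Tingey reference and with it the chi-square(3) null. With
#' covariates (or \code{variantP} supplied, or missing dosages) the prior
#' falls back to score-test p-values under Birnbaum-Tingey.
#'
#' @param G dosage matrix, samples x variants.
#' @param y binary response.
#' @param X covariate design with intercept, or NULL (unadjusted).
#' @param prior "ks" or "skat".
#' @param variantP optional precomputed per-variant p-values for the KS
#'   prior (e.g. from \code{\link{scoreTestPvalues}}); forces the
#'   Birnbaum-Tingey path.
#' @param weights SKAT weights (default Beta(MAF; 1, 25)).
#' @param priorB Monte-Carlo size of the exact KS prior null.
#' @return a one-row data.frame: \code{m_sites}, \code{prior_p},
#'   \code{bf2log} (\eqn{2\log BF_0}), \code{T}, \code{p}, \code{adjusted}.
#' @export
geneBFTest <- function(G, y, X = NULL, prior = c("ks", "skat"),
                       variantP = NULL, weights = NULL, priorB = 2000L) {
  prior <- match.arg(prior)
  G <- as.matrix(G)
  if (prior == "ks") {
    exact <- is.null(variantP) && is.null(X) && !anyNA(G) &&
      all(G == round(G))
    if (exact) {
      n <- length(y)
      n1 <- sum(y == 1)
      alt <- colSums(G)
      fold <- alt > n
      counts <- ifelse(fold, 2 * n - alt, alt)
      setup <- .ksExactSetup(counts, 2 * n1, 2 * (n - n1), B = priorB,
                             seed = .substreamSeed(20240601L,
                                                   paste(counts,
                                                         collapse = ",")))
      u <- drop(crossprod(G, y))
      xObs <- ifelse(fold, 2 * n1 - u, u)
      pPrior <- .ksExactP(setup, xObs)
    } else {
      if (is.null(variantP)) variantP <- scoreTestPvalues(G, y, X)
      pPrior <- ksPriorPvalue(variantP)
    }
  } else {
    pPrior <- skatPvalue(G, y, X, weights = weights)
  }
  flag <- NA_character_
  if (pPrior <= 0) { pPrior <- .Machine$double.xmin; flag <- "prior_floored" }
  bf <- burdenBF(G, y, X)
  T <- as.numeric(bf) - 2 * log(pPrior)
  data.frame(m_sites = ncol(G), prior_p = as.numeric(pPrior),
             bf2log = as.numeric(bf), T = T,
             p = pchisq(T, df = 3, lower.tail = FALSE),
             adjusted = !is.null(X) && ncol(as.matrix(X)) > 1,
             flag = flag, stringsAsFactors = FALSE)
}

#' Genome-wide gene-based scan
#'
#' Runs \code{\link{geneBFTest}} for every analyzable gene of a cohort.
#' Per-variant score-test p-values are computed once against the shared
#' null model and reused across genes for the KS prior.
#'
#' @param cohort an \linkS4class{RVCohort} of QC-passed rare variants.
#' @param geneMap output of \code{\link{assignVariantsToGenes}} (or a named
#'   list of variant-index vectors).
#' @param prior "ks" or "skat".
#' @param covariates colData columns to adjust for, or NULL.
#' @return data.frame with one row per gene (gene, m_sites, prior_p,
#'   bf2log, T, p), sorted by p; failed genes are recorded in
#'   \code{attr(, "failures")}, genes dropped upstream by the site-count
#'   rule in \code{attr(, "dropped")}.
#' @export
genomeScan <- function(cohort, geneMap, prior = c("ks", "skat"),
                       covariates = NULL) {
  prior <- match.arg(prior)
  members <- if (!is.null(geneMap$members)) geneMap$members else geneMap
  y <- phenotype(cohort)
  X <- if (is.null(covariates)) NULL else covariateMatrix(cohort, covariates)
  D <- t(dosages(cohort))                     # samples x variants
  # adjusted scans share covariate-adjusted score tests across genes; the
  # unadjusted KS path lets geneBFTest use the exact conditional prior
  variantP <- if (prior == "ks" && !is.null(X))
    scoreTestPvalues(D, y, X) else NULL
  rows <- vector("list", length(members))
  fails <- character()
  for (i in seq_along(members)) {
    idx <- members[[i]]
    r <- try(geneBFTest(D[, idx, drop = FALSE], y, X, prior = prior,
                        variantP = variantP[idx]), silent = TRUE)
    if (inherits(r, "try-error")) {
      fails <- c(fails, names(members)[i])
    } else {
      r$gene <- names(members)[i]
      rows[[i]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), m_sites = integer(),
                      prior_p = numeric(), bf2log = numeric(), T = numeric(),
                      p = numeric())
  cols <- intersect(c("gene", "m_sites", "prior_p", "bf2log", "T", "p",
                      "adjusted", "flag"), colnames(out))
  out <- out[order(out$p), cols]
  rownames(out) <- NULL
  attr(out, "failures") <- fails
  attr(out, "dropped") <- geneMap$dropped
  out
}
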