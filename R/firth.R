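# Firth bias-reduced logistic regression.
#
# Maximizes the Jeffreys-penalized log-likelihood
#   l*(beta) = l(beta) + 0.5 * log det X'W(beta)X
# by damped Newton iterations on the modified score
#   U*_j = sum_i (y_i - mu_i + h_i (0.5 - mu_i)) x_ij,
# which keeps estimates finite under complete separation and sparse allelic
# counts. Coefficient p-values come from the penalized likelihood-ratio
# test; confidence intervals from the profile penalized likelihood (Wald
# fallback flagged when profiling fails).

.firthCore <- function(y, X, fixed = NULL, fixedValue = 0,
                       maxit = 50, tol = 1e-8) {
  k <- ncol(X)
  free <- setdiff(seq_len(k), fixed)
  beta <- numeric(k)
  beta[fixed] <- fixedValue
  penLoglik <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  }
  ll <- penLoglik(beta)
  conv <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    XtWXinv <- solve(XtWX)
    # leverages of the weighted hat matrix
    h <- rowSums((XW %*% XtWXinv) * XW)
    Ustar <- drop(crossprod(X, y - mu + h * (0.5 - mu)))[free]
    if (sqrt(sum(Ustar^2)) < tol) { conv <- TRUE; break }
    I <- XtWX[free, free, drop = FALSE]
    step <- solve(I, Ustar)
    # step-halving on the penalized likelihood
    for (half in 0:15) {
      cand <- beta
      cand[free] <- beta[free] + step / 2^half
      llNew <- penLoglik(cand)
      if (is.finite(llNew) && llNew > ll - 1e-12) break
    }
    beta <- cand
    ll <- llNew
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * w, X)
  list(beta = beta, loglik = as.numeric(penLoglik(beta)),
       vcov = solve(XtWX), converged = conv, iterations = iter,
       penLoglik = penLoglik, free = free)
}

#' Firth bias-reduced logistic regression
#'
#' @param y binary response (both classes required).
#' @param X design matrix including the intercept; must be full column rank.
#' @param ci "profile" (penalized profile likelihood, default) or "wald".
#' @param level confidence level.
#' @param testCoef indices of coefficients to test/profile (default all);
#'   others get Wald CIs and NA p-values.
#' @param maxit,tol Newton iteration controls.
#' @return a \code{FirthFit} list: \code{coef}, \code{se}, \code{ci}
#'   (matrix), \code{p} (penalized LRT per coefficient), \code{loglik},
#'   \code{converged}, \code{iterations}, \code{ciMethod}.
#' @export
firthLogistic <- function(y, X, ci = c("profile", "wald"), level = 0.95,
                          testCoef = NULL, maxit = 50, tol = 1e-8) {
  ci <- match.arg(ci)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- .firthCore(y, X, maxit = maxit, tol = tol)
  k <- ncol(X)
  if (is.null(testCoef)) testCoef <- seq_len(k)
  se <- sqrt(diag(fit$vcov))
  p <- rep(NA_real_, k)
  for (j in testCoef) {
    red <- .firthCore(y, X, fixed = j, fixedValue = 0, maxit = maxit,
                      tol = tol)
    lr <- 2 * (fit$loglik - red$loglik)
    p[j] <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  ciMat <- cbind(lower = fit$beta - z * se, upper = fit$beta + z * se)
  ciMethod <- rep("wald", k)
  if (ci == "profile") {
    target <- fit$loglik - qchisq(level, 1) / 2
    for (j in testCoef) {
      prof <- function(b) .firthCore(y, X, fixed = j, fixedValue = b,
                                     maxit = maxit, tol = tol)$loglik - target
      lims <- try({
        lo <- uniroot(prof, lower = fit$beta[j] - 10 * se[j] - 2,
                      upper = fit$beta[j], extendInt = "upX",
                      tol = 1e-6)$root
        hi <- uniroot(prof, lower = fit$beta[j],
                      upper = fit$beta[j] + 10 * se[j] + 2,
                      extendInt = "downX", tol = 1e-6)$root
        c(lo, hi)
      }, silent = TRUE)
      if (!inherits(lims, "try-error") && lims[1] < fit$beta[j] &&
          lims[2] > fit$beta[j]) {
        ciMat[j, ] <- lims
        ciMethod[j] <- "profile"
      }
    }
  }
  structure(list(coef = setNames(fit$beta, colnames(X)),
                 se = setNames(se, colnames(X)), ci = ciMat, p = p,
                 loglik = fit$loglik, converged = fit$converged,
                 iterations = fit$iterations, ciMethod = ciMethod),
            class = "FirthFit")
}

#' @export
print.FirthFit <- function(x, ...) {
  cat("Firth bias-reduced logistic fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- data.frame(coef = x$coef, se = x$se, lower = x$ci[, 1],
                    upper = x$ci[, 2], p = x$p)
  print(format(tab, digits = 4), ...)
  invisible(x)
}

#' Rao score test for adding a dosage to a null logistic model
#'
#' \eqn{U = \sum_i g_i (y_i - \hat y_i)} with the efficient information
#' (null-model fit from covariates only); p from \eqn{\chi^2(1)}. Missing
#' dosages are mean-imputed.
#'
#' @param g dosage vector.
#' @param y binary response.
#' @param X null design (covariates + intercept); NULL = intercept only.
#' @return p-value; attribute \code{degenerate} when g is constant.
#' @export
scoreTestPvalue <- function(g, y, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  p <- scoreTestPvalues(matrix(g, ncol = 1), y, X)
  if (var(g) == 0) attr(p, "degenerate") <- TRUE
  drop(p)
}

#' Vectorized score tests for many variants against one null model
#'
#' @param G dosage matrix, samples x variants (missing mean-imputed).
#' @param y binary response.
#' @param X null design matrix (intercept first); NULL = intercept only.
#' @return vector of \eqn{\chi^2(1)} p-values (1 for constant columns).
#' @export
scoreTestPvalues <- function(G, y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (anyNA(G)) {
    mns <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    G[idx] <- mns[(idx - 1L) %/% n + 1L]
  }
  if (ncol(X) == 1L) {
    mu <- rep(mean(y), n)
  } else {
    mu <- glm.fit(X, y, family = binomial())$fitted.values
  }
  w <- mu * (1 - mu)
  U <- drop(crossprod(G, y - mu))
  B <- crossprod(X * w, G)                       # k x m
  A <- solve(crossprod(X * w, X))
  quad <- colSums(B * (A %*% B))
  V <- colSums(G * (G * w)) - quad
  stat <- ifelse(V > 1e-12, U^2 / V, 0)
  ifelse(V > 1e-12, pchisq(stat, 1, lower.tail = FALSE), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, in input order. With \code{method = "storey"} the BH values
#' are scaled by a smoother-based estimate of the null proportion
#' \eqn{\pi_0}.
#'
#' @param p p-values in [0, 1].
#' @param method "bh" (default) or "storey".
#' @return q-values in input order.
#' @export
bhQvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey" && length(p) >= 20) {
    lam <- seq(0.05, 0.9, by = 0.05)
    pi0 <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
    fit <- smooth.spline(lam, pi0, df = 3)
    pi0hat <- min(1, max(predict(fit, x = max(lam))$y, 0))
    q <- pmin(1, q * pi0hat)
  }
  q
}

#' Single-variant association scan with Firth regression
#'
#' Fits a Firth logistic model (genotype + covariates) per variant, reports
#' carrier counts and minor allele frequencies by group, odds ratios with
#' confidence intervals, penalized-LRT p-values and Benjamini-Hochberg
#' q-values over all scanned variants; variants with \eqn{q \le}
#' \code{qThreshold} are flagged selected.
#'
#' @param cohort an \linkS4class{RVCohort} of QC-passed rare variants.
#' @param covariates colData columns to adjust for (NULL = unadjusted).
#' @param qThreshold FDR selection threshold (default 0.01).
#' @param ci CI method passed to \code{\link{firthLogistic}}.
#' @return data.frame: variant, carriers/MAF by group, OR, CI, p, q,
#'   selected. Per-variant failures yield NA rows and the scan continues.
#' @export
singleVariantScan <- function(cohort, covariates = c("age", "sex",
                                                     "smoking_ever",
                                                     paste0("PC", 1:5)),
                              qThreshold = 0.01, ci = "profile") {
  d <- dosages(cohort)
  if (nrow(d) == 0L)
    return(data.frame(variant = character(), carriers_case = integer(),
                      carriers_control = integer(), maf = numeric(),
                      maf_case = numeric(), maf_control = numeric(),
                      or = numeric(), or_lower = numeric(),
                      or_upper = numeric(), p = numeric(), q = numeric(),
                      selected = logical()))
  y <- phenotype(cohort)
  X <- if (is.null(covariates)) matrix(1, length(y), 1,
                                       dimnames = list(NULL, "(Intercept)"))
       else covariateMatrix(cohort, covariates)
  res <- lapply(seq_len(nrow(d)), function(i) {
    g <- d[i, ]
    out <- data.frame(variant = rownames(d)[i],
                      carriers_case = sum(g[y == 1] >= 1, na.rm = TRUE),
                      carriers_control = sum(g[y == 0] >= 1, na.rm = TRUE),
                      maf = computeMaf(g),
                      maf_case = computeMaf(g[y == 1]),
                      maf_control = computeMaf(g[y == 0]),
                      or = NA_real_, or_lower = NA_real_,
                      or_upper = NA_real_, p = NA_real_)
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    fit <- try(firthLogistic(y, cbind(X, genotype = g), ci = ci,
                             testCoef = ncol(X) + 1L),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      j <- length(fit$coef)
      out$or <- exp(fit$coef[j])
      out$or_lower <- exp(fit$ci[j, 1])
      out$or_upper <- exp(fit$ci[j, 2])
      out$p <- fit$p[j]
    }
    out
  })
  res <- do.call(rbind, res)
  ok <- !is.na(res$p)
  res$q <- NA_real_
  res$q[ok] <- bhQvalues(res$p[ok])
  res$selected <- !is.na(res$q) & res$q <= qThreshold
  rownames(res) <- NULL
  res
}
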