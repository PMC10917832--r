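# REML engine for Gaussian linear mixed models.
#
# Two routes share one surface:
#   * factor route -- every random term is a grouping factor with identity
#     covariance (trial-adjustment, entry-mean and channel models); fitted
#     with lme4.
#   * kernel route -- random terms are clone effects with a supplied
#     relationship matrix (GBLUP/MBLUP, Eq. Y = mu + U + eps with
#     U ~ N(0, K sigma2_U)); fitted by profiled eigendecomposition for a
#     single kernel and by direct restricted-likelihood maximization on the
#     log-variance scale for several kernels.

.assertFullRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

.factorFormula <- function(response, fixed, random, noIntercept) {
  fixedPart <- if (length(fixed) == 0) {
    "1"
  } else if (noIntercept) {
    paste(c("0", fixed), collapse = " + ")
  } else {
    paste(fixed, collapse = " + ")
  }
  randomPart <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  as.formula(paste(response, "~", fixedPart, "+", randomPart))
}

.fitFactorReml <- function(response, data, fixed = character(),
                           random = character(), noIntercept = FALSE,
                           startTheta = NULL, optCtrl = NULL) {
  if (length(random) == 0)
    stop("factor route needs at least one random term")
  keep <- !is.na(data[[response]])
  data <- data[keep, , drop = FALSE]
  for (term in unique(unlist(strsplit(c(fixed, random), ":", fixed = TRUE))))
    if (term %in% names(data)) data[[term]] <- factor(data[[term]])
  for (term in random) {
    lev <- interaction(data[strsplit(term, ":", fixed = TRUE)[[1]]],
                       drop = TRUE)
    if (nlevels(lev) < 2)
      stop("random term '", term, "' has fewer than 2 levels")
  }
  if (length(fixed)) {
    fml <- as.formula(paste(
      "~", paste(c(if (noIntercept) "0", fixed), collapse = " + ")))
    X <- stats::model.matrix(fml, data)
    .assertFullRank(X)
  }
  fml <- .factorFormula(response, fixed, random, noIntercept)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            optCtrl = optCtrl %||% list())
  start <- NULL
  if (!is.null(startTheta)) {
    # map a named per-term theta vector onto this model's term order
    lf <- lme4::lFormula(fml, data = data, REML = TRUE, control = ctrl)
    st <- startTheta[names(lf$reTrms$cnms)]
    if (!anyNA(st)) start <- list(theta = unname(st))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data, REML = TRUE, control = ctrl,
                 start = start))),
    error = function(e) {
      # degenerate responses (e.g. zero residual variance) can defeat the
      # default optimizer; bobyqa is slower but tolerant of the boundary
      ctrl2 <- lme4::lmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE,
                                 check.nobs.vs.nlev = "ignore",
                                 check.nobs.vs.nRE = "ignore")
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = data, REML = TRUE, control = ctrl2)))
    })
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", unlist(msgs %||% list()), fixed = TRUE))
  vc <- lme4::VarCorr(fit)
  varComp <- vapply(names(vc), function(nm) as.numeric(vc[[nm]][1, 1]), 0)
  # lme4 names grouping factors as given in the formula
  varComp <- c(varComp, residual = attr(vc, "sc")^2)
  beta <- lme4::fixef(fit)
  Vbeta <- as.matrix(vcov(fit))
  blups <- lapply(lme4::ranef(fit), function(b) setNames(b[, 1], rownames(b)))
  new("LmmFit", varComp = varComp, beta = beta, Vbeta = Vbeta,
      blups = blups, logRL = as.numeric(logLik(fit)),
      converged = converged, nobs = nrow(data),
      details = list(route = "factor", merMod = fit,
                     fixed = fixed, random = random,
                     theta = setNames(
                       lme4::getME(fit, "theta"),
                       sub("\\.\\(Intercept\\)$", "",
                           names(lme4::getME(fit, "theta"))))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.kernelValues <- function(K) {
  if (is(K, "RelationshipMatrix")) relValues(K) else as.matrix(K)
}

# Restricted log-likelihood for V = sigma2_e * (lambda * D + I) in the
# eigenbasis of a single kernel, profiled over beta and sigma2_e.
.eigenProfileLogRL <- function(loglambda, d, yt, Xt) {
  lambda <- exp(loglambda)
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (lambda * d + 1)
  A <- crossprod(Xt, w * Xt)
  b <- crossprod(Xt, w * yt)
  beta <- solve(A, b)
  rssW <- sum(w * (yt - Xt %*% beta)^2)
  sigma2e <- rssW / (n - p)
  logRL <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(sigma2e)) +
                     sum(log(lambda * d + 1)) +
                     determinant(A, logarithm = TRUE)$modulus[1])
  list(logRL = as.numeric(logRL), beta = drop(beta), sigma2e = sigma2e,
       lambda = lambda, w = w, A = A)
}

.fitKernelEigen <- function(y, K, X) {
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  opt <- optimize(function(ll) .eigenProfileLogRL(ll, d, yt, Xt)$logRL,
                  interval = c(-25, 25), maximum = TRUE, tol = 1e-10)
  best <- .eigenProfileLogRL(opt$maximum, d, yt, Xt)
  # allow the boundary sigma2_U = 0
  atZero <- .eigenProfileLogRL(-60, d, yt, Xt)
  if (atZero$logRL > best$logRL) best <- atZero
  sigma2u <- best$lambda * best$sigma2e
  if (best$lambda < 1e-12) sigma2u <- 0
  resRot <- best$w * (yt - Xt %*% best$beta)      # Lambda^-1 (y - Xb), rotated
  Py <- drop(U %*% resRot) / best$sigma2e          # V^-1 (y - X beta)
  u <- sigma2u * drop(K %*% Py)
  beta <- setNames(best$beta, colnames(X))
  Vbeta <- solve(best$A) * best$sigma2e
  new("LmmFit",
      varComp = c(u = sigma2u, residual = best$sigma2e),
      beta = beta, Vbeta = as.matrix(Vbeta),
      blups = list(u = setNames(u, names(y))),
      logRL = best$logRL, converged = TRUE, nobs = length(y),
      details = list(route = "kernel-eigen", Py = Py,
                     cloneIds = names(y), y = y))
}

.kernelNegLogRL <- function(theta, Ks, y, X) {
  n <- length(y); p <- ncol(X)
  V <- diag(exp(theta[length(theta)]), n)
  for (k in seq_along(Ks)) V <- V + exp(theta[k]) * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vinv <- chol2inv(ch)
  A <- crossprod(X, Vinv %*% X)
  beta <- solve(A, crossprod(X, Vinv %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vinv %*% r))
  0.5 * (2 * sum(log(diag(ch))) +
           determinant(A, logarithm = TRUE)$modulus[1] +
           quad + (n - p) * log(2 * pi))
}

.fitKernelDirect <- function(y, Ks, X, maxIter = 200) {
  v0 <- var(y)
  theta0 <- rep(log(v0 / (length(Ks) + 1)), length(Ks) + 1)
  opt <- optim(theta0, .kernelNegLogRL, Ks = Ks, y = y, X = X,
               method = "L-BFGS-B",
               lower = log(v0) - 30, upper = log(v0) + 10,
               control = list(maxit = maxIter, factr = 1e4))
  theta <- opt$par
  sig <- exp(theta)
  n <- length(y)
  V <- diag(sig[length(sig)], n)
  for (k in seq_along(Ks)) V <- V + sig[k] * Ks[[k]]
  Vinv <- chol2inv(chol(V))
  A <- crossprod(X, Vinv %*% X)
  beta <- drop(solve(A, crossprod(X, Vinv %*% y)))
  Py <- drop(Vinv %*% (y - X %*% beta))
  sig[sig < v0 * 1e-10] <- 0
  vcNames <- names(Ks) %||% paste0("u", seq_along(Ks))
  blups <- lapply(seq_along(Ks), function(k)
    setNames(sig[k] * drop(Ks[[k]] %*% Py), names(y)))
  names(blups) <- vcNames
  new("LmmFit",
      varComp = setNames(sig, c(vcNames, "residual")),
      beta = setNames(beta, colnames(X)), Vbeta = as.matrix(solve(A)),
      blups = blups,
      logRL = -opt$value, converged = opt$convergence == 0,
      nobs = n,
      details = list(route = "kernel-direct", Py = Py,
                     cloneIds = names(y), y = y))
}

#' Fit a Gaussian linear mixed model by REML
#'
#' One engine behind every model in the pipeline. With `kernels = NULL`
#' all random terms are grouping factors with identity covariance and the
#' model is `response ~ fixed + (1|random_1) + ...` fitted on the rows of
#' `data` with a non-missing response (listwise deletion). With `kernels`
#' supplied, `response` is a named vector with one entry per clone and the
#' model is the kernel BLUP model `y = X beta + sum_k u_k + eps`,
#' `u_k ~ N(0, K_k sigma2_k)`; a single kernel is solved by a profiled
#' eigendecomposition, several kernels by direct maximization of the
#' restricted likelihood over log-variances (the two routes agree to
#' numerical tolerance for one kernel).
#'
#' @param response column name of the response in `data` (factor route) or
#'   a named numeric vector of clone-level responses (kernel route).
#' @param data data.frame of plots (factor route only).
#' @param fixed character vector of fixed-effect terms (factor route).
#' @param random character vector of random grouping terms; interactions
#'   written as `"a:b"`.
#' @param kernels a [RelationshipMatrix-class] (or plain matrix), or a
#'   named list of them, one random clone effect per kernel.
#' @param noIntercept drop the intercept so that each level of the first
#'   fixed factor is estimated as its own mean (the clone-mean
#'   parameterization used for adjusted entry means).
#' @param method kernel route solver: "auto" (eigendecomposition when a
#'   single kernel, direct otherwise), "eigen" or "direct".
#' @param maxIter iteration cap for the direct solver.
#' @param startTheta optional named vector of per-term relative standard
#'   deviations used to warm-start the factor-route optimizer (e.g. the
#'   `details$theta` of a fit with the same random structure).
#' @param optCtrl optional list of optimizer controls for the factor
#'   route (passed to [lme4::lmerControl()]).
#' @return An [LmmFit-class] with variance components, BLUEs and their
#'   covariance, BLUPs, the log restricted likelihood and a convergence
#'   flag. Non-convergence is reported through the flag, not an error, so
#'   that cross-validation can record a missing prediction.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = gl(5, 4), y = rnorm(20) + rep(rnorm(5), each = 4))
#' fit <- fitReml("y", d, random = "g")
#' varComp(fit)
#' @export
fitReml <- function(response, data = NULL, fixed = character(),
                    random = character(), kernels = NULL,
                    noIntercept = FALSE, method = c("auto", "eigen", "direct"),
                    maxIter = 200, startTheta = NULL, optCtrl = NULL) {
  method <- match.arg(method)
  if (is.null(kernels))
    return(.fitFactorReml(response, data, fixed, random, noIntercept,
                          startTheta = startTheta, optCtrl = optCtrl))
  if (!is.list(kernels) || is(kernels, "RelationshipMatrix"))
    kernels <- list(u = kernels)
  y <- response
  if (is.null(names(y))) stop("kernel route needs a named response vector")
  y <- y[!is.na(y)]
  ids <- names(y)
  Ks <- lapply(kernels, function(K) {
    Kv <- .kernelValues(K)
    if (!all(ids %in% rownames(Kv)))
      stop("kernel does not cover all response clones")
    Kv[ids, ids, drop = FALSE]
  })
  X <- matrix(1, length(y), 1, dimnames = list(ids, "(Intercept)"))
  if (length(Ks) == 1 && method != "direct") {
    fit <- .fitKernelEigen(y, Ks[[1]], X)
    nm <- names(Ks)[1]
    names(fit@varComp)[1] <- nm
    names(fit@blups) <- nm
    fit
  } else {
    .fitKernelDirect(y, Ks, X, maxIter = maxIter)
  }
}

#' Restricted likelihood-ratio test for one random term
#'
#' Tests whether the variance of a single random term (canonically the
#' column effect of the row-column design) is significant, by comparing
#' the restricted likelihoods of the model with and without the term.
#' Because the null value lies on the boundary of the parameter space the
#' p-value comes either from a parametric bootstrap (simulate responses
#' under the reduced fit, refit both models) or from the 50:50
#' chi-square(0)/chi-square(1) mixture approximation.
#'
#' @param response,data,fixed passed to [fitReml()] (factor route).
#' @param randomFull character vector of random terms of the full model.
#' @param term the single term to test; the reduced model is
#'   `randomFull` without `term`.
#' @param nSim number of bootstrap simulations.
#' @param alpha significance level for the inclusion decision.
#' @param seed integer seed for the bootstrap.
#' @param method "bootstrap" or "mixture".
#' @return list with `statistic` (2 * logRL difference, truncated at 0),
#'   `pValue`, and `include` (`pValue < alpha`).
#' @export
rlrtColumnEffect <- function(response, data, fixed = character(),
                             randomFull, term, nSim = 1000, alpha = 0.05,
                             seed = 1,
                             method = c("bootstrap", "mixture")) {
  method <- match.arg(method)
  if (!term %in% randomFull)
    stop("'term' must be one of the full model's random terms")
  randomReduced <- setdiff(randomFull, term)
  if (length(randomReduced) != length(randomFull) - 1)
    stop("full and reduced models must differ by exactly one term")
  full <- .fitFactorReml(response, data, fixed, randomFull)
  red <- .fitFactorReml(response, data, fixed, randomReduced)
  stat <- max(0, 2 * (full@logRL - red@logRL))
  if (method == "mixture") {
    p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    redMer <- red@details$merMod
    fullMer <- full@details$merMod
    sims <- simulate(redMer, nsim = nSim, seed = seed)
    statSim <- vapply(seq_len(nSim), function(i) {
      ys <- sims[[i]]
      f2 <- tryCatch(suppressMessages(suppressWarnings(
        lme4::refit(fullMer, newresp = ys))), error = function(e) NULL)
      r2 <- tryCatch(suppressMessages(suppressWarnings(
        lme4::refit(redMer, newresp = ys))), error = function(e) NULL)
      if (is.null(f2) || is.null(r2)) return(NA_real_)
      max(0, 2 * (as.numeric(logLik(f2)) - as.numeric(logLik(r2))))
    }, 0)
    statSim <- statSim[!is.na(statSim)]
    p <- mean(statSim >= stat)
  }
  list(statistic = stat, pValue = p, include = p < alpha)
}
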