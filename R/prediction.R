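# (M/G)BLUP prediction, cross-validation, predictive ability, the
# quality filter, the scenario runner, the weight grid search and the
# flight-date subset analysis.

.aemVector <- function(aems) {
  if (is(aems, "AdjustedEntryMeans")) aemValues(aems) else aems
}

.kernelList <- function(K) {
  if (!is.list(K) || is(K, "RelationshipMatrix")) K <- list(u = K)
  lapply(K, .kernelValues)
}

#' Fit the kernel BLUP model to training entry means
#'
#' REML fit of `Y = mu + U_1 + ... + U_k + eps` with one random clone
#' effect per supplied relationship matrix (one kernel for GBLUP/MBLUP,
#' two for G+D or the two-matrix spectral+genomic alternative, five for
#' G+D+E). Delegates to the kernel route of [fitReml()].
#'
#' @param aemsTrain named numeric vector of training AEMs (or an
#'   [AdjustedEntryMeans-class]).
#' @param K a [RelationshipMatrix-class] or named list of them covering
#'   all training clones.
#' @param ... passed to [fitReml()].
#' @return An [LmmFit-class]; non-convergence is flagged, not raised.
#' @export
fitBlup <- function(aemsTrain, K, ...) {
  y <- .aemVector(aemsTrain)
  fitReml(y, kernels = K, ...)
}

#' Predict masked clones from a kernel BLUP fit
#'
#' Closed-form conditional expectation: for validation clones v and
#' training clones t,
#' `pred = mu + sum_k sigma2_k K_k[v, t] V_tt^-1 (y_t - mu)`, using the
#' variance components and residual projection of the training fit.
#'
#' @param fit an [LmmFit-class] from [fitBlup()].
#' @param K the same kernel (or list of kernels) passed to the fit, on
#'   the full clone set including the validation clones.
#' @param validationIds clone ids to predict; ids absent from a kernel
#'   yield NA.
#' @return named numeric vector of predicted AEMs.
#' @export
predictMasked <- function(fit, K, validationIds) {
  Ks <- .kernelList(K)
  train <- fit@details$cloneIds
  Py <- fit@details$Py
  mu <- unname(fit@beta[["(Intercept)"]])
  vc <- fit@varComp
  pred <- setNames(rep(mu, length(validationIds)), validationIds)
  ok <- validationIds %in% rownames(Ks[[1]])
  for (k in seq_along(Ks)) {
    nm <- names(Ks)[k]
    s2 <- if (nm %in% names(vc)) vc[[nm]] else vc[[k]]
    ids <- validationIds[ok & validationIds %in% rownames(Ks[[k]])]
    pred[ids] <- pred[ids] +
      s2 * drop(Ks[[k]][ids, train, drop = FALSE] %*% Py)
  }
  pred[!ok] <- NA_real_
  pred
}

#' Predict masked clones through Henderson's mixed-model equations
#'
#' Independent route to the same predictions: all clones (training and
#' validation) enter the mixed-model equations, validation responses are
#' masked (their data rows dropped), and the equations are solved at the
#' training fit's variance components. Kernels are inverted with a small
#' diagonal jitter when numerically singular. Used as a cross-check of
#' [predictMasked()].
#'
#' @inheritParams predictMasked
#' @return named numeric vector of predicted AEMs for the validation set.
#' @export
predictMaskedMME <- function(fit, K, validationIds) {
  Ks <- .kernelList(K)
  train <- fit@details$cloneIds
  y <- fit@details$y
  if (is.null(y)) stop("fit does not carry its training response")
  vc <- fit@varComp
  s2e <- vc[["residual"]]
  if (s2e <= 0)
    stop("residual variance is zero; the mixed-model-equation route is ",
         "undefined at the boundary")
  allIds <- unique(c(train, validationIds))
  nAll <- length(allIds)
  Zobs <- matrix(0, length(train), nAll,
                 dimnames = list(train, allIds))
  Zobs[cbind(train, train)] <- 1
  X <- matrix(1, length(train), 1)
  # kernels whose variance collapsed to (near) zero contribute no BLUP;
  # keeping them would make the equations numerically singular
  s2 <- vapply(seq_along(Ks), function(k) {
    nm <- names(Ks)[k]
    if (nm %in% names(vc)) vc[[nm]] else vc[[k]]
  }, 0)
  active <- s2 > 1e-10 * (sum(s2) + s2e)
  Ks <- Ks[active]
  s2 <- s2[active]
  nK <- length(Ks)
  blocks <- vector("list", nK)
  for (k in seq_len(nK)) {
    Kk <- Ks[[k]][allIds, allIds]
    Kinv <- tryCatch(solve(Kk), error = function(e)
      solve(Kk + diag(1e-8 * mean(diag(Kk)), nAll)))
    blocks[[k]] <- Kinv * (s2e / s2[k])
  }
  ZZ <- crossprod(Zobs)
  p <- 1
  dim <- p + nK * nAll
  Cmat <- matrix(0, dim, dim)
  rhs <- numeric(dim)
  Cmat[1, 1] <- crossprod(X)
  rhs[1] <- sum(y)
  for (k in seq_len(nK)) {
    rows <- p + (k - 1) * nAll + seq_len(nAll)
    Cmat[1, rows] <- crossprod(X, Zobs)
    Cmat[rows, 1] <- t(crossprod(X, Zobs))
    rhs[rows] <- crossprod(Zobs, y)
    for (l in seq_len(nK)) {
      cols <- p + (l - 1) * nAll + seq_len(nAll)
      Cmat[rows, cols] <- ZZ
    }
    Cmat[rows, rows] <- Cmat[rows, rows] + blocks[[k]]
  }
  sol <- solve(Cmat, rhs)
  mu <- sol[1]
  pred <- setNames(rep(mu, length(validationIds)), validationIds)
  for (k in seq_len(nK)) {
    uk <- sol[p + (k - 1) * nAll + seq_len(nAll)]
    names(uk) <- allIds
    pred <- pred + uk[validationIds]
  }
  pred
}

#' Predictive ability: Pearson correlation of observed and predicted AEMs
#'
#' @param observed,predicted paired numeric vectors; pairs with a missing
#'   value on either side are dropped.
#' @return Pearson r, or NA when fewer than 3 complete pairs remain or
#'   either side has zero variance.
#' @export
pearsonPA <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  if (sum(ok) < 3) return(NA_real_)
  o <- observed[ok]; p <- predicted[ok]
  if (sd(o) == 0 || sd(p) == 0) return(NA_real_)
  cor(o, p)
}

.foldAssignments <- function(clones, nFolds, nReps, seed) {
  set.seed(seed)
  lapply(seq_len(nReps), function(r) {
    idx <- sample(length(clones))
    fold <- rep(seq_len(nFolds), length.out = length(clones))
    split(clones[idx], fold)
  })
}

.newPredictionResult <- function(pa, scenario, seed,
                                 cvMax = 150, missingMax = 100) {
  obs <- pa[!is.na(pa)]
  med <- if (length(obs)) median(obs) else NA_real_
  mn <- if (length(obs)) mean(obs) else NA_real_
  cv <- if (length(obs) >= 2 && !is.na(mn) && mn != 0)
    100 * sd(obs) / mn else NA_real_
  nMiss <- sum(is.na(pa))
  failCv <- is.na(cv) || abs(cv) > cvMax  # undefined CV fails the rule
  pass <- !(failCv || nMiss > missingMax)
  new("PredictionResult", pa = pa, medianPA = med, meanPA = mn,
      cv = cv, nMissing = nMiss, passedFilter = pass,
      scenario = scenario, seed = seed)
}

#' Fivefold cross-validated kernel BLUP prediction
#'
#' Per replicate, the clones with an AEM are partitioned uniformly at
#' random into `nFolds` folds (sizes differing by at most one); each fold
#' is predicted from a model trained on the remaining folds and scored by
#' the Pearson correlation between its observed and predicted AEMs. Five
#' folds and 25 replicates give the canonical 125 predictive-ability
#' slots per trait and scenario. Folds whose model fails or does not
#' converge are recorded as missing, feeding the quality filter.
#'
#' @param aems named numeric vector of AEMs (or an
#'   [AdjustedEntryMeans-class]).
#' @param kernels a [RelationshipMatrix-class] or named list of them.
#' @param nFolds,nReps cross-validation geometry (defaults 5 and 25).
#' @param seed integer; fully determines the fold assignments.
#' @param scenario optional label or [ScenarioSpec-class] stored in the
#'   result.
#' @return A [PredictionResult-class] with `nFolds * nReps` PA slots.
#' @export
crossValidate <- function(aems, kernels, nFolds = 5, nReps = 25, seed = 1,
                          scenario = NULL) {
  y <- .aemVector(aems)
  y <- y[!is.na(y)]
  Ks <- .kernelList(kernels)
  covered <- Reduce(intersect, lapply(Ks, rownames))
  y <- y[names(y) %in% covered]
  if (length(y) < nFolds) stop("fewer clones with AEMs than folds")
  folds <- .foldAssignments(names(y), nFolds, nReps, seed)
  pa <- rep(NA_real_, nFolds * nReps)
  i <- 0
  for (r in seq_len(nReps)) {
    for (f in seq_len(nFolds)) {
      i <- i + 1
      val <- folds[[r]][[f]]
      trainY <- y[setdiff(names(y), val)]
      fit <- tryCatch(fitReml(trainY, kernels = Ks),
                      error = function(e) NULL)
      if (is.null(fit) || !isConverged(fit)) next
      pred <- predictMasked(fit, Ks, val)
      pa[i] <- pearsonPA(y[val], pred)
    }
  }
  .newPredictionResult(pa, scenario %||% "cv", seed)
}

#' Quality filter on a cross-validation result
#'
#' A result fails when the absolute coefficient of variation of its
#' predictive abilities exceeds `cvMax` (default 150) or when more than
#' `missingMax` (default 100) of its predictions are missing. CV is
#' computed as 100 * SD / mean over the non-missing PAs; an undefined CV
#' (mean exactly 0) fails the CV clause. Filtered results are flagged,
#' not deleted.
#'
#' @param result a [PredictionResult-class].
#' @param cvMax,missingMax the two thresholds.
#' @return the result with its `passedFilter` flag set.
#' @export
qualityFilter <- function(result, cvMax = 150, missingMax = 100) {
  .newPredictionResult(result@pa, result@scenario, result@seed,
                       cvMax = cvMax, missingMax = missingMax)
}

#' Construct a scenario specification
#'
#' @param id scenario family ("S1".."S7", "S3b").
#' @param phenoScope environment code, "across", or "loo:<env>".
#' @param kernelSource spectral environment code, "cjM", "MAEM", "G",
#'   "G+D", "G+D+E" or "C".
#' @param weight weight of M for kernelSource "C".
#' @return A [ScenarioSpec-class]; invalid combinations error.
#' @export
scenarioSpec <- function(id, phenoScope, kernelSource, weight = NA_real_) {
  sp <- new("ScenarioSpec", id = id, phenoScope = phenoScope,
            kernelSource = kernelSource, weight = weight)
  if (id == "S2" && identical(phenoScope, kernelSource))
    stop("S2 requires the phenotype environment to differ from the ",
         "spectral environment")
  if (id == "S1" && !identical(phenoScope, kernelSource))
    stop("S1 requires matching phenotype and spectral environments")
  if (id == "S3b" && !identical(phenoScope, paste0("loo:", kernelSource)))
    stop("S3b must exclude the spectral source environment from the AEMs")
  if (id %in% c("S6", "S7") && !kernelSource %in% c("G", "G+D", "G+D+E"))
    stop(id, " uses genomic kernels only")
  sp
}

#' Enumerate all valid prediction cases for a study
#'
#' S1: matched (phenotype env, spectral env) pairs; S2: mismatched pairs
#' (8 cases for 5 phenotype environments and 2 spectral environments);
#' S3/S3b: across-environment (or leave-one-out) AEMs against each
#' spectral environment; S4/S5: combined spectra (cjM, MAEM) against
#' single environments / across-environment AEMs; S6/S7: genomic kernel
#' against single environments / across-environment AEMs.
#'
#' @param phenoEnvs environment codes with phenotypes.
#' @param spectraEnvs environment codes with spectra.
#' @param ids scenario families to enumerate (default all).
#' @return data.frame (id, phenoScope, kernelSource).
#' @export
enumerateScenarios <- function(phenoEnvs, spectraEnvs,
                               ids = c("S1", "S2", "S3", "S3b", "S4",
                                       "S5", "S6", "S7")) {
  rows <- list()
  add <- function(id, scope, src)
    rows[[length(rows) + 1]] <<- data.frame(id = id, phenoScope = scope,
                                            kernelSource = src)
  if ("S1" %in% ids)
    for (e in intersect(phenoEnvs, spectraEnvs)) add("S1", e, e)
  if ("S2" %in% ids)
    for (e in phenoEnvs) for (s in spectraEnvs)
      if (e != s) add("S2", e, s)
  if ("S3" %in% ids) for (s in spectraEnvs) add("S3", "across", s)
  if ("S3b" %in% ids)
    for (s in spectraEnvs) add("S3b", paste0("loo:", s), s)
  if ("S4" %in% ids)
    for (e in phenoEnvs) for (m in c("cjM", "MAEM")) add("S4", e, m)
  if ("S5" %in% ids) for (m in c("cjM", "MAEM")) add("S5", "across", m)
  if ("S6" %in% ids) for (e in phenoEnvs) add("S6", e, "G")
  if ("S7" %in% ids) add("S7", "across", "G")
  do.call(rbind, rows)
}

#' Run one prediction case
#'
#' Assembles the phenotype scope and kernel named by the scenario from a
#' prepared data bundle and runs the cross-validation.
#'
#' @param spec a [ScenarioSpec-class] (or one row of
#'   [enumerateScenarios()] coerced with [scenarioSpec()]).
#' @param aems named list of AEM vectors keyed by scope label (an
#'   environment code, "across", or "loo:<env>").
#' @param kernels named list of [RelationshipMatrix-class] objects keyed
#'   by kernel source; for "G+D" / "G+D+E" entries, a named sub-list of
#'   kernels.
#' @param ... passed to [crossValidate()] (nFolds, nReps, seed).
#' @return A [PredictionResult-class].
#' @export
runScenario <- function(spec, aems, kernels, ...) {
  scopeKey <- spec@phenoScope
  if (!scopeKey %in% names(aems))
    stop("no AEMs prepared for scope '", scopeKey, "'")
  srcKey <- spec@kernelSource
  if (!srcKey %in% names(kernels))
    stop("no kernel prepared for source '", srcKey, "'")
  crossValidate(aems[[scopeKey]], kernels[[srcKey]], scenario = spec, ...)
}

#' Grid search over the spectral weight of the combined kernel
#'
#' For each weight x in the grid builds `C = x M + (1 - x) G` and runs
#' the cross-validation with identical fold assignments (shared seed), so
#' that PA differences across x are paired. The endpoints reproduce pure
#' GBLUP (x = 0) and pure MBLUP (x = 1) exactly.
#'
#' @param aems named AEM vector.
#' @param M,G the spectral and genomic [RelationshipMatrix-class].
#' @param grid weights in [0, 1] (default steps of 0.05).
#' @param nFolds,nReps,seed cross-validation settings.
#' @return list with `table` (data.frame x, medianPA, sdPA, nMissing),
#'   `bestX`, and `results` (the PredictionResult per x).
#' @export
weightGridSearch <- function(aems, M, G, grid = seq(0, 1, by = 0.05),
                             nFolds = 5, nReps = 25, seed = 1) {
  if (any(grid < 0 | grid > 1)) stop("grid weights must lie in [0, 1]")
  shared <- intersect(rownames(relValues(M)), rownames(relValues(G)))
  if (!length(shared)) stop("M and G share no clones")
  Ms <- relationshipMatrix(relValues(M)[shared, shared], "M")
  Gs <- relationshipMatrix(relValues(G)[shared, shared], "G")
  results <- lapply(grid, function(x) {
    C <- weightedKernel(Ms, Gs, x)
    crossValidate(aems, C, nFolds = nFolds, nReps = nReps, seed = seed,
                  scenario = sprintf("C(x=%g)", x))
  })
  tab <- data.frame(
    x = grid,
    medianPA = vapply(results, medianPA, 0),
    sdPA = vapply(results, function(r)
      sd(r@pa, na.rm = TRUE), 0),
    nMissing = vapply(results, function(r) r@nMissing, 0))
  list(table = tab, bestX = grid[which.max(tab$medianPA)],
       results = results)
}

#' Predictive ability of flight-date subsets
#'
#' Builds the spectral kernel from the channels of the selected flight
#' dates only and runs the prediction with common folds per subset, to
#' rank the contribution of each acquisition time point.
#'
#' @param S clone-level [SpectraMatrix-class] whose `colMeta$date` tags
#'   every column with its flight date.
#' @param aems named AEM vector to predict.
#' @param subsets list of character vectors of flight dates (default: all
#'   non-empty subsets of the observed dates).
#' @param nFolds,nReps,seed cross-validation settings.
#' @return data.frame (subset, mS, medianPA).
#' @export
flightDateSubsets <- function(S, aems, subsets = NULL, nFolds = 5,
                              nReps = 25, seed = 1) {
  meta <- spectraMeta(S)
  dates <- sort(unique(meta$date))
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(dates), function(k)
      combn(dates, k, simplify = FALSE)), recursive = FALSE)
  }
  rows <- lapply(subsets, function(ss) {
    if (length(ss) == 0) stop("empty flight-date subset")
    keep <- meta$date %in% ss
    Ssub <- spectraMatrix(spectraValues(S)[, keep, drop = FALSE],
                          meta[keep, , drop = FALSE])
    K <- spectralKernel(Ssub)
    res <- crossValidate(aems, K, nFolds = nFolds, nReps = nReps,
                         seed = seed,
                         scenario = paste(ss, collapse = "+"))
    data.frame(subset = paste(ss, collapse = "+"), mS = sum(keep),
               medianPA = medianPA(res))
  })
  do.call(rbind, rows)
}
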