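# Trial adjustment via checks, adjusted entry means, and broad-sense
# heritability for traits and channel reflectances.

.modelTerms <- function(scope, includeColumn) {
  if (scope == "across") {
    r <- c("env", "clone:env", "env:block", "env:row")
    if (includeColumn) r <- c(r, "env:column")
  } else {
    r <- c("block", "row")
    if (includeColumn) r <- c(r, "column")
  }
  r
}

.scopeData <- function(plots, trait, scope, env) {
  d <- plots[plots$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no plots for trait '", trait, "'")
  if (scope == "single") {
    if (is.null(env)) stop("scope 'single' needs an environment")
    d <- d[d$env == env, , drop = FALSE]
  } else if (scope == "loo") {
    if (is.null(env)) stop("scope 'loo' needs the environment to exclude")
    d <- d[d$env != env, , drop = FALSE]
    if (length(unique(d$env)) < 1) stop("no environments left after exclusion")
  }
  if (scope != "single" && length(unique(d$env)) < 2)
    stop("across-environment scope needs at least 2 environments")
  d
}

#' Estimate trial effects from the replicated checks
#'
#' In environments split into two maturity-group trials the test clones
#' are confounded with trials; the replicated checks, present in every
#' block of both trials, identify the trial contrast. Fits, per trait and
#' environment, the check-plot model
#' `value ~ trial + (1|check) + (1|block) + (1|row) + (1|column)` with the
#' trial fixed and everything else random, and returns the fixed trial
#' contrasts relative to the first trial.
#'
#' @param plots canonical long plot table (clone, env, trial, block, row,
#'   column, trait, value).
#' @param trait,env optional filters; default all traits / all
#'   environments with more than one trial.
#' @param checks character vector of check clone ids; by default clones
#'   replicated in more than one block of an environment.
#' @return data.frame (trait, env, trial, effect); single-trial
#'   environments get effect 0.
#' @export
estimateTrialEffects <- function(plots, trait = NULL, env = NULL,
                                 checks = NULL) {
  traits <- if (is.null(trait)) unique(plots$trait) else trait
  envs <- if (is.null(env)) unique(plots$env) else env
  out <- list()
  for (tr in traits) {
    for (e in envs) {
      d <- plots[plots$trait == tr & plots$env == e, , drop = FALSE]
      trials <- sort(unique(d$trial))
      if (length(trials) < 2) {
        out[[paste(tr, e)]] <- data.frame(trait = tr, env = e,
                                          trial = trials,
                                          effect = 0)
        next
      }
      chk <- checks
      if (is.null(chk)) {
        tab <- table(d$clone)
        chk <- names(tab)[tab > 1]
      }
      dc <- d[d$clone %in% chk, , drop = FALSE]
      for (m in trials)
        if (!any(dc$trial == m))
          stop("trial ", m, " of ", e, " has no check plots")
      fit <- fitReml("value", dc, fixed = "trial",
                     random = c("clone", "block", "row", "column"))
      beta <- fixedEffects(fit)
      eff <- setNames(rep(0, length(trials)), trials)
      for (m in trials[-1]) {
        nm <- paste0("trial", m)
        if (nm %in% names(beta)) eff[as.character(m)] <- beta[[nm]]
      }
      out[[paste(tr, e)]] <- data.frame(trait = tr, env = e,
                                        trial = trials,
                                        effect = unname(eff))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subtract estimated trial effects from the plot values
#'
#' Applied to all traits regardless of the significance of the trial
#' contrast.
#'
#' @param plots canonical long plot table.
#' @param trialEffects data.frame from [estimateTrialEffects()].
#' @return plot table with adjusted values.
#' @export
adjustForTrial <- function(plots, trialEffects) {
  key <- paste(plots$trait, plots$env, plots$trial)
  effKey <- paste(trialEffects$trait, trialEffects$env, trialEffects$trial)
  idx <- match(key, effKey)
  eff <- trialEffects$effect[idx]
  eff[is.na(eff)] <- 0
  plots$value <- plots$value - eff
  plots
}

# Mean variance of a difference between entry means from the BLUE
# covariance: average over all clone pairs of C_ii + C_jj - 2 C_ij.
.vbar <- function(C) {
  g <- nrow(C)
  if (g < 2) stop("need at least 2 clones for a difference variance")
  2 * (g * sum(diag(C)) - sum(C)) / (g * (g - 1))
}

#' Adjusted entry means per clone
#'
#' Fits the entry-mean mixed model with the clone as a fixed effect in the
#' clone-mean parameterization (no intercept), so the fixed estimates are
#' the adjusted entry means directly and their covariance feeds the mean
#' variance of a difference in the heritability formula. Scope "across"
#' uses environment, clone-by-environment and the design factors nested in
#' environment as random terms; scope "single" restricts to one
#' environment and drops the environment terms; scope "loo" leaves one
#' environment out (for predictions whose spectra come from the excluded
#' environment).
#'
#' Plots with an absolute studentized residual above `outlierZ` in a first
#' fit are dropped and the model refit once (a deterministic stand-in for
#' manual inspection of residual diagnostics). Traits flagged for
#' square-root transformation are transformed before modelling and
#' reported on the transformed scale.
#'
#' @param plots canonical long plot table (trial effects already
#'   subtracted).
#' @param trait trait (or channel-date) id to model.
#' @param scope "across", "single" or "loo".
#' @param env environment for scopes "single"/"loo".
#' @param includeColumn logical, or "auto" to decide by the restricted
#'   likelihood-ratio test on the column variance (chi-square-mixture
#'   p-value, alpha 0.05).
#' @param sqrtTransform transform the response by square root first.
#' @param outlierZ studentized-residual threshold for the one-pass
#'   outlier drop (default 4; Inf disables).
#' @param withCovariance keep the clone BLUE covariance (needed for
#'   heritability; can be switched off when only the means are used).
#' @param warmStart optional [LmmFit-class] with the clone random (from
#'   [fitCloneRandom()]) whose variance components warm-start the
#'   clone-fixed optimizer. For populations of 150 clones or more a
#'   warm-start fit is run automatically and the optimizer uses a mildly
#'   relaxed stopping tolerance; both shortcuts change the entry means
#'   well below any scientifically relevant digit and can be disabled
#'   with `fast = FALSE`.
#' @param fast allow the warm-start/relaxed-tolerance shortcut at scale.
#' @return An [AdjustedEntryMeans-class].
#' @export
computeAems <- function(plots, trait, scope = c("across", "single", "loo"),
                        env = NULL, includeColumn = TRUE,
                        sqrtTransform = FALSE, outlierZ = 4,
                        withCovariance = TRUE, warmStart = NULL,
                        fast = TRUE) {
  scope <- match.arg(scope)
  d <- .scopeData(plots, trait, scope, env)
  if (sqrtTransform) {
    if (any(d$value < 0, na.rm = TRUE))
      stop("square-root transform needs non-negative values")
    d$value <- sqrt(d$value)
  }
  if (identical(includeColumn, "auto")) {
    full <- .modelTerms(scope, TRUE)
    colTerm <- if (scope == "across") "env:column" else "column"
    rl <- rlrtColumnEffect("value", d, fixed = character(),
                           randomFull = c("clone", setdiff(full, "clone")),
                           term = colTerm, method = "mixture")
    includeColumn <- rl$include
  }
  random <- .modelTerms(scope, includeColumn)
  startTheta <- NULL
  optCtrl <- NULL
  big <- length(unique(d$clone)) >= 150
  if (fast && big) {
    if (is.null(warmStart))
      warmStart <- fitReml("value", d, fixed = character(),
                           random = c("clone", random),
                           optCtrl = list(xtol_abs = 1e-4,
                                          ftol_abs = 1e-5))
    startTheta <- warmStart@details$theta
    optCtrl <- list(xtol_abs = 2e-3, ftol_abs = 5e-4)
  }
  fit <- fitReml("value", d, fixed = "clone", random = random,
                 noIntercept = TRUE, startTheta = startTheta,
                 optCtrl = optCtrl)
  if (is.finite(outlierZ)) {
    mer <- fit@details$merMod
    rs <- stats::residuals(mer) / stats::sigma(mer)
    if (any(abs(rs) > outlierZ)) {
      used <- !is.na(d$value)
      keep <- rep(TRUE, nrow(d))
      keep[which(used)[abs(rs) > outlierZ]] <- FALSE
      fit <- fitReml("value", d[keep, , drop = FALSE], fixed = "clone",
                     random = random, noIntercept = TRUE,
                     startTheta = startTheta, optCtrl = optCtrl)
    }
  }
  beta <- fixedEffects(fit)
  names(beta) <- sub("^clone", "", names(beta))
  V <- if (withCovariance) fit@Vbeta else
    matrix(NA_real_, length(beta), length(beta))
  dimnames(V) <- list(names(beta), names(beta))
  scopeLabel <- switch(scope, across = "across",
                       single = paste0("single:", env),
                       loo = paste0("loo:", env))
  new("AdjustedEntryMeans", values = beta, Vblue = V,
      response = trait, scope = scopeLabel)
}

#' Refit the entry-mean model with the clone as a random effect
#'
#' Provides the genotypic variance sigma2g for the heritability formula
#' (the clone term of the entry-mean model set random).
#'
#' @inheritParams computeAems
#' @param optCtrl optional optimizer controls passed to the engine.
#' @return An [LmmFit-class] whose `"clone"` variance component is
#'   sigma2g.
#' @export
fitCloneRandom <- function(plots, trait, scope = c("across", "single", "loo"),
                           env = NULL, includeColumn = TRUE,
                           sqrtTransform = FALSE, optCtrl = NULL) {
  scope <- match.arg(scope)
  d <- .scopeData(plots, trait, scope, env)
  if (sqrtTransform) d$value <- sqrt(d$value)
  random <- c("clone", .modelTerms(scope, includeColumn))
  fitReml("value", d, fixed = character(), random = random,
          optCtrl = optCtrl)
}

#' Broad-sense heritability (Piepho-Moehring)
#'
#' Entry-mean basis: `H2 = sigma2g / (sigma2g + vbar/2)` where `vbar` is
#' the mean over all clone pairs of the variance of a difference between
#' adjusted entry means, computed exactly from the BLUE covariance. Plot
#' basis: sigma2g over the sum of all variance components.
#'
#' @param fitRandomClone an [LmmFit-class] from [fitCloneRandom()].
#' @param aems the matching [AdjustedEntryMeans-class] (entry-mean basis).
#' @param basis "entry-mean" or "plot".
#' @return A [HeritabilityEstimate-class].
#' @examples
#' # sigma2g = 3, vbar = 2  =>  H2 = 3/4 by the formula
#' @export
heritability <- function(fitRandomClone, aems = NULL,
                         basis = c("entry-mean", "plot")) {
  basis <- match.arg(basis)
  vc <- varComp(fitRandomClone)
  if (!"clone" %in% names(vc)) stop("fit has no 'clone' variance component")
  s2g <- unname(vc[["clone"]])
  if (basis == "plot") {
    return(new("HeritabilityEstimate", sigma2g = s2g, vbar = NA_real_,
               H2 = s2g / sum(vc), basis = basis,
               response = if (is.null(aems)) NA_character_ else
                 aems@response))
  }
  if (is.null(aems)) stop("entry-mean basis needs the AEM object")
  C <- aemCovariance(aems)
  if (anyNA(C)) stop("AEMs were computed without their covariance")
  vbar <- .vbar(C)
  if (vbar <= 0) stop("degenerate design: vbar <= 0")
  new("HeritabilityEstimate", sigma2g = s2g, vbar = vbar,
      H2 = s2g / (s2g + vbar / 2), basis = basis,
      response = aems@response)
}

#' One-call heritability for a trait
#'
#' Convenience wrapper: adjusted entry means (clone fixed), refit with the
#' clone random, then the Piepho-Moehring formula.
#'
#' @inheritParams computeAems
#' @param basis "entry-mean" or "plot".
#' @return A [HeritabilityEstimate-class].
#' @export
traitHeritability <- function(plots, trait,
                              scope = c("across", "single", "loo"),
                              env = NULL, includeColumn = TRUE,
                              sqrtTransform = FALSE,
                              basis = c("entry-mean", "plot"),
                              outlierZ = Inf) {
  scope <- match.arg(scope)
  basis <- match.arg(basis)
  rnd <- fitCloneRandom(plots, trait, scope, env, includeColumn,
                        sqrtTransform)
  aems <- NULL
  if (basis == "entry-mean")
    aems <- computeAems(plots, trait, scope, env, includeColumn,
                        sqrtTransform, outlierZ = outlierZ,
                        warmStart = rnd)
  heritability(rnd, aems, basis)
}

.spectraAsPlots <- function(spectra) {
  d <- spectra
  d$trait <- paste(d$channel, d$flight_date, sep = ".")
  if (!"trial" %in% names(d)) d$trial <- 1
  d[, c("clone", "env", "trial", "block", "row", "column", "trait",
        "value")]
}

#' Channel-reflectance heritabilities
#'
#' Per-date mode analyzes every channel x flight-date combination with
#' the entry-mean model; across-dates mode analyzes each channel with the
#' flight date and all its interactions added as random terms
#' (clone-by-date, date-by-environment, clone-by-date-by-environment, and
#' date interactions with block, row and column), on the entry-mean or
#' plot basis.
#'
#' @param spectra long spectra table (clone, env, block, row, column,
#'   flight_date, channel, value).
#' @param mode "per-date" or "across-dates".
#' @param basis "entry-mean" or "plot".
#' @param includeColumn include the column random effect.
#' @return data.frame (channel, date, basis, sigma2g, vbar, H2).
#' @export
channelHeritability <- function(spectra, mode = c("per-date", "across-dates"),
                                basis = c("entry-mean", "plot"),
                                includeColumn = TRUE) {
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  multiEnv <- length(unique(spectra$env)) > 1
  if (!multiEnv)
    message("single environment: falling back to the single-environment ",
            "model scope")
  out <- list()
  if (mode == "per-date") {
    d <- .spectraAsPlots(spectra)
    for (tr in unique(d$trait)) {
      envsTr <- unique(d$env[d$trait == tr])
      # year-specific channels exist in a single environment only
      scope <- if (multiEnv && length(envsTr) > 1) "across" else "single"
      envArg <- if (scope == "single") envsTr[1] else NULL
      h <- traitHeritability(d, tr, scope = scope, env = envArg,
                             includeColumn = includeColumn, basis = basis)
      parts <- strsplit(tr, ".", fixed = TRUE)[[1]]
      out[[tr]] <- data.frame(channel = parts[1], date = parts[2],
                              basis = basis, sigma2g = h@sigma2g,
                              vbar = h@vbar, H2 = h@H2)
    }
  } else {
    if (length(unique(spectra$flight_date)) < 2)
      stop("across-dates mode needs at least 2 flight dates")
    d <- spectra
    if (!"trial" %in% names(d)) d$trial <- 1
    for (ch in unique(d$channel)) {
      dc <- d[d$channel == ch, , drop = FALSE]
      chMultiEnv <- length(unique(dc$env)) > 1
      base <- if (chMultiEnv)
        c("env", "clone:env", "env:block", "env:row",
          if (includeColumn) "env:column") else
        c("block", "row", if (includeColumn) "column")
      dateTerms <- if (chMultiEnv)
        c("flight_date", "clone:flight_date", "flight_date:env",
          "clone:flight_date:env", "env:block:flight_date",
          "env:row:flight_date",
          if (includeColumn) "env:column:flight_date") else
        c("flight_date", "clone:flight_date", "block:flight_date",
          "row:flight_date", if (includeColumn) "column:flight_date")
      rnd <- fitReml("value", dc, fixed = character(),
                     random = c("clone", base, dateTerms))
      s2g <- unname(varComp(rnd)[["clone"]])
      if (basis == "plot") {
        out[[ch]] <- data.frame(channel = ch, date = NA, basis = basis,
                                sigma2g = s2g, vbar = NA,
                                H2 = s2g / sum(varComp(rnd)))
      } else {
        fx <- fitReml("value", dc, fixed = "clone",
                      random = c(base, dateTerms), noIntercept = TRUE)
        C <- fx@Vbeta
        vb <- .vbar(C)
        out[[ch]] <- data.frame(channel = ch, date = NA, basis = basis,
                                sigma2g = s2g, vbar = vb,
                                H2 = s2g / (s2g + vb / 2))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clone-level spectral features via adjusted entry means
#'
#' Builds the clone x (channel.date) matrix that houses the spectral
#' feature matrix S: per environment (scope "single", the basis of
#' single-environment kernels) or across environments (scope "across",
#' the MAEM summary).
#'
#' @param spectra long spectra table.
#' @param scope "single" (one environment) or "across".
#' @param env environment for scope "single".
#' @param includeColumn include the column random effect.
#' @return A [SpectraMatrix-class] of clone-level channel.date AEMs.
#' @export
spectraAems <- function(spectra, scope = c("single", "across"), env = NULL,
                        includeColumn = TRUE) {
  scope <- match.arg(scope)
  d <- .spectraAsPlots(spectra)
  if (scope == "single") {
    if (is.null(env)) stop("scope 'single' needs an environment")
    d <- d[d$env == env, , drop = FALSE]
    useScope <- "single"
  } else {
    useScope <- if (length(unique(d$env)) > 1) "across" else "single"
    if (useScope == "single") env <- unique(d$env)
  }
  feats <- sort(unique(d$trait))
  cols <- list()
  for (tr in feats) {
    envsTr <- unique(d$env[d$trait == tr])
    if (useScope == "across" && length(envsTr) < 2) {
      # year-specific channel observed in a single environment
      a <- computeAems(d, tr, scope = "single", env = envsTr,
                       includeColumn = includeColumn, outlierZ = Inf,
                       withCovariance = FALSE)
    } else {
      a <- computeAems(d, tr, scope = useScope,
                       env = if (useScope == "single") env else NULL,
                       includeColumn = includeColumn, outlierZ = Inf,
                       withCovariance = FALSE)
    }
    cols[[tr]] <- aemValues(a)
  }
  clones <- sort(unique(unlist(lapply(cols, names))))
  V <- matrix(NA_real_, length(clones), length(feats),
              dimnames = list(clones, feats))
  for (tr in feats) V[names(cols[[tr]]), tr] <- cols[[tr]]
  parts <- strsplit(feats, ".", fixed = TRUE)
  meta <- data.frame(
    env = if (scope == "single") env else NA_character_,
    date = vapply(parts, `[`, "", 2),
    channel = vapply(parts, `[`, "", 1),
    stringsAsFactors = FALSE)
  spectraMatrix(V, meta)
}
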