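# Synthetic tetraploid breeding study generator.
#
# Emulates the statistical structure of a multi-environment potato trial:
# full-sib families from tetraploid founders, augmented row-column designs
# with replicated checks, trial-split environments, traits with
# additive + dominance architecture and configurable entry-mean
# heritability, and multichannel UAV reflectances with a genetic latent
# score partially shared with the traits.

#' Configuration of the synthetic breeding study
#'
#' All defaults emulate the dimensioning of the real study design:
#' 458 test clones in 107 full-sib families plus 8 checks replicated once
#' per block (8 blocks) in each of 5 environments, two of which carry
#' multispectral data from 3 flight dates, with 5 channels shared between
#' the two spectral years, one year-specific channel each, and one shared
#' channel missing in the second year. Trait architectures (heritability,
#' dominance fraction, genotype-by-environment fraction, spectral overlap)
#' are configuration, not claims about potato biology.
#'
#' @slot nFamilies,nClones,nChecks,nFounders population dimensioning.
#' @slot nMarkers,nCausal marker panel size and causal subset.
#' @slot founderFreqRange range of founder allele frequencies.
#' @slot envNames environment codes (location letter + 2-digit year).
#' @slot spectraEnvs environments with multispectral overflights.
#' @slot twoTrialEnvs environments split into two maturity-group trials
#'   (3 + 5 blocks) whose trial effects must be removed via the checks.
#' @slot nBlocks,nColumns,maxRowsPerBlock augmented row-column design:
#'   blocks per environment, columns per block (<= 6), optional row cap
#'   (NA = as many rows as needed).
#' @slot traits data.frame with columns `name`, `h2` (target entry-mean
#'   heritability), `domFrac`, `gxeFrac`, `overlap` (spectral overlap
#'   fraction), `transform` (square-root transform flag).
#' @slot sigma2g genetic variance on the simulated scale (per trait).
#' @slot varEnv,varBlock,varRow,varCol,varTrial nuisance variances.
#' @slot nFlightDates,channelsShared,channelsYearOnly,missingChannel
#'   spectral layout: flight dates, 5 shared channels, one year-specific
#'   channel per year (named by 2-digit year), and the shared channel that
#'   is absent in one year (`c(channel =, year =)`).
#' @slot latentShares length-4 numeric (clone, clone-date, clone-env,
#'   clone-date-env) shares of the spectral genetic latent score; sums
#'   to 1.
#' @slot channelNoise,spectraSpatialVar,spectraEnvVar spectral nuisance
#'   variances.
#' @slot seed integer; fully determines all outputs.
#' @export
setClass("SimConfig", representation(
  nFamilies = "numeric", nClones = "numeric", nChecks = "numeric",
  nFounders = "numeric", nMarkers = "numeric", nCausal = "numeric",
  founderFreqRange = "numeric", envNames = "character",
  spectraEnvs = "character", twoTrialEnvs = "character",
  nBlocks = "numeric", nColumns = "numeric", maxRowsPerBlock = "numeric",
  traits = "data.frame", sigma2g = "numeric",
  varEnv = "numeric", varBlock = "numeric", varRow = "numeric",
  varCol = "numeric", varTrial = "numeric", trialEffects = "list",
  nFlightDates = "numeric", channelsShared = "character",
  channelsYearOnly = "list", missingChannel = "character",
  latentShares = "numeric", channelNoise = "numeric",
  spectraSpatialVar = "numeric", spectraEnvVar = "numeric",
  seed = "numeric"))

setValidity("SimConfig", function(object) {
  tr <- object@traits
  for (col in c("h2", "domFrac", "gxeFrac", "overlap"))
    if (any(tr[[col]] < 0 | tr[[col]] > 1))
      return(paste0("trait column '", col, "' must lie in [0, 1]"))
  if (!all(object@spectraEnvs %in% object@envNames))
    return("spectraEnvs must be a subset of envNames")
  if (object@nColumns > 6) return("augmented design uses at most 6 columns")
  if (abs(sum(object@latentShares) - 1) > 1e-8)
    return("latentShares must sum to 1")
  if (length(object@seed) != 1) return("a single integer seed is required")
  TRUE
})

#' @rdname SimConfig-class
#' @param ... named slots overriding the defaults listed above.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(nClones = 40, nFamilies = 10, nMarkers = 50, seed = 7)
#' @export
simConfig <- function(...) {
  defaults <- list(
    nFamilies = 107, nClones = 458, nChecks = 8, nFounders = 40,
    nMarkers = 300, nCausal = 120, founderFreqRange = c(0.1, 0.9),
    envNames = c("W19", "W20", "G20", "W21", "G21"),
    spectraEnvs = c("W20", "W21"),
    twoTrialEnvs = c("W21", "G21"),
    nBlocks = 8, nColumns = 6, maxRowsPerBlock = NA_real_,
    traits = data.frame(
      name = c("yield", "maturity", "starch"),
      h2 = c(0.55, 0.75, 0.90),
      domFrac = c(0.20, 0.10, 0.05),
      gxeFrac = c(0.30, 0.20, 0.10),
      overlap = c(0.50, 0.70, 0.10),
      transform = c(FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    sigma2g = 1,
    varEnv = 0.5, varBlock = 0.15, varRow = 0.10, varCol = 0.10,
    varTrial = 1, trialEffects = list(),
    nFlightDates = 3,
    channelsShared = c("c490", "c550", "c670", "c700", "c800"),
    channelsYearOnly = list("20" = "c900", "21" = "c720"),
    missingChannel = c(channel = "c670", year = "21"),
    latentShares = c(clone = 0.08, cloneDate = 0.42,
                     cloneEnv = 0.15, cloneDateEnv = 0.35),
    channelNoise = 1, spectraSpatialVar = 0.10, spectraEnvVar = 0.20,
    seed = 1)
  args <- list(...)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig fields: ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  do.call(new, c(list("SimConfig"), defaults))
}

.envYear <- function(env) sub("^[A-Za-z]+", "", env)

.envChannels <- function(config, env) {
  yr <- .envYear(env)
  ch <- c(config@channelsShared, unlist(config@channelsYearOnly[[yr]]))
  if (length(config@missingChannel) &&
      identical(yr, unname(config@missingChannel["year"])))
    ch <- setdiff(ch, config@missingChannel["channel"])
  ch
}

# Gamete dosage for a tetraploid parent with dosage d: two alleles drawn
# without replacement from the four (bivalent pairing, no double
# reduction), i.e. hypergeometric(d of 4, draw 2).
.gameteDosage <- function(d) {
  stats::rhyper(length(d), m = d, n = 4 - d, k = 2)
}

#' Simulate a tetraploid breeding population
#'
#' Founder clones receive marker dosages from Binomial(4, p_m) with
#' marker-wise allele frequencies drawn from `founderFreqRange`. Each
#' full-sib family crosses two founders; an offspring's dosage per marker
#' is the sum of two parental gametes, each gamete carrying 2 of the
#' parent's 4 alleles drawn without replacement. Checks are independent
#' founder-like genotypes.
#'
#' @param config a [SimConfig-class].
#' @return list with `dosage` (a [DosageMatrix-class], clones + checks by
#'   markers, all dosages in 0..4) and `pedigree` (data.frame: clone,
#'   family, parent1, parent2, is_check).
#' @export
simulatePopulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (config@nMarkers < 1) stop("need at least one marker")
  set.seed(config@seed)
  nM <- config@nMarkers
  p <- runif(nM, config@founderFreqRange[1], config@founderFreqRange[2])
  founders <- vapply(seq_len(config@nFounders),
                     function(i) rbinom(nM, 4, p), numeric(nM))
  founders <- t(founders)  # founders x markers
  sizes <- drop(stats::rmultinom(1, config@nClones - config@nFamilies,
                                 rep(1, config@nFamilies))) + 1
  famParents <- t(vapply(seq_len(config@nFamilies),
                         function(i) sample.int(config@nFounders, 2),
                         numeric(2)))
  cloneIdsV <- sprintf("C%03d", seq_len(config@nClones))
  fam <- rep(seq_len(config@nFamilies), sizes)
  geno <- matrix(0, config@nClones, nM)
  for (i in seq_len(config@nClones)) {
    p1 <- founders[famParents[fam[i], 1], ]
    p2 <- founders[famParents[fam[i], 2], ]
    geno[i, ] <- .gameteDosage(p1) + .gameteDosage(p2)
  }
  checks <- t(vapply(seq_len(config@nChecks),
                     function(i) rbinom(nM, 4, p), numeric(nM)))
  checkIds <- sprintf("CHK%d", seq_len(config@nChecks))
  all <- rbind(geno, checks)
  dimnames(all) <- list(c(cloneIdsV, checkIds),
                        sprintf("M%04d", seq_len(nM)))
  ped <- data.frame(
    clone = c(cloneIdsV, checkIds),
    family = c(paste0("F", sprintf("%03d", fam)), rep(NA, config@nChecks)),
    parent1 = c(paste0("P", famParents[fam, 1]), rep(NA, config@nChecks)),
    parent2 = c(paste0("P", famParents[fam, 2]), rep(NA, config@nChecks)),
    is_check = c(rep(FALSE, config@nClones), rep(TRUE, config@nChecks)),
    stringsAsFactors = FALSE)
  list(dosage = dosageMatrix(all), pedigree = ped)
}

# Genetic values with additive (marker effects on centered dosages) and
# digenic dominance (effects on the centered heterozygosity covariate
# d(4-d)/6) components, scaled to the configured variance split.
.simGeneticValues <- function(dos, config) {
  Z <- dosages(dos)
  entries <- rownames(Z)
  causal <- sample.int(ncol(Z), min(config@nCausal, ncol(Z)))
  Zc <- scale(Z[, causal, drop = FALSE], center = TRUE, scale = FALSE)
  W <- Z[, causal, drop = FALSE] * (4 - Z[, causal, drop = FALSE]) / 6
  Wc <- scale(W, center = TRUE, scale = FALSE)
  traits <- config@traits
  g <- matrix(0, nrow(Z), nrow(traits),
              dimnames = list(entries, traits$name))
  comp <- vector("list", nrow(traits))
  for (t in seq_len(nrow(traits))) {
    va <- (1 - traits$domFrac[t]) * config@sigma2g
    vd <- traits$domFrac[t] * config@sigma2g
    ga <- drop(Zc %*% rnorm(length(causal)))
    ga <- if (var(ga) > 0) ga * sqrt(va / var(ga)) else ga
    gd <- drop(Wc %*% rnorm(length(causal)))
    gd <- if (vd > 0 && var(gd) > 0) gd * sqrt(vd / var(gd)) else 0 * gd
    g[, t] <- ga + gd
    comp[[t]] <- list(additive = ga, dominance = gd)
  }
  list(values = g, components = comp, causal = causal)
}

# Field layout for one environment: checks once per block, entries split
# over blocks (and, in trial-split environments, families alternately over
# the early trial with 3 blocks and the late trial with 5 blocks).
.layoutEnv <- function(env, entries, entryFam, checks, config) {
  nB <- config@nBlocks
  split <- env %in% config@twoTrialEnvs
  if (split) {
    famIdx <- as.integer(factor(entryFam, levels = unique(entryFam)))
    trialOfEntry <- ifelse(famIdx %% 2 == 1, 1, 2)
    blocksOfTrial <- list(`1` = seq_len(3), `2` = 4:nB)
  } else {
    trialOfEntry <- rep(1, length(entries))
    blocksOfTrial <- list(`1` = seq_len(nB))
  }
  rows <- list()
  for (tr in names(blocksOfTrial)) {
    bl <- blocksOfTrial[[tr]]
    ent <- sample(entries[trialOfEntry == as.integer(tr)])
    blockOfEnt <- sort(rep(bl, length.out = length(ent)))
    for (b in bl) {
      plotClones <- sample(c(ent[blockOfEnt == b], checks))
      nCol <- config@nColumns
      nRow <- ceiling(length(plotClones) / nCol)
      if (!is.na(config@maxRowsPerBlock) && nRow > config@maxRowsPerBlock)
        stop("infeasible design in ", env, ": block ", b, " needs ", nRow,
             " rows but maxRowsPerBlock = ", config@maxRowsPerBlock,
             " (blocks x rows x columns < plots)")
      idx <- seq_along(plotClones) - 1
      rows[[paste(tr, b)]] <- data.frame(
        clone = plotClones, env = env, trial = as.integer(tr), block = b,
        row = (b - 1) * 1000 + idx %/% nCol + 1,  # rows unique within env
        column = idx %% nCol + 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$row <- as.integer(factor(out$row))  # 1-based consecutive row index
  rownames(out) <- NULL
  out
}

#' Simulate field-trial phenotypes on an augmented row-column design
#'
#' Assigns every test clone one plot per environment and every check one
#' plot per block, then builds trait values as
#' intercept + additive + dominance + environment + clone-by-environment +
#' block + row + column (+ trial, in split environments) + residual.
#' The residual variance is solved per trait so that the expected
#' entry-mean heritability sigma2g / (sigma2g + (sigma2ge + sigma2e)/nEnvs)
#' matches the configured target.
#'
#' @param pop result of [simulatePopulation()].
#' @param config a [SimConfig-class].
#' @return data.frame in the canonical long plot format (clone, env,
#'   trial, block, row, column, trait, value) with a `"truth"` attribute
#'   holding the simulated genetic values, variance components and trial
#'   effects.
#' @export
simulateTrial <- function(pop, config) {
  set.seed(config@seed + 1L)
  dos <- pop$dosage
  ped <- pop$pedigree
  gv <- .simGeneticValues(dos, config)
  entries <- ped$clone[!ped$is_check]
  entryFam <- ped$family[!ped$is_check]
  checks <- ped$clone[ped$is_check]
  traits <- config@traits
  nE <- length(config@envNames)
  varTab <- list()
  allPlots <- list()
  truthTrial <- list()
  layout <- lapply(config@envNames, .layoutEnv, entries = entries,
                   entryFam = entryFam, checks = checks, config = config)
  names(layout) <- config@envNames
  for (t in seq_len(nrow(traits))) {
    h2 <- traits$h2[t]
    if (h2 <= 0) stop("target heritability must be positive")
    s2ge <- traits$gxeFrac[t] * config@sigma2g
    s2e <- nE * config@sigma2g * (1 - h2) / h2 - s2ge
    if (s2e < -1e-9)
      stop("trait '", traits$name[t], "': target heritability ", h2,
           " is not attainable with gxeFrac ", traits$gxeFrac[t],
           " over ", nE, " environments")
    s2e <- max(s2e, 0)
    varTab[[t]] <- c(sigma2g = config@sigma2g, sigma2ge = s2ge,
                     sigma2e = s2e)
    envEff <- setNames(rnorm(nE, 0, sqrt(config@varEnv)), config@envNames)
    gxe <- matrix(rnorm(nrow(dosages(dos)) * nE, 0, sqrt(s2ge)),
                  ncol = nE, dimnames = list(cloneIds(dos),
                                             config@envNames))
    for (env in config@envNames) {
      lay <- layout[[env]]
      nTrial <- length(unique(lay$trial))
      tau <- rep(0, nTrial)
      if (nTrial > 1) {
        tau <- if (!is.null(config@trialEffects[[env]]))
          config@trialEffects[[env]] else rnorm(nTrial, 0, sqrt(config@varTrial))
      }
      truthTrial[[paste(traits$name[t], env)]] <- tau
      bEff <- setNames(rnorm(max(lay$block), 0, sqrt(config@varBlock)),
                       seq_len(max(lay$block)))
      rEff <- setNames(rnorm(max(lay$row), 0, sqrt(config@varRow)),
                       seq_len(max(lay$row)))
      cEff <- setNames(rnorm(max(lay$column), 0, sqrt(config@varCol)),
                       seq_len(max(lay$column)))
      val <- 10 + gv$values[lay$clone, t] + envEff[env] +
        gxe[lay$clone, env] + bEff[lay$block] + rEff[lay$row] +
        cEff[lay$column] + tau[lay$trial] +
        rnorm(nrow(lay), 0, sqrt(s2e))
      if (isTRUE(traits$transform[t])) val <- pmax(val, 0)^2
      allPlots[[paste(traits$name[t], env)]] <- data.frame(
        lay, trait = traits$name[t], value = unname(val),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, allPlots)
  rownames(out) <- NULL
  names(varTab) <- traits$name
  attr(out, "truth") <- list(
    geneticValues = gv$values,
    geneticComponents = gv$components,
    varComp = varTab,
    trialEffects = truthTrial,
    layout = layout)
  out
}

#' Simulate multichannel UAV reflectances for the spectral environments
#'
#' Per plot, flight date and channel the reflectance is
#' loading x latent genetic score + environment + spatial + noise. The
#' latent score decomposes into clone, clone-by-date, clone-by-environment
#' and clone-by-date-by-environment parts per `latentShares`; its stable
#' clone part is correlated with the traits' genetic values through the
#' configured spectral-overlap fractions (overlap 0 means spectra carry no
#' information on the trait). Year-specific channels and the channel
#' missing in one year are dropped so the imputation path is exercised.
#'
#' @param plots trial table from [simulateTrial()] (provides the layout
#'   and the genetic values through its `"truth"` attribute), or a plain
#'   layout data.frame if `geneticValues` is given.
#' @param config a [SimConfig-class].
#' @param geneticValues optional clones x traits matrix overriding the
#'   `"truth"` attribute (NULL with no truth gives spectra that are
#'   genetically unrelated to any trait).
#' @return data.frame (clone, env, trial, block, row, column,
#'   flight_date, channel, value) for the spectral environments.
#' @export
simulateSpectra <- function(plots, config, geneticValues = NULL) {
  if (length(config@spectraEnvs) == 0)
    stop("no environments with spectra configured")
  for (yr in unique(.envYear(config@spectraEnvs)))
    if (is.null(config@channelsYearOnly[[yr]]) &&
        length(config@channelsYearOnly))
      stop("channel sets inconsistent with spectral years: no entry for ",
           yr)
  set.seed(config@seed + 2L)
  if (is.null(geneticValues)) {
    tr <- attr(plots, "truth")
    if (!is.null(tr)) geneticValues <- tr$geneticValues
  }
  lay <- unique(plots[plots$env %in% config@spectraEnvs,
                      c("clone", "env", "trial", "block", "row", "column")])
  clones <- sort(unique(lay$clone))
  nC <- length(clones)
  ov <- config@traits$overlap
  if (!is.null(geneticValues)) {
    z <- scale(geneticValues[clones, , drop = FALSE])
    L <- drop(z %*% sqrt(ov) + rnorm(nC)) / sqrt(sum(ov) + 1)
  } else {
    L <- rnorm(nC)
  }
  names(L) <- clones
  sh <- config@latentShares
  dates <- paste0("D", seq_len(config@nFlightDates))
  envs <- config@spectraEnvs
  xi <- matrix(rnorm(nC * length(dates)), nC,
               dimnames = list(clones, dates))
  ze <- matrix(rnorm(nC * length(envs)), nC,
               dimnames = list(clones, envs))
  zde <- array(rnorm(nC * length(dates) * length(envs)),
               dim = c(nC, length(dates), length(envs)),
               dimnames = list(clones, dates, envs))
  allCh <- unique(c(config@channelsShared,
                    unlist(config@channelsYearOnly)))
  loading <- matrix(runif(length(allCh) * length(dates), 0.7, 1.3),
                    length(allCh), length(dates),
                    dimnames = list(allCh, dates))
  out <- list()
  for (env in envs) {
    chs <- .envChannels(config, env)
    layE <- lay[lay$env == env, ]
    for (d in dates) {
      latent <- sqrt(sh[1]) * L + sqrt(sh[2]) * xi[, d] +
        sqrt(sh[3]) * ze[, env] + sqrt(sh[4]) * zde[, d, env]
      bEff <- rnorm(max(layE$block), 0, sqrt(config@spectraSpatialVar))
      rEff <- rnorm(max(layE$row), 0, sqrt(config@spectraSpatialVar))
      cEff <- rnorm(max(layE$column), 0, sqrt(config@spectraSpatialVar))
      spatial <- bEff[layE$block] + rEff[layE$row] + cEff[layE$column]
      for (ch in chs) {
        envEff <- rnorm(1, 0, sqrt(config@spectraEnvVar))
        val <- loading[ch, d] * latent[layE$clone] + envEff + spatial +
          rnorm(nrow(layE), 0, sqrt(config@channelNoise))
        out[[paste(env, d, ch)]] <- data.frame(
          layE, flight_date = d, channel = ch, value = unname(val),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete study bundle
#'
#' Convenience orchestrator: population, field trials and spectra under a
#' single seed.
#'
#' @param config a [SimConfig-class].
#' @return list with `dosage`, `pedigree`, `plots`, `spectra`, `truth`,
#'   `config`.
#' @examples
#' bundle <- simulateStudy(simConfig(nClones = 30, nFamilies = 10,
#'   nChecks = 4, nMarkers = 40, nBlocks = 4, seed = 3))
#' head(bundle$plots)
#' @export
simulateStudy <- function(config) {
  pop <- simulatePopulation(config)
  plots <- simulateTrial(pop, config)
  spectra <- simulateSpectra(plots, config)
  list(dosage = pop$dosage, pedigree = pop$pedigree, plots = plots,
       spectra = spectra, truth = attr(plots, "truth"), config = config)
}
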