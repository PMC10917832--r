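# Readers/writers for the canonical tab-separated tables, dataset
# validation, study preparation and the end-to-end pipeline runner.
#
# Canonical schemas (TSV, UTF-8, header row, 1-based field coordinates,
# environments coded as location letter + 2-digit year, e.g. "W20"):
#   phenotypes: clone, env, trial, block, row, column, trait, value
#   spectra:    clone, env, trial, block, row, column, flight_date,
#               channel, value
#   genotypes:  clone, <marker ids...>  (wide, dosages 0-4)

.checkEnvCodes <- function(env, file) {
  bad <- which(!grepl("^[A-Za-z]+[0-9]{2}$", env))
  if (length(bad))
    stop(file, ": unknown environment code '", env[bad[1]], "' at line ",
         bad[1] + 1)
}

#' Read / write the canonical long plot table
#'
#' @param path TSV file path.
#' @return data.frame with the phenotype schema.
#' @export
readPlotTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone", "env", "trial", "block", "row", "column", "trait",
            "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  .checkEnvCodes(d$env, path)
  dup <- duplicated(d[, c("clone", "env", "trial", "block", "row",
                          "column", "trait")])
  if (any(dup))
    stop(path, ": duplicate plot rows, first at line ", which(dup)[1] + 1)
  d
}

#' @rdname readPlotTable
#' @param plots data.frame in the phenotype schema.
#' @export
writePlotTable <- function(plots, path) {
  write.table(plots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the long spectra table
#' @param path TSV file path.
#' @export
readSpectraTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone", "env", "block", "row", "column", "flight_date",
            "channel", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  .checkEnvCodes(d$env, path)
  d
}

#' @rdname readSpectraTable
#' @param spectra data.frame in the spectra schema.
#' @export
writeSpectraTable <- function(spectra, path) {
  write.table(spectra, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the wide genotype table
#'
#' Clones in the first column, one column per marker, tetraploid dosages
#' 0--4 (empty = missing).
#'
#' @param path TSV file path.
#' @return A [DosageMatrix-class].
#' @export
readDosageMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  Z <- as.matrix(d[, -1, drop = FALSE])
  rownames(Z) <- d[[1]]
  bad <- which(!is.na(Z) & (Z < 0 | Z > 4 | Z != round(Z)), arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": invalid dosage ", Z[bad[1, , drop = FALSE]],
         " at line ", bad[1, 1] + 1, ", marker ", colnames(Z)[bad[1, 2]])
  dosageMatrix(Z)
}

#' @rdname readDosageMatrix
#' @param dosage a [DosageMatrix-class].
#' @export
writeDosageMatrix <- function(dosage, path) {
  Z <- dosages(dosage)
  d <- data.frame(clone = rownames(Z), Z, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a relationship matrix with its metadata sidecar
#'
#' The kernel goes to `<path>` as a TSV with a header row of clone ids;
#' kind and provenance go to `<path>.meta.tsv`.
#'
#' @param path TSV file path.
#' @export
readRelationshipMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  V <- as.matrix(d[, -1, drop = FALSE])
  rownames(V) <- d[[1]]
  metaPath <- paste0(path, ".meta.tsv")
  kind <- "G"; prov <- list()
  if (file.exists(metaPath)) {
    m <- read.delim(metaPath, stringsAsFactors = FALSE)
    kind <- m$value[m$key == "kind"]
    prov <- as.list(m$value[m$key != "kind"])
    names(prov) <- m$key[m$key != "kind"]
  }
  relationshipMatrix(V, kind, prov)
}

#' @rdname readRelationshipMatrix
#' @param K a [RelationshipMatrix-class].
#' @export
writeRelationshipMatrix <- function(K, path) {
  V <- relValues(K)
  d <- data.frame(clone = rownames(V), V, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- K@provenance
  meta <- data.frame(key = c("kind", names(prov)),
                     value = c(kernelKind(K),
                               vapply(prov, function(x)
                                 paste(format(x), collapse = ","), "")))
  write.table(meta, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load and validate a dataset from canonical files
#'
#' @param phenotypes,genotypes,spectra file paths; `spectra` may be NULL
#'   for genomic-only analyses.
#' @return list bundle (plots, dosage, spectra).
#' @export
loadDataset <- function(phenotypes, genotypes, spectra = NULL) {
  for (f in c(phenotypes, genotypes, spectra))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  list(plots = readPlotTable(phenotypes),
       dosage = readDosageMatrix(genotypes),
       spectra = if (!is.null(spectra)) readSpectraTable(spectra))
}

#' Prepare every input the prediction scenarios need
#'
#' Runs the analysis chain once: marker QC, trial-effect estimation and
#' subtraction, adjusted entry means per trait for every scope the
#' requested scenarios use, spectral preprocessing, and all kernels.
#'
#' @param bundle list with `plots`, `dosage` and optionally `spectra`
#'   (e.g. from [simulateStudy()] or [loadDataset()]).
#' @param traits traits to prepare (default: all in the plot table).
#' @param scenarios scenario families that will be run (controls which
#'   AEM scopes are computed).
#' @param includeColumn column random effect switch or "auto".
#' @param sqrtTraits traits to square-root transform before modelling.
#' @param qc run [qcMarkers()] on the dosage matrix first.
#' @param ... passed to [processSpectra()].
#' @return list with `aems` (per trait, per scope label), `kernels`,
#'   `plotsAdjusted`, `trialEffects`, `processedSpectra`.
#' @export
prepareStudy <- function(bundle, traits = NULL,
                         scenarios = c("S1", "S2", "S3", "S3b", "S4",
                                       "S5", "S6", "S7"),
                         includeColumn = TRUE, sqrtTraits = character(),
                         qc = TRUE, ...) {
  plots <- bundle$plots
  if (is.null(traits)) traits <- unique(plots$trait)
  dosage <- bundle$dosage
  if (qc && !is.null(dosage)) dosage <- qcMarkers(dosage)
  eff <- estimateTrialEffects(plots, trait = traits)
  plots <- adjustForTrial(plots, eff)
  envs <- sort(unique(plots$env))
  spectraEnvs <- if (!is.null(bundle$spectra))
    sort(unique(bundle$spectra$env)) else character()
  needSingle <- any(scenarios %in% c("S1", "S2", "S4", "S6"))
  needAcross <- any(scenarios %in% c("S3", "S5", "S7"))
  needLoo <- "S3b" %in% scenarios
  aems <- list()
  for (tr in traits) {
    sq <- tr %in% sqrtTraits
    scopes <- list()
    if (needAcross)
      scopes[["across"]] <- aemValues(computeAems(
        plots, tr, "across", includeColumn = includeColumn,
        sqrtTransform = sq, withCovariance = FALSE))
    if (needSingle)
      for (e in envs)
        scopes[[e]] <- aemValues(computeAems(
          plots, tr, "single", env = e, includeColumn = includeColumn,
          sqrtTransform = sq, withCovariance = FALSE))
    if (needLoo)
      for (e in spectraEnvs)
        scopes[[paste0("loo:", e)]] <- aemValues(computeAems(
          plots, tr, "loo", env = e, includeColumn = includeColumn,
          sqrtTransform = sq, withCovariance = FALSE))
    aems[[tr]] <- scopes
  }
  processed <- NULL
  if (!is.null(bundle$spectra) &&
      any(scenarios %in% c("S1", "S2", "S3", "S3b", "S4", "S5")))
    processed <- processSpectra(bundle$spectra, ...)
  kernels <- buildKernels(dosage, processed)
  list(aems = aems, kernels = kernels, plotsAdjusted = plots,
       trialEffects = eff, processedSpectra = processed)
}

#' Run the full prediction pipeline and write the result tables
#'
#' Orchestrates preprocess -> trial adjustment -> entry means -> kernels
#' -> scenario predictions, and writes tidy TSVs: per-fold predictive
#' abilities, a per-case summary with the quality-filter flag, the trial
#' effects, and a provenance sidecar with the settings and seed.
#'
#' @param bundle data bundle (see [prepareStudy()]).
#' @param outDir output directory (created if needed).
#' @param scenarios scenario families to run.
#' @param traits traits to analyze (default all).
#' @param nFolds,nReps,seed cross-validation settings.
#' @param ... passed to [prepareStudy()].
#' @return invisibly, the summary data.frame.
#' @export
runPipeline <- function(bundle, outDir, scenarios = c("S6", "S7"),
                        traits = NULL, nFolds = 5, nReps = 25, seed = 1,
                        ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  prep <- prepareStudy(bundle, traits = traits, scenarios = scenarios,
                       ...)
  traits <- names(prep$aems)
  spectraEnvs <- names(prep$processedSpectra$cloneSpectra) %||% character()
  cases <- enumerateScenarios(sort(unique(bundle$plots$env)), spectraEnvs,
                              ids = scenarios)
  rowsPA <- list(); rowsSum <- list()
  for (i in seq_len(nrow(cases))) {
    spec <- scenarioSpec(cases$id[i], cases$phenoScope[i],
                         cases$kernelSource[i])
    for (tr in traits) {
      res <- runScenario(spec, prep$aems[[tr]], prep$kernels,
                         nFolds = nFolds, nReps = nReps, seed = seed)
      pa <- predictiveAbilities(res)
      rowsPA[[paste(i, tr)]] <- data.frame(
        scenario = spec@id, phenoScope = spec@phenoScope,
        kernelSource = spec@kernelSource, trait = tr,
        rep = rep(seq_len(nReps), each = nFolds),
        fold = rep(seq_len(nFolds), nReps), pa = pa)
      rowsSum[[paste(i, tr)]] <- data.frame(
        scenario = spec@id, phenoScope = spec@phenoScope,
        kernelSource = spec@kernelSource, trait = tr,
        medianPA = res@medianPA, meanPA = res@meanPA, cv = res@cv,
        nMissing = res@nMissing, passedFilter = res@passedFilter)
    }
  }
  paTab <- do.call(rbind, rowsPA)
  sumTab <- do.call(rbind, rowsSum)
  write.table(paTab, file.path(outDir, "predictive_abilities.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sumTab, file.path(outDir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prep$trialEffects, file.path(outDir, "trial_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- data.frame(
    key = c("package", "version", "seed", "nFolds", "nReps", "scenarios"),
    value = c("psblup", as.character(utils::packageVersion("psblup")),
              seed, nFolds, nReps, paste(scenarios, collapse = ",")))
  write.table(prov, file.path(outDir, "provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sumTab)
}
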