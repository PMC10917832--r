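# Plot-level spectral preprocessing chain: scale -> PCA outlier flag ->
# median impute -> clone-level AEMs -> predictive-mean-matching of the
# channel-year blocks -> per-environment feature matrices.

.spectraWide <- function(sub) {
  key <- paste(sub$block, sub$row, sub$column, sep = "_")
  feat <- paste(sub$channel, sub$flight_date, sep = ".")
  rows <- sort(unique(key))
  cols <- sort(unique(feat))
  V <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  V[cbind(match(key, rows), match(feat, cols))] <- sub$value
  list(values = V, key = key, feat = feat)
}

#' Preprocess plot-level spectra into clone-level feature matrices
#'
#' Runs the full spectral chain per environment: column scaling and
#' centering, principal-component outlier flagging of whole plot spectra,
#' median imputation of the flagged cells, clone-level adjusted entry
#' means per channel.date, then predictive-mean-matching imputation of
#' the channel blocks entirely missing in one environment-year (using the
#' channels shared across years as predictors and the other year's clones
#' as donors), and a final column standardization. Each environment ends
#' up with the full set of channel x flight-date features (m_s columns).
#'
#' @param spectra long plot-level spectra table (clone, env, block, row,
#'   column, flight_date, channel, value).
#' @param nPcs,zThreshold outlier-flagging settings (see
#'   [flagSpectralOutliers()]).
#' @param kDonors,seed predictive-mean-matching settings.
#' @param includeColumn column random effect in the entry-mean models.
#' @return list with `cloneSpectra` (named list of complete, scaled
#'   clone-level [SpectraMatrix-class] per environment), `cleanLong` (the
#'   outlier-handled long table on the scaled scale), and
#'   `outlierFraction` per environment.
#' @export
processSpectra <- function(spectra, nPcs = 5, zThreshold = 4,
                           kDonors = 5, seed = 1, includeColumn = TRUE) {
  envs <- sort(unique(spectra$env))
  cleaned <- list()
  outFrac <- setNames(numeric(length(envs)), envs)
  for (e in envs) {
    sub <- spectra[spectra$env == e, , drop = FALSE]
    w <- .spectraWide(sub)
    S <- scaleSpectra(spectraMatrix(w$values))
    fl <- flagSpectralOutliers(S, nPcs = nPcs, zThreshold = zThreshold)
    outFrac[e] <- fl$flaggedFraction
    S <- medianImpute(fl$spectra)
    V <- spectraValues(S)
    sub$value <- V[cbind(match(w$key, rownames(V)),
                         match(w$feat, colnames(V)))]
    cleaned[[e]] <- sub
  }
  cleanLong <- do.call(rbind, cleaned)
  rownames(cleanLong) <- NULL
  # clone-level AEMs per environment on the observed channels
  aems <- lapply(envs, function(e)
    spectraAems(cleanLong[cleanLong$env == e, , drop = FALSE],
                scope = "single", env = e,
                includeColumn = includeColumn))
  names(aems) <- envs
  # stack environments, pad to the union of features, PMM the year blocks
  allFeats <- sort(unique(unlist(lapply(aems, function(a)
    colnames(spectraValues(a))))))
  stacked <- do.call(rbind, lapply(envs, function(e) {
    V <- spectraValues(aems[[e]])
    out <- matrix(NA_real_, nrow(V), length(allFeats),
                  dimnames = list(paste(e, rownames(V), sep = ":"),
                                  allFeats))
    out[, colnames(V)] <- V
    out
  }))
  if (anyNA(stacked)) {
    stacked <- spectraValues(pmmImpute(spectraMatrix(stacked),
                                       kDonors = kDonors, seed = seed))
  }
  cloneSpectra <- lapply(envs, function(e) {
    rows <- startsWith(rownames(stacked), paste0(e, ":"))
    V <- stacked[rows, , drop = FALSE]
    rownames(V) <- sub("^[^:]+:", "", rownames(V))
    scaleSpectra(spectraMatrix(V))
  })
  names(cloneSpectra) <- envs
  list(cloneSpectra = cloneSpectra, cleanLong = cleanLong,
       outlierFraction = outFrac)
}

#' Assemble the relationship matrices of a study
#'
#' Builds every kernel the prediction scenarios use: a multispectral
#' kernel per spectral environment, the column-joined (cjM) and
#' across-environment AEM (MAEM) kernels when two spectral environments
#' exist, and the genomic additive, additive+dominance and
#' additive+dominance+epistasis kernel sets.
#'
#' @param dosage complete [DosageMatrix-class] (post-QC).
#' @param processed result of [processSpectra()] (optional; omit for
#'   genomic-only scenarios).
#' @param center center the dosage matrix in the additive kernel.
#' @return named list: one [RelationshipMatrix-class] per spectral
#'   environment, "cjM", "MAEM", "G", and kernel lists "G+D", "G+D+E".
#' @export
buildKernels <- function(dosage, processed = NULL, center = TRUE) {
  G <- additiveKernel(dosage, center = center)
  D <- dominanceKernel(dosage)
  epi <- epistaticKernels(G, D)
  kernels <- list(G = G,
                  "G+D" = list(G = G, D = D),
                  "G+D+E" = list(G = G, D = D, AA = epi$AA, AD = epi$AD,
                                 DD = epi$DD))
  if (!is.null(processed)) {
    cs <- processed$cloneSpectra
    for (e in names(cs)) kernels[[e]] <- spectralKernel(cs[[e]], "M")
    if (length(cs) >= 2) {
      # sources are already column-scaled, so the joined kernel is the
      # average of the two single-environment kernels
      cj <- combineSpectra(cs[[1]], cs[[2]], mode = "cjM")
      kernels$cjM <- spectralKernel(cj, "cjM")
      maem <- combineSpectra(mode = "MAEM",
                             spectraPlots = processed$cleanLong)
      kernels$MAEM <- spectralKernel(scaleSpectra(maem), "MAEM")
    }
  }
  kernels
}
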