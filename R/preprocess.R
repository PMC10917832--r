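# Quality control and imputation for dosage and spectral matrices.

#' Marker quality control for tetraploid dosages
#'
#' Removes markers with more than `maxMissing` missing calls, then markers
#' whose minor allele frequency (mean dosage / 4, computed after the
#' missingness filter) falls below `minMaf`, and median-imputes the
#' remaining missing calls so the output is complete.
#'
#' @param raw a [DosageMatrix-class] (NA allowed).
#' @param maxMissing maximum tolerated missing fraction per marker
#'   (default 0.20: markers with >= 20% missing are discarded).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @return A complete [DosageMatrix-class].
#' @examples
#' z <- matrix(c(0, 1, 2, 3, 4, NA), 3, 2,
#'   dimnames = list(paste0("c", 1:3), c("m1", "m2")))
#' qcMarkers(dosageMatrix(z))
#' @export
qcMarkers <- function(raw, maxMissing = 0.20, minMaf = 0.05) {
  stopifnot(maxMissing > 0, maxMissing < 1, minMaf > 0, minMaf < 1)
  Z <- dosages(raw)
  missFrac <- colMeans(is.na(Z))
  Z <- Z[, missFrac < maxMissing, drop = FALSE]
  if (ncol(Z)) {
    p <- colMeans(Z, na.rm = TRUE) / 4
    maf <- pmin(p, 1 - p)
    Z <- Z[, maf >= minMaf, drop = FALSE]
  }
  if (ncol(Z) == 0)
    stop("all markers removed by quality control")
  for (j in which(colSums(is.na(Z)) > 0)) {
    Z[is.na(Z[, j]), j] <- median(Z[, j], na.rm = TRUE)
  }
  dosageMatrix(Z)
}

#' Scale and center a spectral matrix
#'
#' Each column is centered to mean 0 and scaled to unit standard
#' deviation over its non-missing entries; missing entries stay missing.
#'
#' @param raw a [SpectraMatrix-class].
#' @return scaled [SpectraMatrix-class].
#' @export
scaleSpectra <- function(raw) {
  S <- spectraValues(raw)
  nObs <- colSums(!is.na(S))
  if (any(nObs < 2))
    stop("columns with fewer than 2 observed values: ",
         paste(colnames(S)[nObs < 2], collapse = ", "))
  sds <- apply(S, 2, sd, na.rm = TRUE)
  if (any(sds == 0))
    stop("zero-variance columns: ",
         paste(colnames(S)[sds == 0], collapse = ", "))
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  spectraMatrix(S, spectraMeta(raw))
}

#' Flag spectral outliers by principal-component scores
#'
#' Rows whose score on any of the first `nPcs` principal components
#' exceeds `zThreshold` standard deviations of that component are flagged
#' and all their channels are set to missing (a corrupted flight frame
#' affects every channel of a plot). PCA runs on the observed pattern with
#' missing cells filled by column medians for the decomposition only.
#'
#' @param S a scaled [SpectraMatrix-class].
#' @param nPcs number of leading components inspected.
#' @param zThreshold flag threshold in SD units of each component score.
#' @return list with `spectra` (flagged rows set to NA), `mask` (logical
#'   vector of flagged rows) and `flaggedFraction`.
#' @export
flagSpectralOutliers <- function(S, nPcs = 5, zThreshold = 4) {
  if (nPcs <= 0) stop("nPcs must be positive")
  V <- spectraValues(S)
  nPcs <- min(nPcs, ncol(V), nrow(V) - 1)
  Vc <- V
  for (j in seq_len(ncol(Vc))) {
    mj <- median(Vc[, j], na.rm = TRUE)
    Vc[is.na(Vc[, j]), j] <- mj
  }
  pc <- prcomp(Vc, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(nPcs), drop = FALSE]
  zs <- sweep(scores, 2, apply(scores, 2, sd), "/")
  mask <- apply(abs(zs) > zThreshold, 1, any)
  V[mask, ] <- NA
  list(spectra = spectraMatrix(V, spectraMeta(S)),
       mask = setNames(mask, rownames(V)),
       flaggedFraction = mean(mask))
}

#' Median imputation of missing spectral cells
#'
#' @param S a [SpectraMatrix-class]; every column needs at least one
#'   observed value.
#' @return complete [SpectraMatrix-class]; observed cells are untouched.
#' @export
medianImpute <- function(S) {
  V <- spectraValues(S)
  if (any(colSums(!is.na(V)) == 0))
    stop("fully missing columns cannot be median imputed: ",
         paste(colnames(V)[colSums(!is.na(V)) == 0], collapse = ", "))
  for (j in which(colSums(is.na(V)) > 0)) {
    V[is.na(V[, j]), j] <- median(V[, j], na.rm = TRUE)
  }
  spectraMatrix(V, spectraMeta(S))
}

#' Predictive-mean-matching imputation of channel-year blocks
#'
#' For each target column (a channel entirely missing in one
#' environment-year but observed in another): fit a least-squares
#' regression of the column on the complete predictor columns using the
#' rows where it is observed; predict all rows; for every missing row find
#' the `kDonors` observed rows with the nearest predicted values and copy
#' one donor's observed value chosen uniformly at random. Imputed values
#' therefore always occur among observed donors (semi-parametric
#' plausibility).
#'
#' @param S a [SpectraMatrix-class] whose non-target columns are complete.
#' @param targetColumns column names to impute (default: all columns with
#'   any missing value).
#' @param kDonors donor-pool size (default 5).
#' @param seed integer seed for the donor draw.
#' @return [SpectraMatrix-class] with targets imputed; observed cells are
#'   untouched.
#' @export
pmmImpute <- function(S, targetColumns = NULL, kDonors = 5, seed = 1) {
  V <- spectraValues(S)
  if (is.null(targetColumns))
    targetColumns <- colnames(V)[colSums(is.na(V)) > 0]
  if (length(targetColumns) == 0) return(S)
  predictors <- setdiff(colnames(V), targetColumns)
  if (any(is.na(V[, predictors])))
    stop("predictor columns must be complete before PMM")
  set.seed(seed)
  for (col in targetColumns) {
    obs <- !is.na(V[, col])
    if (!any(obs))
      stop("no observed rows anywhere for target column ", col)
    if (sum(obs) < kDonors)
      stop("fewer than kDonors = ", kDonors,
           " observed rows for target column ", col)
    if (all(obs)) next
    Xo <- cbind(1, V[obs, predictors, drop = FALSE])
    Xa <- cbind(1, V[, predictors, drop = FALSE])
    b <- qr.solve(Xo, V[obs, col])
    pred <- drop(Xa %*% b)
    predObs <- pred[obs]
    obsVals <- V[obs, col]
    for (i in which(!obs)) {
      donors <- order(abs(predObs - pred[i]))[seq_len(kDonors)]
      V[i, col] <- obsVals[donors[sample.int(kDonors, 1)]]
    }
  }
  spectraMatrix(V, spectraMeta(S))
}
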