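#' @import methods
#' @importFrom stats median sd var cor quantile rnorm runif rbinom optim
#'   optimize logLik vcov simulate formula as.formula setNames prcomp
#'   complete.cases coef lm predict pchisq
#' @importFrom utils read.delim write.table combn head
NULL

#' Tetraploid allele-dosage matrix
#'
#' Clones-by-markers matrix of tetraploid allele dosages coded 0--4
#' (AAAA = 0 ... BBBB = 4), with `NA` allowed for missing calls before
#' quality control.
#'
#' @slot dosages integer-valued matrix, rows = clones, columns = markers,
#'   values in `{0,...,4, NA}`; dimnames carry clone and marker ids.
#' @export
setClass("DosageMatrix", representation(dosages = "matrix"))

setValidity("DosageMatrix", function(object) {
  x <- object@dosages
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x))))
    return("dosage matrix needs clone rownames and marker colnames")
  if (anyDuplicated(rownames(x))) return("duplicated clone ids")
  if (anyDuplicated(colnames(x))) return("duplicated marker ids")
  v <- x[!is.na(x)]
  if (length(v) && (any(v < 0) || any(v > 4) || any(v != round(v))))
    return("dosages must be integers in 0..4 or NA")
  TRUE
})

#' Multispectral feature matrix
#'
#' Rows are clones (or plots), columns are environment x flight-date x
#' channel combinations. `colMeta` describes each column; the column count
#' is the spectral feature dimension m_s that scales the multispectral
#' relationship matrix M = SS'/m_s.
#'
#' @slot values numeric matrix of reflectances (unitless after scaling).
#' @slot colMeta data.frame with one row per column: `env`, `date`,
#'   `channel` (any may be NA when not applicable).
#' @export
setClass("SpectraMatrix", representation(values = "matrix",
                                         colMeta = "data.frame"))

setValidity("SpectraMatrix", function(object) {
  if (nrow(object@colMeta) != ncol(object@values))
    return("colMeta must have one row per column of values")
  if (is.null(rownames(object@values)))
    return("values needs row ids")
  TRUE
})

#' Clone-by-clone relationship matrix
#'
#' Symmetric positive semidefinite kernel over clones with a `kind` tag
#' recording how it was built (additive genomic G, dominance D, epistatic
#' AA/AD/DD, multispectral M, column-joined cjM, across-environment MAEM,
#' or weighted combination C).
#'
#' @slot values symmetric numeric matrix with clone ids as dimnames.
#' @slot kind character, one of "G","D","AA","AD","DD","M","cjM","MAEM","C".
#' @slot provenance list of construction metadata (marker count m, spectral
#'   feature count m_s, weight x, centering flag, source environments).
#' @export
setClass("RelationshipMatrix", representation(values = "matrix",
                                              kind = "character",
                                              provenance = "list"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("kernel must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("kernel needs identical clone ids on rows and columns")
  if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v))))
    return("kernel not symmetric within 1e-10")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    return("kernel not positive semidefinite within tolerance")
  TRUE
})

#' REML fit of a Gaussian linear mixed model
#'
#' @slot varComp named numeric vector of variance components, one per
#'   random term plus `"residual"`; all >= 0.
#' @slot beta named numeric vector of fixed-effect estimates (BLUEs).
#' @slot Vbeta covariance matrix of `beta`.
#' @slot blups list of named numeric vectors of random-effect predictions.
#' @slot logRL log restricted likelihood at the optimum.
#' @slot converged logical convergence flag; non-converged fits propagate
#'   to missing predictions downstream.
#' @slot nobs number of (non-missing) observations used.
#' @slot details list of engine internals (e.g. residual projections used
#'   for kernel prediction).
#' @export
setClass("LmmFit", representation(varComp = "numeric", beta = "numeric",
                                  Vbeta = "matrix", blups = "list",
                                  logRL = "numeric", converged = "logical",
                                  nobs = "numeric", details = "list"))

setValidity("LmmFit", function(object) {
  if (any(object@varComp < -1e-10)) return("variance components must be >= 0")
  TRUE
})

#' Adjusted entry means with their estimation covariance
#'
#' One adjusted entry mean (AEM) per clone for a single response and
#' scope, together with the covariance matrix of the clone BLUEs needed
#' for the mean variance of a difference in the heritability formula.
#'
#' @slot values named numeric vector, one AEM per estimable clone.
#' @slot Vblue covariance matrix of the clone BLUEs (same order as values).
#' @slot response character, trait or channel-date id.
#' @slot scope character, e.g. "across", "single:W20", "loo:W20".
#' @export
setClass("AdjustedEntryMeans", representation(values = "numeric",
                                              Vblue = "matrix",
                                              response = "character",
                                              scope = "character"))

setValidity("AdjustedEntryMeans", function(object) {
  if (length(object@values) != nrow(object@Vblue))
    return("Vblue dimension must match number of clones")
  if (is.null(names(object@values))) return("AEMs must be named by clone")
  TRUE
})

#' Broad-sense heritability estimate
#'
#' Entry-mean basis uses H2 = sigma2g / (sigma2g + vbar/2), where vbar is
#' the mean variance of a difference between adjusted entry means; plot
#' basis uses sigma2g over the sum of all variance components.
#'
#' @slot sigma2g genotypic variance (trait units squared).
#' @slot vbar mean variance of a difference of AEMs (entry-mean basis;
#'   NA on plot basis).
#' @slot H2 heritability in [0, 1).
#' @slot basis "entry-mean" or "plot".
#' @slot response trait or channel id.
#' @export
setClass("HeritabilityEstimate", representation(sigma2g = "numeric",
                                                vbar = "numeric",
                                                H2 = "numeric",
                                                basis = "character",
                                                response = "character"))

setValidity("HeritabilityEstimate", function(object) {
  if (object@basis == "entry-mean" && !is.na(object@vbar) &&
      object@vbar > 0) {
    h <- object@sigma2g / (object@sigma2g + object@vbar / 2)
    if (abs(h - object@H2) > 1e-10)
      return("H2 must equal sigma2g/(sigma2g + vbar/2)")
  }
  TRUE
})

#' Prediction-scenario specification
#'
#' Describes one prediction case: which phenotype scope is predicted and
#' which relationship matrix predicts it.
#'
#' @slot id scenario family, one of "S1".."S7" or "S3b".
#' @slot phenoScope phenotype scope: an environment code, "across", or
#'   "loo:<env>" (AEMs excluding one environment).
#' @slot kernelSource kernel id: a spectral environment code, "cjM",
#'   "MAEM", "G", "G+D", "G+D+E", or "C".
#' @slot weight weight x of M when kernelSource is "C" (NA otherwise).
#' @export
setClass("ScenarioSpec", representation(id = "character",
                                        phenoScope = "character",
                                        kernelSource = "character",
                                        weight = "numeric"),
         prototype(weight = NA_real_))

#' Cross-validated prediction result
#'
#' @slot pa numeric vector of per-fold predictive abilities (Pearson r),
#'   NA where a fold's model failed; length n_folds * n_reps.
#' @slot medianPA median of non-missing PAs.
#' @slot meanPA mean of non-missing PAs.
#' @slot cv coefficient of variation of PAs in percent (100 * sd / mean).
#' @slot nMissing count of missing predictions.
#' @slot passedFilter quality-filter flag (|CV| <= 150 and <= 100 missing).
#' @slot scenario the ScenarioSpec (or a label) that produced the result.
#' @slot seed integer seed of the fold randomization.
#' @export
setClass("PredictionResult", representation(pa = "numeric",
                                            medianPA = "numeric",
                                            meanPA = "numeric",
                                            cv = "numeric",
                                            nMissing = "numeric",
                                            passedFilter = "logical",
                                            scenario = "ANY",
                                            seed = "numeric"))

setValidity("PredictionResult", function(object) {
  p <- object@pa[!is.na(object@pa)]
  if (length(p) && (min(p) < -1 - 1e-12 || max(p) > 1 + 1e-12))
    return("predictive abilities must lie in [-1, 1]")
  TRUE
})
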