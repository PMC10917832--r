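# Constructors, accessors and show methods for the core containers.

#' Construct a DosageMatrix
#'
#' @param x matrix of tetraploid dosages 0--4 (NA allowed), rows = clones,
#'   columns = markers.
#' @return A [DosageMatrix-class] object.
#' @examples
#' dm <- dosageMatrix(matrix(c(0, 2, 4, 1), 2, 2,
#'   dimnames = list(c("c1", "c2"), c("m1", "m2"))))
#' markerCount(dm)
#' @export
dosageMatrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  new("DosageMatrix", dosages = x)
}

#' @rdname dosageMatrix
#' @param object a DosageMatrix
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname dosageMatrix
#' @export
setMethod("dosages", "DosageMatrix", function(object) object@dosages)

#' @rdname dosageMatrix
#' @export
setGeneric("markerCount", function(object) standardGeneric("markerCount"))

#' @rdname dosageMatrix
#' @export
setMethod("markerCount", "DosageMatrix", function(object)
  ncol(object@dosages))

#' Clone identifiers of a container
#' @param object a DosageMatrix, SpectraMatrix, RelationshipMatrix or
#'   AdjustedEntryMeans object.
#' @return character vector of clone ids.
#' @export
setGeneric("cloneIds", function(object) standardGeneric("cloneIds"))

#' @rdname cloneIds
#' @export
setMethod("cloneIds", "DosageMatrix", function(object)
  rownames(object@dosages))

setMethod("show", "DosageMatrix", function(object) {
  cat("DosageMatrix:", nrow(object@dosages), "clones x",
      ncol(object@dosages), "markers;",
      sum(is.na(object@dosages)), "missing calls\n")
})

#' Construct a SpectraMatrix
#'
#' @param values numeric matrix, rows = clones (or plots), columns =
#'   channel/flight-date features; row and column names required.
#' @param colMeta data.frame with columns `env`, `date`, `channel`
#'   describing each column. Defaults to parsing column names of the
#'   form `env.Dx.channel`.
#' @return A [SpectraMatrix-class].
#' @export
spectraMatrix <- function(values, colMeta = NULL) {
  values <- as.matrix(values)
  if (is.null(colMeta)) {
    parts <- strsplit(colnames(values), ".", fixed = TRUE)
    colMeta <- data.frame(
      env = vapply(parts, function(p) p[1], ""),
      date = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
      channel = vapply(parts, function(p) if (length(p) > 2) p[3] else NA_character_, ""),
      stringsAsFactors = FALSE)
  }
  new("SpectraMatrix", values = values, colMeta = colMeta)
}

#' @rdname spectraMatrix
#' @param object a SpectraMatrix
#' @export
setGeneric("spectraValues", function(object) standardGeneric("spectraValues"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraValues", "SpectraMatrix", function(object) object@values)

#' @rdname spectraMatrix
#' @export
setGeneric("featureCount", function(object) standardGeneric("featureCount"))

#' Number of spectral features m_s (channel x flight-date columns)
#' @rdname spectraMatrix
#' @export
setMethod("featureCount", "SpectraMatrix", function(object)
  ncol(object@values))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMeta", function(object) standardGeneric("spectraMeta"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraMeta", "SpectraMatrix", function(object) object@colMeta)

#' @rdname cloneIds
#' @export
setMethod("cloneIds", "SpectraMatrix", function(object)
  rownames(object@values))

setMethod("show", "SpectraMatrix", function(object) {
  cat("SpectraMatrix:", nrow(object@values), "rows x",
      ncol(object@values), "features (m_s);",
      sum(is.na(object@values)), "missing cells\n")
})

#' Construct a RelationshipMatrix
#'
#' @param values symmetric PSD matrix with clone ids as dimnames.
#' @param kind kernel kind tag ("G","D","AA","AD","DD","M","cjM","MAEM","C").
#' @param provenance list of construction metadata.
#' @return A [RelationshipMatrix-class].
#' @export
relationshipMatrix <- function(values, kind, provenance = list()) {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2  # kill round-off asymmetry
  new("RelationshipMatrix", values = values, kind = kind,
      provenance = provenance)
}

#' @rdname relationshipMatrix
#' @param object a RelationshipMatrix
#' @export
setGeneric("relValues", function(object) standardGeneric("relValues"))

#' @rdname relationshipMatrix
#' @export
setMethod("relValues", "RelationshipMatrix", function(object) object@values)

#' @rdname relationshipMatrix
#' @export
setGeneric("kernelKind", function(object) standardGeneric("kernelKind"))

#' @rdname relationshipMatrix
#' @export
setMethod("kernelKind", "RelationshipMatrix", function(object) object@kind)

#' @rdname cloneIds
#' @export
setMethod("cloneIds", "RelationshipMatrix", function(object)
  rownames(object@values))

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix (", object@kind, "): ",
      nrow(object@values), " clones; mean diagonal ",
      signif(mean(diag(object@values)), 4), "\n", sep = "")
})

#' @rdname computeAems
#' @param object an AdjustedEntryMeans object
#' @export
setGeneric("aemValues", function(object) standardGeneric("aemValues"))

#' @rdname computeAems
#' @export
setMethod("aemValues", "AdjustedEntryMeans", function(object) object@values)

#' @rdname computeAems
#' @export
setGeneric("aemCovariance", function(object) standardGeneric("aemCovariance"))

#' @rdname computeAems
#' @export
setMethod("aemCovariance", "AdjustedEntryMeans", function(object)
  object@Vblue)

#' @rdname cloneIds
#' @export
setMethod("cloneIds", "AdjustedEntryMeans", function(object)
  names(object@values))

setMethod("show", "AdjustedEntryMeans", function(object) {
  cat("AdjustedEntryMeans:", object@response, "[", object@scope, "]",
      length(object@values), "clones\n")
})

#' @rdname fitReml
#' @param object an LmmFit
#' @export
setGeneric("varComp", function(object) standardGeneric("varComp"))

#' @rdname fitReml
#' @export
setMethod("varComp", "LmmFit", function(object) object@varComp)

#' @rdname fitReml
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname fitReml
#' @export
setMethod("fixedEffects", "LmmFit", function(object) object@beta)

#' @rdname fitReml
#' @export
setGeneric("ranefBlups", function(object) standardGeneric("ranefBlups"))

#' @rdname fitReml
#' @export
setMethod("ranefBlups", "LmmFit", function(object) object@blups)

#' @rdname fitReml
#' @export
setGeneric("logRestrictedLik", function(object)
  standardGeneric("logRestrictedLik"))

#' @rdname fitReml
#' @export
setMethod("logRestrictedLik", "LmmFit", function(object) object@logRL)

#' @rdname fitReml
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname fitReml
#' @export
setMethod("isConverged", "LmmFit", function(object) object@converged)

setMethod("show", "LmmFit", function(object) {
  cat("LmmFit (REML): logRL =", signif(object@logRL, 6),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(object@varComp, 4))
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat("H2[", object@response, ", ", object@basis, "] = ",
      signif(object@H2, 3), " (sigma2g = ", signif(object@sigma2g, 3),
      ", vbar = ", signif(object@vbar, 3), ")\n", sep = "")
})

#' @rdname crossValidate
#' @param object a PredictionResult
#' @export
setGeneric("predictiveAbilities", function(object)
  standardGeneric("predictiveAbilities"))

#' @rdname crossValidate
#' @export
setMethod("predictiveAbilities", "PredictionResult", function(object)
  object@pa)

#' @rdname crossValidate
#' @export
setGeneric("medianPA", function(object) standardGeneric("medianPA"))

#' @rdname crossValidate
#' @export
setMethod("medianPA", "PredictionResult", function(object) object@medianPA)

#' @rdname qualityFilter
#' @param object a PredictionResult
#' @export
setGeneric("passedFilter", function(object) standardGeneric("passedFilter"))

#' @rdname qualityFilter
#' @export
setMethod("passedFilter", "PredictionResult", function(object)
  object@passedFilter)

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult: median PA =", signif(object@medianPA, 3),
      "over", sum(!is.na(object@pa)), "folds;",
      object@nMissing, "missing;",
      if (isTRUE(object@passedFilter)) "passed" else "FAILED",
      "quality filter\n")
})
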