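# Relationship matrices: additive, dominance, epistatic, multispectral,
# column-joined / AEM-combined spectral sources, and weighted combinations.

#' Additive genomic relationship matrix
#'
#' `G = Z Z' / m` from the clones x markers dosage matrix, with `Z`
#' column-centered by the marker mean dosage by default (the VanRaden
#' convention); `center = FALSE` reproduces the raw cross-product form.
#' The denominator is the marker count `m`;
#' `normalize = "hetsum"` divides instead by the tetraploid
#' heterozygosity sum `sum(c_m * (4 - c_m) / 4)` of the marker mean
#' dosages c_m.
#'
#' @param Z a complete (post-QC) [DosageMatrix-class].
#' @param center center each marker by its mean dosage.
#' @param normalize "markers" (divide by m) or "hetsum".
#' @return A [RelationshipMatrix-class] of kind "G".
#' @examples
#' z <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' relValues(additiveKernel(dosageMatrix(z)))  # [[1,-1],[-1,1]]
#' @export
additiveKernel <- function(Z, center = TRUE,
                           normalize = c("markers", "hetsum")) {
  normalize <- match.arg(normalize)
  z <- dosages(Z)
  if (ncol(z) == 0) stop("no markers (m = 0)")
  if (anyNA(z)) stop("dosage matrix must be complete; run qcMarkers first")
  cm <- colMeans(z)
  if (center) z <- sweep(z, 2, cm)
  denom <- if (normalize == "markers") ncol(z) else
    sum(cm * (4 - cm) / 4)
  G <- tcrossprod(z) / denom
  relationshipMatrix(G, "G",
                     list(m = ncol(z), centered = center,
                          normalize = normalize))
}

#' Tetraploid digenic dominance relationship matrix
#'
#' Per marker the dominance covariate is the fraction of heterozygous
#' allele pairs among the C(4,2) = 6 pairings of the four alleles,
#' `w = d (4 - d) / 6` for dosage d (0 for the homozygotes, 4/6 for the
#' duplex class). Covariates are column-centered and `D = W W'` is
#' rescaled to mean diagonal 1.
#'
#' @param Z a complete [DosageMatrix-class].
#' @return A [RelationshipMatrix-class] of kind "D"; a zero matrix (with a
#'   warning) when every marker is monomorphic for the covariate.
#' @export
dominanceKernel <- function(Z) {
  z <- dosages(Z)
  if (anyNA(z)) stop("dosage matrix must be complete")
  W <- z * (4 - z) / 6
  W <- scale(W, center = TRUE, scale = FALSE)
  D <- tcrossprod(W)
  md <- mean(diag(D))
  if (md <= 0) {
    warning("no dominance variation: returning the zero matrix")
    D[] <- 0
  } else {
    D <- D / md
  }
  relationshipMatrix(D, "D", list(m = ncol(z)))
}

#' First-degree epistatic relationship matrices
#'
#' Element-wise (Hadamard) products of the additive and dominance kernels
#' -- additive x additive, additive x dominance, dominance x dominance --
#' each rescaled to mean diagonal 1 so variance components stay
#' comparable in the five-kernel model.
#'
#' @param G,D additive and dominance [RelationshipMatrix-class] objects on
#'   the same clones.
#' @return list with elements `AA`, `AD`, `DD`.
#' @export
epistaticKernels <- function(G, D) {
  g <- relValues(G); d <- relValues(D)
  if (!identical(rownames(g), rownames(d)))
    stop("G and D must be on identical clone sets")
  scaleDiag <- function(M, kind) {
    md <- mean(diag(M))
    if (md > 0) M <- M / md
    relationshipMatrix(M, kind, list())
  }
  list(AA = scaleDiag(g * g, "AA"),
       AD = scaleDiag(g * d, "AD"),
       DD = scaleDiag(d * d, "DD"))
}

#' Multispectral relationship matrix
#'
#' `M = S S' / m_s` where S holds clone-level channel x flight-date
#' adjusted entry means (scaled and centered, post-imputation) and m_s is
#' the number of spectral features.
#'
#' @param S a complete [SpectraMatrix-class] of clone-level features.
#' @param kind tag recording the source ("M", "cjM" or "MAEM").
#' @return A [RelationshipMatrix-class].
#' @export
spectralKernel <- function(S, kind = "M") {
  V <- spectraValues(S)
  if (ncol(V) == 0) stop("no spectral features (m_s = 0)")
  if (anyNA(V)) stop("spectral matrix must be complete before the kernel")
  M <- tcrossprod(V) / ncol(V)
  relationshipMatrix(M, kind,
                     list(m_s = ncol(V),
                          envs = unique(spectraMeta(S)$env)))
}

#' Combine spectra of two environments
#'
#' `cjM` column-joins the two clone-level feature matrices (m_s is the sum
#' of the two widths; for equal widths the resulting kernel is the average
#' of the two single-environment kernels). `MAEM` summarizes each
#' channel.date feature by its per-clone adjusted entry mean across the
#' two environments (the across-environment entry-mean model applied to
#' every channel.date of the plot-level spectra).
#'
#' @param S1,S2 clone-level [SpectraMatrix-class] objects (mode "cjM").
#' @param mode "cjM" or "MAEM".
#' @param spectraPlots long plot-level spectra table covering both
#'   environments (mode "MAEM").
#' @param includeColumn column random effect for the MAEM models.
#' @return A [SpectraMatrix-class].
#' @export
combineSpectra <- function(S1, S2 = NULL, mode = c("cjM", "MAEM"),
                           spectraPlots = NULL, includeColumn = TRUE) {
  mode <- match.arg(mode)
  if (mode == "MAEM") {
    if (is.null(spectraPlots))
      stop("mode 'MAEM' needs the plot-level spectra table")
    return(spectraAems(spectraPlots, scope = "across",
                       includeColumn = includeColumn))
  }
  v1 <- spectraValues(S1); v2 <- spectraValues(S2)
  shared <- intersect(rownames(v1), rownames(v2))
  if (length(shared) == 0) stop("no clones shared between the two spectra")
  m1 <- spectraMeta(S1); m2 <- spectraMeta(S2)
  cn1 <- paste0(m1$env, ".", colnames(v1))
  cn2 <- paste0(m2$env, ".", colnames(v2))
  V <- cbind(v1[shared, , drop = FALSE], v2[shared, , drop = FALSE])
  colnames(V) <- c(cn1, cn2)
  spectraMatrix(V, rbind(m1, m2))
}

#' Weighted combination of the spectral and genomic kernels
#'
#' `C = x M + (1 - x) G` for a weight x in [0, 1]; a convex combination
#' of PSD kernels, hence PSD.
#'
#' @param M,G [RelationshipMatrix-class] objects on identical clone sets.
#' @param x weight of M.
#' @return A [RelationshipMatrix-class] of kind "C" recording x.
#' @export
weightedKernel <- function(M, G, x) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("weight x must lie in [0, 1]")
  m <- relValues(M); g <- relValues(G)
  if (!identical(rownames(m), rownames(g)))
    stop("M and G must be on identical clone sets")
  relationshipMatrix(x * m + (1 - x) * g, "C", list(x = x))
}
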