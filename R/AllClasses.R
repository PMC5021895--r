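#' @useDynLib fuzzybias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Truncated Gaussian kernel
#'
#' Spatial weighting kernel for the local clustering criterion: a Gaussian
#' with standard deviation \code{sigma}, set to zero outside Chebyshev radius
#' \code{rho} and normalized to sum to one over the window.
#'
#' @slot sigma Gaussian standard deviation in pixels.
#' @slot rho truncation radius in pixels (the window spans \code{2*rho+1}
#'   samples per axis).
#' @slot weights the normalized weight array, dimension
#'   \code{rep(2*rho+1, ndim)}.
#' @seealso [truncatedGaussianKernel()], [localWeightedSum()]
#' @export
setClass("GaussianKernel",
  representation(sigma = "numeric", rho = "integer", weights = "array"))

setValidity("GaussianKernel", function(object) {
  w <- object@weights
  if (any(w < 0)) return("kernel weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-10) return("kernel weights must sum to 1")
  if (any(dim(w) != 2L * object@rho + 1L))
    return("weight array dimension must be 2*rho+1 per axis")
  TRUE
})

#' Nonlocal similarity weights
#'
#' Dense per-pixel table of nonlocal-means similarity weights
#' \eqn{S_{kl} = \exp(-\|patch_k - patch_l\|^2_\sigma / h)/Z_k} over the
#' search window of radius \code{u}. Row \code{k} holds the weights of pixel
#' \code{k}'s (clipped) search window; \code{index} holds the 1-based linear
#' pixel index of each neighbour (0 marks unused columns at borders).
#' Intended for small images; the segmentation pipeline never materializes
#' this table.
#'
#' @slot weights numeric matrix, one row per pixel.
#' @slot index integer matrix matching \code{weights}.
#' @slot h similarity decay constant.
#' @slot s patch radius. @slot u search radius.
#' @slot dim image dimension.
#' @export
setClass("SimilarityWeights",
  representation(weights = "matrix", index = "matrix", h = "numeric",
                 s = "integer", u = "integer", dim = "integer"))

setValidity("SimilarityWeights", function(object) {
  live <- object@index > 0L
  if (any(object@weights[live] <= 0) || any(object@weights[live] >= 1))
    return("stored similarity weights must lie strictly in (0, 1)")
  rs <- rowSums(object@weights)
  if (any(abs(rs - 1) > 1e-8))
    return("per-pixel similarity weights must sum to 1")
  TRUE
})

#' Segmentation result
#'
#' Output container of the clustering models: hard labels (argmax
#' membership), fuzzy memberships, cluster prototypes, the estimated
#' multiplicative bias field, the bias-corrected image, and the objective
#' trace across update sweeps.
#'
#' @slot labels integer array of hard class labels (0 = outside mask).
#' @slot memberships numeric array, image dimensions plus a trailing
#'   cluster dimension; per-pixel rows sum to 1 inside the mask.
#' @slot prototypes numeric vector of cluster centre intensities
#'   (ascending at initialization).
#' @slot biasField numeric array, the multiplicative field b (1 where the
#'   model does not estimate a bias).
#' @slot correctedImage numeric array x / b inside the mask.
#' @slot objective numeric vector, objective value after each sweep.
#' @slot iterations number of completed sweeps.
#' @slot converged whether the prototype-change criterion was met.
#' @slot method model name ("fcm", "bcfcm", "gifp", "clic", "proposed").
#' @slot parameters list of the parameters the run used (including seed).
#' @export
setClass("SegmentationResult",
  representation(labels = "array", memberships = "array",
                 prototypes = "numeric", biasField = "array",
                 correctedImage = "array", objective = "numeric",
                 iterations = "integer", converged = "logical",
                 method = "character", parameters = "list"))

setValidity("SegmentationResult", function(object) {
  nc <- length(object@prototypes)
  md <- dim(object@memberships)
  if (md[length(md)] != nc)
    return("last membership dimension must equal the number of clusters")
  u <- matrix(object@memberships, ncol = nc)
  inside <- object@labels > 0L
  if (any(u < -1e-8) || any(u > 1 + 1e-8))
    return("memberships must lie in [0, 1]")
  if (any(abs(rowSums(u)[inside] - 1) > 1e-6))
    return("memberships must sum to 1 per pixel inside the mask")
  if (any(object@biasField[inside] <= 0))
    return("bias field must be strictly positive inside the mask")
  TRUE
})

#' Synthetic phantom with ground truth
#'
#' A piecewise-constant multi-tissue image X0, a smooth multiplicative bias
#' field b, and the observed image X = Rician(b * X0) at a stated percent
#' noise level, together with the true label map.
#'
#' @slot labels integer array of true class labels (1..c).
#' @slot cleanImage the piecewise-constant image X0.
#' @slot trueBias the applied bias field (1 everywhere when bias = "none").
#' @slot observed the observed image X.
#' @slot classMeans per-class intensities of X0 (strictly increasing).
#' @slot noiseLevel Rician noise level, percent of the brightest class mean.
#' @slot spec list of generator settings (geometry, bias model, seed, ...).
#' @export
setClass("PhantomTruth",
  representation(labels = "array", cleanImage = "array", trueBias = "array",
                 observed = "array", classMeans = "numeric",
                 noiseLevel = "numeric", spec = "list"))

setValidity("PhantomTruth", function(object) {
  if (is.unsorted(object@classMeans, strictly = TRUE))
    return("class means must be strictly increasing")
  if (!all(seq_along(object@classMeans) %in% object@labels))
    return("every class must occupy at least one pixel")
  if (any(object@trueBias <= 0)) return("bias field must be positive")
  TRUE
})

#' Jaccard evaluation report
#'
#' Per-class Jaccard similarity after optimal cluster-to-truth label
#' matching, the matched permutation, and (when ground truth carries a bias
#' field) the Pearson correlation between estimated and true bias.
#'
#' @slot js per-class Jaccard similarity values in [0, 1].
#' @slot permutation integer permutation: predicted label i was matched to
#'   truth label \code{permutation[i]}.
#' @slot meanJS mean of the per-class values.
#' @slot biasCorrelation Pearson r between mean-one-normalized estimated and
#'   true bias (NA when unavailable).
#' @export
setClass("JSReport",
  representation(js = "numeric", permutation = "integer", meanJS = "numeric",
                 biasCorrelation = "numeric"))

setValidity("JSReport", function(object) {
  if (any(object@js < -1e-12 | object@js > 1 + 1e-12))
    return("Jaccard values must lie in [0, 1]")
  TRUE
})
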