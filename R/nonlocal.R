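# Nonlocal-means machinery: ring-weighted patch profile, patch distances,
# similarity weights over a search window, and the nonlocal mean image.

.imgdims <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L)
    stop("image must be a matrix or a 2D/3D array")
  if (length(d) > 3L) stop("only 2D and 3D images are supported")
  as.integer(c(d, rep(1L, 3L - length(d))))
}

.checkIndex <- function(idx, dims, what) {
  if (length(idx) < length(dims)) idx <- c(idx, rep(1L, length(dims) - length(idx)))
  if (any(idx < 1L) || any(idx > dims))
    stop(sprintf("%s index out of range", what))
  as.integer(idx)
}

#' Ring weights of the patch similarity profile
#'
#' Per-ring weight \eqn{\sigma(d) = \sum_{v=\max(d,1)}^{s} 1/((2v+1)^2 s)}
#' for Chebyshev rings \eqn{d = 0, \ldots, s} of a patch of radius s.
#' Internal building block of [patchSigmaProfile()].
#'
#' @param s patch radius (integer >= 1).
#' @return numeric vector of length \code{s + 1}; element \code{d + 1} is the
#'   weight of every patch element at Chebyshev distance \code{d} from the
#'   patch centre.
#' @keywords internal
ringWeights <- function(s) {
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L)
    stop("patch radius s must be an integer >= 1")
  vapply(0:s, function(d) {
    v <- seq.int(max(d, 1L), s)
    sum(1 / ((2 * v + 1)^2 * s))
  }, numeric(1))
}

#' Gaussian-weighted patch profile
#'
#' The per-element weights \eqn{\sigma^{(p)}} of the patch-distance measure:
#' every element of the \eqn{(2s+1)^d} patch window receives the weight of
#' its Chebyshev ring, \eqn{\sigma^{(p)} = \sum_{v=\max(d_p,1)}^{s}
#' 1/((2v+1)^2 s)}, where \eqn{d_p} is the element's Chebyshev distance from
#' the patch centre (coordinates taken 1-based in \code{1..2s+1}). In 2D the
#' weights sum to one; in 3D the same per-ring weight is applied ring-wise.
#'
#' @param s patch radius (integer >= 1).
#' @param ndim image dimensionality, 2 (default) or 3.
#' @return numeric array of dimension \code{rep(2s+1, ndim)} of non-negative
#'   weights, non-increasing in ring index.
#' @examples
#' patchSigmaProfile(1)          # all 9 weights equal 1/9
#' sum(patchSigmaProfile(2))     # 1
#' @export
patchSigmaProfile <- function(s, ndim = 2) {
  if (!ndim %in% c(2, 3)) stop("ndim must be 2 or 3")
  rw <- ringWeights(s)
  side <- 2 * s + 1
  ax <- abs(seq_len(side) - s - 1L)
  if (ndim == 2) {
    d <- outer(ax, ax, pmax)
  } else {
    d <- outer(outer(ax, ax, pmax), ax, pmax)
  }
  array(rw[d + 1L], dim = rep(side, ndim))
}

#' Gaussian-weighted squared patch distance
#'
#' Distance between the patches of radius \code{s} centred at pixels
#' \code{k} and \code{l}: \eqn{\sum_p \sigma^{(p)} (x^{(p)}(N_k) -
#' x^{(p)}(N_l))^2}. Patches crossing the image border are mirror-padded.
#'
#' @param image numeric matrix or 3D array.
#' @param k,l integer coordinate vectors (row, col[, slice]), 1-based.
#' @param s patch radius.
#' @return a non-negative scalar, symmetric in (k, l).
#' @export
patchDistance <- function(image, k, l, s = 3) {
  dims <- .imgdims(image)
  rw <- ringWeights(s)
  k <- .checkIndex(k, dims, "k")
  l <- .checkIndex(l, dims, "l")
  cpp_patch_distance(as.double(image), dims, k - 1L, l - 1L, as.integer(s), rw)
}

# Robust image noise estimate: MAD of mirror-padded Laplacian-of-image
# residuals (Immerkaer's 3x3 operator, coefficient norm 6), applied
# slice-wise for volumes.
estimateNoiseSd <- function(image) {
  dims <- .imgdims(image)
  L <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  res <- cpp_local_weighted_sum(as.double(image), dims, as.double(L),
                                c(1L, 1L, 0L))
  stats::mad(res, center = 0) / 6
}

# Default decay constant: twice the estimated noise variance. Because the
# patch profile weights sum to one, the expected profile-weighted distance
# between two patches differing only by noise is 2*sigma^2 regardless of
# patch size, so this sets the decay at the noise floor.
.autoH <- function(image, s, ndim) {
  sig <- estimateNoiseSd(image)
  max(2 * sig^2, 1e-12)
}

#' Nonlocal similarity weights
#'
#' Computes \eqn{S_{kl} = \exp(-\|x(N_k) - x(N_l)\|^2_\sigma / h) / Z_k}
#' for every pixel k over its search window of radius \code{u} (clipped at
#' the image border; the pixel itself is included). \eqn{Z_k} normalizes
#' each pixel's weights to sum to one.
#'
#' The dense weight table grows as \eqn{N (2u+1)^d}; this constructor is
#' meant for inspection and testing on small images. The segmentation
#' pipeline computes the nonlocal mean directly without storing weights.
#'
#' @param image numeric matrix or 3D array.
#' @param s patch radius (default 3).
#' @param u search-window radius (default 10).
#' @param h decay constant; when \code{NULL}, set to
#'   \eqn{2 \hat\sigma^2 (2s+1)^d} from a MAD-of-Laplacian noise estimate.
#' @return a [SimilarityWeights-class] object.
#' @export
similarityWeights <- function(image, s = 3, u = 10, h = NULL) {
  dims <- .imgdims(image)
  ndim <- if (dims[3] > 1L) 3L else 2L
  if (u < 1) stop("search radius u must be >= 1")
  if (is.null(h)) h <- .autoH(image, s, ndim)
  if (h <= 0) stop("decay constant h must be > 0")
  out <- cpp_nlm(as.double(image), dims, as.integer(s), as.integer(u),
                 h, ringWeights(s), TRUE)
  new("SimilarityWeights", weights = out$weights, index = out$index,
      h = h, s = as.integer(s), u = as.integer(u), dim = dims)
}

#' Nonlocal mean image
#'
#' Per-pixel weighted average \eqn{\bar x_k = \sum_{l \in w_k^u} S_{kl} x_l}
#' using the nonlocal similarity weights of [similarityWeights()]. Each
#' value is a convex combination of the window's intensities.
#'
#' @inheritParams similarityWeights
#' @return numeric array of the same dimension as \code{image}. When
#'   \code{u = 0} the image is returned unchanged.
#' @export
nonlocalMeanImage <- function(image, s = 3, u = 10, h = NULL) {
  dims <- .imgdims(image)
  ndim <- if (dims[3] > 1L) 3L else 2L
  if (u == 0) return(image)
  if (u < 0) stop("search radius u must be >= 0")
  if (is.null(h)) h <- .autoH(image, s, ndim)
  if (h <= 0) stop("decay constant h must be > 0")
  out <- cpp_nlm(as.double(image), dims, as.integer(s), as.integer(u),
                 h, ringWeights(s), FALSE)
  array(out$xbar, dim = dim(image))
}
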