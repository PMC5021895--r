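# Truncated Gaussian kernel and the windowed weighted-sum operator used by
# the local clustering criterion.

#' Truncated Gaussian kernel
#'
#' \eqn{K(y) = a^{-1} \exp(-\|y\|^2 / 2\sigma^2)} for \eqn{\|y\|_\infty \le
#' \rho}, zero outside, with \eqn{a} chosen so the window sums to one. The
#' window is the square (cube) of side \code{2*rho+1} centred on the pixel.
#'
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param rho truncation radius in pixels (integer >= 1).
#' @param ndim 2 (default) or 3.
#' @return a [GaussianKernel-class] object.
#' @examples
#' k <- truncatedGaussianKernel(sigma = 2, rho = 4)
#' sum(k@weights)  # 1
#' @export
truncatedGaussianKernel <- function(sigma, rho, ndim = 2) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 1L) stop("rho must be an integer >= 1")
  if (!ndim %in% c(2, 3)) stop("ndim must be 2 or 3")
  ax <- (-rho):rho
  if (ndim == 2) {
    r2 <- outer(ax^2, ax^2, `+`)
  } else {
    r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  }
  w <- exp(-r2 / (2 * sigma^2))
  w <- array(w / sum(w), dim = rep(2L * rho + 1L, ndim))
  new("GaussianKernel", sigma = sigma, rho = rho, weights = w)
}

# Identity ("delta") kernel: makes the local criterion collapse to the
# pixel-wise one. Used by the reduction lattice (CLIC -> GIFP -> FCM).
.deltaKernel <- function(ndim = 2) {
  w <- array(0, dim = rep(3L, ndim))
  w[matrix(2L, 1L, ndim)] <- 1
  new("GaussianKernel", sigma = 1e-6, rho = 1L, weights = w)
}

#' Windowed weighted sum (local kernel smoothing)
#'
#' \eqn{(K \circledast f)_k = \sum_{r \in \Omega_k} K(r - k) f_r} with
#' mirror padding at the image border. Linear in \code{f}; preserves
#' constants because the kernel is normalized.
#'
#' @param field numeric matrix or 3D array on the image grid.
#' @param kernel a [GaussianKernel-class] (see
#'   [truncatedGaussianKernel()]).
#' @return numeric array of the same dimension as \code{field}.
#' @export
localWeightedSum <- function(field, kernel) {
  stopifnot(is(kernel, "GaussianKernel"))
  dims <- .imgdims(field)
  kd <- dim(kernel@weights)
  ndim <- length(kd)
  if ((dims[3] > 1L) != (ndim == 3L))
    stop("kernel dimensionality does not match the field")
  khalf <- as.integer((kd - 1L) / 2L)
  if (ndim == 2L) khalf <- c(khalf, 0L)
  out <- cpp_local_weighted_sum(as.double(field), dims,
                                as.double(kernel@weights), khalf)
  array(out, dim = dim(field))
}
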