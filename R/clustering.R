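# Baseline clustering models: standard FCM, FCM with spatial neighbourhood
# regularization (BCFCM), FCM with improved fuzzy partitions (GIFP_FCM),
# and kernel-weighted local intensity clustering (CLIC).

# standard FCM: alternating u/v updates on raw intensities
.fcmLoop <- function(x, dims, c, m, v, tol, maxIter, mask) {
  w <- as.double(mask)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (t in seq_len(maxIter)) {
    D <- outer(x, v, function(xx, vv) (xx - vv)^2)
    u <- .membershipFromDistances(D, m)
    um <- u^m * w
    vNew <- colSums(um * x) / colSums(um)
    bad <- which(!is.finite(vNew))
    if (length(bad)) {
      warning("re-seeding ", length(bad), " empty cluster(s)")
      vNew[bad] <- x[order(apply(u, 1, max))[seq_along(bad)]]
    }
    D <- outer(x, vNew, function(xx, vv) (xx - vv)^2)
    obj <- c(obj, sum(w * u^m * D))
    dv <- max(abs(vNew - v))
    v <- vNew
    iter <- t
    if (dv < tol) { converged <- TRUE; break }
  }
  list(u = u, v = v, b = rep(1, length(x)), objective = obj,
       iterations = iter, converged = converged)
}

# GIFP_FCM: distances offset by a_k = alpha * min_i ||x_k - v_i||^2, which
# sharpens memberships; prototypes as plain fuzzy means
.gifpLoop <- function(x, dims, c, m, alpha, v, tol, maxIter, mask) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  w <- as.double(mask)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (t in seq_len(maxIter)) {
    D <- outer(x, v, function(xx, vv) (xx - vv)^2)
    a <- alpha * do.call(pmin, lapply(asplit(D, 2), as.vector))
    u <- .membershipFromDistances(D - a, m)
    um <- u^m * w
    vNew <- colSums(um * x) / colSums(um)
    bad <- which(!is.finite(vNew))
    if (length(bad)) {
      warning("re-seeding ", length(bad), " empty cluster(s)")
      vNew[bad] <- x[order(apply(u, 1, max))[seq_along(bad)]]
    }
    # a is held fixed across the sweep so the recorded objective tracks the
    # same Lagrangian the u update minimized
    D <- outer(x, vNew, function(xx, vv) (xx - vv)^2)
    obj <- c(obj, sum(w * u^m * D) +
               sum(w * a * rowSums(u * (1 - u^(m - 1)))))
    dv <- max(abs(vNew - v))
    v <- vNew
    iter <- t
    if (dv < tol) { converged <- TRUE; break }
  }
  list(u = u, v = v, b = rep(1, length(x)), objective = obj,
       iterations = iter, converged = converged)
}

# BCFCM: neighbourhood term (alpha/N) sum_{r in Omega_k} ||x_r - v_i||^2
# over the (2*radius+1)^d window excluding the centre, mirror-padded.
# Realized through the neighbour sums S1 = sum x_r, S2 = sum x_r^2.
.bcfcmLoop <- function(x, dims, c, m, alpha, nbRadius, v, tol, maxIter, mask) {
  ndim <- if (dims[3] > 1L) 3L else 2L
  side <- 2L * nbRadius + 1L
  box <- array(1, dim = rep(side, ndim))
  box[matrix(nbRadius + 1L, 1L, ndim)] <- 0   # exclude the centre pixel
  nOmega <- sum(box)
  khalf <- rep(as.integer(nbRadius), ndim)
  if (ndim == 2L) khalf <- c(khalf, 0L)
  S1 <- cpp_local_weighted_sum(x, dims, as.double(box), khalf)
  S2 <- cpp_local_weighted_sum(x^2, dims, as.double(box), khalf)
  ratio <- alpha / nOmega
  w <- as.double(mask)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  distTerms <- function(v) {
    vapply(v, function(vi) (x - vi)^2 + ratio * (S2 - 2 * vi * S1 + nOmega * vi^2),
           numeric(length(x)))
  }
  for (t in seq_len(maxIter)) {
    u <- .membershipFromDistances(distTerms(v), m)
    um <- u^m * w
    vNew <- colSums(um * (x + ratio * S1)) / ((1 + alpha) * colSums(um))
    bad <- which(!is.finite(vNew))
    if (length(bad)) {
      warning("re-seeding ", length(bad), " empty cluster(s)")
      vNew[bad] <- x[order(apply(u, 1, max))[seq_along(bad)]]
    }
    obj <- c(obj, sum(w * u^m * distTerms(vNew)))
    dv <- max(abs(vNew - v))
    v <- vNew
    iter <- t
    if (dv < tol) { converged <- TRUE; break }
  }
  list(u = u, v = v, b = rep(1, length(x)), objective = obj,
       iterations = iter, converged = converged)
}

#' Standard fuzzy c-means
#'
#' Pixel-wise FCM on raw intensities: memberships \eqn{u_{ik} \propto
#' \|x_k - v_i\|^{-2/(m-1)}}, prototypes as fuzzy weighted means. Pixels
#' exactly at a prototype get crisp membership.
#'
#' @inheritParams segmentImage
#' @param ... passed on to [segmentImage()] (\code{epsilon},
#'   \code{maxIter}, \code{seed}, \code{mask}, \code{init}, ...).
#' @return a [SegmentationResult-class] (bias field identically 1).
#' @export
fcm <- function(image, clusters = 4, m = 2, ...) {
  segmentImage(image, method = "fcm", clusters = clusters, m = m, ...)
}

#' FCM with spatial neighbourhood regularization (BCFCM)
#'
#' Adds \eqn{(\alpha/N_\Omega) \sum_{r \in \Omega_k} \|x_r - v_i\|^2} over
#' a local window to every pixel's distance term; with \code{alphaBcfcm =
#' 0} this is exactly standard FCM.
#'
#' @inheritParams segmentImage
#' @param ... passed on to [segmentImage()].
#' @return a [SegmentationResult-class].
#' @export
bcfcm <- function(image, clusters = 4, m = 2, alphaBcfcm = 0.85, ...) {
  segmentImage(image, method = "bcfcm", clusters = clusters, m = m,
               alphaBcfcm = alphaBcfcm, ...)
}

#' FCM with improved fuzzy partitions (GIFP_FCM)
#'
#' Subtracts \eqn{a_k = \alpha \min_i \|x_k - v_i\|^2} from every cluster's
#' distance, which sharpens each pixel's membership towards its nearest
#' prototype; \eqn{\alpha \to 0} recovers standard FCM.
#'
#' @inheritParams segmentImage
#' @param ... passed on to [segmentImage()].
#' @return a [SegmentationResult-class].
#' @export
gifpFcm <- function(image, clusters = 4, m = 2, alpha = 0.9, ...) {
  segmentImage(image, method = "gifp", clusters = clusters, m = m,
               alpha = alpha, ...)
}

#' Kernel-weighted local intensity clustering with bias field (CLIC)
#'
#' Minimizes \eqn{\sum_i \sum_k u_{ik}^m \sum_{r \in \Omega_k}
#' K(r-k)\|x_k - b_r v_i\|^2}: the joint model with the nonlocal weight
#' \eqn{\beta \equiv 0} and sharpening \eqn{a \equiv 0}, whose updates
#' coincide with CLIC's.
#'
#' @inheritParams segmentImage
#' @param ... passed on to [segmentImage()].
#' @return a [SegmentationResult-class] with an estimated bias field.
#' @export
clic <- function(image, clusters = 4, m = 2, kernelSigma = NULL,
                 kernelRho = 4, ...) {
  segmentImage(image, method = "clic", clusters = clusters, m = m,
               kernelSigma = kernelSigma, kernelRho = kernelRho, ...)
}
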