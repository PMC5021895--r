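# The joint segmentation / bias-field model: adaptive local-nonlocal fuzzy
# objective with a coupled multiplicative bias field, plus the exported
# single-update building blocks.
#
# Per sweep (u -> v -> b) all kernel-weighted sums over the bias are
# realized through the smoothed fields K*b and K*b^2:
#   sum_r K(r-k) ||x_k - b_r v_i||^2
#     = x_k^2 - 2 x_k v_i (K*b)_k + v_i^2 (K*b^2)_k
# so each update is exact for the objective with b varying inside the
# window.

.CLAMP <- 1e-12

# membership from per-cluster bracket terms (rows = pixels); brackets at or
# below the clamp get crisp membership, split equally among ties
.membershipFromDistances <- function(D, m, clamp = .CLAMP) {
  E <- pmax(D, clamp)^(-1 / (m - 1))
  u <- E / rowSums(E)
  hit <- D <= clamp
  rows <- which(rowSums(hit) > 0L)
  if (length(rows)) {
    h <- hit[rows, , drop = FALSE]
    u[rows, ] <- h / rowSums(h)
  }
  u
}

# kernel-weighted sum on a flat vector; NULL kernel means the identity
# (delta) operator
.lws <- function(f, dims, kernel) {
  if (is.null(kernel)) return(f)
  kd <- dim(kernel@weights)
  khalf <- as.integer((kd - 1L) / 2L)
  if (length(khalf) == 2L) khalf <- c(khalf, 0L)
  cpp_local_weighted_sum(as.double(f), dims, as.double(kernel@weights), khalf)
}

# per-cluster bracket terms of the membership update (without -a_k):
# local + beta * nonlocal kernel-weighted squared residuals
.bracketTerms <- function(x, v, Kb, Kb2, xbar, beta) {
  c <- length(v)
  D <- matrix(0, length(x), c)
  for (i in seq_len(c)) {
    loc <- x^2 - 2 * x * v[i] * Kb + v[i]^2 * Kb2
    nl  <- xbar^2 - 2 * xbar * v[i] * Kb + v[i]^2 * Kb2
    D[, i] <- loc + beta * nl
  }
  D
}

#' Adaptive local/global weight field
#'
#' Per-pixel balance \eqn{\beta_k = (\max w_k^u - \min w_k^u) / \max
#' w_k^u} between the local coupling term and the nonlocal regularization
#' term, computed over the search window of radius \code{u} (clipped at the
#' border). Defined as 0 on windows with \eqn{\max w_k^u = 0} or constant
#' intensity, so flat regions rely purely on the local term.
#'
#' @param image non-negative numeric matrix or 3D array.
#' @param u search-window radius (default 10).
#' @return numeric array in [0, 1] with the image's dimensions.
#' @export
computeBeta <- function(image, u = 10) {
  dims <- .imgdims(image)
  rng <- cpp_window_range(as.double(image), dims, as.integer(u))
  beta <- ifelse(rng$max > 0, (rng$max - rng$min) / rng$max, 0)
  array(beta, dim = dim(image))
}

#' Membership-sharpening offset a_k
#'
#' The improved-fuzzy-partition offset \eqn{a_k = \alpha \min_i \|x_k -
#' v_i\|^2} subtracted from every cluster's distance term, which pushes each
#' pixel's membership towards its nearest prototype. Computed on raw
#' intensities and recomputed whenever the prototypes change.
#'
#' @param image numeric matrix or 3D array.
#' @param prototypes numeric vector of cluster centres.
#' @param alpha sharpening strength, strictly inside (0, 1).
#' @return numeric array of per-pixel offsets.
#' @export
computeAk <- function(image, prototypes, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  D <- outer(as.vector(image), prototypes, function(x, v) (x - v)^2)
  array(alpha * do.call(pmin, lapply(asplit(D, 2), as.vector)), dim = dim(image))
}

.asMembershipArray <- function(u, image) {
  array(u, dim = c(dim(image), ncol(u)))
}

.asMembershipMatrix <- function(memberships, image) {
  nc <- length(memberships) / length(image)
  matrix(memberships, ncol = nc)
}

#' Membership update of the joint model
#'
#' One closed-form membership sweep: \eqn{u_{ik} \propto [\sum_{r}
#' K(r-k)\|x_k - b_r v_i\|^2 + \beta_k \sum_r K(r-k) \|\bar x_k - b_r
#' v_i\|^2 - a_k]^{-1/(m-1)}}, normalized over clusters. Brackets at or
#' below 1e-12 (possible because \eqn{a_k} is subtracted) receive crisp
#' membership, split equally among tied clusters.
#'
#' @param image numeric matrix or 3D array.
#' @param prototypes numeric vector of cluster centres.
#' @param biasField multiplicative bias field array (use 1 when none).
#' @param kernel a [GaussianKernel-class], or \code{NULL} for the identity
#'   (pixel-wise) kernel.
#' @param m fuzzifier (> 1), default 2.
#' @param xbar nonlocal mean image; defaults to \code{image} (only relevant
#'   where \code{beta > 0}).
#' @param beta adaptive weight array; default 0 (local model).
#' @param ak sharpening offset array; default 0.
#' @return membership array with dimensions \code{c(dim(image), c)}.
#' @export
updateMembership <- function(image, prototypes, biasField, kernel = NULL,
                             m = 2, xbar = image, beta = 0, ak = 0) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  dims <- .imgdims(image)
  x <- as.double(image)
  Kb <- .lws(as.double(biasField), dims, kernel)
  Kb2 <- .lws(as.double(biasField)^2, dims, kernel)
  D <- .bracketTerms(x, prototypes, Kb, Kb2, as.double(xbar), as.double(beta))
  D <- D - as.double(ak)
  .asMembershipArray(.membershipFromDistances(D, m), image)
}

#' Prototype update of the joint model
#'
#' Closed-form centre update \eqn{v_i = \sum_k u_{ik}^m (x_k + \beta_k \bar
#' x_k)(K \circledast b)_k / \sum_k u_{ik}^m (1 + \beta_k)(K \circledast
#' b^2)_k}. A cluster whose denominator vanishes (empty cluster) is
#' re-seeded from the pixel with the lowest maximum membership, with a
#' warning.
#'
#' @inheritParams updateMembership
#' @param memberships membership array from [updateMembership()].
#' @param mask optional logical array restricting the sums.
#' @return numeric vector of updated prototypes.
#' @export
updatePrototypes <- function(image, memberships, biasField, kernel = NULL,
                             m = 2, xbar = image, beta = 0, mask = NULL) {
  dims <- .imgdims(image)
  x <- as.double(image)
  u <- .asMembershipMatrix(memberships, image)
  w <- if (is.null(mask)) 1 else as.double(mask)
  Kb <- .lws(as.double(biasField), dims, kernel)
  Kb2 <- .lws(as.double(biasField)^2, dims, kernel)
  beta <- as.double(beta)
  xbar <- as.double(xbar)
  um <- u^m * w
  num <- colSums(um * ((x + beta * xbar) * Kb))
  den <- colSums(um * ((1 + beta) * Kb2))
  v <- num / den
  bad <- which(!is.finite(v) | den <= .CLAMP)
  if (length(bad)) {
    warning("re-seeding ", length(bad), " empty cluster(s)")
    worst <- order(apply(u, 1, max))[seq_along(bad)]
    v[bad] <- x[worst]
  }
  v
}

#' Bias-field update of the joint model
#'
#' Closed-form multiplicative-field update
#' \eqn{b_k = \sum_i v_i [K \circledast (u_i^m (x + \beta \bar x))]_k /
#' \sum_i v_i^2 [K \circledast (u_i^m (1 + \beta))]_k}. Because b and the
#' prototypes enter the objective only through their product, \code{normalize
#' = TRUE} rescales b to mean one over the mask; callers rescale the
#' prototypes by the removed mean so the products are unchanged.
#'
#' @inheritParams updatePrototypes
#' @param prototypes current cluster centres.
#' @param normalize rescale the field to mean 1 over the mask.
#' @return list with the field array (\code{bias}) and the removed mean
#'   (\code{scale}, 1 when \code{normalize = FALSE}).
#' @export
updateBias <- function(image, memberships, prototypes, kernel = NULL, m = 2,
                       xbar = image, beta = 0, mask = NULL, normalize = FALSE) {
  dims <- .imgdims(image)
  x <- as.double(image)
  u <- .asMembershipMatrix(memberships, image)
  w <- if (is.null(mask)) rep(1, length(x)) else as.double(mask)
  beta <- as.double(beta)
  xbar <- as.double(xbar)
  num <- den <- numeric(length(x))
  for (i in seq_along(prototypes)) {
    um <- u[, i]^m * w
    num <- num + prototypes[i] * .lws(um * (x + beta * xbar), dims, kernel)
    den <- den + prototypes[i]^2 * .lws(um * (1 + beta), dims, kernel)
  }
  inside <- w > 0
  if (any(den[inside] <= .CLAMP)) {
    k <- which(inside & den <= .CLAMP)[1]
    stop("bias denominator vanished near pixel ", k,
         " (prototypes all ~0 there?)")
  }
  b <- rep(1, length(x))
  b[inside] <- num[inside] / den[inside]
  scale <- 1
  if (normalize) {
    scale <- mean(b[inside])
    b[inside] <- b[inside] / scale
  }
  list(bias = array(b, dim = dim(image)), scale = scale)
}

#' Joint objective value
#'
#' Evaluates \deqn{J_m = \sum_i \sum_k u_{ik}^m \sum_r K(r-k)\|x_k - b_r
#' v_i\|^2 + \sum_k a_k \sum_i u_{ik}(1 - u_{ik}^{m-1}) + \sum_i \sum_k
#' \beta_k u_{ik}^m \sum_r K(r-k)\|\bar x_k - b_r v_i\|^2.} With \code{beta
#' = 0} and \code{ak = 0} this is exactly the kernel-weighted local
#' clustering (CLIC) criterion.
#'
#' @inheritParams updatePrototypes
#' @param prototypes current cluster centres.
#' @param ak sharpening offset array (0 disables the term).
#' @return a finite scalar.
#' @export
jointObjective <- function(image, memberships, prototypes, biasField,
                           kernel = NULL, m = 2, xbar = image, beta = 0,
                           ak = 0, mask = NULL) {
  dims <- .imgdims(image)
  x <- as.double(image)
  u <- .asMembershipMatrix(memberships, image)
  w <- if (is.null(mask)) 1 else as.double(mask)
  Kb <- .lws(as.double(biasField), dims, kernel)
  Kb2 <- .lws(as.double(biasField)^2, dims, kernel)
  beta <- as.double(beta)
  xbar <- as.double(xbar)
  ak <- as.double(ak)
  J <- 0
  for (i in seq_along(prototypes)) {
    loc <- x^2 - 2 * x * prototypes[i] * Kb + prototypes[i]^2 * Kb2
    nl  <- xbar^2 - 2 * xbar * prototypes[i] * Kb + prototypes[i]^2 * Kb2
    J <- J + sum(w * u[, i]^m * (loc + beta * nl))
    J <- J + sum(w * ak * u[, i] * (1 - u[, i]^(m - 1)))
  }
  J
}

#' Bias-correct an image
#'
#' Divides the observed image by the estimated multiplicative field inside
#' the mask; pixels outside the mask are passed through unchanged.
#'
#' @param image numeric matrix or 3D array.
#' @param biasField strictly positive field inside the mask.
#' @param mask optional logical array.
#' @return corrected image array.
#' @export
correctImage <- function(image, biasField, mask = NULL) {
  if (!identical(dim(image), dim(biasField)))
    stop("image and bias field dimensions differ")
  inside <- if (is.null(mask)) rep(TRUE, length(image)) else as.vector(mask)
  if (any(biasField[inside] <= 0))
    stop("bias field must be strictly positive inside the mask")
  out <- as.double(image)
  out[inside] <- out[inside] / as.double(biasField)[inside]
  array(out, dim = dim(image))
}

# k-means++ seeding followed by Lloyd iterations on the (masked) intensities
.initPrototypes <- function(x, c, seed) {
  if (length(unique(x)) < c)
    stop("degenerate image: fewer than ", c, " distinct intensities")
  set.seed(seed)
  centers <- numeric(c)
  centers[1] <- x[sample.int(length(x), 1L)]
  for (i in seq_len(c - 1L)) {
    d2 <- apply(outer(x, centers[seq_len(i)], function(a, b) (a - b)^2), 1, min)
    if (sum(d2) <= 0) {
      centers[i + 1L] <- x[sample.int(length(x), 1L)]
    } else {
      centers[i + 1L] <- x[sample.int(length(x), 1L, prob = d2)]
    }
  }
  km <- suppressWarnings(
    stats::kmeans(x, centers = matrix(unique(centers), ncol = 1),
                  iter.max = 100))
  cen <- as.vector(km$centers)
  # guard against collapsed seeds
  while (length(cen) < c) cen <- c(cen, max(x) * stats::runif(1))
  sort(cen)
}

# Full iteration driver for the kernel-coupled models (proposed, CLIC).
.jointEngine <- function(x, dims, c, m, alpha, kernel, useNonlocal,
                         estimateBias, normalizeBias, mask, v, tol, maxIter,
                         s, u, h) {
  N <- prod(dims)
  w <- as.double(mask)
  inside <- mask
  b <- rep(1, N)
  if (useNonlocal) {
    xbar <- as.double(nonlocalMeanImage(array(x, dim = dims[dims > 1L]),
                                        s = s, u = u, h = h))
    beta <- as.double(computeBeta(array(x, dim = dims[dims > 1L]), u = u))
  } else {
    xbar <- x
    beta <- rep(0, N)
  }
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  uM <- NULL
  for (t in seq_len(maxIter)) {
    Kb <- .lws(b, dims, kernel)
    Kb2 <- .lws(b^2, dims, kernel)
    a <- if (alpha > 0) {
      D0 <- outer(x, v, function(xx, vv) (xx - vv)^2)
      alpha * do.call(pmin, lapply(asplit(D0, 2), as.vector))
    } else rep(0, N)
    D <- .bracketTerms(x, v, Kb, Kb2, xbar, beta) - a
    uM <- .membershipFromDistances(D, m)
    um <- uM^m * w
    num <- colSums(um * ((x + beta * xbar) * Kb))
    den <- colSums(um * ((1 + beta) * Kb2))
    vNew <- num / den
    bad <- which(!is.finite(vNew) | den <= .CLAMP)
    if (length(bad)) {
      warning("re-seeding ", length(bad), " empty cluster(s)")
      worst <- order(apply(uM, 1, max))[seq_along(bad)]
      vNew[bad] <- x[worst]
    }
    # a is held fixed for the whole sweep (recomputed from the updated
    # prototypes at the start of the next one), so every update inside the
    # sweep is an exact coordinate minimization of the same Lagrangian
    if (estimateBias) {
      numB <- denB <- numeric(N)
      for (i in seq_len(c)) {
        umi <- uM[, i]^m * w
        numB <- numB + vNew[i] * .lws(umi * (x + beta * xbar), dims, kernel)
        denB <- denB + vNew[i]^2 * .lws(umi * (1 + beta), dims, kernel)
      }
      if (any(denB[inside] <= .CLAMP))
        stop("bias denominator vanished near pixel ",
             which(inside & denB <= .CLAMP)[1])
      b[inside] <- numB[inside] / denB[inside]
      if (normalizeBias) {
        mu <- mean(b[inside])
        b[inside] <- b[inside] / mu
        vNew <- vNew * mu
      }
    }
    Kb <- .lws(b, dims, kernel)
    Kb2 <- .lws(b^2, dims, kernel)
    J <- 0
    for (i in seq_len(c)) {
      loc <- x^2 - 2 * x * vNew[i] * Kb + vNew[i]^2 * Kb2
      nl  <- xbar^2 - 2 * xbar * vNew[i] * Kb + vNew[i]^2 * Kb2
      J <- J + sum(w * uM[, i]^m * (loc + beta * nl)) +
        sum(w * a * uM[, i] * (1 - uM[, i]^(m - 1)))
    }
    obj <- c(obj, J)
    dv <- max(abs(vNew - v))
    v <- vNew
    iter <- t
    if (dv < tol) { converged <- TRUE; break }
  }
  list(u = uM, v = v, b = b, xbar = xbar, beta = beta, objective = obj,
       iterations = iter, converged = converged)
}

.buildResult <- function(image, mask, fit, method, params) {
  dims <- dim(image)
  u <- fit$u
  u[!mask, ] <- 0
  labels <- max.col(u, ties.method = "first")
  labels[!mask] <- 0L
  b <- fit$b
  b[!mask] <- 1
  corrected <- as.double(image)
  corrected[mask] <- corrected[mask] / b[mask]
  new("SegmentationResult",
      labels = array(as.integer(labels), dim = dims),
      memberships = array(u, dim = c(dims, ncol(u))),
      prototypes = as.numeric(fit$v),
      biasField = array(b, dim = dims),
      correctedImage = array(corrected, dim = dims),
      objective = fit$objective,
      iterations = as.integer(fit$iterations),
      converged = fit$converged,
      method = method,
      parameters = params)
}

#' Segment an image with joint bias-field estimation
#'
#' Runs one of the five clustering models on a 2D image or 3D volume:
#' \describe{
#'   \item{\code{"proposed"}}{the full joint model: truncated-Gaussian
#'     local coupling, nonlocal-means global constraint with per-pixel
#'     adaptive weight \eqn{\beta_k}, membership sharpening \eqn{a_k}, and
#'     a coupled multiplicative bias field.}
#'   \item{\code{"clic"}}{kernel-weighted local intensity clustering with
#'     bias field: the joint model with \eqn{\beta \equiv 0},
#'     \eqn{a \equiv 0}.}
#'   \item{\code{"fcm"}, \code{"bcfcm"}, \code{"gifp"}}{the classical
#'     baselines (see [fcm()], [bcfcm()], [gifpFcm()]).}
#' }
#' All models share the same seeded k-means++ prototype initialization,
#' start from bias \eqn{b_0 \equiv 1}, iterate membership, prototype and
#' (where applicable) bias updates, and stop when the maximum prototype
#' change falls below \code{epsilon}.
#'
#' @param image non-negative numeric matrix or 3D array.
#' @param method one of \code{"proposed"}, \code{"fcm"}, \code{"bcfcm"},
#'   \code{"gifp"}, \code{"clic"}.
#' @param clusters number of classes c (>= 2).
#' @param m fuzzifier (default 2).
#' @param alpha sharpening strength for the a_k term, in (0, 1)
#'   (default 0.9; used by \code{"proposed"} and \code{"gifp"}).
#' @param alphaBcfcm neighbour-term weight of BCFCM (default 0.85).
#' @param kernelSigma,kernelRho truncated-Gaussian kernel parameters
#'   (defaults \code{rho = 4}, \code{sigma = rho/2}).
#' @param patchRadius,searchRadius,h nonlocal-means parameters (defaults
#'   s = 3, u = 10, h auto from the noise estimate).
#' @param epsilon stop criterion on the maximum prototype change
#'   (default 0.001).
#' @param maxIter maximum update sweeps (default 100). Non-convergence
#'   returns the last state with a warning.
#' @param seed RNG seed for the shared k-means++ initialization.
#' @param mask optional logical array; pixels outside get label 0, bias 1.
#' @param normalizeBias rescale the bias field to mean one over the mask
#'   after each update (prototypes are rescaled back, so the objective is
#'   unchanged); default TRUE.
#' @param init optional numeric vector of initial prototypes (overrides the
#'   seeded initialization).
#' @return a [SegmentationResult-class].
#' @examples
#' ph <- makePhantom(shape = c(48, 48), classes = 3, noisePercent = 5,
#'                   biasModel = "gaussian-bump", biasAmplitude = 0.2,
#'                   seed = 7)
#' res <- segmentImage(observedImage(ph), method = "proposed", clusters = 3,
#'                     searchRadius = 5, seed = 7)
#' evaluate(res, ph)
#' @export
segmentImage <- function(image,
                         method = c("proposed", "fcm", "bcfcm", "gifp", "clic"),
                         clusters = 4, m = 2, alpha = 0.9, alphaBcfcm = 0.85,
                         kernelSigma = NULL, kernelRho = 4, patchRadius = 3,
                         searchRadius = 10, h = NULL, epsilon = 1e-3,
                         maxIter = 100, seed = 1, mask = NULL,
                         normalizeBias = TRUE, init = NULL) {
  method <- match.arg(method)
  dims <- .imgdims(image)
  if (clusters < 2) stop("clusters must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (any(image < 0)) stop("image intensities must be non-negative")
  if (is.null(mask)) mask <- rep(TRUE, length(image))
  mask <- as.vector(mask)
  x <- as.double(image)
  v0 <- if (is.null(init)) .initPrototypes(x[mask], clusters, seed) else sort(init)
  if (length(v0) != clusters) stop("init must supply one prototype per cluster")
  params <- list(method = method, clusters = clusters, m = m, alpha = alpha,
                 alphaBcfcm = alphaBcfcm, kernelSigma = kernelSigma,
                 kernelRho = kernelRho, patchRadius = patchRadius,
                 searchRadius = searchRadius, h = h, epsilon = epsilon,
                 maxIter = maxIter, seed = seed,
                 normalizeBias = normalizeBias, init = v0)

  fit <- switch(method,
    fcm = .fcmLoop(x, dims, clusters, m, v0, epsilon, maxIter, mask),
    gifp = .gifpLoop(x, dims, clusters, m, alpha, v0, epsilon, maxIter, mask),
    bcfcm = .bcfcmLoop(x, dims, clusters, m, alphaBcfcm, 1L, v0, epsilon,
                       maxIter, mask),
    clic = {
      if (is.null(kernelSigma)) kernelSigma <- kernelRho / 2
      ndim <- if (dims[3] > 1L) 3L else 2L
      kern <- truncatedGaussianKernel(kernelSigma, kernelRho, ndim)
      .jointEngine(x, dims, clusters, m, 0, kern, FALSE, TRUE, normalizeBias,
                   mask, v0, epsilon, maxIter, patchRadius, searchRadius, h)
    },
    proposed = {
      if (is.null(kernelSigma)) kernelSigma <- kernelRho / 2
      ndim <- if (dims[3] > 1L) 3L else 2L
      kern <- truncatedGaussianKernel(kernelSigma, kernelRho, ndim)
      .jointEngine(x, dims, clusters, m, alpha, kern, TRUE, TRUE,
                   normalizeBias, mask, v0, epsilon, maxIter, patchRadius,
                   searchRadius, h)
    })
  if (!fit$converged)
    warning(sprintf("%s did not converge within %d sweeps (max |dV| still >= %g)",
                    method, maxIter, epsilon))
  .buildResult(image, mask, fit, method, params)
}
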