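# Synthetic multi-tissue phantoms: piecewise-constant images, smooth
# multiplicative bias fields, and Rician noise at percent levels defined
# relative to the brightest class mean.

.normCoord <- function(n) if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)

#' Smooth multiplicative bias field
#'
#' Generates a smooth field with values inside \code{[1 - amplitude,
#' 1 + amplitude]} and mean ~1 over the grid:
#' \describe{
#'   \item{\code{"none"}}{identically 1.}
#'   \item{\code{"linear-ramp"}}{linear gradient along the main diagonal,
#'     hitting the extremes at opposite corners.}
#'   \item{\code{"gaussian-bump"}}{centred Gaussian bump, mean-removed and
#'     rescaled so the extreme deviation equals the amplitude.}
#'   \item{\code{"polynomial"}}{smooth low-order polynomial surface,
#'     mean-removed and rescaled likewise.}
#' }
#'
#' @param shape integer vector of grid dimensions (2D or 3D).
#' @param model one of \code{"none"}, \code{"linear-ramp"},
#'   \code{"gaussian-bump"}, \code{"polynomial"}.
#' @param amplitude maximum fractional deviation from 1, in [0, 0.8].
#' @return numeric array of dimension \code{shape}.
#' @export
makeBias <- function(shape, model = "gaussian-bump", amplitude = 0.2) {
  if (amplitude < 0 || amplitude > 0.8)
    stop("bias amplitude must lie in [0, 0.8]")
  shape <- as.integer(shape)
  ndim <- length(shape)
  if (!ndim %in% c(2, 3)) stop("shape must be 2D or 3D")
  if (model == "none" || amplitude == 0)
    return(array(1, dim = shape))
  cs <- lapply(shape, .normCoord)
  grid <- expand.grid(cs)
  g <- switch(model,
    "linear-ramp" = rowMeans(grid) * 2 - 1,
    "gaussian-bump" = {
      r2 <- rowSums((grid - 0.5)^2)
      exp(-r2 / (2 * 0.25^2))
    },
    "polynomial" = {
      a <- 2 * grid[[1]] - 1
      b <- 2 * grid[[2]] - 1
      a * b + 0.5 * a^2 - 0.3 * b + 0.2 * b^3
    },
    stop("unknown bias model: ", model))
  g <- g - mean(g)
  g <- g / max(abs(g))
  array(1 + amplitude * g, dim = shape)
}

#' Rician noise
#'
#' Applies magnitude-MR noise \eqn{\sqrt{(x + n_1)^2 + n_2^2}} with
#' \eqn{n_1, n_2} i.i.d. zero-mean Gaussian fields of standard deviation
#' \eqn{\sigma_N = (\mathrm{level}/100) \cdot I_{\mathrm{ref}}}. At zero
#' signal the output is Rayleigh-distributed; far above \eqn{\sigma_N} it
#' tends to additive Gaussian noise.
#'
#' @param image non-negative numeric array.
#' @param levelPercent noise level as a percentage of
#'   \code{referenceIntensity}.
#' @param referenceIntensity intensity defining 100 units of noise level;
#'   conventionally the brightest tissue mean (default \code{max(image)}).
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @return noisy image array, same dimensions.
#' @export
addRicianNoise <- function(image, levelPercent, referenceIntensity = max(image),
                           seed = 1) {
  if (levelPercent < 0) stop("noise level must be >= 0")
  if (levelPercent == 0) return(image)
  sigma <- levelPercent / 100 * referenceIntensity
  set.seed(seed)
  n1 <- stats::rnorm(length(image), sd = sigma)
  n2 <- stats::rnorm(length(image), sd = sigma)
  array(sqrt((as.double(image) + n1)^2 + n2^2), dim = dim(image))
}

# geometry presets -----------------------------------------------------

.geomNestedRings <- function(shape, c) {
  cs <- lapply(shape, function(n) seq_len(n) - (n + 1) / 2)
  grid <- expand.grid(cs)
  r <- sqrt(rowSums(grid^2))
  rmax <- min(shape) / 2
  lab <- pmin(floor(r / (rmax / c)) + 1, c)
  array(as.integer(lab), dim = shape)
}

.geomChecker <- function(shape, c) {
  block <- max(2L, floor(min(shape) / (2 * c)))
  cs <- lapply(shape, function(n) (seq_len(n) - 1L) %/% block)
  grid <- expand.grid(cs)
  lab <- (rowSums(grid) %% c) + 1L
  array(as.integer(lab), dim = shape)
}

# smooth seeded random field cut at equal-area quantiles; gives each class
# compact blobs plus thin boundary bands
.geomBlobs <- function(shape, c, seed) {
  set.seed(seed + 1000L)
  cs <- lapply(shape, .normCoord)
  grid <- expand.grid(cs)
  f <- numeric(nrow(grid))
  for (j in 1:4) {
    freq <- stats::runif(length(shape), 1, 4)
    phase <- stats::runif(length(shape), 0, 2 * pi)
    wave <- rep(0, nrow(grid))
    for (d in seq_along(shape))
      wave <- wave + 2 * pi * freq[d] * grid[[d]]
    f <- f + stats::runif(1, 0.5, 1) * sin(wave + phase[1])
  }
  q <- stats::quantile(f, probs = seq(0, 1, length.out = c + 1))
  lab <- cut(f, breaks = q, labels = FALSE, include.lowest = TRUE)
  array(as.integer(lab), dim = shape)
}

#' Generate a synthetic multi-tissue phantom
#'
#' Builds a piecewise-constant image \eqn{X_0} from a geometry preset,
#' multiplies it by a smooth bias field, and adds Rician noise:
#' \eqn{X = \mathrm{Rician}(b \cdot X_0)}. Deterministic given the seed.
#'
#' @param shape grid dimensions, e.g. \code{c(64, 64)}.
#' @param classes number of tissue classes c (>= 2).
#' @param classMeans strictly increasing class intensities; default
#'   equally spaced in \code{[0.2, 0.8]}.
#' @param geometry \code{"nested-rings"} (concentric annuli),
#'   \code{"blobs"} (smooth random regions) or \code{"checker"}.
#' @param biasModel,biasAmplitude passed to [makeBias()].
#' @param noisePercent Rician level as percent of the brightest class mean
#'   (0 to 20).
#' @param seed RNG seed.
#' @return a [PhantomTruth-class].
#' @examples
#' ph <- makePhantom(shape = c(64, 64), classes = 3, noisePercent = 5,
#'                   seed = 1)
#' table(labelMap(ph))
#' @export
makePhantom <- function(shape = c(64, 64), classes = 3, classMeans = NULL,
                        geometry = c("nested-rings", "blobs", "checker"),
                        biasModel = "none", biasAmplitude = 0,
                        noisePercent = 0, seed = 1) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (classes < 2) stop("classes must be >= 2")
  if (noisePercent < 0 || noisePercent > 20)
    stop("noise level must lie in [0, 20] percent")
  if (is.null(classMeans))
    classMeans <- seq(0.2, 0.8, length.out = classes)
  if (is.unsorted(classMeans, strictly = TRUE))
    stop("class means must be strictly increasing")
  labels <- switch(geometry,
    "nested-rings" = .geomNestedRings(shape, classes),
    "checker" = .geomChecker(shape, classes),
    "blobs" = .geomBlobs(shape, classes, seed))
  if (!all(seq_len(classes) %in% labels))
    stop("degenerate geometry: some class has zero pixels")
  x0 <- array(classMeans[labels], dim = shape)
  b <- makeBias(shape, biasModel, biasAmplitude)
  x <- addRicianNoise(b * x0, noisePercent,
                      referenceIntensity = max(classMeans), seed = seed)
  new("PhantomTruth", labels = labels, cleanImage = x0, trueBias = b,
      observed = x, classMeans = as.numeric(classMeans),
      noiseLevel = as.numeric(noisePercent),
      spec = list(shape = shape, geometry = geometry, biasModel = biasModel,
                  biasAmplitude = biasAmplitude, seed = seed,
                  rng = "Mersenne-Twister"))
}
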