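#' Accessors for result and phantom objects
#'
#' Slot accessors for [SegmentationResult-class], [PhantomTruth-class] and
#' [JSReport-class] objects.
#'
#' @param object a \code{SegmentationResult}, \code{PhantomTruth} or
#'   \code{JSReport}.
#' @return the corresponding component: an integer label array
#'   (\code{labelMap}), a membership array (\code{memberships}), prototype
#'   intensities (\code{prototypes}), the bias field array
#'   (\code{biasField}/\code{trueBias}), image arrays
#'   (\code{correctedImage}, \code{cleanImage}, \code{observedImage}), the
#'   per-sweep objective values (\code{objectiveTrace}), per-class Jaccard
#'   values (\code{jaccardValues}), or phantom class means
#'   (\code{classMeans}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))
#' @rdname accessors
#' @export
setGeneric("biasField", function(object) standardGeneric("biasField"))
#' @rdname accessors
#' @export
setGeneric("correctedImage", function(object) standardGeneric("correctedImage"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("cleanImage", function(object) standardGeneric("cleanImage"))
#' @rdname accessors
#' @export
setGeneric("trueBias", function(object) standardGeneric("trueBias"))
#' @rdname accessors
#' @export
setGeneric("observedImage", function(object) standardGeneric("observedImage"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("jaccardValues", function(object) standardGeneric("jaccardValues"))

#' @rdname accessors
#' @export
setMethod("labelMap", "SegmentationResult", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("memberships", "SegmentationResult", function(object) object@memberships)
#' @rdname accessors
#' @export
setMethod("prototypes", "SegmentationResult", function(object) object@prototypes)
#' @rdname accessors
#' @export
setMethod("biasField", "SegmentationResult", function(object) object@biasField)
#' @rdname accessors
#' @export
setMethod("correctedImage", "SegmentationResult", function(object) object@correctedImage)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "SegmentationResult", function(object) object@objective)

#' @rdname accessors
#' @export
setMethod("labelMap", "PhantomTruth", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("cleanImage", "PhantomTruth", function(object) object@cleanImage)
#' @rdname accessors
#' @export
setMethod("trueBias", "PhantomTruth", function(object) object@trueBias)
#' @rdname accessors
#' @export
setMethod("observedImage", "PhantomTruth", function(object) object@observed)
#' @rdname accessors
#' @export
setMethod("classMeans", "PhantomTruth", function(object) object@classMeans)

#' @rdname accessors
#' @export
setMethod("jaccardValues", "JSReport", function(object) object@js)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult [%s]\n", object@method))
  cat(sprintf("  grid: %s, %d clusters\n",
              paste(dim(object@labels), collapse = " x "),
              length(object@prototypes)))
  cat(sprintf("  prototypes: %s\n",
              paste(signif(object@prototypes, 4), collapse = ", ")))
  cat(sprintf("  sweeps: %d (%s), final objective %.6g\n",
              object@iterations,
              if (object@converged) "converged" else "max-iter",
              utils::tail(object@objective, 1)))
  br <- range(object@biasField[object@labels > 0L])
  cat(sprintf("  bias field range: [%.4f, %.4f]\n", br[1], br[2]))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %s grid, %d classes (%s geometry)\n",
              paste(dim(object@labels), collapse = " x "),
              length(object@classMeans),
              object@spec$geometry))
  cat(sprintf("  class means: %s\n",
              paste(object@classMeans, collapse = ", ")))
  cat(sprintf("  bias: %s (amplitude %.2f), noise: %.1f%%, seed %s\n",
              object@spec$biasModel, object@spec$biasAmplitude,
              object@noiseLevel, object@spec$seed))
})

setMethod("show", "JSReport", function(object) {
  cat("Jaccard similarity report\n")
  cat(sprintf("  per class: %s\n",
              paste(sprintf("%.4f", object@js), collapse = ", ")))
  cat(sprintf("  mean: %.4f\n", object@meanJS))
  if (!is.na(object@biasCorrelation))
    cat(sprintf("  bias-field Pearson r: %.4f\n", object@biasCorrelation))
})

setMethod("show", "GaussianKernel", function(object) {
  cat(sprintf("GaussianKernel: sigma = %.3g, rho = %d, %s window\n",
              object@sigma, object@rho,
              paste(dim(object@weights), collapse = " x ")))
})
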