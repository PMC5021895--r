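# Image input/output: NIfTI (2D slices and 3D volumes), greyscale PNG and
# TIFF, plus the output bundle (label map, bias field, corrected image,
# membership maps, objective trace, metadata sidecar).

# fixed label palette for PNG label maps: background black, then
# CSF-blue, GM-grey, WM-white, and two spares
.labelPalette <- matrix(c(
  0,    0,    0,     # 0 background
  0.10, 0.30, 0.95,  # 1
  0.55, 0.55, 0.55,  # 2
  1.00, 1.00, 1.00,  # 3
  0.90, 0.35, 0.10,  # 4
  0.20, 0.80, 0.30   # 5
), ncol = 3, byrow = TRUE)

#' Read a greyscale image
#'
#' Reads NIfTI (\code{.nii}, \code{.nii.gz}), greyscale PNG or TIFF into a
#' numeric array of non-negative intensities. PNG and TIFF intensities are
#' returned on [0, 1] (16-bit PNGs are scaled by 1/65535 by the reader);
#' NIfTI intensities are returned as stored, and the header/affine is kept
#' as an attribute for pass-through on output.
#'
#' @param path file path.
#' @return numeric array (a \code{niftiImage} for NIfTI input).
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    return(img)
  }
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      ch <- dim(img)[3]
      rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
      if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1]))) > 1e-9)
        stop("non-greyscale PNG: ", path)
      img <- rgb[, , 1]
    }
    return(img)
  }
  if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) {
      if (max(abs(sweep(img, c(1, 2), img[, , 1]))) > 1e-9)
        stop("non-greyscale TIFF: ", path)
      img <- img[, , 1]
    }
    return(img)
  }
  stop("unsupported image format: ", path)
}

#' Write a greyscale image
#'
#' Writes a numeric array as NIfTI, PNG or TIFF (chosen by extension). For
#' PNG/TIFF the values are clipped to [0, 1]; pass \code{rescale = TRUE}
#' to map the array's range onto [0, 1] first. For NIfTI an optional
#' \code{reference} image supplies the affine/header to pass through.
#'
#' @param image numeric array.
#' @param path output path ending in .nii, .nii.gz, .png or .tif(f).
#' @param reference optional NIfTI image whose header is reused.
#' @param rescale map the range to [0, 1] before writing PNG/TIFF.
#' @return the path, invisibly.
#' @export
writeImage <- function(image, path, reference = NULL, rescale = FALSE) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- if (is.null(reference)) RNifti::asNifti(unclass(image))
           else RNifti::asNifti(unclass(image), reference = reference)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  x <- as.array(image)
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  if (length(dim(x)) != 2L)
    stop("PNG/TIFF output supports 2D images only: ", path)
  if (rescale) {
    rng <- range(x)
    x <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  }
  x <- pmin(pmax(x, 0), 1)
  if (grepl("\\.png$", lower)) {
    png::writePNG(x, path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::writeTIFF(x, path, bits.per.sample = 16L)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

# label map as paletted RGB PNG
.writeLabelPng <- function(labels, path) {
  lab <- as.array(labels)
  if (length(dim(lab)) == 3L && dim(lab)[3] == 1L) lab <- lab[, , 1]
  pal <- .labelPalette
  idx <- pmin(lab, nrow(pal) - 1L) + 1L
  rgb <- array(0, dim = c(dim(lab), 3L))
  for (ch in 1:3) rgb[, , ch] <- pal[idx, ch]
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write the full output bundle of a segmentation run
#'
#' Writes, into \code{dir}: the hard label map, estimated bias field,
#' bias-corrected image, one membership map per class, the per-sweep
#' objective trace (tab-delimited text), and a YAML metadata sidecar with
#' every parameter and the seed, sufficient to reproduce the run.
#'
#' @param result a [SegmentationResult-class].
#' @param dir output directory (created if missing).
#' @param format \code{"nifti"} (default) or \code{"png"}. PNG output
#'   rescales the bias field and corrected image onto [0, 1] and writes the
#'   label map with a fixed palette; NIfTI writes raw values.
#' @param reference optional NIfTI image whose header/affine is passed
#'   through to all NIfTI outputs.
#' @return the directory path, invisibly.
#' @export
writeOutputs <- function(result, dir, format = c("nifti", "png"),
                         reference = NULL) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  wr <- function(img, name, rescale = FALSE)
    writeImage(img, file.path(dir, paste0(name, ext)),
               reference = reference, rescale = rescale && format == "png")
  if (format == "nifti") {
    wr(labelMap(result) * 1.0, "labels")
  } else {
    .writeLabelPng(labelMap(result), file.path(dir, "labels.png"))
  }
  wr(biasField(result), "bias_field", rescale = TRUE)
  wr(correctedImage(result), "corrected", rescale = TRUE)
  u <- memberships(result)
  nc <- dim(u)[length(dim(u))]
  idx <- slice.index(u, length(dim(u)))
  for (i in seq_len(nc)) {
    ui <- array(u[idx == i], dim = dim(labelMap(result)))
    wr(ui, sprintf("membership_class%02d", i))
  }
  trace <- data.frame(sweep = seq_along(objectiveTrace(result)),
                      objective = objectiveTrace(result))
  utils::write.table(trace, file.path(dir, "objective_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- result@parameters
  meta$iterations <- result@iterations
  meta$converged <- result@converged
  meta$prototypes <- as.numeric(prototypes(result))
  meta$rng <- "Mersenne-Twister"
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
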