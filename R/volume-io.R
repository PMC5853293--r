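#' Construct a Volume3D
#'
#' @param data a 3D numeric array in `(z, y, x)` order, or a matrix (treated
#'   as a single-page stack).
#' @param spacing micrometres per voxel along `(z, y, x)`; a single value is
#'   recycled (isotropic voxels).
#' @param calibration calibration state; new volumes are `"raw"`.
#' @param provenance free-text scan identifier.
#' @return a [Volume3D-class] object.
#' @examples
#' v <- Volume3D(array(0, c(4, 10, 10)), spacing = c(1, 1, 1))
#' dim(volData(v))
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), calibration = "raw",
                     provenance = "") {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  storage.mode(data) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      calibration = calibration, provenance = as.character(provenance))
}

#' Construct a SubsetROI
#'
#' @param lo inclusive 0-based start voxel `(z, y, x)`.
#' @param hi exclusive end voxel `(z, y, x)`.
#' @return a [SubsetROI-class].
#' @examples
#' subsetROI(c(0, 0, 0), c(4, 10, 10))
#' @export
subsetROI <- function(lo, hi) {
  new("SubsetROI", lo = as.integer(lo), hi = as.integer(hi))
}

## ---- accessors ------------------------------------------------------------

#' @describeIn Volume3D the raw 3D array.
#' @param x,object a Volume3D, BinaryMask or LabelMap.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @export
setMethod("volData", "Volume3D", function(x) x@data)
#' @export
setMethod("volData", "BinaryMask", function(x) x@data)
#' @export
setMethod("volData", "LabelMap", function(x) x@data)

#' @describeIn Volume3D voxel spacing in micrometres per voxel `(z, y, x)`.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @describeIn Volume3D physical volume of one voxel in cubic micrometres.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setMethod("voxelVolume", "ANY", function(x) prod(voxelSpacing(x)))

#' @describeIn Volume3D the calibration state.
#' @export
setGeneric("calibrationState", function(x) standardGeneric("calibrationState"))

#' @export
setMethod("calibrationState", "Volume3D", function(x) x@calibration)

#' @describeIn LabelMap number of labelled objects.
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @export
setMethod("nLabels", "LabelMap", function(x) x@nLabels)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D %d x %d x %d (z,y,x), spacing %s um, %s%s\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              object@calibration,
              if (nzchar(object@provenance))
                paste0(", '", object@provenance, "'") else ""))
  cat(sprintf("  grey range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap %d x %d x %d, %d objects\n",
              d[1], d[2], d[3], object@nLabels))
})

setMethod("show", "SubsetROI", function(object) {
  cat(sprintf("SubsetROI [%s) - [%s) (z,y,x), %d voxels\n",
              paste(object@lo, collapse = ","),
              paste(object@hi, collapse = ","),
              prod(object@hi - object@lo)))
})

## ---- TIFF I/O -------------------------------------------------------------

.LABEL_SCALE <- 2^24  # float32 mantissa: labels up to 2^24 survive exactly

#' Read a multi-page TIFF stack as a Volume3D
#'
#' Pages become the `z` axis.  8- and 16-bit integer samples are read
#' unscaled (a 16-bit value of 65535 stays 65535); 32-bit float samples are
#' read as stored.  Scan metadata does not travel inside the image files, so
#' the voxel spacing must be supplied by the caller.
#'
#' @param path path to a multi-page TIFF file.
#' @param spacing micrometres per voxel `(z, y, x)`.
#' @param provenance free-text scan identifier (defaults to the file name).
#' @return a [Volume3D-class].
#' @seealso [writeVolume()], [readLabelMap()]
#' @export
readVolume <- function(path, spacing = c(1, 1, 1), provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!length(pages)) stop("no pages in TIFF file: ", path)
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    di <- dim(pages[[i]])
    if (length(di) != 2L)
      stop("unsupported sample format (non-greyscale) at page ", i)
    if (!identical(di, shp))
      stop("ragged TIFF stack: page ", i, " has shape ",
           paste(di, collapse = "x"), ", expected ", paste(shp, collapse = "x"))
  }
  arr <- array(0, c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  Volume3D(arr, spacing = spacing, provenance = provenance)
}

#' Write a Volume3D to a multi-page TIFF
#'
#' Integer-valued data are written losslessly at the requested bit depth
#' (values must fit `[0, 2^bits - 1]`); other data are written as 32-bit
#' float, which is lossless for values already in `[0, 1]`.  Calibrated
#' volumes are kept as floating point internally; quantization happens only
#' here at export.
#'
#' @param vol a [Volume3D-class].
#' @param path output file path.
#' @param bits 8, 16 or 32 bits per sample.  Default: 8 if all values fit
#'   `[0, 255]` integers, else 16 if they fit 16-bit integers, else 32.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, bits = NULL) {
  stopifnot(is(vol, "Volume3D"))
  v <- vol@data
  isInt <- all(v == round(v))
  if (is.null(bits)) {
    bits <- if (isInt && min(v) >= 0 && max(v) <= 255) 8L
            else if (isInt && min(v) >= 0 && max(v) <= 65535) 16L
            else 32L
  }
  if (bits %in% c(8L, 16L)) {
    mx <- 2^bits - 1
    if (!isInt || min(v) < 0 || max(v) > mx)
      stop("values do not fit unsigned ", bits, "-bit integers; use bits = 32")
    pages <- lapply(seq_len(dim(v)[1]), function(z)
      matrix(v[z, , ], dim(v)[2], dim(v)[3]) / mx)
  } else {
    if (min(v) < 0 || max(v) > 1)
      stop("32-bit float TIFF export requires values in [0, 1]; rescale first")
    pages <- lapply(seq_len(dim(v)[1]), function(z)
      matrix(v[z, , ], dim(v)[2], dim(v)[3]))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Write / read a LabelMap as 32-bit TIFF
#'
#' Labels are stored as 32-bit float scaled by `2^-24`, which represents
#' every label up to 2^24 (about 16.7 million objects) exactly.
#'
#' @param lm a [LabelMap-class].
#' @param path file path.
#' @return `writeLabelMap`: `path` invisibly; `readLabelMap`: a
#'   [LabelMap-class].
#' @export
writeLabelMap <- function(lm, path) {
  stopifnot(is(lm, "LabelMap"))
  v <- lm@data
  if (max(v) >= .LABEL_SCALE) stop("more than 2^24 labels cannot be stored")
  pages <- lapply(seq_len(dim(v)[1]), function(z)
    matrix(v[z, , ], dim(v)[2], dim(v)[3]) / .LABEL_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname writeLabelMap
#' @param spacing micrometres per voxel `(z, y, x)`.
#' @export
readLabelMap <- function(path, spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages))
    arr[i, , ] <- as.integer(round(pages[[i]] * .LABEL_SCALE))
  new("LabelMap", data = arr, spacing = as.numeric(spacing),
      nLabels = max(arr, 0L))
}

## ---- cropping -------------------------------------------------------------

.roiIndices <- function(roi, d) {
  if (any(roi@hi > d))
    stop("ROI exceeds volume bounds (", paste(d, collapse = "x"), ")")
  lapply(1:3, function(a) seq.int(roi@lo[a] + 1L, roi@hi[a]))
}

#' Crop a volume, mask or label map to a subset window
#'
#' @param x a [Volume3D-class], [BinaryMask-class] or [LabelMap-class].
#' @param roi a [SubsetROI-class]; must lie within bounds.
#' @return an object of the same class with shape `hi - lo` and unchanged
#'   spacing.
#' @examples
#' v <- Volume3D(array(1:64, c(4, 4, 4)))
#' cropVolume(v, subsetROI(c(0, 0, 0), c(2, 2, 2)))
#' @export
setGeneric("cropVolume", function(x, roi) standardGeneric("cropVolume"))

#' @export
setMethod("cropVolume", "Volume3D", function(x, roi) {
  ix <- .roiIndices(roi, dim(x@data))
  initialize(x, data = x@data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
})

#' @export
setMethod("cropVolume", "BinaryMask", function(x, roi) {
  ix <- .roiIndices(roi, dim(x@data))
  initialize(x, data = x@data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
})

#' @export
setMethod("cropVolume", "LabelMap", function(x, roi) {
  ix <- .roiIndices(roi, dim(x@data))
  initialize(x, data = x@data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
})

#' Logical membership array of an ROI within a volume's frame
#'
#' @param roi a [SubsetROI-class].
#' @param d integer(3) volume dimensions `(nz, ny, nx)`.
#' @return logical array marking voxels inside the window.
#' @keywords internal
roiMask <- function(roi, d) {
  m <- array(FALSE, d)
  ix <- .roiIndices(roi, d)
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  m
}

## rounding used for reported counts: half-up, not banker's
roundHalfUp <- function(x) floor(x + 0.5)
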