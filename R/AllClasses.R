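#' @useDynLib ctcount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dist lm coef median optimize optim pf pnorm pt pwilcox
#'   qnorm rnorm runif rlnorm sd setNames var complete.cases terms
#'   model.matrix printCoefmat
#' @importFrom utils read.csv write.csv combn head
NULL

.CALIBRATION_STATES <- c("raw", "byte_scaled", "ct_scaled")

#' Volume3D: a 3D greyscale scan with voxel spacing
#'
#' The central image container of the package: a 3D numeric array in
#' `(z, y, x)` order (`z` = page index of the TIFF stack) together with the
#' physical voxel spacing in micrometres per voxel along each axis and a
#' calibration state.  The calibration state records which of the two
#' greyscale normalizations (byte scaling or CT scaling) has been applied;
#' a volume can undergo at most one of the two, starting from `"raw"`.
#'
#' @slot data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @slot spacing numeric(3), micrometres per voxel along `(z, y, x)`;
#'   anisotropic spacing is supported and used in all volume conversions.
#' @slot calibration one of `"raw"`, `"byte_scaled"`, `"ct_scaled"`.
#' @slot provenance free-text scan identifier.
#' @exportClass Volume3D
setClass("Volume3D",
  representation(data = "array", spacing = "numeric",
                 calibration = "character", provenance = "character"),
  prototype(spacing = c(1, 1, 1), calibration = "raw", provenance = ""))

setValidity("Volume3D", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  else if (any(dim(object@data) < 1L))
    msg <- c(msg, "data must have at least one voxel on each axis")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three finite positive values (z,y,x)")
  if (length(object@calibration) != 1L ||
      !object@calibration %in% .CALIBRATION_STATES)
    msg <- c(msg, sprintf("calibration must be one of %s",
                          paste(.CALIBRATION_STATES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a foreground mask aligned to a parent volume
#'
#' @slot data logical 3D array, same shape as the parent [Volume3D].
#' @slot spacing numeric(3), inherited voxel spacing (micrometres).
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1)))

setValidity("BinaryMask", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a logical 3D array")
  if (anyNA(object@data))
    msg <- c(msg, "mask must not contain NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three finite positive values")
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer-labelled objects in a volume
#'
#' Voxels share a positive label when they belong to the same separated
#' object; 0 is background.  Labels form the contiguous range `1..nLabels`
#' in raster-scan order of each object's first voxel, so labelling is
#' deterministic.
#'
#' @slot data integer 3D array (0 = background).
#' @slot spacing numeric(3), micrometres per voxel along `(z, y, x)`.
#' @slot nLabels number of objects (max label).
#' @exportClass LabelMap
setClass("LabelMap",
  representation(data = "array", spacing = "numeric", nLabels = "integer"),
  prototype(spacing = c(1, 1, 1), nLabels = 0L))

setValidity("LabelMap", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L || !is.integer(object@data))
    msg <- c(msg, "data must be an integer 3D array")
  if (length(object@nLabels) != 1L || is.na(object@nLabels) ||
      object@nLabels < 0L)
    msg <- c(msg, "nLabels must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' SubsetROI: a half-open axis-aligned voxel window
#'
#' ROIs use 0-based half-open voxel coordinates `[lo, hi)` in `(z, y, x)`
#' order, so that the window's voxel extent is exactly `hi - lo` per axis
#' and subset-volume arithmetic is unambiguous.
#'
#' @slot lo integer(3), inclusive start voxel (0-based).
#' @slot hi integer(3), exclusive end voxel.
#' @exportClass SubsetROI
setClass("SubsetROI", representation(lo = "integer", hi = "integer"))

setValidity("SubsetROI", function(object) {
  msg <- character(0)
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    msg <- c(msg, "lo and hi must each have length 3 (z,y,x)")
  else {
    if (any(object@lo < 0L)) msg <- c(msg, "lo must be >= 0")
    if (any(object@hi <= object@lo)) msg <- c(msg, "need lo < hi on every axis")
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationModel: two-point linear greyscale calibration
#'
#' The linear map fixed by requiring that the measured mean greyscale of air
#' maps to `airTarget` and that of the reference liquid (one-percent PTA in FAA) maps
#' to `refTarget`: `slope * g + intercept`.
#'
#' @slot airGrey measured mean greyscale of air on the dummy scan.
#' @slot refGrey measured mean greyscale of the reference liquid.
#' @slot airTarget calibrated value assigned to air.
#' @slot refTarget calibrated value assigned to the reference liquid.
#' @slot slope,intercept the derived linear map.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(airGrey = "numeric", refGrey = "numeric",
                 airTarget = "numeric", refTarget = "numeric",
                 slope = "numeric", intercept = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- character(0)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@airGrey, object@refGrey, object@airTarget,
                       object@refTarget, object@slope, object@intercept),
                  num1, logical(1))))
    msg <- c(msg, "all slots must be single finite numbers")
  else {
    if (object@airGrey == object@refGrey)
      msg <- c(msg, "air and reference greyscale must differ")
    tol <- 1e-8 * max(1, abs(object@airTarget), abs(object@refTarget))
    if (abs(object@slope * object@airGrey + object@intercept - object@airTarget) > tol ||
        abs(object@slope * object@refGrey + object@intercept - object@refTarget) > tol)
      msg <- c(msg, "slope/intercept do not pass through the two reference points")
  }
  if (length(msg)) msg else TRUE
})

#' CountEstimate: the subset-to-whole extrapolation record
#'
#' Records every quantity of the extrapolation: the number of objects counted
#' in the subset, the segmented foreground volume of the subset and of the
#' whole structure (both measured on the overview scan), the derived mean
#' object volume, and the extrapolated total count, raw and rounded half-up.
#'
#' @slot nSubset objects counted in the subset.
#' @slot vSubset segmented foreground volume inside the subset (um^3).
#' @slot vTotal total segmented foreground volume (um^3).
#' @slot meanObjectVolume `vSubset / nSubset` (um^3).
#' @slot nTotalRaw `vTotal / meanObjectVolume`, unrounded.
#' @slot nTotal `nTotalRaw` rounded half-up to an integer.
#' @slot workflow one of `"pollen"`, `"ovule"`, `"massulae"`.
#' @exportClass CountEstimate
setClass("CountEstimate",
  representation(nSubset = "numeric", vSubset = "numeric", vTotal = "numeric",
                 meanObjectVolume = "numeric", nTotalRaw = "numeric",
                 nTotal = "numeric", workflow = "character"))

setValidity("CountEstimate", function(object) {
  msg <- character(0)
  if (object@meanObjectVolume <= 0)
    msg <- c(msg, "mean object volume must be positive")
  if (!object@workflow %in% c("pollen", "ovule", "massulae"))
    msg <- c(msg, "workflow must be pollen, ovule or massulae")
  raw <- object@vTotal * object@nSubset / object@vSubset
  if (abs(raw - object@nTotalRaw) > 1e-8 * max(1, abs(raw)))
    msg <- c(msg, "nTotalRaw must equal vTotal * nSubset / vSubset")
  if (length(msg)) msg else TRUE
})
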