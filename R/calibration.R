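## Greyscale normalization: the two procedures that make grey values
## comparable across scans.  Byte scaling rescales a chosen grey window to
## 0..255; CT scaling fits a linear map through the measured greys of two
## reference materials (air and the 1% PTA/FAA fixative) taken from a dummy
## scan, so that the same material lands on the same value in every scan.

#' Byte scaling: rescale a grey window to 0..255
#'
#' Values are mapped by `clamp((v - gmin) / (gmax - gmin)) * 255` and rounded
#' half-up, producing an 8-bit-range volume with state `"byte_scaled"`.
#'
#' @param vol a raw [Volume3D-class].
#' @param gmin,gmax the grey window; `gmin < gmax`.  `gmin` maps to 0 and
#'   `gmax` to 255; values outside are clamped.
#' @return a byte-scaled [Volume3D-class].
#' @examples
#' v <- Volume3D(array(c(0, 50, 100, 150), c(1, 2, 2)))
#' range(volData(byteScale(v, 0, 100)))
#' @export
byteScale <- function(vol, gmin, gmax) {
  stopifnot(is(vol, "Volume3D"))
  if (gmin >= gmax) stop("need gmin < gmax")
  if (vol@calibration != "raw")
    stop("volume is already ", vol@calibration, "; byte scaling needs a raw volume")
  x <- (vol@data - gmin) / (gmax - gmin)
  x <- pmin(pmax(x, 0), 1)
  initialize(vol, data = array(roundHalfUp(x * 255), dim(vol@data)),
             calibration = "byte_scaled")
}

#' Fit the two-point CT-scaling model
#'
#' The unique linear map sending the measured air grey to `airTarget` and the
#' measured reference-liquid grey to `refTarget`.  Default targets are
#' air = 0 and reference = 1000 (configurable; only linearity through the two
#' reference materials is fixed by the procedure).  The measured density of
#' the reference liquid (0.937 g/ml for the 1-percent PTA/FAA solution) is
#' conventionally recorded alongside the model as metadata; it does not
#' enter the greyscale map.
#'
#' @param airGrey,refGrey measured mean greyscale of air and of the reference
#'   liquid on the dummy scan; must differ.
#' @param airTarget,refTarget calibrated values assigned to the two materials.
#' @return a [CalibrationModel-class].
#' @examples
#' fitCTScaling(10, 200, 0, 1000)
#' @export
fitCTScaling <- function(airGrey, refGrey, airTarget = 0, refTarget = 1000) {
  if (!is.finite(airGrey) || !is.finite(refGrey) || airGrey == refGrey)
    stop("air and reference greyscale must be finite and distinct")
  slope <- (refTarget - airTarget) / (refGrey - airGrey)
  intercept <- airTarget - slope * airGrey
  new("CalibrationModel", airGrey = airGrey, refGrey = refGrey,
      airTarget = airTarget, refTarget = refTarget,
      slope = slope, intercept = intercept)
}

#' Measure reference greys on a dummy scan
#'
#' Returns the arithmetic mean greyscale inside an air window and a
#' reference-liquid window of the dummy (phantom) scan.
#'
#' @param dummy a [Volume3D-class] of the dummy scan.
#' @param airROI,refROI [SubsetROI-class] windows containing only air and
#'   only reference liquid, respectively.
#' @return named numeric: `airGrey`, `refGrey`.
#' @export
measureDummy <- function(dummy, airROI, refROI) {
  stopifnot(is(dummy, "Volume3D"))
  d <- dim(dummy@data)
  ia <- .roiIndices(airROI, d)
  ir <- .roiIndices(refROI, d)
  overlap <- all(pmax(airROI@lo, refROI@lo) < pmin(airROI@hi, refROI@hi))
  if (overlap) warning("air and reference ROIs overlap")
  c(airGrey = mean(dummy@data[ia[[1]], ia[[2]], ia[[3]]]),
    refGrey = mean(dummy@data[ir[[1]], ir[[2]], ir[[3]]]))
}

#' Apply CT scaling to a raw volume
#'
#' Every voxel is mapped by `slope * v + intercept`; the result is kept as
#' floating point (quantization happens only at file export) with state
#' `"ct_scaled"`.
#'
#' @param vol a raw [Volume3D-class].
#' @param model a [CalibrationModel-class].
#' @return a CT-scaled [Volume3D-class].
#' @export
applyCTScaling <- function(vol, model) {
  stopifnot(is(vol, "Volume3D"), is(model, "CalibrationModel"))
  if (vol@calibration != "raw")
    stop("volume is already ", vol@calibration, "; refusing to re-calibrate")
  initialize(vol, data = model@slope * vol@data + model@intercept,
             calibration = "ct_scaled")
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(paste0("CT scaling: grey %.4g -> %.4g (air), ",
                     "%.4g -> %.4g (reference)\n  v' = %.6g * v + %.6g\n"),
              object@airGrey, object@airTarget,
              object@refGrey, object@refTarget,
              object@slope, object@intercept))
})
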