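## The filtering chain applied before object separation: greyscale
## thresholding (drop voxels darker than a set value), 3D median noise
## reduction (kernel 3x3x3) and 3D Gaussian smoothing (kernel 9x9x9).
## Both filters use symmetric (mirror) boundary padding so object fragments
## at scan edges are not darkened, which would bias volume estimates.

#' Greyscale threshold
#'
#' Foreground is every voxel with value `>= t`.  Extreme thresholds yield an
#' empty or full mask; this is permitted but reported via a message.
#'
#' @param vol a [Volume3D-class].
#' @param t threshold, in the volume's current grey scale, or `"otsu"` for
#'   automatic selection by [otsuThreshold()].
#' @return a [BinaryMask-class] aligned to `vol`.
#' @examples
#' v <- Volume3D(array(0:9, c(1, 2, 5)))
#' sum(volData(thresholdGrey(v, 5)))
#' @export
thresholdGrey <- function(vol, t) {
  stopifnot(is(vol, "Volume3D"))
  if (identical(t, "otsu")) t <- otsuThreshold(vol)
  m <- vol@data >= t
  nf <- sum(m)
  if (nf == 0L) message("threshold ", signif(t, 6), ": empty mask")
  if (nf == length(m)) message("threshold ", signif(t, 6), ": full mask")
  new("BinaryMask", data = m, spacing = vol@spacing)
}

#' Otsu's automatic threshold for a 3D volume
#'
#' Maximizes between-class variance over a 256-bin grey histogram of the
#' whole volume; returns the threshold on the volume's grey scale (the lower
#' edge of the first foreground bin).
#'
#' @param vol a [Volume3D-class].
#' @param nbins number of histogram bins.
#' @return a single threshold value.
#' @export
otsuThreshold <- function(vol, nbins = 256L) {
  v <- as.numeric(vol@data)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])
  br[k + 1L]
}

#' 3D median noise-reduction filter
#'
#' Each voxel is replaced by the median of its `kernel^3` neighbourhood
#' (symmetric padding at boundaries).  `kernel = 1` is the identity.
#'
#' @param vol a [Volume3D-class].
#' @param kernel odd kernel edge length in voxels; the pipeline default is 3.
#' @return a filtered [Volume3D-class] with unchanged shape and spacing.
#' @export
median3d <- function(vol, kernel = 3L) {
  stopifnot(is(vol, "Volume3D"))
  if (kernel < 1L || kernel %% 2L == 0L) stop("kernel must be odd and >= 1")
  out <- cpp_median3d(as.numeric(vol@data), dim(vol@data), as.integer(kernel))
  initialize(vol, data = array(out, dim(vol@data)))
}

## truncated, renormalized 1D Gaussian kernel (sums to 1 exactly)
gaussianKernel1d <- function(kernel, sigma) {
  h <- (kernel - 1L) / 2
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w / sum(w)
}

#' 3D Gaussian smoothing filter
#'
#' Separable Gaussian convolution truncated to `kernel^3` support, with the
#' 1D kernel renormalized to sum exactly 1 so constant volumes are preserved.
#' The pipeline default support is 9 voxels; `sigma` defaults to 1.5 voxels
#' (about 6 sigma of support for a 9-wide truncated kernel).
#'
#' @param vol a [Volume3D-class].
#' @param kernel odd kernel edge length in voxels.
#' @param sigma Gaussian standard deviation in voxels, `> 0`.
#' @return a smoothed [Volume3D-class] with unchanged shape and spacing.
#' @export
gaussian3d <- function(vol, kernel = 9L, sigma = 1.5) {
  stopifnot(is(vol, "Volume3D"))
  if (kernel < 1L || kernel %% 2L == 0L) stop("kernel must be odd and >= 1")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  k1 <- gaussianKernel1d(as.integer(kernel), sigma)
  d <- dim(vol@data)
  out <- as.numeric(vol@data)
  for (axis in 0:2) out <- cpp_conv_axis(out, d, k1, axis)
  initialize(vol, data = array(out, d))
}

#' Run the preprocessing chain of the counting pipeline
#'
#' Fixed stage order: greyscale threshold, 3D median filter, 3D Gaussian
#' smoothing, then a final re-threshold at the same grey value to define the
#' foreground handed to object separation.  Greyscale is retained within the
#' mask (sub-threshold voxels are zeroed, supra-threshold voxels keep their
#' values) because the later iterative-threshold separation operates on grey
#' levels, not on a binary mask.
#'
#' @param vol a [Volume3D-class].
#' @param threshold grey threshold, or `"otsu"`.
#' @param medianKernel,gaussianKernel,gaussianSigma filter parameters; see
#'   [median3d()] and [gaussian3d()].
#' @return a list with `vol` (the filtered [Volume3D-class]) , `mask` (the
#'   final [BinaryMask-class]) and `threshold` (the grey value used).
#' @export
preprocessVolume <- function(vol, threshold = "otsu", medianKernel = 3L,
                             gaussianKernel = 9L, gaussianSigma = 1.5) {
  stopifnot(is(vol, "Volume3D"))
  if (identical(threshold, "otsu")) threshold <- otsuThreshold(vol)
  x <- vol@data
  x[x < threshold] <- 0
  v <- initialize(vol, data = x)
  v <- median3d(v, medianKernel)
  v <- gaussian3d(v, gaussianKernel, gaussianSigma)
  list(vol = v,
       mask = new("BinaryMask", data = v@data >= threshold,
                  spacing = vol@spacing),
       threshold = threshold)
}
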