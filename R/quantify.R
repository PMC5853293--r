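## The two counting workflows.  Pollen grains cannot be resolved on an
## overview scan of the whole pollinium, so a high-resolution scan of a
## subset is segmented and counted, the mean grain volume is derived from
## the subset's segmented volume ON THE OVERVIEW SCAN, and the total
## segmented pollen volume is divided by that mean.  Ovules are resolvable
## on a single scan, so subset count, subset volume and total volume all
## come from the same segmentation.  Massulae (the sub-aggregates of the
## pollinium) are resolvable whole and are counted directly.

.countEstimate <- function(nSubset, vSubset, vTotal, workflow) {
  vbar <- meanObjectVolume(vSubset, nSubset)
  raw <- extrapolateTotal(vTotal, vbar)
  new("CountEstimate", nSubset = as.numeric(nSubset), vSubset = vSubset,
      vTotal = vTotal, meanObjectVolume = vbar, nTotalRaw = raw,
      nTotal = roundHalfUp(raw), workflow = workflow)
}

setMethod("show", "CountEstimate", function(object) {
  cat(sprintf(paste0("CountEstimate (%s workflow)\n",
                     "  subset: %g objects in %.6g um^3\n",
                     "  mean object volume: %.6g um^3\n",
                     "  total volume %.6g um^3 -> %.6g objects (%g rounded)\n"),
              object@workflow, object@nSubset, object@vSubset,
              object@meanObjectVolume, object@vTotal, object@nTotalRaw,
              object@nTotal))
})

#' Count objects of a label map inside a subset window
#'
#' @param lm a [LabelMap-class].
#' @param roi a [SubsetROI-class] within bounds.
#' @param edgeRule how objects at the window faces are treated:
#'   \describe{
#'     \item{`centroid`}{count objects whose centroid lies inside the window
#'       (the default; unbiased under stationary object placement).}
#'     \item{`counting_frame`}{stereological counting frame: count objects
#'       intersecting the window except those touching the three exclusion
#'       faces (low-z, low-y, low-x).}
#'     \item{`all`}{count every object intersecting the window.}
#'   }
#' @param tbl optional precomputed [objectStats()] table for `lm`.
#' @param vmin,vmax optional physical volume window applied to the objects.
#' @return integer count.
#' @export
subsetCount <- function(lm, roi, edgeRule = c("centroid", "counting_frame",
                                              "all"),
                        tbl = NULL, vmin = 0, vmax = Inf) {
  stopifnot(is(lm, "LabelMap"), is(roi, "SubsetROI"))
  edgeRule <- match.arg(edgeRule)
  d <- dim(lm@data)
  if (any(roi@hi > d)) stop("ROI exceeds volume bounds")
  if (is.null(tbl)) tbl <- objectStats(lm)
  tbl <- tbl[tbl$volumeUm3 >= vmin & tbl$volumeUm3 <= vmax, , drop = FALSE]
  if (!nrow(tbl)) return(0L)
  sp <- lm@spacing
  loUm <- roi@lo * sp
  hiUm <- roi@hi * sp
  if (edgeRule == "centroid") {
    inside <- tbl$czUm >= loUm[1] & tbl$czUm < hiUm[1] &
              tbl$cyUm >= loUm[2] & tbl$cyUm < hiUm[2] &
              tbl$cxUm >= loUm[3] & tbl$cxUm < hiUm[3]
    return(sum(inside))
  }
  ## bounding-box test is exact for intersection/touch decisions used here
  intersects <- tbl$z1 >= roi@lo[1] & tbl$z0 < roi@hi[1] &
                tbl$y1 >= roi@lo[2] & tbl$y0 < roi@hi[2] &
                tbl$x1 >= roi@lo[3] & tbl$x0 < roi@hi[3]
  if (edgeRule == "all") return(sum(intersects))
  ## an object touches an exclusion face when it occupies the face's voxel
  ## layer or extends beyond it
  touchesExclusion <- tbl$z0 <= roi@lo[1] | tbl$y0 <= roi@lo[2] |
                      tbl$x0 <= roi@lo[3]
  sum(intersects & !touchesExclusion)
}

#' Mean object volume from a counted subset
#'
#' @param vSubset segmented foreground volume of the subset (um^3), `> 0`.
#' @param nSubset number of objects counted in the subset, `>= 1`.
#' @return mean object volume `vSubset / nSubset` (um^3).
#' @examples
#' meanObjectVolume(1000, 100)
#' @export
meanObjectVolume <- function(vSubset, nSubset) {
  if (!is.finite(nSubset) || nSubset < 1)
    stop("subset count must be >= 1 (unusable subset)")
  if (!is.finite(vSubset) || vSubset <= 0)
    stop("subset volume must be positive")
  vSubset / nSubset
}

#' Extrapolate a total count from total volume and mean object volume
#'
#' @param vTotal total segmented foreground volume (um^3).
#' @param vbar mean object volume (um^3), `> 0`.
#' @return the raw (unrounded) total count `vTotal / vbar`.
#' @export
extrapolateTotal <- function(vTotal, vbar) {
  if (!is.finite(vbar) || vbar <= 0) stop("mean object volume must be positive")
  vTotal / vbar
}

#' Pollen counting workflow (two scans)
#'
#' Runs preprocessing and iterative-threshold separation on the
#' high-resolution scan to count the grains of the subset, measures the
#' subset's and the whole pollinium's segmented volume on the overview scan,
#' and extrapolates.  The subset window must be expressed in overview voxel
#' coordinates (scan registration is up to the operator).
#'
#' @param highres high-resolution [Volume3D-class] of the subset.
#' @param overview overview [Volume3D-class] of the whole pollinium,
#'   calibrated consistently with `highres`.
#' @param roiOverview [SubsetROI-class]: the high-resolution scan's footprint
#'   in overview voxel coordinates.
#' @param vmin,vmax grain volume bounds in um^3 (mandatory).
#' @param threshold grey threshold for the high-resolution scan, or
#'   `"otsu"`.
#' @param overviewThreshold grey threshold for the overview scan; defaults
#'   to `threshold` resolved on the overview scan when `"otsu"`.
#' @param edgeRule subset edge rule for the grain count, see [subsetCount()].
#' @param guardUm guard-zone width in micrometres.  Grains clipped by the
#'   high-resolution scan border leave fragments whose apparent centroids
#'   drift into the frame, which biases the centroid rule upward; a guard
#'   zone of about one grain diameter restricts counting (and the matching
#'   overview subset volume) to an interior window where centroids are
#'   exact.  For voxel-exact windows use a multiple of both scans' spacings.
#' @param medianKernel,gaussianKernel,gaussianSigma,step,criterion,connectivity
#'   pipeline parameters, see [preprocessVolume()] and
#'   [iterativeThresholdSplit()].
#' @return a [CountEstimate-class] with `workflow = "pollen"`.
#' @export
pollenWorkflow <- function(highres, overview, roiOverview, vmin, vmax,
                           threshold = "otsu", overviewThreshold = NULL,
                           edgeRule = "centroid", guardUm = 0,
                           medianKernel = 3L, gaussianKernel = 9L,
                           gaussianSigma = 1.5, step = NULL,
                           criterion = "volume_stability",
                           connectivity = 26L) {
  stopifnot(is(highres, "Volume3D"), is(overview, "Volume3D"), guardUm >= 0)
  if (highres@calibration != overview@calibration)
    warning("high-resolution and overview scans have different calibration ",
            "states (", highres@calibration, " vs ", overview@calibration, ")")
  pre <- preprocessVolume(highres, threshold, medianKernel, gaussianKernel,
                          gaussianSigma)
  lm <- iterativeThresholdSplit(pre$vol, pre$mask, vmin = vmin, vmax = vmax,
                                step = step, criterion = criterion,
                                connectivity = connectivity)
  if (nLabels(lm) == 0L) stop("no objects validated in the high-resolution scan")
  dHr <- dim(volData(highres))
  sHr <- voxelSpacing(highres)
  gHr <- as.integer(round(guardUm / sHr))
  if (any(2L * gHr >= dHr)) stop("guard zone swallows the whole scan")
  nSubset <- subsetCount(lm, subsetROI(gHr, dHr - gHr), edgeRule = edgeRule)
  if (nSubset < 1) stop("subset count is zero under the ", edgeRule, " rule")
  if (is.null(overviewThreshold))
    overviewThreshold <- if (identical(threshold, "otsu"))
      otsuThreshold(overview) else threshold
  ovMask <- thresholdGrey(overview, overviewThreshold)
  voxOv <- voxelVolume(overview)
  vTotal <- sum(ovMask@data) * voxOv
  if (vTotal <= 0) stop("overview scan has zero segmented foreground")
  ## overview counting window = subset footprint eroded by the realized
  ## guard width (voxel membership by voxel-centre coordinate)
  sOv <- voxelSpacing(overview)
  loUm <- roiOverview@lo * sOv + gHr * sHr
  hiUm <- roiOverview@hi * sOv - gHr * sHr
  dOv <- dim(ovMask@data)
  inWin <- .windowMaskUm(dOv, sOv, loUm, hiUm)
  vSubset <- sum(ovMask@data & inWin) * voxOv
  .countEstimate(nSubset, vSubset, vTotal, "pollen")
}

## logical array marking voxels whose centre (i + 0.5) * spacing falls in
## the half-open micrometre window [loUm, hiUm)
.windowMaskUm <- function(d, spacing, loUm, hiUm) {
  m <- array(FALSE, d)
  ix <- lapply(1:3, function(a) {
    ctr <- (seq_len(d[a]) - 0.5) * spacing[a]
    which(ctr >= loUm[a] & ctr < hiUm[a])
  })
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  m
}

#' Ovule counting workflow (single scan)
#'
#' Segments the ovules on one scan of the whole gynoecium, counts those of a
#' subset window (automatically by centroid membership, or with an
#' operator-supplied manual landmark count) and extrapolates the total from
#' the segmented volumes of the subset and the whole ovary.
#'
#' @param vol [Volume3D-class] of the gynoecium; ovules must be resolvable.
#' @param roi subset window ([SubsetROI-class]).
#' @param vmin,vmax ovule volume bounds in um^3.
#' @param manualN optional manual count of ovules inside the subset; when
#'   given it replaces the automatic count.
#' @param separate run the iterative-threshold separation (default); if
#'   `FALSE`, plain connected-component labelling is used.
#' @param edgeRule,threshold,medianKernel,gaussianKernel,gaussianSigma,step,criterion,connectivity
#'   as in [pollenWorkflow()].
#' @return a [CountEstimate-class] with `workflow = "ovule"`.
#' @export
ovuleWorkflow <- function(vol, roi, vmin, vmax, manualN = NULL,
                          separate = TRUE, edgeRule = "centroid",
                          threshold = "otsu", medianKernel = 3L,
                          gaussianKernel = 9L, gaussianSigma = 1.5,
                          step = NULL, criterion = "volume_stability",
                          connectivity = 26L) {
  stopifnot(is(vol, "Volume3D"))
  pre <- preprocessVolume(vol, threshold, medianKernel, gaussianKernel,
                          gaussianSigma)
  lm <- if (separate)
    iterativeThresholdSplit(pre$vol, pre$mask, vmin = vmin, vmax = vmax,
                            step = step, criterion = criterion,
                            connectivity = connectivity)
  else labelComponents(pre$mask, connectivity)
  if (nLabels(lm) == 0L) stop("no ovules segmented")
  tbl <- objectStats(lm, pre$vol)
  keep <- tbl$volumeUm3 >= vmin & tbl$volumeUm3 <= vmax
  labKeep <- array(lm@data %in% tbl$label[keep] & lm@data > 0L, dim(lm@data))
  voxv <- voxelVolume(vol)
  vTotal <- sum(labKeep) * voxv
  inRoi <- roiMask(roi, dim(lm@data))
  vSubset <- sum(labKeep & inRoi) * voxv
  nAuto <- subsetCount(lm, roi, edgeRule = edgeRule, tbl = tbl,
                       vmin = vmin, vmax = vmax)
  nSubset <- if (is.null(manualN)) nAuto else manualN
  .countEstimate(nSubset, vSubset, vTotal, "ovule")
}

#' Massulae count (direct, no extrapolation)
#'
#' Massulae are resolvable whole on the overview scan, so the count is the
#' number of connected components within massula-scale volume bounds; no
#' subset extrapolation is involved.
#'
#' @param vol [Volume3D-class] of the pollinium overview scan.
#' @param vmin,vmax massula volume bounds in um^3.
#' @param separate use the iterative-threshold separation instead of plain
#'   labelling (default `FALSE`: well-separated massulae need no splitting).
#' @param threshold,medianKernel,gaussianKernel,gaussianSigma,step,criterion,connectivity
#'   as in [pollenWorkflow()].
#' @return integer massulae count.
#' @export
massulaeWorkflow <- function(vol, vmin, vmax, separate = FALSE,
                             threshold = "otsu", medianKernel = 3L,
                             gaussianKernel = 9L, gaussianSigma = 1.5,
                             step = NULL, criterion = "volume_stability",
                             connectivity = 26L) {
  stopifnot(is(vol, "Volume3D"))
  pre <- preprocessVolume(vol, threshold, medianKernel, gaussianKernel,
                          gaussianSigma)
  lm <- if (separate)
    iterativeThresholdSplit(pre$vol, pre$mask, vmin = vmin, vmax = vmax,
                            step = step, criterion = criterion,
                            connectivity = connectivity)
  else labelComponents(pre$mask, connectivity)
  countObjects(objectStats(lm), vmin, vmax)
}

#' Append a flower record to a per-flower count table
#'
#' Adds one row to a flower-record CSV (creating it with a header when
#' absent): species, individual, flower position, pollination strategy, the
#' pollen/ovule/massulae counts that are available, and P:O when both
#' counts are present.
#'
#' @param path CSV file path.
#' @param species,individual character identifiers.
#' @param position one of `"bottom"`, `"middle"`, `"top"`.
#' @param strategy `"deceptive"` or `"rewarding"`.
#' @param pollen,ovule,massulae counts (`NA` when not measured).
#' @return the appended row, invisibly.
#' @export
appendFlowerRecord <- function(path, species, individual, position,
                               strategy, pollen = NA, ovule = NA,
                               massulae = NA) {
  position <- match.arg(position, c("bottom", "middle", "top"))
  strategy <- match.arg(strategy, c("deceptive", "rewarding"))
  row <- data.frame(species = species, individual = individual,
                    position = position, strategy = strategy,
                    pollen = pollen, ovule = ovule, massulae = massulae,
                    po = if (!is.na(pollen) && !is.na(ovule) && ovule > 0)
                      pollen / ovule else NA_real_)
  fresh <- !file.exists(path)
  suppressWarnings(utils::write.table(row, path, sep = ",", dec = ".",
                                      row.names = FALSE, col.names = fresh,
                                      append = !fresh, qmethod = "double"))
  invisible(row)
}

#' Pollen-to-ovule ratio
#'
#' Computed per flower (and only then summarized), never as a ratio of group
#' means.
#'
#' @param pollen pollen grain count.
#' @param ovule ovule count, `> 0`.
#' @return `pollen / ovule`.
#' @examples
#' pollenOvuleRatio(100000, 5000)
#' @export
pollenOvuleRatio <- function(pollen, ovule) {
  if (any(!is.finite(ovule)) || any(ovule <= 0))
    stop("ovule count must be positive")
  pollen / ovule
}
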