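## Object separation and counting.  Touching objects are separated by a
## descending threshold sweep over the grey values: as the threshold drops,
## connected components appear, grow and merge, forming a merge tree.  Each
## branch of the tree is validated against physical volume bounds and a
## stability criterion (smallest relative volume change between consecutive
## thresholds, MSER-style); where a parent and its children both validate,
## the children win, which is what splits merged grains.

#' 3D connected-component labelling
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6 (face-adjacent) or 26 (face, edge or vertex
#'   adjacent; the default, standard for blob counting in 3D).
#' @return a [LabelMap-class]; labels are assigned in raster-scan order of
#'   each component's first voxel, so the result is deterministic.
#' @examples
#' m <- array(FALSE, c(1, 3, 3)); m[1, 1, 1] <- m[1, 3, 3] <- TRUE
#' lm <- labelComponents(new("BinaryMask", data = m, spacing = c(1, 1, 1)), 6)
#' nLabels(lm)
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  d <- dim(mask@data)
  lab <- cpp_label3d(as.logical(mask@data), d, as.integer(connectivity))
  new("LabelMap", data = array(as.integer(lab), d), spacing = mask@spacing,
      nLabels = as.integer(attr(lab, "n_labels")))
}

#' Separate touching objects by an iterative threshold sweep
#'
#' Thresholds sweep from the volume's maximum grey value down to the
#' preprocessing threshold (the smallest grey inside the mask) in decrements
#' of `step`, maintaining the component merge tree.  A branch is validated
#' where its physical volume lies within `[vmin, vmax]` at the threshold
#' optimizing the criterion:
#' \describe{
#'   \item{`volume_stability`}{the threshold with the smallest relative
#'     volume change to the next lower threshold (MSER-style plateau);
#'     ties resolve to the higher threshold, which favours splitting.}
#'   \item{`max_count`}{the highest valid threshold on each branch, the
#'     most aggressive splitting rule.}
#' }
#' When both a merged parent and its children validate, the children are
#' kept.  Output labels are the validated components' voxel sets at their
#' selected thresholds, renumbered in raster-scan order.
#'
#' @param vol a (preprocessed) [Volume3D-class]; grey values drive the sweep.
#' @param mask foreground [BinaryMask-class]; if `NULL`, all voxels `> 0`.
#' @param vmin,vmax object volume bounds in cubic micrometres; these are
#'   mandatory, physically meaningful settings (approximate grain/ovule
#'   volume bracket).
#' @param step sweep decrement in grey levels.  Default: 1 for
#'   integer-valued volumes, 1/255 of the swept range otherwise.
#' @param criterion `"volume_stability"` (default) or `"max_count"`.
#' @param connectivity 6 or 26 (default).
#' @return a [LabelMap-class] of separated objects.
#' @export
iterativeThresholdSplit <- function(vol, mask = NULL, vmin, vmax, step = NULL,
                                    criterion = c("volume_stability",
                                                  "max_count"),
                                    connectivity = 26L) {
  stopifnot(is(vol, "Volume3D"))
  criterion <- match.arg(criterion)
  if (!is.finite(vmin) || !is.finite(vmax) || vmin >= vmax)
    stop("need finite volume bounds with vmin < vmax")
  d <- dim(vol@data)
  v <- vol@data
  if (is.null(mask)) {
    m <- v > 0
  } else {
    stopifnot(is(mask, "BinaryMask"))
    if (!identical(dim(mask@data), d)) stop("mask shape mismatch")
    m <- mask@data
  }
  if (!any(m)) stop("empty foreground")
  vals <- v[m]
  tmax <- max(vals)
  tmin <- min(vals)
  if (is.null(step)) {
    step <- if (all(vals == round(vals))) 1 else max((tmax - tmin) / 255, .Machine$double.eps)
  }
  if (step <= 0) stop("step must be positive")
  thresholds <- if (tmax == tmin) tmin else rev(seq(tmin, tmax, by = step))
  if (thresholds[length(thresholds)] > tmin)
    thresholds <- c(thresholds, tmin)
  voxvol <- prod(vol@spacing)
  conn <- as.integer(connectivity)

  ## one pass builds the complete merge tree: per-voxel attachment node and
  ## entry level, per-node parent, start level and volume profile
  sweep <- cpp_threshold_sweep(as.numeric(v), d, as.logical(m),
                               as.numeric(thresholds), conn)
  nnode <- length(sweep$parent)
  if (nnode == 0L)
    return(new("LabelMap", data = array(0L, d), spacing = vol@spacing,
               nLabels = 0L))
  parent <- sweep$parent
  startLevel <- sweep$startLevel
  profiles <- sweep$profile
  live <- !sweep$defunct

  ## validate each node: pick its level, if any volume is within bounds
  selLevel <- rep(NA_integer_, nnode)
  for (i in seq_len(nnode)) {
    if (!live[i]) next
    pv <- profiles[[i]] * voxvol
    ok <- which(pv >= vmin & pv <= vmax)
    if (!length(ok)) next
    if (criterion == "max_count") {
      selLevel[i] <- startLevel[i] + ok[1] - 1L
    } else {
      ## relative growth to the next lower threshold; the last profile entry
      ## continues into the parent's first (merged) volume where one exists
      nxt <- c(profiles[[i]][-1], NA)
      if (parent[i] > 0L) nxt[length(nxt)] <- profiles[[parent[i]]][1]
      stab <- abs(nxt - profiles[[i]]) / profiles[[i]]
      stab[!is.finite(stab)] <- Inf
      ## a lone in-bounds entry is still selectable
      sel <- if (all(is.infinite(stab[ok]))) ok[1] else ok[which.min(stab[ok])]
      selLevel[i] <- startLevel[i] + sel - 1L
    }
  }

  ## children win over validated parents: a node is kept iff it validates
  ## and none of its descendants was kept (ids increase towards the root)
  keep <- logical(nnode)
  subtreeKept <- logical(nnode)
  for (i in seq_len(nnode)) {
    if (!live[i]) next
    below <- subtreeKept[i]
    keep[i] <- !is.na(selLevel[i]) && !below
    up <- if (keep[i] || below) parent[i] else 0L
    if (up > 0L) subtreeKept[up] <- TRUE
  }

  kept <- which(keep)
  if (!length(kept))
    return(new("LabelMap", data = array(0L, d), spacing = vol@spacing,
               nLabels = 0L))

  ## nearest kept ancestor-or-self of every node; parents always carry
  ## larger ids, so a descending pass resolves ancestors first
  selAnc <- integer(nnode)
  selAnc[kept] <- kept
  for (i in rev(seq_len(nnode))) {
    if (selAnc[i] == 0L && parent[i] > 0L) selAnc[i] <- selAnc[parent[i]]
  }

  ## a voxel belongs to a kept node's component when its attachment node
  ## falls in that subtree and it entered at or above the selected level
  attach <- sweep$attach
  appear <- sweep$appear + 1L       # 1-based levels; 0 -> never entered
  fgIdx <- which(attach > 0L)
  anc <- selAnc[attach[fgIdx]]
  inSel <- anc > 0L & appear[fgIdx] <= selLevel[pmax(anc, 1L)]
  out <- array(0L, d)
  out[fgIdx[inSel]] <- anc[inSel]

  ## renumber 1..K in raster-scan order of first voxel
  firstVox <- vapply(split(fgIdx[inSel], anc[inSel]), min, numeric(1))
  ord <- as.integer(names(sort(firstVox)))
  relab <- integer(max(ord))
  relab[ord] <- seq_along(ord)
  out[out > 0L] <- relab[out[out > 0L]]
  new("LabelMap", data = out, spacing = vol@spacing,
      nLabels = length(ord))
}

#' Per-object statistics
#'
#' One row per label: voxel count, physical volume (voxel count times voxel
#' volume), intensity-unweighted centroid in micrometres (volume frame, voxel
#' centres at `(i + 0.5) * spacing`), voxel bounding box (0-based, inclusive)
#' and mean intensity.
#'
#' @param lm a [LabelMap-class].
#' @param vol the matching [Volume3D-class] (for mean intensity); optional.
#' @return a `data.frame` with columns `label`, `voxelCount`, `volumeUm3`,
#'   `czUm`, `cyUm`, `cxUm`, `z0`, `z1`, `y0`, `y1`, `x0`, `x1`,
#'   `meanIntensity`.
#' @export
objectStats <- function(lm, vol = NULL) {
  stopifnot(is(lm, "LabelMap"))
  if (!is.null(vol)) {
    stopifnot(is(vol, "Volume3D"))
    if (!identical(dim(vol@data), dim(lm@data)))
      stop("volume and label map shapes differ")
  }
  K <- lm@nLabels
  sp <- lm@spacing
  if (K == 0L)
    return(data.frame(label = integer(0), voxelCount = integer(0),
                      volumeUm3 = numeric(0), czUm = numeric(0),
                      cyUm = numeric(0), cxUm = numeric(0),
                      z0 = integer(0), z1 = integer(0), y0 = integer(0),
                      y1 = integer(0), x0 = integer(0), x1 = integer(0),
                      meanIntensity = numeric(0)))
  d <- dim(lm@data)
  idx <- which(lm@data > 0L)
  lab <- lm@data[idx]
  z <- (idx - 1L) %% d[1]
  rest <- (idx - 1L) %/% d[1]
  y <- rest %% d[2]
  x <- rest %/% d[2]
  cnt <- tabulate(lab, nbins = K)
  stat <- function(w) vapply(split(w, lab), mean, numeric(1))
  mn <- function(w) vapply(split(w, lab), min, numeric(1))
  mx <- function(w) vapply(split(w, lab), max, numeric(1))
  data.frame(
    label = seq_len(K),
    voxelCount = cnt,
    volumeUm3 = cnt * prod(sp),
    czUm = (stat(z) + 0.5) * sp[1],
    cyUm = (stat(y) + 0.5) * sp[2],
    cxUm = (stat(x) + 0.5) * sp[3],
    z0 = as.integer(mn(z)), z1 = as.integer(mx(z)),
    y0 = as.integer(mn(y)), y1 = as.integer(mx(y)),
    x0 = as.integer(mn(x)), x1 = as.integer(mx(x)),
    meanIntensity = if (is.null(vol)) NA_real_ else stat(vol@data[idx]),
    row.names = NULL)
}

#' Count objects within a physical volume window
#'
#' @param tbl an object table from [objectStats()].
#' @param vmin,vmax inclusive physical volume bounds (um^3).
#' @return number of objects with `volumeUm3` in `[vmin, vmax]`.
#' @export
countObjects <- function(tbl, vmin = 0, vmax = Inf) {
  if (vmin > vmax) stop("need vmin <= vmax")
  sum(tbl$volumeUm3 >= vmin & tbl$volumeUm3 <= vmax)
}
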