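## Phantom generators with exact ground truth.  They emulate the three kinds
## of input the counting pipeline sees: a pollinium (thousands of mutually
## touching quasi-spherical grains, optionally clustered into a few large and
## many small massulae), an ovary (resolvable ovules along a cylindrical
## placenta, optionally with contiguous gaps), and a two-compartment
## calibration dummy.  Every generator is a pure function of its parameters
## and seed.

## run `expr` under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Bundles the geometric and imaging parameters of the pollinium phantom.
#' The defaults describe the benchmark condition used throughout the
#' package's validation: a 256^3 voxel volume at 1 um/voxel holding 3000
#' mutually touching grains with mean radius 5.5 um and radius CV 0.15,
#' imaged with a 1-voxel Gaussian PSF and additive Gaussian noise at
#' signal-to-noise ratio 10 (foreground 180, background 20, noise SD 16).
#'
#' @param nObjects number of grains to pack.
#' @param rMeanUm,rCV lognormal grain radius distribution: mean radius in um
#'   and coefficient of variation.
#' @param mode `"touching"` (tangency permitted, overlap limited to
#'   `overlapFrac`), `"loose"` (disjoint with a five-percent clearance), or
#'   `"massulae"` (grains clustered into unequal sub-aggregates).
#' @param dim volume shape in voxels `(z, y, x)`.
#' @param spacingUm voxel spacing in um `(z, y, x)`.
#' @param psfSigmaUm Gaussian point-spread sigma in um (0 disables).
#' @param bgGrey,fgGrey background and object grey levels (8-bit range).
#' @param noiseSD additive Gaussian noise standard deviation (0 disables).
#' @param gradient linear shading: relative intensity slope across the x
#'   axis (0 disables).
#' @param massulaCount number of massulae in `"massulae"` mode.
#' @param massulaSizeSDLog log-scale SD of massula sizes (a large value
#'   gives a few large and many small massulae).
#' @param overlapFrac maximum allowed centre-distance shortfall as a
#'   fraction of the radius sum in `"touching"`/`"massulae"` modes.
#' @param seed integer seed fixing every stochastic draw.
#' @return a `ctPhantomSpec` list.
#' @export
phantomSpec <- function(nObjects = 3000, rMeanUm = 5.5, rCV = 0.15,
                        mode = c("touching", "loose", "massulae"),
                        dim = c(256, 256, 256), spacingUm = c(1, 1, 1),
                        psfSigmaUm = 1, bgGrey = 20, fgGrey = 180,
                        noiseSD = 16, gradient = 0, massulaCount = 40,
                        massulaSizeSDLog = 0.8, overlapFrac = 0.1,
                        seed = 1) {
  mode <- match.arg(mode)
  stopifnot(nObjects >= 1, rMeanUm > 0, rCV >= 0, all(dim >= 1),
            all(spacingUm > 0), psfSigmaUm >= 0, noiseSD >= 0,
            overlapFrac >= 0, overlapFrac < 1)
  structure(list(nObjects = as.integer(nObjects), rMeanUm = rMeanUm,
                 rCV = rCV, mode = mode, dim = as.integer(dim),
                 spacingUm = as.numeric(spacingUm), psfSigmaUm = psfSigmaUm,
                 bgGrey = bgGrey, fgGrey = fgGrey, noiseSD = noiseSD,
                 gradient = gradient, massulaCount = as.integer(massulaCount),
                 massulaSizeSDLog = massulaSizeSDLog,
                 overlapFrac = overlapFrac, seed = as.integer(seed)),
            class = "ctPhantomSpec")
}

## lognormal radii with the requested mean and CV
.sampleRadii <- function(n, rMean, rCV) {
  if (rCV <= 0) return(rep(rMean, n))
  sdlog <- sqrt(log(1 + rCV^2))
  rlnorm(n, meanlog = log(rMean) - sdlog^2 / 2, sdlog = sdlog)
}

## Random sequential addition of spheres with a uniform cell grid for the
## neighbour search.  `propose()` returns candidate centres (um);  `sep` is
## the required centre distance as a multiple of the radius sum.
.packSpheres <- function(n, radii, propose, sep, maxTries) {
  centers <- matrix(NA_real_, n, 3)
  rmax <- max(radii)
  cell <- 2 * rmax + 1e-9
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ci) paste(ci, collapse = ",")
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < maxTries) {
    tries <- tries + 1L
    i <- placed + 1L
    p <- propose(i)
    ci <- floor(p / cell)
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      nb <- grid[[key(ci + c(dz, dy, dx))]]
      if (is.null(nb)) next
      for (j in nb) {
        need <- sep * (radii[i] + radii[j])
        if (sum((p - centers[j, ])^2) < need^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    centers[placed, ] <- p
    k <- key(ci)
    grid[[k]] <- c(grid[[k]], placed)
  }
  list(centers = centers[seq_len(placed), , drop = FALSE], placed = placed)
}

#' Render a set of spheres as a CT-like volume
#'
#' Solid spheres at the foreground grey level on a uniform background,
#' convolved with a Gaussian PSF, with optional additive Gaussian noise and
#' linear shading, finally clamped to `[0, 255]` and rounded to integer grey
#' levels (8-bit-like data).  Voxel centres sit at `(i + 0.5) * spacing`;
#' `originUm` shifts the coordinate frame, which is how the same ground
#' truth is rendered as an overview scan and as a high-resolution scan of a
#' subset.
#'
#' @param centersUm n x 3 matrix of sphere centres (um, `(z, y, x)`).
#' @param radiiUm sphere radii (um).
#' @param dim,spacingUm output shape (voxels) and spacing (um).
#' @param originUm coordinate of the volume's low corner in the ground-truth
#'   frame (um).
#' @param fgGrey,bgGrey,psfSigmaUm,noiseSD,gradient see [phantomSpec()].
#' @param seed seed for the noise draw.
#' @return a raw [Volume3D-class].
#' @export
renderPhantom <- function(centersUm, radiiUm, dim, spacingUm,
                          originUm = c(0, 0, 0), fgGrey = 180, bgGrey = 20,
                          psfSigmaUm = 1, noiseSD = 16, gradient = 0,
                          seed = 1) {
  dim <- as.integer(dim)
  base <- rep(as.numeric(bgGrey), prod(dim))
  v <- cpp_render_spheres(base, dim, as.numeric(spacingUm),
                          as.numeric(originUm),
                          as.matrix(centersUm), as.numeric(radiiUm),
                          as.numeric(fgGrey))
  if (psfSigmaUm > 0) {
    for (axis in 0:2) {
      sig <- psfSigmaUm / spacingUm[axis + 1]
      k <- 2L * as.integer(ceiling(3 * sig)) + 1L
      v <- cpp_conv_axis(v, dim, gaussianKernel1d(k, sig), axis)
    }
  }
  arr <- array(v, dim)
  if (gradient != 0) {
    xs <- ((seq_len(dim[3]) - 0.5) / dim[3] - 0.5) * gradient
    arr <- arr * (1 + rep(xs, each = dim[1] * dim[2]))
  }
  if (noiseSD > 0)
    arr <- arr + withSeed(seed, array(rnorm(length(arr), 0, noiseSD), dim))
  arr <- roundHalfUp(pmin(pmax(arr, 0), 255))
  Volume3D(array(arr, dim), spacing = spacingUm, provenance = "phantom")
}

#' Generate a pollinium phantom
#'
#' Packs grains by random sequential addition inside a spherical pollinium
#' domain (in `"massulae"` mode, cluster centres and lognormal cluster sizes
#' are sampled first and grains are packed within clusters) and renders the
#' result.  Packing that stalls within the retry budget returns the achieved
#' number of grains with a warning.
#'
#' @param spec a [phantomSpec()].
#' @param render render the volume (set `FALSE` for geometry only).
#' @param maxTries retry budget for the sphere packing.
#' @return a list: `volume` (a [Volume3D-class], or `NULL`), `truth` (a
#'   `data.frame` with columns `zUm`, `yUm`, `xUm`, `rUm`, `massula`),
#'   `count`, `totalVolumeUm3` (analytic), and `spec`.
#' @export
generatePollinium <- function(spec = phantomSpec(), render = TRUE,
                              maxTries = 400L * spec$nObjects) {
  stopifnot(inherits(spec, "ctPhantomSpec"))
  withSeed(spec$seed, {
    extent <- spec$dim * spec$spacingUm
    centre <- extent / 2
    ## constant margin: the packed geometry must not depend on rendering
    ## parameters such as the PSF width
    margin <- 6
    rDom <- min(extent) / 2 - margin
    if (rDom <= spec$rMeanUm) stop("volume too small for the pollinium domain")
    radii <- .sampleRadii(spec$nObjects, spec$rMeanUm, spec$rCV)
    sep <- switch(spec$mode, loose = 1.05, 1 - spec$overlapFrac)
    inBall <- function(c0, R) function(i) {
      repeat {
        p <- runif(3, -1, 1) * R
        if (sum(p^2) <= R^2) return(c0 + p)
      }
    }
    if (spec$mode == "massulae") {
      w <- rlnorm(spec$massulaCount, 0, spec$massulaSizeSDLog)
      sizes <- pmax(1L, as.integer(round(spec$nObjects * w / sum(w))))
      ## cluster radius from its grain load at a moderate packing fraction
      ev3 <- spec$rMeanUm^3 * (1 + 3 * spec$rCV^2)
      cRad <- (sizes * ev3 / 0.30)^(1 / 3) + spec$rMeanUm
      if (sum(cRad^3) > 0.15 * rDom^3)
        stop("massulae do not fit the volume: reduce nObjects, ",
             "massulaCount or grain radius, or enlarge the volume")
      ord <- order(cRad, decreasing = TRUE)   # place big clusters first
      cRad <- cRad[ord]; sizes <- sizes[ord]
      ## massulae are resolvably distinct sub-aggregates: keep a clearance
      ## of a quarter of the radius sum so smoothing cannot bridge them
      cPack <- .packSpheres(spec$massulaCount, cRad, function(i)
                            inBall(centre, max(rDom - cRad[i],
                                               0.1 * rDom))(i), 1.25,
                            2000L * spec$massulaCount)
      if (cPack$placed < spec$massulaCount)
        warning("placed only ", cPack$placed, " of ", spec$massulaCount,
                " massulae")
      sizes <- sizes[seq_len(cPack$placed)]
      massula <- rep(seq_len(cPack$placed), sizes)
      ## rounding can push the grain total past nObjects: redraw to match
      radii <- .sampleRadii(sum(sizes), spec$rMeanUm, spec$rCV)
      ## a uniform placement margin (the cluster's largest grain) keeps
      ## grain size independent of position; a size-dependent margin would
      ## deplete large grains near the boundary and bias subset estimates
      cMargin <- vapply(seq_len(cPack$placed), function(k)
        max(radii[massula == k]), numeric(1))
      prop <- function(i) {
        k <- massula[i]
        inBall(cPack$centers[k, ], cRad[k] - cMargin[k])(i)
      }
      pk <- .packSpheres(sum(sizes), radii, prop, sep, maxTries)
      massula <- massula[seq_len(pk$placed)]
    } else {
      rMargin <- max(radii)
      prop <- function(i) inBall(centre, rDom - rMargin)(i)
      pk <- .packSpheres(spec$nObjects, radii, prop, sep, maxTries)
      massula <- rep(1L, pk$placed)
    }
    if (pk$placed < spec$nObjects)
      warning("packing stalled: placed ", pk$placed, " of ",
              spec$nObjects, " objects")
    radii <- radii[seq_len(pk$placed)]
    truth <- data.frame(zUm = pk$centers[, 1], yUm = pk$centers[, 2],
                        xUm = pk$centers[, 3], rUm = radii,
                        massula = massula)
    ## a massula is a compact stained aggregate: render each cluster as a
    ## solid blob (its grains are embedded in it), so massulae are connected
    ## objects like in real overview scans
    centers <- pk$centers
    if (spec$mode == "massulae" && cPack$placed > 0L) {
      centers <- rbind(cPack$centers, centers)
      radii2 <- c(cRad[seq_len(cPack$placed)], radii)
    } else radii2 <- radii
    vol <- if (render)
      renderPhantom(centers, radii2, spec$dim, spec$spacingUm,
                    originUm = c(0, 0, 0), fgGrey = spec$fgGrey,
                    bgGrey = spec$bgGrey, psfSigmaUm = spec$psfSigmaUm,
                    noiseSD = spec$noiseSD, gradient = spec$gradient,
                    seed = spec$seed + 1L)
    else NULL
    list(volume = vol, truth = truth, count = pk$placed,
         totalVolumeUm3 = sum(4 / 3 * pi * radii^3), spec = spec)
  })
}

#' Generate an ovary phantom
#'
#' Ovules are placed along a cylindrical placenta model (axis = z), at
#' uniform axial positions outside an optional contiguous gap covering
#' `gapFraction` of the placenta length, and at uniform positions within an
#' annular radial band.
#'
#' @param spec a [phantomSpec()]; sensible ovary defaults are
#'   `phantomSpec(nObjects = 800, rMeanUm = 5, rCV = 0.1, mode = "loose")`.
#' @param gapFraction fraction of the placenta length occupied by a single
#'   contiguous ovule-free gap (0 disables).
#' @param render,maxTries as in [generatePollinium()].
#' @return as [generatePollinium()]; `truth$massula` is always 1.
#' @export
generateOvary <- function(spec = phantomSpec(nObjects = 800, rMeanUm = 5,
                                             rCV = 0.1, mode = "loose"),
                          gapFraction = 0, render = TRUE,
                          maxTries = 400L * spec$nObjects) {
  stopifnot(inherits(spec, "ctPhantomSpec"), gapFraction >= 0, gapFraction < 1)
  withSeed(spec$seed, {
    extent <- spec$dim * spec$spacingUm
    margin <- 6
    z0 <- margin + 0.1 * extent[1]
    z1 <- extent[1] - margin - 0.1 * extent[1]
    rMax <- min(extent[2], extent[3]) / 2 - margin
    radii <- .sampleRadii(spec$nObjects, spec$rMeanUm, spec$rCV)
    rInner <- 2 * spec$rMeanUm
    gap <- NULL
    if (gapFraction > 0) {
      gLen <- gapFraction * (z1 - z0)
      gStart <- runif(1, z0, z1 - gLen)
      gap <- c(gStart, gStart + gLen)
    }
    rMargin <- max(radii)   # uniform margin: size independent of position
    prop <- function(i) {
      repeat {
        z <- runif(1, z0, z1)
        if (!is.null(gap) && z >= gap[1] && z <= gap[2]) next
        rr <- sqrt(runif(1, (rInner / rMax)^2,
                         ((rMax - rMargin) / rMax)^2)) * rMax
        th <- runif(1, 0, 2 * pi)
        return(c(z, extent[2] / 2 + rr * sin(th), extent[3] / 2 + rr * cos(th)))
      }
    }
    sep <- if (spec$mode == "loose") 1.05 else 1 - spec$overlapFrac
    pk <- .packSpheres(spec$nObjects, radii, prop, sep, maxTries)
    if (pk$placed < spec$nObjects)
      warning("packing stalled: placed ", pk$placed, " of ",
              spec$nObjects, " ovules")
    radii <- radii[seq_len(pk$placed)]
    truth <- data.frame(zUm = pk$centers[, 1], yUm = pk$centers[, 2],
                        xUm = pk$centers[, 3], rUm = radii, massula = 1L)
    vol <- if (render)
      renderPhantom(pk$centers, radii, spec$dim, spec$spacingUm,
                    fgGrey = spec$fgGrey, bgGrey = spec$bgGrey,
                    psfSigmaUm = spec$psfSigmaUm, noiseSD = spec$noiseSD,
                    gradient = spec$gradient, seed = spec$seed + 1L)
    else NULL
    list(volume = vol, truth = truth, count = pk$placed,
         totalVolumeUm3 = sum(4 / 3 * pi * radii^3), spec = spec,
         gap = gap)
  })
}

#' Generate a calibration dummy phantom
#'
#' A cylinder of reference liquid (axis = z) surrounded by air, with
#' optional Gaussian noise: the synthetic analogue of the reference-filled
#' pipette tip scanned for CT scaling.
#'
#' @param airGrey,refGrey raw mean grey levels of the two compartments.
#' @param noiseSD additive Gaussian noise SD.
#' @param dim volume shape (voxels).
#' @param spacingUm voxel spacing (um).
#' @param seed noise seed.
#' @return a list: `volume` ([Volume3D-class]), `airROI`, `refROI`
#'   ([SubsetROI-class] windows lying fully in the respective compartments).
#' @export
generateDummy <- function(airGrey = 20, refGrey = 200, noiseSD = 0,
                          dim = c(64, 64, 64), spacingUm = c(1, 1, 1),
                          seed = 1) {
  if (airGrey == refGrey) stop("compartment greys must be distinct")
  dim <- as.integer(dim)
  cy <- dim[2] / 2; cx <- dim[3] / 2
  rad <- 0.35 * min(dim[2], dim[3])
  yy <- matrix(rep(seq_len(dim[2]) - 0.5 - cy, dim[3]), dim[2])
  xx <- matrix(rep(seq_len(dim[3]) - 0.5 - cx, each = dim[2]), dim[2])
  slice <- ifelse(yy^2 + xx^2 <= rad^2, refGrey, airGrey)
  arr <- aperm(array(slice, c(dim[2], dim[3], dim[1])), c(3, 1, 2))
  if (noiseSD > 0)
    arr <- arr + withSeed(seed, array(rnorm(length(arr), 0, noiseSD), dim))
  vol <- Volume3D(array(arr, dim), spacing = spacingUm, provenance = "dummy")
  eighth <- pmax(2L, dim %/% 8L)
  list(volume = vol,
       airROI = subsetROI(c(0, 0, 0), c(dim[1], eighth[2], eighth[3])),
       refROI = subsetROI(c(0, dim[2] %/% 2 - eighth[2] %/% 2,
                            dim[3] %/% 2 - eighth[3] %/% 2),
                          c(dim[1], dim[2] %/% 2 + eighth[2] %/% 2,
                            dim[3] %/% 2 + eighth[3] %/% 2)))
}

#' Default species parameters for the synthetic flower table
#'
#' Eight species (three rewarding, five deceptive) with pollen and ovule
#' scales spanning the ranges typical of European orchids (tens of thousands
#' to hundreds of thousands of pollen grains; thousands of ovules, with
#' deceptive species carrying more ovules than rewarding ones).
#'
#' @return a `data.frame` with per-species generator parameters.
#' @export
defaultSpeciesParams <- function() {
  data.frame(
    species = paste0("species_", letters[1:8]),
    strategy = c("deceptive", "deceptive", "rewarding", "deceptive",
                 "deceptive", "rewarding", "deceptive", "rewarding"),
    pollenMean = c(105000, 74000, 52000, 79000, 72000, 36000, 176000, 216000),
    pollenCV = 0.12,
    ovuleBottom = c(9800, 4350, 3400, 9000, 5450, 1770, 14200, 4930),
    ovuleCV = 0.15,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic per-flower count table
#'
#' Draws per-flower pollen and ovule counts from lognormal per-species
#' distributions with a multiplicative ovule position effect (ovule numbers
#' declining from bottom to top of the inflorescence) and computes the
#' per-flower pollen-to-ovule ratio.  The true effect sizes are recorded as
#' attributes.
#'
#' @param speciesParams per-species parameters, see [defaultSpeciesParams()].
#' @param nIndividuals inflorescences per species (each contributes one
#'   flower per position).
#' @param positionEffect multiplicative change in expected ovule number per
#'   position step bottom -> middle -> top (1 = no effect; the default 0.8
#'   is a 20 percent decline per step).
#' @param pollenPositionEffect same for pollen (default 1: no effect).
#' @param seed integer seed.
#' @return a `data.frame` (the flower-record table) with columns `species`,
#'   `individual`, `position`, `strategy`, `pollen`, `ovule`, `po`, plus
#'   attributes `positionEffect` and `pollenPositionEffect`.
#' @export
generateFlowerTable <- function(speciesParams = defaultSpeciesParams(),
                                nIndividuals = 3, positionEffect = 0.8,
                                pollenPositionEffect = 1, seed = 1) {
  positions <- c("bottom", "middle", "top")
  withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(speciesParams)), function(s) {
      p <- speciesParams[s, ]
      do.call(rbind, lapply(seq_len(nIndividuals), function(ind) {
        step <- 0:2
        sdP <- sqrt(log(1 + p$pollenCV^2))
        sdO <- sqrt(log(1 + p$ovuleCV^2))
        pollen <- rlnorm(3, log(p$pollenMean * pollenPositionEffect^step) -
                           sdP^2 / 2, sdP)
        ovule <- rlnorm(3, log(p$ovuleBottom * positionEffect^step) -
                          sdO^2 / 2, sdO)
        data.frame(species = p$species,
                   individual = paste0(p$species, "_", ind),
                   position = positions, strategy = p$strategy,
                   pollen = round(pollen), ovule = round(ovule),
                   stringsAsFactors = FALSE)
      }))
    }))
    rows$po <- pollenOvuleRatio(rows$pollen, rows$ovule)
    attr(rows, "positionEffect") <- positionEffect
    attr(rows, "pollenPositionEffect") <- pollenPositionEffect
    rownames(rows) <- NULL
    rows
  })
}
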