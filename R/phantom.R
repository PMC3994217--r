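## Synthetic voxel limb phantoms and Hounsfield-threshold volumetry.
##
## The phantom family is piecewise conical: at every measurement level the
## outer radius comes from the circumference series (r = C / 2*pi) and the
## lean (muscle + bone) and bone radii are fixed fractions of it; radii are
## interpolated linearly between levels. For such solids the frustum model
## is exact, so ground-truth volumes are available in closed form and both
## arms of the method comparison (tape vs CT) can be run on the same object.
##
## Rasterization convention: voxel centers sit at integer multiples of the
## spacing on all three axes, with the limb axis through the voxel-center
## lattice and the limb occupying the closed axial interval [0, L]. A voxel
## belongs to a compartment when its center does (no partial-volume
## weighting). The closed interval makes the axial discretization error a
## deterministic half-voxel slab at each end, so the total error shrinks
## linearly with the spacing — the behaviour a convergence study wants —
## instead of oscillating erratically the way a lattice count of a disk
## does.

#' Default tissue Hounsfield values
#'
#' Literature-typical CT attenuations: air -1000 HU, subcutaneous fat
#' -100 HU, muscle +50 HU, cortical bone +700 HU.
#'
#' @return Named numeric vector `c(air, fat, muscle, bone)`.
#' @export
defaultTissueHu <- function() {
  c(air = -1000, fat = -100, muscle = 50, bone = 700)
}

#' Construct a phantom profile
#'
#' @param series Outer-surface [CircumferenceSeries-class].
#' @param fatFraction Fat-ring fraction of the outer radius, one value per
#'   level or a single value recycled; in `[0, 1)`.
#' @param boneFraction Bone-core fraction of the outer radius, recycled
#'   likewise; `fatFraction + boneFraction < 1`.
#' @param tissueHu Named HU values, see [defaultTissueHu()].
#' @param noiseSdHu Gaussian image noise SD in HU (default 0).
#' @return A [PhantomProfile-class] object.
#' @export
PhantomProfile <- function(series, fatFraction = 0, boneFraction = 0,
                           tissueHu = defaultTissueHu(), noiseSdHu = 0) {
  if (!is(series, "CircumferenceSeries"))
    vstop("'series' must be a CircumferenceSeries", field = "series")
  n <- nLevels(series)
  fatFraction <- rep_len(as.numeric(fatFraction), n)
  boneFraction <- rep_len(as.numeric(boneFraction), n)
  obj <- new("PhantomProfile", series = series, fatFraction = fatFraction,
             boneFraction = boneFraction, tissueHu = tissueHu,
             noiseSdHu = noiseSdHu)
  validObject(obj)
  obj
}

setMethod("show", "PhantomProfile", function(object) {
  cat(sprintf(
    "PhantomProfile (%s): %d levels over %g cm, fat fraction %.2f-%.2f, noise %g HU\n",
    limbType(object@series), nLevels(object@series),
    max(levelPositions(object@series)) - min(levelPositions(object@series)),
    min(object@fatFraction), max(object@fatFraction), object@noiseSdHu))
})

## Per-level analytic radii (cm) of a profile.
profileRadiiCm <- function(profile) {
  rOut <- circumferences(profile@series) / (2 * pi)
  data.frame(
    positionCm = levelPositions(profile@series) -
      min(levelPositions(profile@series)),
    outer = rOut,
    lean = rOut * (1 - profile@fatFraction),
    bone = rOut * profile@boneFraction
  )
}

## Closed-form compartment volumes (liters) of a profile.
profileGroundTruthL <- function(profile) {
  rad <- profileRadiiCm(profile)
  c(total = frustumSumFromRadii(rad$positionCm, rad$outer) / 1000,
    noFat = frustumSumFromRadii(rad$positionCm, rad$lean) / 1000)
}

#' Rasterize a phantom profile into a voxel grid
#'
#' Generates the voxelized limb: each voxel is labeled by the compartment
#' its center falls in (bone core, muscle annulus, fat ring, surrounding
#' air), HU values are assigned per tissue plus optional Gaussian noise,
#' and the analytic ground-truth volumes are attached. Deterministic for a
#' fixed profile, spacing and seed.
#'
#' @param profile A [PhantomProfile-class].
#' @param spacingMm Isotropic voxel spacing in mm (> 0). An error is raised
#'   when the spacing is too coarse to resolve the smallest non-zero
#'   compartment radius with at least 2 voxels.
#' @param seed Optional integer seed for the HU noise; the caller's RNG
#'   state is left untouched.
#' @return A [Phantom-class] object.
#' @examples
#' cyl <- PhantomProfile(CircumferenceSeries(c(40, 40, 40), "leg"))
#' ph <- generatePhantom(cyl, spacingMm = 4)
#' groundTruthTotalL(ph)
#' ctVolume(ph, thresholdHu = -200)
#' @export
generatePhantom <- function(profile, spacingMm, seed = NULL) {
  if (!is(profile, "PhantomProfile"))
    vstop("'profile' must be a PhantomProfile", field = "profile")
  validObject(profile)
  assertScalarNumber(spacingMm, "spacingMm", positive = TRUE)
  h <- spacingMm

  rad <- profileRadiiCm(profile)
  pMm <- rad$positionCm * 10
  rOutMm <- rad$outer * 10
  rLeanMm <- rad$lean * 10
  rBoneMm <- rad$bone * 10
  lengthMm <- max(pMm)

  allR <- c(rOutMm, rLeanMm, rBoneMm)
  minR <- min(allR[allR > 0])
  if (minR < 2 * h)
    vstop("resolution too coarse: spacing %g mm cannot resolve the smallest radius (%.2f mm) with 2 voxels",
          h, minR, field = "spacingMm")

  ## In-plane lattice offset by half a voxel: the limb axis passes through a
  ## voxel corner, so the center-inside disk count is 4-fold symmetric and
  ## nearly unbiased; the dominant discretization error is then the axial
  ## end-slab term (~ spacing / limb length), which shrinks linearly.
  half <- ceiling(max(rOutMm) / h) + 2L
  xy <- (seq.int(-half, half) + 0.5) * h
  nxy <- length(xy)
  d2 <- as.vector(outer(xy^2, xy^2, "+"))

  zMargin <- 2L
  ks <- seq.int(-zMargin, floor(lengthMm / h) + zMargin)
  z <- ks * h
  nz <- length(z)

  interp <- function(r) {
    out <- rep(0, nz)
    inside <- z >= 0 & z <= lengthMm
    out[inside] <- stats::approx(pMm, r, xout = z[inside], rule = 2)$y
    out
  }
  rOutZ <- interp(rOutMm)
  rLeanZ <- interp(rLeanMm)
  rBoneZ <- interp(rBoneMm)
  inLimbZ <- z >= 0 & z <= lengthMm

  labels <- array(0L, dim = c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    if (!inLimbZ[k] || rOutZ[k] <= 0) next
    labels[, , k] <- (d2 < rOutZ[k]^2) + (d2 < rLeanZ[k]^2) +
      (d2 < rBoneZ[k]^2)
  }

  huVals <- unname(profile@tissueHu)
  hu <- array(huVals[labels + 1L], dim = dim(labels))
  if (profile@noiseSdHu > 0) {
    hu <- hu + withSeed(seed,
      array(stats::rnorm(length(hu), 0, profile@noiseSdHu), dim = dim(hu)))
  }

  gt <- profileGroundTruthL(profile)
  obj <- new("Phantom",
             spacingMm = h, hu = hu, labels = labels, zMm = z,
             levelRadiiCm = rad,
             groundTruthTotalL = unname(gt["total"]),
             groundTruthNoFatL = unname(gt["noFat"]),
             profile = profile)
  validObject(obj)
  obj
}

#' @rdname limbvol-generics
#' @export
setMethod("voxelSpacing", "Phantom", function(object) object@spacingMm)

#' @rdname limbvol-generics
#' @export
setMethod("groundTruthTotalL", "Phantom",
          function(object) object@groundTruthTotalL)

#' @rdname limbvol-generics
#' @export
setMethod("groundTruthNoFatL", "Phantom",
          function(object) object@groundTruthNoFatL)

setMethod("show", "Phantom", function(object) {
  d <- dim(object@hu)
  cat(sprintf("Phantom: %d x %d x %d voxels at %g mm\n", d[1], d[2], d[3],
              object@spacingMm))
  if (is.finite(object@groundTruthTotalL))
    cat(sprintf("  ground truth: total %.3f L, no-fat %.3f L\n",
                object@groundTruthTotalL, object@groundTruthNoFatL))
})

#' Hounsfield-threshold volumetry
#'
#' Counts the voxels with HU strictly above the threshold and multiplies by
#' the voxel volume — the automatic-segmentation step of CT limb
#' volumetry. With the default tissue attenuations a threshold of -200 HU
#' captures the whole limb (air excluded, fat included) and -20 HU the
#' no-fat (muscle + bone) volume.
#'
#' @param object A [Phantom-class], or a 3-D HU array (then `spacingMm`
#'   must be supplied).
#' @param thresholdHu Threshold in HU.
#' @param spacingMm Voxel spacing in mm for the array method.
#' @param ... Unused.
#' @return Segmented volume in liters.
#' @export
setMethod("ctVolume", "Phantom", function(object, thresholdHu, ...) {
  assertScalarNumber(thresholdHu, "thresholdHu")
  sum(object@hu > thresholdHu) * object@spacingMm^3 / 1e6
})

#' @rdname ctVolume-Phantom-method
#' @export
setMethod("ctVolume", "array", function(object, thresholdHu, spacingMm, ...) {
  assertScalarNumber(thresholdHu, "thresholdHu")
  assertScalarNumber(spacingMm, "spacingMm", positive = TRUE)
  sum(object > thresholdHu) * spacingMm^3 / 1e6
})

#' Simulated tape measurement of a phantom
#'
#' Recovers a circumference series from the voxel grid: at every level the
#' tissue cross-section area A (non-air voxels times the voxel area) is
#' converted to the circumference of the area-equivalent circle,
#' `C = 2 * sqrt(pi * A)`. The equivalent-circle girth mimics a tape under
#' tension and is insensitive to voxel jaggedness.
#'
#' @param object A [Phantom-class] generated by [generatePhantom()].
#' @param levelSpacingCm Level spacing of the simulated tape in cm
#'   (default 5).
#' @param ... Unused.
#' @return A [CircumferenceSeries-class] with levels every
#'   `levelSpacingCm` from the proximal baseline.
#' @export
setMethod("measurePhantomCircumferences", "Phantom",
          function(object, levelSpacingCm = 5, ...) {
  assertScalarNumber(levelSpacingCm, "levelSpacingCm", positive = TRUE)
  if (nrow(object@levelRadiiCm)) {
    zStart <- 0
    lengthMm <- max(object@levelRadiiCm$positionCm) * 10
  } else {
    ## re-imported phantom: take the axial extent of the tissue itself
    hasTissue <- vapply(seq_along(object@zMm), function(k)
      any(object@labels[, , k] != 0L), logical(1))
    if (!any(hasTissue))
      vstop("phantom contains no tissue to measure", field = "object")
    zStart <- min(object@zMm[hasTissue])
    lengthMm <- max(object@zMm[hasTissue]) - zStart
  }
  if (lengthMm <= levelSpacingCm * 10)
    vstop("phantom (%g cm) is shorter than one level spacing (%g cm)",
          lengthMm / 10, levelSpacingCm, field = "levelSpacingCm")
  zLevels <- zStart + seq(0, lengthMm, by = levelSpacingCm * 10)
  circ <- vapply(zLevels, function(zl) {
    k <- which.min(abs(object@zMm - zl))
    nVox <- sum(object@labels[, , k] != 0L)
    if (nVox == 0L)
      vstop("empty slice at z = %g mm: no tissue to measure", zl,
            field = "levelSpacingCm")
    areaMm2 <- nVox * object@spacingMm^2
    2 * sqrt(pi * areaMm2) / 10
  }, numeric(1))
  lt <- if (is(object@profile, "PhantomProfile"))
    limbType(object@profile@series) else "leg"
  CircumferenceSeries(circ, limbType = lt,
                      positionsCm = (zLevels - zStart) / 10)
})
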