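## Frustum-of-cone volume model over a circumference series.
##
## Each 5-cm segment of the extremity is modelled as the frustum of a right
## circular cone whose end radii come from the two neighbouring tape
## circumferences, r = C / (2*pi):
##
##   V = h * (pi/3) * (r1^2 + r1*r2 + r2^2)  =  h * (C1^2 + C1*C2 + C2^2) / (12*pi)
##
## Summing the segments gives the total limb volume; segments proximal to
## the tourniquet can be subtracted for the perfused volume.

#' Construct a circumference series
#'
#' @param circumferencesCm Numeric vector of circumferences in cm, ordered
#'   proximal (baseline, level 0) to distal; length >= 2. A value of 0 is
#'   accepted only at the terminal distal level (a cone tip).
#' @param limbType `"arm"` or `"leg"`.
#' @param spacingCm Uniform level spacing in cm (default 5, the standard
#'   marking interval). Ignored when `positionsCm` is given.
#' @param positionsCm Optional explicit level positions in cm from the
#'   baseline, strictly increasing, for non-uniform spacing (extra distal
#'   hand/foot levels).
#' @return A [CircumferenceSeries-class] object.
#' @examples
#' thigh <- CircumferenceSeries(c(58, 55, 51, 46, 40), limbType = "leg")
#' totalVolumeL(totalVolume(thigh))
#' @export
CircumferenceSeries <- function(circumferencesCm, limbType = c("leg", "arm"),
                                spacingCm = 5, positionsCm = NULL) {
  limbType <- normalizeLimbType(limbType[1])
  if (!is.numeric(circumferencesCm) || length(circumferencesCm) < 2L)
    vstop("'circumferencesCm' must be a numeric vector with at least 2 levels",
          field = "circumferencesCm")
  if (is.null(positionsCm)) {
    assertScalarNumber(spacingCm, "spacingCm", positive = TRUE)
    positionsCm <- (seq_along(circumferencesCm) - 1) * spacingCm
  }
  if (any(!is.finite(circumferencesCm)) || any(circumferencesCm < 0))
    vstop("circumferences must be finite and non-negative",
          field = "circumferencesCm")
  obj <- new("CircumferenceSeries",
             limbType = limbType,
             positionsCm = as.numeric(positionsCm),
             circumferencesCm = as.numeric(circumferencesCm))
  validObject(obj)
  obj
}

#' @rdname limbvol-generics
#' @export
setMethod("limbType", "CircumferenceSeries", function(object) object@limbType)

#' @rdname limbvol-generics
#' @export
setMethod("circumferences", "CircumferenceSeries",
          function(object) object@circumferencesCm)

#' @rdname limbvol-generics
#' @export
setMethod("levelPositions", "CircumferenceSeries",
          function(object) object@positionsCm)

#' @rdname limbvol-generics
#' @export
setMethod("nLevels", "CircumferenceSeries",
          function(object) length(object@circumferencesCm))

setMethod("show", "CircumferenceSeries", function(object) {
  n <- nLevels(object)
  cat(sprintf("CircumferenceSeries (%s): %d levels, %g-%g cm from baseline\n",
              object@limbType, n,
              object@positionsCm[1], object@positionsCm[n]))
  cat("  circumferences (cm): ",
      paste(format(object@circumferencesCm, trim = TRUE), collapse = ", "),
      "\n", sep = "")
})

#' Volume of a conical frustum from its end circumferences
#'
#' Exact volume of a linearly tapering circular solid of height `h` whose
#' end circumferences are `circProximal` and `circDistal`:
#' `V = h * (C1^2 + C1*C2 + C2^2) / (12 * pi)`. Equal circumferences reduce
#' to the cylinder `h * C^2 / (4*pi)`; a zero end to the cone
#' `h * C^2 / (12*pi)`.
#'
#' @param circProximal,circDistal End circumferences in cm (>= 0).
#' @param h Segment height in cm (> 0).
#' @return Volume in cm^3 (= mL).
#' @examples
#' frustumVolume(40, 40, 5)  # cylinder: 636.6198
#' frustumVolume(40, 0, 5)   # cone:     212.2066
#' @export
frustumVolume <- function(circProximal, circDistal, h) {
  if (!is.numeric(circProximal) || any(!is.finite(circProximal)) ||
      any(circProximal < 0))
    vstop("'circProximal' must be >= 0", field = "circProximal")
  if (!is.numeric(circDistal) || any(!is.finite(circDistal)) ||
      any(circDistal < 0))
    vstop("'circDistal' must be >= 0", field = "circDistal")
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0))
    vstop("'h' must be > 0", field = "h")
  h * (circProximal^2 + circProximal * circDistal + circDistal^2) / (12 * pi)
}

## Frustum sum over per-level radii (cm) -> volume in cm^3.
frustumSumFromRadii <- function(positionsCm, radiiCm) {
  n <- length(radiiCm)
  h <- diff(positionsCm)
  r1 <- radiiCm[-n]
  r2 <- radiiCm[-1]
  sum(h * (pi / 3) * (r1^2 + r1 * r2 + r2^2))
}

#' Frustum-sum limb volume of a circumference series
#'
#' One frustum segment per adjacent level pair; the total limb volume is
#' the sum of all segments, with no segment excluded. Use
#' [subtractAboveLevel()] afterwards for tourniquet bookkeeping.
#'
#' @param object A [CircumferenceSeries-class].
#' @param ... Unused.
#' @return A [LimbVolumeResult-class].
#' @examples
#' totalVolumeL(totalVolume(CircumferenceSeries(c(40, 40, 40), "leg")))
#' @aliases totalVolume,CircumferenceSeries-method
#' @export
setMethod("totalVolume", "CircumferenceSeries", function(object, ...) {
  validObject(object)
  circ <- object@circumferencesCm
  n <- length(circ)
  seg <- frustumVolume(circ[-n], circ[-1], diff(object@positionsCm))
  new("LimbVolumeResult",
      segmentVolumesMl = seg,
      excludedSegments = integer(0),
      positionsCm = object@positionsCm,
      limbType = object@limbType)
})

includedSegmentVolumes <- function(object) {
  v <- object@segmentVolumesMl
  if (length(object@excludedSegments)) v[-object@excludedSegments] else v
}

#' @rdname limbvol-generics
#' @export
setMethod("segmentVolumes", "LimbVolumeResult",
          function(object) object@segmentVolumesMl)

#' @rdname limbvol-generics
#' @export
setMethod("excludedSegments", "LimbVolumeResult",
          function(object) object@excludedSegments)

#' @rdname limbvol-generics
#' @export
setMethod("totalVolumeL", "LimbVolumeResult",
          function(object) sum(includedSegmentVolumes(object)) / 1000)

#' @rdname limbvol-generics
#' @export
setMethod("excludedVolumeL", "LimbVolumeResult", function(object)
  sum(object@segmentVolumesMl[object@excludedSegments]) / 1000)

#' @rdname limbvol-generics
#' @export
setMethod("cumulativeVolumeL", "LimbVolumeResult", function(object) {
  v <- object@segmentVolumesMl
  if (length(object@excludedSegments)) v[object@excludedSegments] <- 0
  cumsum(v) / 1000
})

#' @rdname limbvol-generics
#' @export
setMethod("limbType", "LimbVolumeResult", function(object) object@limbType)

setMethod("show", "LimbVolumeResult", function(object) {
  ns <- length(object@segmentVolumesMl)
  nex <- length(object@excludedSegments)
  cat(sprintf("LimbVolumeResult (%s): %d segments%s\n", object@limbType, ns,
              if (nex) sprintf(" (%d excluded)", nex) else ""))
  cat(sprintf("  perfused volume: %.2f L", totalVolumeL(object)))
  if (nex) cat(sprintf("  (excluded: %.2f L)", excludedVolumeL(object)))
  cat("\n")
})

#' Tourniquet subtraction of proximal segments
#'
#' Marks every segment strictly proximal to the tourniquet level as
#' excluded and recomputes the perfused total over the remaining segments.
#' Levels are counted from 0 at the groin/axilla baseline, so
#' `tourniquetLevel = 0` leaves the result unchanged and the last level
#' excludes all segments (0 L remaining). The excluded and remaining
#' volumes always sum exactly to the unadjusted total.
#'
#' @param object A [LimbVolumeResult-class].
#' @param tourniquetLevel Integer level index (0-based, 0 = baseline) of
#'   the most proximal level actually perfused.
#' @return A [LimbVolumeResult-class] with updated exclusions.
#' @aliases subtractAboveLevel,LimbVolumeResult-method
#' @export
setMethod("subtractAboveLevel", "LimbVolumeResult",
          function(object, tourniquetLevel) {
  ns <- length(object@segmentVolumesMl)
  if (!is.numeric(tourniquetLevel) || length(tourniquetLevel) != 1L ||
      !is.finite(tourniquetLevel) || tourniquetLevel != round(tourniquetLevel))
    vstop("'tourniquetLevel' must be a single integer",
          field = "tourniquetLevel")
  if (tourniquetLevel < 0 || tourniquetLevel > ns)
    vstop("tourniquet level %d out of range (limb has levels 0..%d)",
          tourniquetLevel, ns, field = "tourniquetLevel")
  ex <- seq_len(tourniquetLevel)
  initialize(object, excludedSegments = as.integer(ex))
})
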