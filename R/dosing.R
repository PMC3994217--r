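## Per-liter drug dosing for isolated limb perfusion.

#' Construct a dose specification
#'
#' The established melphalan rates are 10 to 11 mg per liter of leg volume
#' and 13 mg per liter of arm volume. The conservative lower bound of the
#' leg range is used as the headline rate; both bounds are always reported.
#'
#' @param drug Drug name (default `"melphalan"`).
#' @param armRateMgPerL Arm rate in mg per liter of limb volume.
#' @param legRateMgPerL Leg rate range `c(low, high)` in mg/L; a single
#'   value is accepted and used for both bounds.
#' @return A [DoseSpec-class] object.
#' @export
DoseSpec <- function(drug = "melphalan", armRateMgPerL = 13,
                     legRateMgPerL = c(10, 11)) {
  if (length(legRateMgPerL) == 1L) legRateMgPerL <- rep(legRateMgPerL, 2)
  obj <- new("DoseSpec", drug = as.character(drug),
             armRateMgPerL = armRateMgPerL,
             legRateMgPerL = as.numeric(legRateMgPerL))
  validObject(obj)
  obj
}

setMethod("show", "DoseSpec", function(object) {
  cat(sprintf("DoseSpec: %s, leg %g-%g mg/L, arm %g mg/L\n", object@drug,
              object@legRateMgPerL[1], object@legRateMgPerL[2],
              object@armRateMgPerL))
})

#' Drug dose from limb volume
#'
#' `dose = volume x rate`, exactly linear in both. For legs the dose at both
#' bounds of the rate range is reported, with the lower bound as the
#' headline value; arms have a single rate.
#'
#' @param volumeL Limb volume in liters (> 0). Pass whichever volume is
#'   clinically intended — raw or IBW-corrected; the result records which
#'   rate was applied, not where the volume came from.
#' @param limbType `"arm"` or `"leg"`.
#' @param spec A [DoseSpec-class]; default melphalan rates.
#' @return A list with `doseMg` (headline, unrounded), `doseMgRounded`
#'   (0.1 mg), `doseRangeMg` (length 2; identical bounds for arms),
#'   `rateMgPerL` (headline rate), `rateRangeMgPerL`, `volumeL`, `limbType`
#'   and `drug`.
#' @examples
#' limbDose(8.1, "leg")   # 81.0 - 89.1 mg
#' limbDose(2.4, "arm")   # 31.2 mg
#' @export
limbDose <- function(volumeL, limbType, spec = DoseSpec()) {
  if (!is(spec, "DoseSpec"))
    vstop("'spec' must be a DoseSpec object", field = "spec")
  if (!is.numeric(volumeL) || length(volumeL) != 1L || !is.finite(volumeL))
    vstop("'volumeL' must be a single finite number", field = "volumeL")
  if (volumeL <= 0)
    vstop("volume must be > 0 to compute a dose (got %g L)", volumeL,
          field = "volumeL")
  limbType <- normalizeLimbType(limbType)
  rates <- if (limbType == "leg") spec@legRateMgPerL
           else rep(spec@armRateMgPerL, 2)
  range <- volumeL * rates
  list(doseMg = range[1],
       doseMgRounded = round(range[1], 1),
       doseRangeMg = range,
       rateMgPerL = rates[1],
       rateRangeMgPerL = rates,
       volumeL = volumeL,
       limbType = limbType,
       drug = spec@drug)
}
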