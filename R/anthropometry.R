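## Body-size metrics and the ideal-body-weight volume correction.
##
## The measured limb volume tracks the true limb volume including any
## obesity-excess fat, which should not drive a cytostatic dose. Rescaling
## by the ideal-to-actual body weight quotient (IBW/ABW) discounts exactly
## that excess: the quotient is ~1 for normal-weight patients and ~0.5 for
## class-III obesity, halving the dosing volume.

#' Construct patient anthropometrics
#'
#' @param sex `"male"`/`"m"` or `"female"`/`"f"`.
#' @param heightCm Height in centimetres; values outside 100-230 cm are
#'   rejected to catch heights entered in metres.
#' @param weightKg Actual body weight (ABW) in kilograms.
#' @return A [PatientAnthro-class] object.
#' @examples
#' p <- PatientAnthro("male", heightCm = 180, weightKg = 95)
#' bodyMassIndex(p)
#' idealBodyWeight(p)
#' correctionQuotient(p)
#' @export
PatientAnthro <- function(sex, heightCm, weightKg) {
  sex <- normalizeSex(sex)
  assertScalarNumber(heightCm, "heightCm", positive = TRUE)
  if (heightCm < 100 || heightCm > 230)
    vstop("heightCm = %g is outside the plausible range [100, 230] cm; was the height entered in metres?",
          heightCm, field = "heightCm")
  assertScalarNumber(weightKg, "weightKg", positive = TRUE)
  obj <- new("PatientAnthro", sex = sex, heightCm = heightCm,
             weightKg = weightKg)
  validObject(obj)
  obj
}

setMethod("show", "PatientAnthro", function(object) {
  cat(sprintf(
    "PatientAnthro: %s, %.1f cm, %.1f kg  (BMI %.1f, IBW %.1f kg, IBW/ABW %.3f)\n",
    object@sex, object@heightCm, object@weightKg,
    bodyMassIndex(object), idealBodyWeight(object),
    correctionQuotient(object)))
})

#' Body mass index
#'
#' WHO definition: weight in kilograms divided by the square of height in
#' metres.
#'
#' @param weightKg Weight in kg, or a [PatientAnthro-class] object.
#' @param heightCm Height in cm (ignored when `weightKg` is a
#'   `PatientAnthro`).
#' @return BMI in kg/m^2.
#' @examples
#' bodyMassIndex(100, 200)  # 25
#' @export
bodyMassIndex <- function(weightKg, heightCm) {
  if (is(weightKg, "PatientAnthro")) {
    heightCm <- weightKg@heightCm
    weightKg <- weightKg@weightKg
  }
  assertScalarNumber(weightKg, "weightKg", positive = TRUE)
  assertScalarNumber(heightCm, "heightCm", positive = TRUE)
  weightKg / (heightCm / 100)^2
}

#' Ideal body weight
#'
#' Sex-specific linear formula with a common slope of 0.89 kg per cm of
#' height above 152.4 cm (= 5 ft):
#' `IBW = 49.9 + 0.89 * (height_cm - 152.4)` for men and
#' `IBW = 45.4 + 0.89 * (height_cm - 152.4)` for women. The formula is
#' applied as-is below 152.4 cm (the offset terms then dominate).
#'
#' @param sex `"male"` or `"female"`, or a [PatientAnthro-class] object.
#' @param heightCm Height in cm (ignored for a `PatientAnthro`).
#' @return Ideal body weight in kg.
#' @examples
#' idealBodyWeight("male", 152.4)    # 49.9
#' idealBodyWeight("female", 152.4)  # 45.4
#' @export
idealBodyWeight <- function(sex, heightCm) {
  if (is(sex, "PatientAnthro")) {
    heightCm <- sex@heightCm
    sex <- sex@sex
  }
  sex <- normalizeSex(sex)
  assertScalarNumber(heightCm, "heightCm", positive = TRUE)
  offset <- if (sex == "male") 49.9 else 45.4
  offset + 0.89 * (heightCm - 152.4)
}

#' Ideal-to-actual body weight quotient
#'
#' `IBW / ABW`: < 1 for overweight patients, > 1 for underweight ones.
#'
#' @param anthro A [PatientAnthro-class] object.
#' @return The quotient (dimensionless, > 0).
#' @export
correctionQuotient <- function(anthro) {
  if (!is(anthro, "PatientAnthro"))
    vstop("'anthro' must be a PatientAnthro object", field = "anthro")
  idealBodyWeight(anthro) / anthro@weightKg
}

#' IBW-corrected limb volume
#'
#' Rescales a measured limb volume by the ideal-to-actual body weight
#' quotient, `Vcorrected = Vmeasured * IBW / ABW`, discounting
#' obesity-excess fat from the dosing volume. For underweight patients the
#' quotient exceeds 1 and would inflate the volume; `capAtOne = TRUE` clamps
#' the applied quotient to 1 (an explicit opt-in safety flag — the printed
#' formula itself is uncapped, and uncapped is the default).
#'
#' @param volumeL Measured limb volume in liters (>= 0).
#' @param anthro A [PatientAnthro-class] object.
#' @param capAtOne Clamp the quotient to at most 1? Default `FALSE`.
#' @return A list with elements `volumeL` (corrected volume), `quotient`
#'   (as applied), `rawQuotient` (IBW/ABW before any clamp) and `clamped`
#'   (logical).
#' @examples
#' p <- PatientAnthro("male", 170, 130)  # obese: quotient well below 1
#' ibwCorrectedVolume(10, p)
#' @export
ibwCorrectedVolume <- function(volumeL, anthro, capAtOne = FALSE) {
  assertScalarNumber(volumeL, "volumeL", nonNegative = TRUE)
  q <- correctionQuotient(anthro)
  clamped <- isTRUE(capAtOne) && q > 1
  applied <- if (clamped) 1 else q
  list(volumeL = volumeL * applied,
       quotient = applied,
       rawQuotient = q,
       clamped = clamped)
}
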