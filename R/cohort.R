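## Synthetic validation cohorts.
##
## Each simulated subject gets anthropometrics (sex, height, log-normal
## BMI), a piecewise-conical limb whose lean girth scales with height and
## whose subcutaneous fat ring grows with BMI, a noisy tape measurement of
## that limb, and a phantom recipe so that the CT arm of the method
## comparison runs on exactly the same solid as the tape arm.

#' Construct a cohort specification
#'
#' Defaults emulate the clinical ILP population the method-comparison
#' design targets: 32 legs and 10 arms, 23/42 male, heights 178/165 +- 7 cm
#' by sex, log-normal BMI with median 26 spanning normal weight to
#' class-III obesity, 0.5 cm tape noise per level, 15 HU CT noise, and
#' girth coefficients calibrated so that mean limb volumes land near 10 L
#' (legs) and 2.7 L (arms).
#'
#' @param nLegs,nArms Number of leg and arm subjects.
#' @param pMale Probability of a male subject.
#' @param heightMeanCm Named `c(male=, female=)` mean heights (cm).
#' @param heightSdCm Height SD (cm).
#' @param bmiMeanlog,bmiSdlog Log-normal BMI parameters.
#' @param girthPerHeight Named `c(leg=, arm=)` lean proximal radius (cm)
#'   per cm of height.
#' @param distalTaper Named `c(leg=, arm=)` distal/proximal lean radius
#'   ratio.
#' @param lengthPerHeight Named `c(leg=, arm=)` limb length as a fraction
#'   of height (rounded down to whole 5-cm levels).
#' @param fatFractionBase Fat-ring radius fraction at BMI 21.
#' @param fatFractionPerBmi Added fraction per BMI unit above 21.
#' @param boneFraction Bone-core radius fraction.
#' @param subjectSdLog Log-normal subject girth scatter.
#' @param tapeNoiseSdCm Tape noise SD per level (cm).
#' @param ctNoiseSdHu CT image noise SD (HU).
#' @param heightLink If `FALSE`, lean girth ignores the subject's height
#'   (null model for the weight/height panels).
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(nLegs = 32, nArms = 10,
                       pMale = 23 / 42,
                       heightMeanCm = c(male = 178, female = 165),
                       heightSdCm = 7,
                       bmiMeanlog = log(26), bmiSdlog = 0.22,
                       girthPerHeight = c(leg = 0.0425, arm = 0.025),
                       distalTaper = c(leg = 0.38, arm = 0.40),
                       lengthPerHeight = c(leg = 0.47, arm = 0.36),
                       fatFractionBase = 0.10, fatFractionPerBmi = 0.012,
                       boneFraction = 0.25, subjectSdLog = 0.07,
                       tapeNoiseSdCm = 0.5, ctNoiseSdHu = 15,
                       heightLink = TRUE, seed = 1L) {
  obj <- new("CohortSpec",
             nLegs = as.integer(nLegs), nArms = as.integer(nArms),
             pMale = pMale,
             heightMeanCm = heightMeanCm, heightSdCm = heightSdCm,
             bmiMeanlog = bmiMeanlog, bmiSdlog = bmiSdlog,
             girthPerHeight = girthPerHeight, distalTaper = distalTaper,
             lengthPerHeight = lengthPerHeight,
             fatFractionBase = fatFractionBase,
             fatFractionPerBmi = fatFractionPerBmi,
             boneFraction = boneFraction, subjectSdLog = subjectSdLog,
             tapeNoiseSdCm = tapeNoiseSdCm, ctNoiseSdHu = ctNoiseSdHu,
             heightLink = isTRUE(heightLink), seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d legs + %d arms, tape noise %g cm, CT noise %g HU, seed %d\n",
    object@nLegs, object@nArms, object@tapeNoiseSdCm, object@ctNoiseSdHu,
    object@seed))
})

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

simulateSubject <- function(spec, id, limb) {
  sex <- if (stats::runif(1) < spec@pMale) "male" else "female"
  height <- clamp(stats::rnorm(1, spec@heightMeanCm[[sex]], spec@heightSdCm),
                  150, 205)
  bmi <- clamp(stats::rlnorm(1, spec@bmiMeanlog, spec@bmiSdlog), 16, 55)
  weight <- bmi * (height / 100)^2
  anthro <- PatientAnthro(sex, height, weight)

  lengthCm <- 5 * floor(spec@lengthPerHeight[[limb]] * height / 5)
  nLev <- lengthCm / 5 + 1
  girthHeight <- if (spec@heightLink) height else
    spec@pMale * spec@heightMeanCm[["male"]] +
      (1 - spec@pMale) * spec@heightMeanCm[["female"]]
  r0 <- spec@girthPerHeight[[limb]] * girthHeight *
    exp(stats::rnorm(1, 0, spec@subjectSdLog))
  taper <- seq(1, spec@distalTaper[[limb]], length.out = nLev)
  rLean <- r0 * taper
  fat <- clamp(spec@fatFractionBase +
                 spec@fatFractionPerBmi * (bmi - 21), 0.05, 0.55)
  rOut <- rLean / (1 - fat)
  circTrue <- 2 * pi * rOut

  seriesTrue <- CircumferenceSeries(circTrue, limbType = limb, spacingCm = 5)
  circTape <- pmax(circTrue +
                     stats::rnorm(nLev, 0, spec@tapeNoiseSdCm), 1)
  seriesTape <- CircumferenceSeries(circTape, limbType = limb, spacingCm = 5)

  profile <- PhantomProfile(seriesTrue,
                            fatFraction = fat,
                            boneFraction = spec@boneFraction,
                            noiseSdHu = spec@ctNoiseSdHu)
  list(id = id, limbType = limb, anthro = anthro,
       bmi = bmi,
       seriesTrue = seriesTrue, seriesTape = seriesTape,
       profile = profile,
       phantomSeed = sample.int(.Machine$integer.max, 1L))
}

#' Simulate a validation cohort
#'
#' Draws the full cohort described by a [CohortSpec()]: per subject the
#' anthropometrics, the true outer circumference series, the noisy tape
#' series, and the phantom recipe plus rasterization seed. Tape and CT arm
#' therefore describe the identical analytic solid; with zero tape noise
#' the circumference volume equals the phantom ground truth exactly
#' (piecewise-conical limbs are exactly frustum-modelled). Deterministic
#' for a fixed spec (including its seed).
#'
#' @param spec A [CohortSpec-class].
#' @return A [LimbCohort-class].
#' @examples
#' coh <- simulateCohort(CohortSpec(nLegs = 2, nArms = 1, seed = 7))
#' length(subjects(coh))
#' @export
simulateCohort <- function(spec) {
  if (!is(spec, "CohortSpec"))
    vstop("'spec' must be a CohortSpec", field = "spec")
  validObject(spec)
  withSeed(spec@seed, {
    limbs <- c(rep("leg", spec@nLegs), rep("arm", spec@nArms))
    subjects <- lapply(seq_along(limbs), function(i)
      simulateSubject(spec, i, limbs[i]))
    new("LimbCohort", subjects = subjects, spec = spec)
  })
}

#' @rdname limbvol-generics
#' @export
setMethod("subjects", "LimbCohort", function(object) object@subjects)

setMethod("show", "LimbCohort", function(object) {
  lt <- vapply(object@subjects, `[[`, character(1), "limbType")
  cat(sprintf("LimbCohort: %d subjects (%d legs, %d arms), seed %d\n",
              length(lt), sum(lt == "leg"), sum(lt == "arm"),
              object@spec@seed))
})
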