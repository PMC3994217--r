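## Central S4 containers. Constructors (exported, same name as the class)
## perform the user-facing validation and unit bookkeeping; the validity
## methods guard the invariants that must survive any manipulation.

#' CircumferenceSeries: tape-measured limb circumferences
#'
#' Ordered circumference measurements of one extremity, proximal (groin or
#' axilla baseline, level 0) to distal, the raw input of the truncated-cone
#' volume model. Levels sit every `spacingCm` centimetres unless explicit
#' `positionsCm` are given (non-uniform spacing is allowed so that extra
#' hand/foot levels can be appended).
#'
#' @slot limbType `"arm"` or `"leg"`.
#' @slot positionsCm Numeric, distance of each level from the baseline in cm,
#'   strictly increasing, first element 0.
#' @slot circumferencesCm Numeric, one circumference (cm) per level. All
#'   values must be positive except that the terminal distal level may be 0
#'   (a cone tip); a zero anywhere else is rejected as a probable data-entry
#'   error.
#' @exportClass CircumferenceSeries
setClass("CircumferenceSeries",
  representation(
    limbType = "character",
    positionsCm = "numeric",
    circumferencesCm = "numeric"
  )
)

setValidity("CircumferenceSeries", function(object) {
  n <- length(object@circumferencesCm)
  if (n < 2L)
    return("at least 2 levels are required (no segment exists otherwise)")
  if (length(object@positionsCm) != n)
    return("positionsCm and circumferencesCm must have equal length")
  if (!(object@limbType %in% c("arm", "leg")))
    return("limbType must be 'arm' or 'leg'")
  if (anyNA(object@positionsCm) || anyNA(object@circumferencesCm))
    return("positions and circumferences must not contain NA")
  if (any(diff(object@positionsCm) <= 0))
    return("level positions must be strictly increasing")
  if (any(object@circumferencesCm < 0))
    return("circumferences must be non-negative")
  if (any(object@circumferencesCm[-n] == 0))
    return("a circumference of 0 is only legal at the terminal distal level")
  TRUE
})

#' LimbVolumeResult: per-segment frustum volumes of one limb
#'
#' One frustum volume per adjacent level pair of a [CircumferenceSeries],
#' with tourniquet bookkeeping: segments marked excluded (proximal to the
#' tourniquet level) do not count towards the perfused total.
#'
#' @slot segmentVolumesMl Numeric, frustum volume (mL = cm^3) of segment i
#'   spanning levels i-1 -> i (1-based segment indices).
#' @slot excludedSegments Integer, 1-based indices of excluded segments.
#' @slot positionsCm Level positions copied from the input series.
#' @slot limbType Limb type copied from the input series.
#' @exportClass LimbVolumeResult
setClass("LimbVolumeResult",
  representation(
    segmentVolumesMl = "numeric",
    excludedSegments = "integer",
    positionsCm = "numeric",
    limbType = "character"
  )
)

setValidity("LimbVolumeResult", function(object) {
  ns <- length(object@segmentVolumesMl)
  if (ns < 1L) return("at least one segment is required")
  if (length(object@positionsCm) != ns + 1L)
    return("positionsCm must have one more element than segmentVolumesMl")
  if (any(object@segmentVolumesMl < 0))
    return("segment volumes must be non-negative")
  ex <- object@excludedSegments
  if (length(ex) && (any(ex < 1L) || any(ex > ns) || anyDuplicated(ex)))
    return("excludedSegments must be unique indices in 1..nSegments")
  TRUE
})

#' PatientAnthro: patient anthropometrics
#'
#' Sex, height and actual body weight (ABW) of one patient. Body mass index,
#' ideal body weight (IBW) and the IBW/ABW correction quotient are derived
#' deterministically via [bodyMassIndex()], [idealBodyWeight()] and
#' [correctionQuotient()].
#'
#' @slot sex `"male"` or `"female"`.
#' @slot heightCm Height in centimetres (validated to 100-230 cm to catch
#'   metre-entered values).
#' @slot weightKg Actual body weight in kilograms.
#' @exportClass PatientAnthro
setClass("PatientAnthro",
  representation(sex = "character", heightCm = "numeric", weightKg = "numeric")
)

setValidity("PatientAnthro", function(object) {
  if (!(object@sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  if (length(object@heightCm) != 1L || !is.finite(object@heightCm) ||
      object@heightCm < 100 || object@heightCm > 230)
    return("heightCm must be a single value in [100, 230] cm")
  if (length(object@weightKg) != 1L || !is.finite(object@weightKg) ||
      object@weightKg <= 0)
    return("weightKg must be a single positive value")
  TRUE
})

#' DoseSpec: per-liter drug dose rates
#'
#' Dosing rule for isolated limb perfusion: a fixed rate per liter of
#' (corrected) limb volume, with a low-high range for legs and a single rate
#' for arms. Defaults are the established melphalan rates of 10-11 mg/L for
#' legs and 13 mg/L for arms; the conservative lower bound is the headline
#' leg rate.
#'
#' @slot drug Drug name, default `"melphalan"`.
#' @slot armRateMgPerL Single arm rate in mg per liter.
#' @slot legRateMgPerL Numeric length 2, `c(low, high)` leg rates in mg/L.
#' @exportClass DoseSpec
setClass("DoseSpec",
  representation(
    drug = "character",
    armRateMgPerL = "numeric",
    legRateMgPerL = "numeric"
  ),
  prototype(drug = "melphalan", armRateMgPerL = 13, legRateMgPerL = c(10, 11))
)

setValidity("DoseSpec", function(object) {
  if (length(object@armRateMgPerL) != 1L || object@armRateMgPerL <= 0)
    return("armRateMgPerL must be a single positive rate")
  if (length(object@legRateMgPerL) != 2L || any(object@legRateMgPerL <= 0))
    return("legRateMgPerL must be two positive rates c(low, high)")
  if (diff(object@legRateMgPerL) < 0)
    return("leg rate range must satisfy low <= high")
  TRUE
})

#' PhantomProfile: recipe for a synthetic voxel limb
#'
#' Analytic description of a piecewise-conical limb with concentric bone,
#' muscle and subcutaneous-fat compartments, from which a voxelized phantom
#' of known ground-truth volume is rasterized. At every measurement level
#' the outer radius comes from the circumference series; the fat ring
#' occupies the outer `fatFraction` of the radius and the bone core the
#' inner `boneFraction`.
#'
#' @slot series Outer-surface [CircumferenceSeries].
#' @slot fatFraction Numeric, per-level fat-ring fraction of the outer
#'   radius, in `[0, 1)`.
#' @slot boneFraction Numeric, per-level bone-core fraction of the outer
#'   radius; `fatFraction + boneFraction < 1` so a muscle annulus exists.
#' @slot tissueHu Named numeric `c(air=, fat=, muscle=, bone=)` Hounsfield
#'   values, strictly increasing in that order.
#' @slot noiseSdHu Gaussian HU noise standard deviation (>= 0).
#' @exportClass PhantomProfile
setClass("PhantomProfile",
  representation(
    series = "CircumferenceSeries",
    fatFraction = "numeric",
    boneFraction = "numeric",
    tissueHu = "numeric",
    noiseSdHu = "numeric"
  )
)

setValidity("PhantomProfile", function(object) {
  n <- length(object@series@circumferencesCm)
  if (length(object@fatFraction) != n || length(object@boneFraction) != n)
    return("fatFraction and boneFraction must have one value per level")
  if (any(object@fatFraction < 0) || any(object@fatFraction >= 1) ||
      any(object@boneFraction < 0) || any(object@boneFraction >= 1))
    return("tissue fractions must lie in [0, 1)")
  if (any(object@fatFraction + object@boneFraction >= 1))
    return("fatFraction + boneFraction must be < 1 at every level")
  hu <- object@tissueHu
  if (!identical(names(hu), c("air", "fat", "muscle", "bone")))
    return("tissueHu must be named c(air=, fat=, muscle=, bone=)")
  if (any(diff(hu) <= 0))
    return("tissue HU must satisfy air < fat < muscle < bone")
  if (length(object@noiseSdHu) != 1L || object@noiseSdHu < 0)
    return("noiseSdHu must be a single value >= 0")
  TRUE
})

#' Phantom: voxelized synthetic limb with analytic ground truth
#'
#' A rasterized [PhantomProfile]: isotropic voxel grid of Hounsfield values
#' and tissue labels, plus the closed-form ground-truth volumes of the
#' piecewise-conical compartments. Voxel centers sit at integer multiples of
#' the spacing; the limb axis runs along the third array dimension with the
#' baseline at z = 0.
#'
#' @slot spacingMm Isotropic voxel spacing in millimetres.
#' @slot hu 3-D numeric array of Hounsfield values.
#' @slot labels 3-D integer array, 0 = air, 1 = fat, 2 = muscle, 3 = bone.
#' @slot zMm Axial coordinate (mm) of each slice center; the limb occupies
#'   z in `[0, L]`.
#' @slot levelRadiiCm Data frame of per-level analytic radii (cm): columns
#'   `positionCm`, `outer`, `lean`, `bone`.
#' @slot groundTruthTotalL Closed-form total limb volume in liters (frustum
#'   sum over the outer radii); `NA` for phantoms re-imported from disk.
#' @slot groundTruthNoFatL Closed-form lean (muscle + bone) volume in
#'   liters; `NA` when unknown.
#' @slot profile The generating [PhantomProfile] (may be absent for
#'   re-imported phantoms).
#' @exportClass Phantom
setClass("Phantom",
  representation(
    spacingMm = "numeric",
    hu = "array",
    labels = "array",
    zMm = "numeric",
    levelRadiiCm = "data.frame",
    groundTruthTotalL = "numeric",
    groundTruthNoFatL = "numeric",
    profile = "ANY"
  )
)

setValidity("Phantom", function(object) {
  if (length(object@spacingMm) != 1L || !is.finite(object@spacingMm) ||
      object@spacingMm <= 0)
    return("spacingMm must be a single positive value")
  if (length(dim(object@hu)) != 3L)
    return("hu must be a 3-D array")
  if (!identical(dim(object@hu), dim(object@labels)))
    return("hu and labels must have identical dimensions")
  if (length(object@zMm) != dim(object@hu)[3])
    return("zMm must hold one axial coordinate per slice")
  gt <- object@groundTruthTotalL
  gn <- object@groundTruthNoFatL
  if (is.finite(gt) && is.finite(gn) && gn > gt + 1e-12)
    return("ground-truth no-fat volume cannot exceed the total volume")
  TRUE
})

#' CohortSpec: parameters of a synthetic validation cohort
#'
#' Describes the simulated patient population used to replicate the
#' circumference-versus-CT method-comparison study: limb counts, the sex /
#' height / BMI distributions, the anthropometry-to-limb-size link, and the
#' measurement noise of the tape and of CT. See [simulateCohort()].
#'
#' @slot nLegs,nArms Number of leg and arm subjects.
#' @slot pMale Probability that a subject is male.
#' @slot heightMeanCm Named numeric `c(male=, female=)` mean height (cm).
#' @slot heightSdCm Height standard deviation (cm), common to both sexes.
#' @slot bmiMeanlog,bmiSdlog Log-normal BMI parameters (kg/m^2 scale).
#' @slot girthPerHeight Named numeric `c(leg=, arm=)`: lean proximal radius
#'   (cm) per cm of height.
#' @slot distalTaper Named numeric `c(leg=, arm=)`: distal/proximal lean
#'   radius ratio.
#' @slot lengthPerHeight Named numeric `c(leg=, arm=)`: limb length as a
#'   fraction of height (rounded down to whole 5-cm levels).
#' @slot fatFractionBase Fat-ring radius fraction at BMI 21.
#' @slot fatFractionPerBmi Added fat fraction per BMI unit above 21.
#' @slot boneFraction Bone-core radius fraction (constant over levels).
#' @slot subjectSdLog Log-normal subject-to-subject girth scatter.
#' @slot tapeNoiseSdCm Tape-measurement noise per level (cm).
#' @slot ctNoiseSdHu CT image noise (HU).
#' @slot heightLink If `FALSE`, lean girth is decoupled from the subject's
#'   height (null-model option for the weight/height correlation panels).
#' @slot seed Integer RNG seed making the cohort deterministic.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nLegs = "integer", nArms = "integer",
    pMale = "numeric",
    heightMeanCm = "numeric", heightSdCm = "numeric",
    bmiMeanlog = "numeric", bmiSdlog = "numeric",
    girthPerHeight = "numeric", distalTaper = "numeric",
    lengthPerHeight = "numeric",
    fatFractionBase = "numeric", fatFractionPerBmi = "numeric",
    boneFraction = "numeric", subjectSdLog = "numeric",
    tapeNoiseSdCm = "numeric", ctNoiseSdHu = "numeric",
    heightLink = "logical",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@nLegs < 0L || object@nArms < 0L)
    return("limb counts must be non-negative")
  if (object@nLegs + object@nArms < 1L)
    return("the cohort must contain at least one subject")
  if (object@pMale < 0 || object@pMale > 1)
    return("pMale must lie in [0, 1]")
  if (object@tapeNoiseSdCm < 0 || object@ctNoiseSdHu < 0)
    return("noise standard deviations must be >= 0")
  for (nm in c("girthPerHeight", "distalTaper", "lengthPerHeight")) {
    v <- slot(object, nm)
    if (!identical(names(v), c("leg", "arm")))
      return(sprintf("%s must be named c(leg=, arm=)", nm))
  }
  if (!identical(names(object@heightMeanCm), c("male", "female")))
    return("heightMeanCm must be named c(male=, female=)")
  TRUE
})

#' LimbCohort: simulated subjects of a validation study
#'
#' The output of [simulateCohort()]: one record per subject holding the
#' anthropometrics, the true (noise-free) outer circumference series, the
#' tape-measured (noisy) series, the phantom recipe and its rasterization
#' seed. Phantoms are rasterized lazily by [runValidationStudy()] so that a
#' cohort of dozens of subjects stays small in memory.
#'
#' @slot subjects List of per-subject records.
#' @slot spec The generating [CohortSpec].
#' @exportClass LimbCohort
setClass("LimbCohort",
  representation(subjects = "list", spec = "CohortSpec"))

#' CorrelationReport: one paired-measurement comparison panel
#'
#' Pearson product-moment correlation of two paired samples with its
#' two-tailed significance, the least-squares line for scatter plots, and
#' one-sample Kolmogorov-Smirnov normality statistics per variable.
#'
#' @slot label Human-readable panel label.
#' @slot xLabel,yLabel Variable labels.
#' @slot x,y The paired samples.
#' @slot n Number of pairs.
#' @slot r Pearson correlation coefficient.
#' @slot p Two-tailed p-value from the t transform with n - 2 df.
#' @slot slope,intercept Ordinary least-squares line of y on x.
#' @slot normality Data frame with one row per variable: `variable`,
#'   `statistic` (K-S D against a normal with the sample moments), `p`
#'   (asymptotic).
#' @exportClass CorrelationReport
setClass("CorrelationReport",
  representation(
    label = "character", xLabel = "character", yLabel = "character",
    x = "numeric", y = "numeric", n = "integer",
    r = "numeric", p = "numeric",
    slope = "numeric", intercept = "numeric",
    normality = "data.frame"
  )
)

setValidity("CorrelationReport", function(object) {
  if (length(object@x) != object@n || length(object@y) != object@n)
    return("n must equal the length of both samples")
  if (is.finite(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
    return("r must lie in [-1, 1]")
  if (is.finite(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})

#' ValidationStudy: the five-panel method-comparison report
#'
#' Result of [runValidationStudy()]: the per-subject measurement table, the
#' five correlation panels (circumference vs CT volume pooled; ABW, BMI and
#' IBW vs volume split by limb; IBW-corrected volume vs no-fat CT pooled)
#' and group means with standard deviations.
#'
#' @slot measurements Per-subject data frame.
#' @slot panels Named list of [CorrelationReport-class] objects.
#' @slot groupMeans Data frame of group means and SDs by limb type.
#' @slot spacingMm Voxel spacing used for the CT arm, mm (NA if CT skipped).
#' @exportClass ValidationStudy
setClass("ValidationStudy",
  representation(
    measurements = "data.frame",
    panels = "list",
    groupMeans = "data.frame",
    spacingMm = "numeric"
  )
)
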