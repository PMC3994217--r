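---
title: "Circumference-based limb volumetry and ILP dosing: models and design"
author: "limbvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumference-based limb volumetry and ILP dosing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbvol)
```

## The clinical problem

Isolated limb perfusion (ILP) delivers high-dose chemotherapy — typically
melphalan, often with TNF-alpha — to a tourniquet-isolated extremity. The
melphalan dose is prescribed *per liter of perfused limb volume* (10–11
mg/L for legs, 13 mg/L for arms), so the quality of the volume estimate
directly controls the balance between tumour response and regional
toxicity; overdosing is a suspected contributor to post-perfusion
compartment syndrome. `limbvol` implements the practical measurement chain
used at the bedside — tape circumferences, a geometric volume model, an
obesity correction, the dose — together with a synthetic CT pipeline to
validate that chain end to end without patient data.

## The truncated-cone volume model

The limb is marked every 5 cm from the groin/axilla baseline down to the
ankle/wrist (further, when the hand or foot must be included), and the
circumference is taped at each mark. Each segment between neighbouring
marks is modelled as a frustum of a right circular cone with end radii
$r_i = C_i / 2\pi$:

$$ V = h \cdot \frac{\pi}{3}\left[
  \left(\frac{C_1}{2\pi}\right)^2 +
  \frac{C_1}{2\pi}\frac{C_2}{2\pi} +
  \left(\frac{C_2}{2\pi}\right)^2 \right]
  = \frac{h\,(C_1^2 + C_1 C_2 + C_2^2)}{12\pi}, $$

and the limb volume is the segment sum. Two limits anchor the formula:
equal circumferences give the cylinder $hC^2/4\pi$ and a vanishing distal
circumference the cone $hC^2/12\pi$.

```{r}
frustumVolume(40, 40, 5)   # cylinder limit (cm^3)
frustumVolume(40, 0, 5)    # cone limit
```

Conventions worth making explicit, because the field leaves them implicit:

* **Indexing.** Levels are indexed from 0 at the baseline, increasing
  distally; segment $i$ spans levels $i-1 \to i$ (1-based segment indices
  in R). `subtractAboveLevel(result, k)` excludes every segment proximal
  to level $k$ — the femoral/brachial tourniquet case, where the proximal
  thigh can hold half the leg volume and would otherwise be dosed.
  Excluded plus remaining volume always equals the unadjusted total.
* **Spacing.** $h = 5$ cm is the standard, but explicit level positions
  are accepted, so extra distal hand/foot levels (for which no geometric
  rule exists — their interpretation stays with the clinician) and odd
  final segments cost nothing. No partial-segment correction is applied at
  the distal end; the measurement itself defines where the limb stops.
* **Units.** Segments are kept unrounded in mL; totals are reported in
  liters. Dose math always consumes unrounded values.
* **Degenerate inputs.** A circumference of 0 is legal only at the
  terminal distal level (a cone tip); anywhere else it is almost certainly
  a data-entry error and is rejected. Fewer than two levels define no
  segment and are rejected.

## Ideal-body-weight correction

The taped volume tracks the *true* limb volume — including obesity-excess
subcutaneous fat, which should not drive a cytostatic dose. The correction
rescales the measured volume by the ideal-to-actual body weight quotient:

$$ V_\mathrm{corr} = V_\mathrm{meas} \cdot \frac{IBW}{ABW}, \qquad
   IBW = \begin{cases} 49.9 + 0.89\,(H_{cm} - 152.4) & \text{men} \\
                       45.4 + 0.89\,(H_{cm} - 152.4) & \text{women.}
         \end{cases} $$

The height term is in centimetres: 152.4 cm is exactly 5 ft, and these
constants are the established ideal-body-weight formula used in isolated
limb infusion dosing. Heights are validated to 100–230 cm to catch
metre-entered values. A normal-weight patient has a quotient near 1; a
class-III obese patient can reach 0.5, halving the dosing volume.

For *underweight* patients the quotient exceeds 1 and would inflate the
volume. The formula itself is uncapped and that is the default
(`capAtOne = FALSE`); clamping the quotient to 1 is an explicit opt-in
safety flag whose use is reported in the output, because silently changing
a published formula in either direction is worse than making the choice
visible.

## Dosing

`limbDose()` is deliberately dumb: dose = volume × rate, exactly linear in
both. Legs carry the printed 10–11 mg/L range; since no per-patient rule
for resolving the range exists, the conservative lower bound is the
headline value and both bounds are always reported. The function doses
whatever volume it is given — raw or IBW-corrected — and records the rate,
so the clinical choice of input volume stays explicit and auditable
(`fullReport()` prints both volumes labelled).

## The synthetic CT phantom

The reference measurement in the validation design is Hounsfield-threshold
CT volumetry. To exercise that arm without patients, `generatePhantom()`
rasterizes an analytic limb: piecewise-conical outer surface defined by a
circumference series, with concentric compartments — a bone core and a
subcutaneous fat ring, each a per-level fraction of the outer radius, and
muscle between. Because the family is piecewise conical, the frustum model
is *exact* on it, and ground-truth total and lean (no-fat) volumes come in
closed form. Default attenuations are literature-typical: air −1000, fat
−100, muscle +50, bone +700 HU, plus optional Gaussian image noise.

`ctVolume()` reproduces the automatic segmentation step: count voxels
strictly above a threshold, times the voxel volume. Two thresholds matter:

* **Total limb, −200 HU.** The clinical description of the total-limb
  segmentation is "everything denser than the surrounding air". A
  threshold of +200 HU — which appears in print — would cut away fat
  *and* muscle; with fat at ≈ −100 HU the intended "air excluded,
  everything else included" behaviour requires a negative threshold, so
  the package defaults to −200 HU and treats the printed sign as a typo.
  The threshold is an ordinary argument, so +200 remains runnable.
* **No-fat, −20 HU.** Removes the subcutaneous fat ring, leaving muscle
  and bone — the comparator for the IBW-corrected volume.

### Rasterization and convergence

Voxel membership is decided by the voxel *center* (no partial-volume
weighting). Two lattice conventions are deliberate:

* In-plane, the limb axis passes through a voxel **corner**. A
  center-inside count of a disk is then four-fold symmetric and nearly
  unbiased; lattice counts of disks otherwise oscillate erratically with
  the radius-to-spacing ratio rather than shrinking smoothly.
* Axially, voxel centers sit at integer multiples of the spacing and the
  limb occupies the **closed** interval $[0, L]$, which adds one
  deterministic half-voxel slab of tissue at each end.

The second convention makes the leading discretization error
$\approx$ spacing$/L$ — about 1% for a 10-cm test cylinder at 1 mm, 0.12%
for an 80-cm leg — and makes it *halve* when the spacing halves, which is
exactly the behaviour a convergence check can lean on. Without it the
total error would be dominated by the erratic in-plane term and
convergence plots would be noise.

`measurePhantomCircumferences()` closes the loop: at each 5-cm level the
tissue cross-section area $A$ is converted to the area-equivalent girth
$C = 2\sqrt{\pi A}$, mimicking a tape under tension and insulating the
measurement from voxel jaggedness. On 1-mm phantoms the round trip
(series → phantom → measured series) is accurate to well under 1% per
level.

## The simulated cohort

`CohortSpec()` describes the population on which the five-panel
method-comparison study runs. Defaults emulate the clinical ILP cohort
the design targets — 32 legs and 10 arms, 23/42 male — with parameters
chosen once as field-realistic values:

| parameter | default | rationale |
|---|---|---|
| heights | N(178, 7) / N(165, 7) cm by sex | adult European reference |
| BMI | log-normal, median 26, sdlog 0.22 | normal weight through class-III obesity |
| lean girth | 0.0425 (leg) / 0.025 (arm) cm radius per cm height, ×e^{N(0,0.07)} | calibrated so mean volumes land near 10 L (legs) and 2.7 L (arms), the clinically reported scale |
| taper | distal/proximal lean radius 0.38 (leg) / 0.40 (arm) | groin-to-ankle, axilla-to-wrist girth ratios |
| limb length | 0.47 (leg) / 0.36 (arm) × height, floored to 5-cm levels | anthropometric proportions |
| fat ring | radius fraction 0.10 + 0.012·(BMI − 21), clipped to [0.05, 0.55] | links obesity to subcutaneous fat so the IBW-correction panel has signal |
| tape noise | 0.5 cm per level | realistic inter-observer tape error |
| CT noise | 15 HU | typical soft-tissue CT noise |

Each subject's phantom is generated *from their circumference series*, so
the tape arm and the CT arm measure the identical solid; with zero tape
noise the circumference volume equals the phantom ground truth exactly.
`heightLink = FALSE` decouples girth from height, a null model under which
the ideal-body-weight panel should (and does) lose significance.

What the generator does **not** emulate: non-circular cross-sections,
bone marrow cavities, limb posture, segmentation errors needing manual
correction, tumour masses, and any real covariance structure between
height, sex and adiposity beyond the explicit links above. Passing panels
therefore validate the *measurement chain* — geometry, thresholds,
correction, statistics — not the anthropometric realism of any particular
patient population.

## Statistics

`pearsonCorrelation()` computes the product-moment coefficient with its
two-tailed significance from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees
of freedom, plus the OLS line used for the scatter panels (OLS is assumed
for plotting; nothing in the analysis depends on it).
`ksNormality()` is the one-sample Kolmogorov–Smirnov screen against a
normal with the sample mean and SD, with the asymptotic Kolmogorov
p-value. Both are written out explicitly rather than delegated, so the
test suite can hold them against `cor.test()` and `ks.test()` as
independent references (agreement within 1e-10 on $r$, 1e-6 on p). The
asymptotic tail is evaluated with the conventional 1e-6 series tolerance
of standard statistical software, switching between the theta-function
and alternating series at $t = 1$. p-values are reported to full
precision; thresholding ("< 0.01") is presentation. No multiple-testing
correction is applied, matching the original five-panel analysis.
`runValidationStudy()` pools arms and legs for the two volume-vs-volume
panels (both limb types lie on one regression line) and splits by limb
type for the ABW/BMI/IBW panels; groups under 3 subjects are skipped with
a warning.

## Problem sizes and runtime

The package's own validation uses: 1000 random frusta against adaptive
quadrature (< 5 s); the 10-cm reference cylinder at 1 and 0.5 mm for the
convergence check; and the full 42-subject cohort at 1-mm voxels for the
study replication (~2–3 minutes, one phantom in memory at a time — a
1-mm leg grid is ≈ 4×10⁷ voxels, ≈ 0.5 GB transiently). Unit tests run
the same code at 2–4 mm on small cohorts in seconds.

## Known limitations

* The frustum model assumes circular cross-sections; real thighs are
  elliptical and the tape reads the convex girth. The model is exact only
  on the phantom family, by construction — that is what isolates
  discretization and noise effects from model error.
* The printed +200/−200 HU question is resolved by intent, not by
  re-measurement of patient data; both thresholds are runnable.
* Melphalan only: TNF-alpha has no per-liter dosing rule and is out of
  scope, as are water-displacement volumetry, real DICOM segmentation and
  pharmacokinetics.
* The cohort generator's correlations (e.g. ABW vs leg volume) emerge
  from its structural links, not from fitted patient data; they mirror
  the qualitative ordering of the clinical findings, and no exact
  reproduction of patient-cohort statistics should be expected.
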