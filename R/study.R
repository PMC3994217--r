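## The five-panel method-comparison study on a simulated cohort:
##   (1) circumference volume vs CT volume, arms + legs pooled;
##   (2) actual body weight vs circumference volume, split by limb;
##   (3) BMI vs circumference volume, split by limb;
##   (4) ideal body weight vs circumference volume, split by limb;
##   (5) IBW-corrected volume vs no-fat CT volume, arms + legs pooled.
## Pooling follows the clinical design: both limb types lie on one
## regression line for the volume-vs-volume panels, while the
## anthropometric predictors are assessed per limb type.

panelOrSkip <- function(x, y, label, xLabel, yLabel, minN = 3L) {
  if (length(x) < minN) {
    warning(sprintf("panel '%s' skipped: only %d subjects (need >= %d)",
                    label, length(x), minN), call. = FALSE)
    return(NULL)
  }
  tryCatch(
    pearsonCorrelation(x, y, label = label, xLabel = xLabel, yLabel = yLabel),
    limbvolValidationError = function(e) {
      warning(sprintf("panel '%s' skipped: %s", label, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
}

#' Run the circumference-versus-CT validation study
#'
#' For every cohort subject the limb volume is measured twice on the same
#' synthetic limb: by the frustum model over the noisy tape series, and by
#' Hounsfield-threshold volumetry of the rasterized phantom (total-limb and
#' no-fat thresholds). The five correlation panels of the
#' method-comparison design are then computed, together with group means.
#' Phantoms are rasterized one at a time and discarded, so memory stays
#' flat in the cohort size.
#'
#' @param cohort A [LimbCohort-class] from [simulateCohort()].
#' @param spacingMm Isotropic voxel spacing of the CT arm in mm (default 1).
#' @param thresholdTotalHu Total-limb segmentation threshold (default
#'   -200 HU: everything denser than air).
#' @param thresholdNoFatHu No-fat segmentation threshold (default -20 HU:
#'   muscle and bone only).
#' @param withCT Rasterize phantoms and compute the CT panels? With
#'   `FALSE` only the anthropometric panels (2)-(4) are produced, which is
#'   fast since no voxel grid is built.
#' @param verbose Emit per-subject progress messages (standard error).
#' @return A [ValidationStudy-class] object.
#' @examples
#' coh <- simulateCohort(CohortSpec(nLegs = 4, nArms = 3, seed = 11))
#' st <- runValidationStudy(coh, spacingMm = 4)
#' panels(st)[["circ_vs_ct"]]
#' @export
runValidationStudy <- function(cohort, spacingMm = 1,
                               thresholdTotalHu = -200,
                               thresholdNoFatHu = -20,
                               withCT = TRUE, verbose = FALSE) {
  if (!is(cohort, "LimbCohort"))
    vstop("'cohort' must be a LimbCohort", field = "cohort")
  subs <- cohort@subjects
  rows <- lapply(subs, function(s) {
    tapeVol <- totalVolumeL(totalVolume(s$seriesTape))
    corr <- ibwCorrectedVolume(tapeVol, s$anthro)
    ctTot <- ctNoFat <- gtTot <- gtNoFat <- NA_real_
    gt <- profileGroundTruthL(s$profile)
    gtTot <- unname(gt["total"])
    gtNoFat <- unname(gt["noFat"])
    if (withCT) {
      if (verbose)
        message(sprintf("rasterizing subject %d/%d (%s) at %g mm",
                        s$id, length(subs), s$limbType, spacingMm))
      ph <- generatePhantom(s$profile, spacingMm, seed = s$phantomSeed)
      ctTot <- ctVolume(ph, thresholdTotalHu)
      ctNoFat <- ctVolume(ph, thresholdNoFatHu)
      rm(ph)
    }
    data.frame(
      id = s$id, limbType = s$limbType, sex = s$anthro@sex,
      heightCm = s$anthro@heightCm, weightKg = s$anthro@weightKg,
      bmi = bodyMassIndex(s$anthro), ibwKg = idealBodyWeight(s$anthro),
      quotient = correctionQuotient(s$anthro),
      tapeVolumeL = tapeVol, correctedVolumeL = corr$volumeL,
      ctTotalL = ctTot, ctNoFatL = ctNoFat,
      groundTruthTotalL = gtTot, groundTruthNoFatL = gtNoFat)
  })
  meas <- do.call(rbind, rows)

  panels <- list()
  if (withCT) {
    panels[["circ_vs_ct"]] <- panelOrSkip(
      meas$tapeVolumeL, meas$ctTotalL,
      "circumference volume vs CT volume (pooled)",
      "circumference volume (L)", "CT volume (L)")
  }
  for (limb in c("leg", "arm")) {
    d <- meas[meas$limbType == limb, ]
    for (pred in c("abw", "bmi", "ibw")) {
      x <- switch(pred, abw = d$weightKg, bmi = d$bmi, ibw = d$ibwKg)
      xl <- switch(pred, abw = "actual body weight (kg)",
                   bmi = "BMI (kg/m^2)", ibw = "ideal body weight (kg)")
      panels[[paste(pred, limb, sep = "_")]] <- panelOrSkip(
        x, d$tapeVolumeL,
        sprintf("%s vs circumference volume (%ss)", toupper(pred), limb),
        xl, "circumference volume (L)")
    }
  }
  if (withCT) {
    panels[["corr_vs_nofat"]] <- panelOrSkip(
      meas$correctedVolumeL, meas$ctNoFatL,
      "IBW-corrected volume vs no-fat CT volume (pooled)",
      "IBW-corrected volume (L)", "no-fat CT volume (L)")
  }
  panels <- Filter(Negate(is.null), panels)

  vars <- c("tapeVolumeL", "correctedVolumeL", "ctTotalL", "ctNoFatL")
  gm <- do.call(rbind, lapply(c("leg", "arm"), function(limb) {
    d <- meas[meas$limbType == limb, ]
    if (!nrow(d)) return(NULL)
    do.call(rbind, lapply(vars, function(v) data.frame(
      limbType = limb, variable = v, n = nrow(d),
      mean = mean(d[[v]]), sd = stats::sd(d[[v]]))))
  }))
  rownames(gm) <- NULL

  new("ValidationStudy", measurements = meas, panels = panels,
      groupMeans = gm, spacingMm = if (withCT) spacingMm else NA_real_)
}

#' @rdname limbvol-generics
#' @export
setMethod("panels", "ValidationStudy", function(object) object@panels)

#' @rdname limbvol-generics
#' @export
setMethod("measurements", "ValidationStudy",
          function(object) object@measurements)

#' @rdname limbvol-generics
#' @export
setMethod("groupMeans", "ValidationStudy", function(object) object@groupMeans)

setMethod("show", "ValidationStudy", function(object) {
  cat(sprintf("ValidationStudy: %d subjects, %d panels%s\n",
              nrow(object@measurements), length(object@panels),
              if (is.finite(object@spacingMm))
                sprintf(", CT at %g mm", object@spacingMm) else " (no CT arm)"))
  for (nm in names(object@panels)) {
    p <- object@panels[[nm]]
    cat(sprintf("  %-14s r = %6.3f  p = %.3g  (n = %d)\n", nm, p@r, p@p, p@n))
  }
})

#' Scatter plot of one study panel
#'
#' Figure-style scatter of a correlation panel with the ordinary
#' least-squares regression line and its 95% confidence band. Requires
#' ggplot2.
#'
#' @param study A [ValidationStudy-class].
#' @param panel Panel name (see `names(panels(study))`).
#' @return A ggplot object.
#' @export
plotPanel <- function(study, panel) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotPanel requires the ggplot2 package")
  if (!panel %in% names(study@panels))
    vstop("unknown panel '%s' (available: %s)", panel,
          paste(names(study@panels), collapse = ", "), field = "panel")
  p <- study@panels[[panel]]
  df <- data.frame(x = p@x, y = p@y)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey30", fill = "grey80") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = p@xLabel, y = p@yLabel,
                  title = p@label,
                  subtitle = sprintf("r = %.3f, two-tailed p = %.3g, n = %d",
                                     p@r, p@p, p@n)) +
    ggplot2::theme_minimal()
}
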