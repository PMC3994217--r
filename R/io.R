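## Measurement-sheet CSV I/O and the composed dosing report.

#' Read a circumference measurement sheet
#'
#' Canonical sheet format: CSV with header `level_cm,circumference_cm`,
#' decimal point, one row per level ordered proximal to distal. Blank
#' trailing rows are ignored; non-numeric cells, missing columns and
#' non-increasing levels are rejected with the offending row number
#' (row 1 = header).
#'
#' @param path CSV path.
#' @param limbType `"arm"` or `"leg"`.
#' @return A [CircumferenceSeries-class].
#' @export
readMeasurementSheet <- function(path, limbType = c("leg", "arm")) {
  limbType <- normalizeLimbType(limbType[1])
  if (!file.exists(path))
    vstop("measurement sheet '%s' does not exist", path, field = "path")
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, blank.lines.skip = FALSE)
  if (!all(c("level_cm", "circumference_cm") %in% names(raw)))
    vstop("sheet '%s' must have columns level_cm,circumference_cm (found: %s)",
          path, paste(names(raw), collapse = ","), field = "path")

  blank <- !nzchar(raw$level_cm) & !nzchar(raw$circumference_cm)
  ## only trailing blanks are tolerated
  keep <- if (any(blank)) {
    lastData <- max(c(0L, which(!blank)))
    if (any(blank[seq_len(lastData)]))
      vstop("blank row %d in the middle of sheet '%s'",
            which(blank[seq_len(lastData)])[1] + 1L, path, field = "path")
    seq_len(lastData)
  } else seq_len(nrow(raw))
  raw <- raw[keep, , drop = FALSE]

  parseNum <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      vstop("non-numeric %s '%s' in row %d of '%s'",
            name, raw[[col]][bad[1]], bad[1] + 1L, path, field = col)
    v
  }
  lev <- parseNum("level_cm", "level")
  circ <- parseNum("circumference_cm", "circumference")
  nonInc <- which(diff(lev) <= 0)
  if (length(nonInc))
    vstop("levels must be strictly increasing: row %d of '%s' (level %g after %g)",
          nonInc[1] + 2L, path, lev[nonInc[1] + 1], lev[nonInc[1]],
          field = "level_cm")
  CircumferenceSeries(circ, limbType = limbType, positionsCm = lev)
}

#' Write a circumference series as a measurement sheet
#'
#' Inverse of [readMeasurementSheet()]; a written sheet reads back to an
#' identical series.
#'
#' @param series A [CircumferenceSeries-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeMeasurementSheet <- function(series, path) {
  if (!is(series, "CircumferenceSeries"))
    vstop("'series' must be a CircumferenceSeries", field = "series")
  df <- data.frame(level_cm = levelPositions(series),
                   circumference_cm = circumferences(series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composed dosing report
#'
#' The full calculator workflow in one call: frustum volume from the
#' circumference series, tourniquet subtraction, BMI / IBW / correction
#' quotient from the anthropometrics, IBW-corrected volume, and the drug
#' dose with its rate range. The `audit` block echoes every input so the
#' report can be reproduced bit-for-bit from itself.
#'
#' @param series A [CircumferenceSeries-class].
#' @param anthro Optional [PatientAnthro-class]; without it no IBW
#'   correction is applied and the raw perfused volume is dosed.
#' @param spec A [DoseSpec-class].
#' @param tourniquetLevel 0-based level index of the most proximal perfused
#'   level (default 0 = baseline, nothing subtracted).
#' @param capAtOne Clamp the IBW/ABW quotient at 1 (see
#'   [ibwCorrectedVolume()]).
#' @return A nested list ready for JSON serialization: `volumes` (raw,
#'   tourniquet-adjusted, corrected; per-segment table), `anthropometry`,
#'   `dose`, and `audit`.
#' @examples
#' s <- CircumferenceSeries(c(58, 55, 51, 46, 40), "leg")
#' p <- PatientAnthro("male", 180, 95)
#' rep <- fullReport(s, p)
#' rep$dose$doseMg
#' @export
fullReport <- function(series, anthro = NULL, spec = DoseSpec(),
                       tourniquetLevel = 0, capAtOne = FALSE) {
  if (!is(series, "CircumferenceSeries"))
    vstop("'series' must be a CircumferenceSeries", field = "series")
  res <- totalVolume(series)
  adj <- subtractAboveLevel(res, tourniquetLevel)
  rawL <- totalVolumeL(res)
  adjL <- totalVolumeL(adj)

  anthroBlock <- NULL
  doseVolumeL <- adjL
  corrected <- NULL
  if (!is.null(anthro)) {
    if (!is(anthro, "PatientAnthro"))
      vstop("'anthro' must be a PatientAnthro object", field = "anthro")
    corrected <- ibwCorrectedVolume(adjL, anthro, capAtOne = capAtOne)
    doseVolumeL <- corrected$volumeL
    anthroBlock <- list(
      sex = anthro@sex, heightCm = anthro@heightCm,
      weightKg = anthro@weightKg,
      bmi = bodyMassIndex(anthro), ibwKg = idealBodyWeight(anthro),
      quotient = corrected$rawQuotient,
      quotientApplied = corrected$quotient,
      clamped = corrected$clamped)
  }

  dose <- limbDose(doseVolumeL, limbType(series), spec)

  segments <- data.frame(
    segment = seq_along(segmentVolumes(adj)),
    fromCm = levelPositions(series)[-nLevels(series)],
    toCm = levelPositions(series)[-1],
    volumeMl = segmentVolumes(adj),
    excluded = seq_along(segmentVolumes(adj)) %in% excludedSegments(adj))

  list(
    volumes = list(
      rawL = rawL,
      perfusedL = adjL,
      excludedL = excludedVolumeL(adj),
      correctedL = if (!is.null(corrected)) corrected$volumeL else adjL,
      segments = segments),
    anthropometry = anthroBlock,
    dose = dose,
    audit = list(
      limbType = limbType(series),
      levelPositionsCm = levelPositions(series),
      circumferencesCm = circumferences(series),
      tourniquetLevel = tourniquetLevel,
      capAtOne = capAtOne,
      sex = if (is.null(anthro)) NULL else anthro@sex,
      heightCm = if (is.null(anthro)) NULL else anthro@heightCm,
      weightKg = if (is.null(anthro)) NULL else anthro@weightKg,
      drug = spec@drug,
      armRateMgPerL = spec@armRateMgPerL,
      legRateMgPerL = spec@legRateMgPerL))
}

#' Re-run a dosing report from its audit block
#'
#' @param audit The `audit` element of a [fullReport()] result.
#' @return A new report computed from the audited parameters; identical to
#'   the original.
#' @export
reportFromAudit <- function(audit) {
  series <- CircumferenceSeries(audit$circumferencesCm,
                                limbType = audit$limbType,
                                positionsCm = audit$levelPositionsCm)
  anthro <- if (!is.null(audit$sex))
    PatientAnthro(audit$sex, audit$heightCm, audit$weightKg) else NULL
  spec <- DoseSpec(drug = audit$drug, armRateMgPerL = audit$armRateMgPerL,
                   legRateMgPerL = audit$legRateMgPerL)
  fullReport(series, anthro, spec,
             tourniquetLevel = audit$tourniquetLevel,
             capAtOne = audit$capAtOne)
}

#' Serialize a validation study for JSON reports
#'
#' @param study A [ValidationStudy-class].
#' @return A nested list mirroring the five panels and the group means.
#' @export
studyToList <- function(study) {
  if (!is(study, "ValidationStudy"))
    vstop("'study' must be a ValidationStudy", field = "study")
  list(
    spacingMm = study@spacingMm,
    nSubjects = nrow(study@measurements),
    panels = lapply(study@panels, reportToList),
    groupMeans = study@groupMeans)
}
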