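## NIfTI export / import of phantoms, and the JSON profile format.

#' Write a phantom's HU grid to NIfTI
#'
#' Stores the Hounsfield grid with the isotropic spacing in the header
#' (`.nii` or `.nii.gz` by file extension).
#'
#' @param phantom A [Phantom-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writePhantomNifti <- function(phantom, file) {
  if (!is(phantom, "Phantom"))
    vstop("'phantom' must be a Phantom object", field = "phantom")
  img <- RNifti::asNifti(phantom@hu)
  RNifti::pixdim(img) <- rep(phantom@spacingMm, 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a phantom back from NIfTI
#'
#' Reconstructs a [Phantom-class] from an HU grid on disk. Tissue labels
#' are recovered by nearest-tissue cutpoints (midway between the reference
#' attenuations of `tissueHu`); the analytic ground-truth volumes and the
#' generating profile are not stored in NIfTI and come back as `NA`/`NULL`.
#' Threshold volumetry via [ctVolume()] is unaffected.
#'
#' @param file NIfTI path written by [writePhantomNifti()].
#' @param tissueHu Reference attenuations used to re-derive labels.
#' @return A [Phantom-class] object.
#' @export
readPhantomNifti <- function(file, tissueHu = defaultTissueHu()) {
  img <- RNifti::readNifti(file)
  h <- RNifti::pixdim(img)[1]
  hu <- array(as.numeric(img), dim = dim(img))
  cuts <- (tissueHu[-1] + tissueHu[-length(tissueHu)]) / 2
  labels <- array(findInterval(hu, cuts), dim = dim(hu))
  storage.mode(labels) <- "integer"
  new("Phantom",
      spacingMm = h, hu = hu, labels = labels,
      zMm = (seq_len(dim(hu)[3]) - 1) * h,
      levelRadiiCm = data.frame(),
      groundTruthTotalL = NA_real_, groundTruthNoFatL = NA_real_,
      profile = NULL)
}

#' Write a phantom profile as JSON
#'
#' @param profile A [PhantomProfile-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writePhantomProfile <- function(profile, file) {
  if (!is(profile, "PhantomProfile"))
    vstop("'profile' must be a PhantomProfile", field = "profile")
  x <- list(
    limb_type = limbType(profile@series),
    level_positions_cm = levelPositions(profile@series),
    circumferences_cm = circumferences(profile@series),
    fat_fraction = profile@fatFraction,
    bone_fraction = profile@boneFraction,
    tissue_hu = as.list(profile@tissueHu),
    noise_sd_hu = profile@noiseSdHu
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a phantom profile from JSON
#'
#' @param file Path written by [writePhantomProfile()].
#' @return A [PhantomProfile-class] object.
#' @export
readPhantomProfile <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  series <- CircumferenceSeries(x$circumferences_cm, limbType = x$limb_type,
                                positionsCm = x$level_positions_cm)
  PhantomProfile(series,
                 fatFraction = x$fat_fraction,
                 boneFraction = x$bone_fraction,
                 tissueHu = unlist(x$tissue_hu),
                 noiseSdHu = x$noise_sd_hu)
}
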