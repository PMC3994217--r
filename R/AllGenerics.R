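#' @name limbvol-generics
#' @title Generics for limb volumetry containers
#' @description Accessor and computation generics shared by the package's
#'   S4 classes.
#' @param object,x An object.
#' @param ... Further arguments passed to methods.
NULL

#' @rdname limbvol-generics
#' @export
setGeneric("limbType", function(object) standardGeneric("limbType"))

#' @rdname limbvol-generics
#' @export
setGeneric("circumferences", function(object) standardGeneric("circumferences"))

#' @rdname limbvol-generics
#' @export
setGeneric("levelPositions", function(object) standardGeneric("levelPositions"))

#' @rdname limbvol-generics
#' @export
setGeneric("nLevels", function(object) standardGeneric("nLevels"))

#' @rdname limbvol-generics
#' @export
setGeneric("totalVolume", function(object, ...) standardGeneric("totalVolume"))

#' @rdname limbvol-generics
#' @export
setGeneric("totalVolumeL", function(object) standardGeneric("totalVolumeL"))

#' @rdname limbvol-generics
#' @export
setGeneric("segmentVolumes", function(object) standardGeneric("segmentVolumes"))

#' @rdname limbvol-generics
#' @export
setGeneric("excludedSegments",
           function(object) standardGeneric("excludedSegments"))

#' @rdname limbvol-generics
#' @export
setGeneric("excludedVolumeL",
           function(object) standardGeneric("excludedVolumeL"))

#' @rdname limbvol-generics
#' @export
setGeneric("cumulativeVolumeL",
           function(object) standardGeneric("cumulativeVolumeL"))

#' @rdname limbvol-generics
#' @export
setGeneric("subtractAboveLevel",
           function(object, tourniquetLevel)
             standardGeneric("subtractAboveLevel"))

#' @rdname limbvol-generics
#' @export
setGeneric("ctVolume",
           function(object, thresholdHu, ...) standardGeneric("ctVolume"))

#' @rdname limbvol-generics
#' @export
setGeneric("groundTruthTotalL",
           function(object) standardGeneric("groundTruthTotalL"))

#' @rdname limbvol-generics
#' @export
setGeneric("groundTruthNoFatL",
           function(object) standardGeneric("groundTruthNoFatL"))

#' @rdname limbvol-generics
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname limbvol-generics
#' @export
setGeneric("measurePhantomCircumferences",
           function(object, levelSpacingCm = 5, ...)
             standardGeneric("measurePhantomCircumferences"))

#' @rdname limbvol-generics
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname limbvol-generics
#' @export
setGeneric("panels", function(object) standardGeneric("panels"))

#' @rdname limbvol-generics
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname limbvol-generics
#' @export
setGeneric("groupMeans", function(object) standardGeneric("groupMeans"))
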