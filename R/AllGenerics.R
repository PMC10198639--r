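#' Accessors for sulcparc classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("gmMask", function(x) standardGeneric("gmMask"))
#' @rdname accessors
#' @export
setGeneric("wmMask", function(x) standardGeneric("wmMask"))
#' @rdname accessors
#' @export
setGeneric("csfMask", function(x) standardGeneric("csfMask"))
#' @rdname accessors
#' @export
setGeneric("maskAffine", function(x) standardGeneric("maskAffine"))
#' @rdname accessors
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))
#' @rdname accessors
#' @export
setGeneric("runData", function(x) standardGeneric("runData"))
#' @rdname accessors
#' @export
setGeneric("runTr", function(x) standardGeneric("runTr"))
#' @rdname accessors
#' @export
setGeneric("runMotion", function(x) standardGeneric("runMotion"))
#' @rdname accessors
#' @export
setGeneric("fingerprintValues", function(x) standardGeneric("fingerprintValues"))
#' @rdname accessors
#' @export
setGeneric("roiIndex", function(x) standardGeneric("roiIndex"))
#' @rdname accessors
#' @export
setGeneric("targetIndex", function(x) standardGeneric("targetIndex"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setGeneric("clusterProbabilities", function(x) standardGeneric("clusterProbabilities"))
#' @rdname accessors
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))
#' @rdname accessors
#' @export
setGeneric("landmarkTable", function(x) standardGeneric("landmarkTable"))
#' @rdname accessors
#' @export
setGeneric("apExtent", function(x) standardGeneric("apExtent"))

#' @rdname accessors
#' @export
setMethod("roiMask", "MaskSet", function(x) x@roi)
#' @rdname accessors
#' @export
setMethod("gmMask", "MaskSet", function(x) x@gm)
#' @rdname accessors
#' @export
setMethod("wmMask", "MaskSet", function(x) x@wm)
#' @rdname accessors
#' @export
setMethod("csfMask", "MaskSet", function(x) x@csf)
#' @rdname accessors
#' @export
setMethod("maskAffine", "MaskSet", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("zoneLabels", "PhantomMasks", function(x) x@zoneLabels)
#' @rdname accessors
#' @export
setMethod("runData", "Run4D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("runTr", "Run4D", function(x) x@tr)
#' @rdname accessors
#' @export
setMethod("runMotion", "Run4D", function(x) x@motion)
#' @rdname accessors
#' @export
setMethod("fingerprintValues", "FingerprintMatrix", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("roiIndex", "FingerprintMatrix", function(x) x@roiIndex)
#' @rdname accessors
#' @export
setMethod("targetIndex", "FingerprintMatrix", function(x) x@targetIndex)
#' @rdname accessors
#' @export
setMethod("roiIndex", "ParcellationResult", function(x) x@roiIndex)
#' @rdname accessors
#' @export
setMethod("roiIndex", "ClusterProbabilityMap", function(x) x@roiIndex)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ParcellationResult", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("chosenK", "ParcellationResult", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("scoreTable", "ParcellationResult", function(x) x@scoresByK)
#' @rdname accessors
#' @export
setMethod("clusterProbabilities", "ClusterProbabilityMap", function(x) x@prob)
#' @rdname accessors
#' @export
setMethod("graphWeights", "SimilarityGraph", function(x) x@W)
#' @rdname accessors
#' @export
setMethod("landmarkTable", "LandmarkSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("apExtent", "LandmarkSet", function(x) x@apExtent)
#' @rdname accessors
#' @export
setMethod("apExtent", "SpeciesConfig", function(x) x@apExtent)

#' Reorder clusters along the caudo-rostral axis
#'
#' @param result object carrying cluster labels.
#' @param masks a \linkS4class{MaskSet} providing the voxel-to-world affine.
#' @export
setGeneric("orderClustersCaudorostral",
           function(result, masks) standardGeneric("orderClustersCaudorostral"))
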