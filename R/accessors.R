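# Accessor generics and methods. Slot access from user code should go through
# these so the internal representation can change without breaking callers.

#' @rdname accessors
#' @param object one of the package's S4 objects.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "SegmentationProfile", function(object) object@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "SegmentFeatureVector", function(object) object@sampleId)

#' @rdname accessors
#' @export
setGeneric("tumorFraction", function(object) standardGeneric("tumorFraction"))
#' @rdname accessors
#' @export
setMethod("tumorFraction", "SegmentationProfile",
          function(object) object@tumorFraction)
#' @rdname accessors
#' @export
setMethod("tumorFraction", "SegmentFeatureVector",
          function(object) object@tumorFraction)
#' @rdname accessors
#' @export
setMethod("tumorFraction", "SignatureScoreMatrix",
          function(object) object@tumorFraction)

#' @rdname accessors
#' @export
setGeneric("ploidy", function(object) standardGeneric("ploidy"))
#' @rdname accessors
#' @export
setMethod("ploidy", "SegmentationProfile", function(object) object@ploidy)
#' @rdname accessors
#' @export
setMethod("ploidy", "Archetype", function(object) object@ploidy)

#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setMethod("segments", "SegmentationProfile", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("isAdjusted", function(object) standardGeneric("isAdjusted"))
#' @rdname accessors
#' @export
setMethod("isAdjusted", "SegmentationProfile", function(object) object@adjusted)
#' @rdname accessors
#' @export
setMethod("isAdjusted", "SegmentFeatureVector", function(object) object@adjusted)
#' @rdname accessors
#' @export
setMethod("isAdjusted", "SignatureScoreMatrix", function(object) object@adjusted)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "SegmentFeatureVector", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("imputedFlags", function(object) standardGeneric("imputedFlags"))
#' @rdname accessors
#' @export
setMethod("imputedFlags", "SegmentFeatureVector", function(object) object@imputed)

#' @rdname accessors
#' @export
setGeneric("signatureNames", function(object) standardGeneric("signatureNames"))
#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureSet", function(object) names(object@weights))
#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureScoreMatrix",
          function(object) rownames(object@scores))
#' @rdname accessors
#' @export
setMethod("signatureNames", "SubtypeModel", function(object) object@signatures)

#' @rdname accessors
#' @export
setGeneric("schemeSize", function(object) standardGeneric("schemeSize"))
#' @rdname accessors
#' @export
setMethod("schemeSize", "SignatureSet", function(object) length(object@scheme))

#' @rdname accessors
#' @export
setGeneric("segmentScheme", function(object) standardGeneric("segmentScheme"))
#' @rdname accessors
#' @export
setMethod("segmentScheme", "SignatureSet", function(object) object@scheme)

#' @rdname accessors
#' @export
setGeneric("signatureWeights",
           function(object, signature) standardGeneric("signatureWeights"))
#' @rdname accessors
#' @param signature signature name.
#' @export
setMethod("signatureWeights", "SignatureSet", function(object, signature) {
  if (!signature %in% names(object@weights)) {
    stop("unknown signature: ", signature)
  }
  object@weights[[signature]]
})

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "SignatureScoreMatrix", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("lowConfidence", function(object) standardGeneric("lowConfidence"))
#' @rdname accessors
#' @export
setMethod("lowConfidence", "SignatureScoreMatrix",
          function(object) object@lowConfidence)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setMethod("chosenK", "ConsensusResult", function(object) object@chosenK)

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "SubtypeModel", function(object) object@centroids)

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setMethod("clinicalData", "ClinicalTable", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("schemeBins", function(object) standardGeneric("schemeBins"))
#' @rdname accessors
#' @export
setMethod("schemeBins", "GenomeScheme", function(object) object@bins)

#' @rdname accessors
#' @export
setGeneric("schemeGenes", function(object) standardGeneric("schemeGenes"))
#' @rdname accessors
#' @export
setMethod("schemeGenes", "GenomeScheme", function(object) object@genes)

#' @rdname accessors
#' @export
setGeneric("schemeSegments", function(object) standardGeneric("schemeSegments"))
#' @rdname accessors
#' @export
setMethod("schemeSegments", "GenomeScheme", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("archetypeCopyNumber",
           function(object) standardGeneric("archetypeCopyNumber"))
#' @rdname accessors
#' @export
setMethod("archetypeCopyNumber", "Archetype", function(object) object@copyNumber)

#' @rdname accessors
#' @export
setGeneric("binTable", function(object) standardGeneric("binTable"))
#' @rdname accessors
#' @export
setMethod("binTable", "SegmentationProfile", function(object) object@bins)

#' Accessors for ctDNAsig S4 classes
#'
#' Small read-only accessors for the package's S4 containers:
#' \code{sampleId}, \code{tumorFraction}, \code{ploidy}, \code{segments},
#' \code{featureValues}, \code{scores}, \code{centroids}, \code{clusterLabels}
#' and friends.
#'
#' @name accessors
NULL
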