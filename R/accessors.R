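# Accessors for the core S4 containers. Slot access elsewhere in the
# package goes through these.

#' @rdname Structure-class
#' @param object,x a package object
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname Structure-class
#' @export
setMethod("atomTable", "Structure", function(object) object@atoms)

#' @rdname Structure-class
#' @export
setMethod("atomTable", "Trajectory", function(object) object@structure@atoms)

#' @rdname Trajectory-class
#' @export
setGeneric("coordArray", function(object) standardGeneric("coordArray"))

#' @rdname Trajectory-class
#' @export
setMethod("coordArray", "Trajectory", function(object) object@coords)

#' @rdname Structure-class
#' @export
setMethod("coordArray", "Structure", function(object) {
  array(object@coords, dim = c(nrow(object@coords), 3L, 1L))
})

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setMethod("nFrames", "Trajectory", function(object) dim(object@coords)[3])

#' @rdname Trajectory-class
#' @export
setGeneric("frameIds", function(object) standardGeneric("frameIds"))

#' @rdname Trajectory-class
#' @export
setMethod("frameIds", "Trajectory", function(object) object@frameIds)

#' @rdname FeatureMatrix-class
#' @export
setMethod("frameIds", "FeatureMatrix",
          function(object) SummarizedExperiment::colData(object)$frameId)

#' @rdname Trajectory-class
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))

#' @rdname Trajectory-class
#' @export
setMethod("conditionLabel", "Trajectory", function(object) object@condition)

#' @rdname FeatureMatrix-class
#' @export
setMethod("conditionLabel", "FeatureMatrix",
          function(object) S4Vectors::metadata(object)$condition %||% NA_character_)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("conditionLabel", "ConsensusNetwork", function(object) object@condition)

#' Feature descriptors of a FeatureMatrix
#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureDescriptors",
           function(object) standardGeneric("featureDescriptors"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureDescriptors", "FeatureMatrix", function(object) {
  as.data.frame(SummarizedExperiment::rowData(object))
})

#' Per-frame feature values (frames x features)
#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) {
  t(SummarizedExperiment::assay(object, "values"))
})

#' @rdname SubsegmentScheme-class
#' @export
setGeneric("schemeTable", function(object) standardGeneric("schemeTable"))

#' @rdname SubsegmentScheme-class
#' @export
setMethod("schemeTable", "SubsegmentScheme", function(object) object@table)

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("networkPairs", function(object) standardGeneric("networkPairs"))

#' @rdname ConsensusNetwork-class
#' @export
setMethod("networkPairs", "ConsensusNetwork", function(object) object@pairs)

#' @rdname GapResult-class
#' @export
setGeneric("gapTable", function(object) standardGeneric("gapTable"))

#' @rdname GapResult-class
#' @export
setMethod("gapTable", "GapResult", function(object) {
  data.frame(k = object@k, logW = object@logW, eLogW = object@eLogW,
             gap = object@gap, sdk = object@sdk, sk = object@sk)
})

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

#' @rdname ClusterResult-class
#' @export
setGeneric("withinSS", function(object) standardGeneric("withinSS"))

#' @rdname ClusterResult-class
#' @export
setMethod("withinSS", "ClusterResult", function(object) object@wk)
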