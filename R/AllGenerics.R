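#' @rdname KeystrokeSession-class
#' @param object,x a keyfatigue object.
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname KeystrokeSession-class
#' @export
setGeneric("sessionLabel", function(object) standardGeneric("sessionLabel"))

#' @rdname KeystrokeSession-class
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))

#' @rdname KeystrokeSession-class
#' @export
setGeneric("sessionStart", function(object) standardGeneric("sessionStart"))

#' @rdname KeystrokeSession-class
#' @export
setGeneric("nKeys", function(object) standardGeneric("nKeys"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("validLength", function(object) standardGeneric("validLength"))

#' @rdname SimulatedCorpus-class
#' @export
setGeneric("sessions", function(object) standardGeneric("sessions"))

#' @rdname SimulatedCorpus-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname SimulatedCorpus-class
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' Embed typing windows into the 128-dimensional typing-pattern space
#'
#' @param object a [KeystrokeBackbone-class].
#' @param x a [FeatureMatrix-class], a list of them, or a window set from
#'   [cohortWindows()].
#' @param ... passed to methods.
#' @return numeric matrix, one 128-dimensional embedding v(x) per row.
#' @export
setGeneric("embed", function(object, x, ...) standardGeneric("embed"))

#' Transform typing embeddings into the fatigue-detection space
#'
#' Applies the trained adaptation layer g(.) to backbone embeddings v(x),
#' yielding fatigue embeddings g(v(x)) of the same dimension.
#'
#' @param object a [FatigueHead-class].
#' @param embeddings numeric matrix of backbone embeddings (rows).
#' @return numeric matrix of fatigue-space embeddings.
#' @export
setGeneric("transformEmbeddings",
           function(object, embeddings) standardGeneric("transformEmbeddings"))

#' Per-sample fatigue probabilities from the softmax comparison head
#'
#' @param object a [SoftmaxHead-class].
#' @param embeddings numeric matrix of backbone embeddings (rows).
#' @return matrix with columns `rest` and `fatigue`, rows summing to 1.
#' @export
setGeneric("predictProb",
           function(object, embeddings) standardGeneric("predictProb"))
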