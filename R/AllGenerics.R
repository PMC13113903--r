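#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EEGRecording-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EpochSet-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname FoldPlan-class
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))
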