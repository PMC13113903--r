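# Accessors and show methods for the core containers.

#' @rdname EEGRecording-class
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

#' @rdname EEGRecording-class
#' @export
setMethod("classLabel", "EEGRecording", function(x) x@label)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @rdname EEGRecording-class
#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId,
              ifelse(is.na(object@label), "unlabelled", object@label),
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

#' @rdname EpochSet-class
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])

#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)

#' @rdname EpochSet-class
#' @export
setMethod("subjectIds", "EpochSet", function(x) x@subjectIds)

#' @rdname EpochSet-class
#' @export
setMethod("classLabels", "EpochSet", function(x) x@labels)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  window %g s, overlap %g s; %d subjects\n",
              object@epochLen, object@overlap,
              length(unique(object@subjectIds))))
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("subjectIds", "FeatureMatrix", function(x) x@subjectIds)

#' @rdname FeatureMatrix-class
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) x@labels)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d epochs x %d features; %d subjects (%s)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@subjectIds)),
              paste(sprintf("%s=%d", names(table(object@labels)),
                            as.integer(table(object@labels))),
                    collapse = ", ")))
})

#' Subset a FeatureMatrix by rows and/or feature names
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param i row indices.
#' @param j column indices or feature names.
#' @param ... ignored.
#' @param drop ignored; a FeatureMatrix is always returned.
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  FeatureMatrix(x@values[i, j, drop = FALSE],
                x@subjectIds[i], x@labels[i])
})

#' @rdname SelectionResult-class
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d features selected (k = %g)\n",
              object@method, length(object@selected), object@k))
  if (length(object@selected))
    cat("  top:", paste(utils::head(object@selected, 5), collapse = ", "), "\n")
})

#' @rdname FoldPlan-class
#' @export
setMethod("folds", "FoldPlan", function(x) x@folds)

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan '%s': %d folds (seed %g)\n",
              object@scheme, length(object@folds), object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s): %d folds\n", object@scheme,
              length(object@foldAccuracies)))
  cat(sprintf("  epoch accuracy   %.4f\n", object@epochMetrics$accuracy))
  if (length(object@subjectMetrics))
    cat(sprintf("  subject accuracy %.4f\n", object@subjectMetrics$accuracy))
  if (length(object@bootstrap))
    cat(sprintf("  subject 95%% CI   [%.2f%%, %.2f%%]\n",
                object@bootstrap$lower, object@bootstrap$upper))
})
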