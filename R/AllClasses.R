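#' @import methods
NULL

CLASS_LEVELS <- c("control", "patient")

#' EEGRecording: one subject's multichannel EEG signal
#'
#' Container for a single continuous recording: a channels x samples matrix
#' of voltages in microvolts, the sampling rate, channel names, the subject
#' identifier and (optionally) the diagnostic class label.
#'
#' @slot subjectId character(1), subject identifier.
#' @slot label character(1), one of \code{"control"}, \code{"patient"}, or
#'   \code{NA} when unknown.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot channelNames character vector of channel labels, one per row of
#'   \code{data}.
#' @slot data numeric matrix, channels x samples, in microvolts.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    subjectId = "character",
    label = "character",
    fs = "numeric",
    channelNames = "character",
    data = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "data row count must equal the number of channel names")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "signal contains non-finite samples")
  if (!is.na(object@label) && !object@label %in% CLASS_LEVELS)
    msg <- c(msg, "label must be 'control', 'patient' or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames character vector of channel labels.
#' @param subjectId subject identifier.
#' @param label class label (\code{"control"}, \code{"patient"} or \code{NA}).
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), fs = 100,
#'                     channelNames = c("Fp1", "O1"), subjectId = "s1")
#' nSamples(rec)
#' @export
EEGRecording <- function(data, fs, channelNames = rownames(data),
                         subjectId = "unknown", label = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channelNames
  new("EEGRecording", subjectId = as.character(subjectId),
      label = as.character(label), fs = as.numeric(fs),
      channelNames = as.character(channelNames), data = data)
}

#' EpochSet: segmented EEG windows
#'
#' Fixed-length windows cut from one or more recordings, stored as an
#' epochs x channels x samples array together with per-epoch subject ids
#' and class labels.
#'
#' @slot data numeric array, n_epochs x n_channels x n_samples (microvolts).
#' @slot fs numeric(1), Hz.
#' @slot channelNames character vector.
#' @slot subjectIds character, one per epoch.
#' @slot labels character, one per epoch.
#' @slot epochLen numeric(1), window length in seconds.
#' @slot overlap numeric(1), window overlap in seconds.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    channelNames = "character",
    subjectIds = "character",
    labels = "character",
    epochLen = "numeric",
    overlap = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (epochs x channels x samples)")
  else {
    if (d[2] != length(object@channelNames))
      msg <- c(msg, "channel dimension must match channelNames")
    if (d[1] != length(object@subjectIds) || d[1] != length(object@labels))
      msg <- c(msg, "subjectIds and labels must align with epochs")
  }
  # every epoch of a subject must carry that subject's (single) label
  if (length(object@subjectIds)) {
    bySub <- split(object@labels, object@subjectIds)
    if (any(vapply(bySub, function(l) length(unique(l)) > 1L, logical(1))))
      msg <- c(msg, "a subject's epochs must share one label")
  }
  if (length(msg)) msg else TRUE
})

EpochSet <- function(data, fs, channelNames, subjectIds, labels,
                     epochLen, overlap) {
  new("EpochSet", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      subjectIds = as.character(subjectIds), labels = as.character(labels),
      epochLen = as.numeric(epochLen), overlap = as.numeric(overlap))
}

#' FeatureMatrix: epochs x named features
#'
#' Numeric feature matrix with one row per epoch, named columns in
#' \code{CHANNEL__FEATURE} format, and aligned subject ids and labels.
#'
#' @slot values numeric matrix, n_epochs x p, with unique column names.
#' @slot subjectIds character, one per row.
#' @slot labels character, one per row.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    subjectIds = "character",
    labels = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (is.null(colnames(object@values)))
    msg <- c(msg, "feature columns must be named")
  else if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "feature names must be unique")
  if (nrow(object@values) != length(object@subjectIds) ||
      nrow(object@values) != length(object@labels))
    msg <- c(msg, "subjectIds and labels must align with rows")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values epochs x features numeric matrix with column names.
#' @param subjectIds per-row subject ids.
#' @param labels per-row class labels.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, subjectIds, labels) {
  new("FeatureMatrix", values = as.matrix(values),
      subjectIds = as.character(subjectIds), labels = as.character(labels))
}

#' SelectionResult: ordered feature panel
#'
#' @slot selected character, selected feature names in selection order.
#' @slot scores named numeric, per-feature criterion scores.
#' @slot method character(1): variance, mi, rfe or mrmr.
#' @slot k numeric(1), requested panel size.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(selected = "character", scores = "numeric",
                 method = "character", k = "numeric")
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (anyDuplicated(object@selected))
    msg <- c(msg, "selected features must be unique")
  if (!object@method %in% c("variance", "mi", "rfe", "mrmr"))
    msg <- c(msg, "unknown selection method")
  if (length(object@selected) > object@k)
    msg <- c(msg, "more features selected than k")
  if (length(msg)) msg else TRUE
})

#' FoldPlan: train/test splits under a named validation scheme
#'
#' @slot scheme character(1): random_split, kfold_epoch or loso.
#' @slot folds list of \code{list(train=, test=)} integer index pairs.
#' @slot params list of scheme parameters (k or testFrac).
#' @slot seed numeric(1).
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(scheme = "character", folds = "list",
                 params = "list", seed = "numeric")
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (!object@scheme %in% c("random_split", "kfold_epoch", "loso"))
    msg <- c(msg, "unknown validation scheme")
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)))
      msg <- c(msg, "train and test indices overlap within a fold")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' EvalReport: epoch- and subject-level evaluation results
#'
#' Returned by \code{\link{runProtocol}}. Pooled out-of-fold predictions,
#' per-fold accuracies, epoch and subject metrics, bootstrap confidence
#' intervals and the threshold sweep.
#'
#' @slot scheme character(1).
#' @slot foldAccuracies numeric, epoch accuracy per fold.
#' @slot pooled data.frame with columns epoch, subjectId, label, predicted,
#'   probPatient (out-of-fold).
#' @slot epochMetrics list, see \code{\link{classificationMetrics}}.
#' @slot subjectMetrics list with subject table, accuracy and metrics.
#' @slot bootstrap list with level, B, seed and percent bounds.
#' @slot thresholdCurve list, see \code{\link{thresholdSweep}}.
#' @slot details list: per-fold selections, hyperparameters, audit log.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(scheme = "character", foldAccuracies = "numeric",
                 pooled = "data.frame", epochMetrics = "list",
                 subjectMetrics = "list", bootstrap = "list",
                 thresholdCurve = "list", details = "list")
)
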