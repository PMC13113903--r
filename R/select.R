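# Feature selection: low-variance filtering, mutual-information ranking,
# recursive feature elimination (tree importance), and a native greedy
# minimum-redundancy-maximum-relevance (MRMR) selector.
#
# Mutual information uses equal-frequency discretization into nBins bins
# and the plug-in estimator, in bits. Ties in greedy selection are broken
# by ascending feature name for cross-platform determinism.

discretize <- function(x, nBins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# plug-in mutual information (bits) between two discrete vectors
discreteMI <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

asFeatureMatrix <- function(X) {
  stopifnot(is(X, "FeatureMatrix"))
  X
}

#' Low-variance feature filter
#'
#' Keeps features whose sample variance (over the provided rows) exceeds
#' \code{tau}.
#'
#' @param X a \linkS4class{FeatureMatrix}.
#' @param tau variance threshold (>= 0; default 1e-10).
#' @return A \linkS4class{SelectionResult} (scores are the variances).
#' @export
varianceFilter <- function(X, tau = 1e-10) {
  X <- asFeatureMatrix(X)
  stopIf(tau < 0, "tau must be >= 0")
  v <- apply(featureValues(X), 2, stats::var)
  keep <- names(v)[v > tau]
  new("SelectionResult", selected = keep, scores = v,
      method = "variance", k = as.numeric(length(keep)))
}

#' Mutual information of each feature with the class label
#'
#' Features are discretized into equal-frequency bins; the plug-in MI with
#' the label is returned in bits.
#'
#' @param X a \linkS4class{FeatureMatrix}.
#' @param y class labels (defaults to the labels carried by \code{X}).
#' @param nBins number of quantile bins (default 10).
#' @return Named numeric vector of nonnegative MI scores, one per feature.
#' @export
miScores <- function(X, y = classLabels(X), nBins = 10) {
  X <- asFeatureMatrix(X)
  stopIf(length(unique(y)) < 2, "need at least 2 classes")
  vals <- featureValues(X)
  vapply(seq_len(ncol(vals)), function(j)
    discreteMI(discretize(vals[, j], nBins), y), 0) |>
    stats::setNames(colnames(vals))
}

#' Recursive feature elimination with tree-ensemble importance
#'
#' Repeatedly fits a random forest and drops the lowest-importance 10\%
#' (at least one) of the remaining features until \code{nKeep} remain.
#' Deterministic for a fixed seed.
#'
#' @param X a \linkS4class{FeatureMatrix}.
#' @param y class labels (defaults to those carried by \code{X}).
#' @param nKeep number of features to retain.
#' @param seed integer seed.
#' @param numTrees trees per forest (default 100).
#' @return A \linkS4class{SelectionResult}; scores are the final-round
#'   importances of the retained features.
#' @export
rfeSelect <- function(X, y = classLabels(X), nKeep, seed = 1L,
                      numTrees = 100) {
  X <- asFeatureMatrix(X)
  vals <- featureValues(X)
  stopIf(nKeep > ncol(vals), "nKeep exceeds the number of features")
  current <- colnames(vals)
  if (nKeep == length(current))
    return(new("SelectionResult", selected = current,
               scores = stats::setNames(rep(NA_real_, length(current)),
                                        current),
               method = "rfe", k = as.numeric(nKeep)))
  yf <- factor(y)
  imp <- NULL
  round <- 0L
  while (length(current) > nKeep) {
    round <- round + 1L
    fit <- ranger::ranger(x = vals[, current, drop = FALSE], y = yf,
                          num.trees = numTrees, importance = "impurity",
                          seed = deriveSeed(seed, round),
                          num.threads = 1)
    imp <- fit$variable.importance
    nDrop <- max(1L, floor(0.1 * length(current)))
    nDrop <- min(nDrop, length(current) - nKeep)
    # lowest importance first; name order breaks ties deterministically
    ord <- order(imp, names(imp))
    current <- setdiff(current, names(imp)[ord[seq_len(nDrop)]])
  }
  new("SelectionResult", selected = current, scores = imp[current],
      method = "rfe", k = as.numeric(nKeep))
}

#' Greedy minimum-redundancy-maximum-relevance selection
#'
#' The first pick maximizes relevance MI(feature; label); each later pick
#' maximizes relevance minus the mean MI with the already-selected features
#' (the MID, difference, variant; set \code{variant = "quotient"} for MIQ).
#' Ties are broken by ascending feature name.
#'
#' @param X a \linkS4class{FeatureMatrix}.
#' @param y class labels (defaults to those carried by \code{X}).
#' @param k panel size (default 50).
#' @param nBins quantile bins for the MI estimator.
#' @param variant \code{"difference"} (default) or \code{"quotient"}.
#' @return A \linkS4class{SelectionResult} with features in selection order
#'   and their criterion scores.
#' @export
mrmrSelect <- function(X, y = classLabels(X), k = 50, nBins = 10,
                       variant = c("difference", "quotient")) {
  X <- asFeatureMatrix(X)
  variant <- match.arg(variant)
  vals <- featureValues(X)
  p <- ncol(vals)
  stopIf(k > p, "k exceeds the number of features")
  stopIf(length(unique(y)) < 2, "need at least 2 classes")
  disc <- apply(vals, 2, discretize, nBins = nBins)
  rel <- vapply(seq_len(p), function(j) discreteMI(disc[, j], y), 0)
  names(rel) <- colnames(vals)
  nm <- colnames(vals)
  selected <- character(0)
  scores <- numeric(0)
  redSum <- stats::setNames(rep(0, p), nm)
  remaining <- nm
  for (step in seq_len(k)) {
    crit <- if (step == 1) rel[remaining]
    else {
      red <- redSum[remaining] / length(selected)
      if (variant == "difference") rel[remaining] - red
      else rel[remaining] / (red + 1e-12)
    }
    ord <- order(-crit, remaining)        # ties: ascending name
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[[ord[1]]])
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    redSum[remaining] <- redSum[remaining] +
      vapply(remaining, function(f) discreteMI(disc[, f], disc[, pick]), 0)
  }
  new("SelectionResult", selected = selected,
      scores = stats::setNames(scores, selected),
      method = "mrmr", k = as.numeric(k))
}

#' Selection pipeline configuration
#'
#' The default chain reproduces the framework's default: variance filter
#' then MRMR to \code{k} features.
#'
#' @param chain character vector drawn from \code{"variance"}, \code{"mi"},
#'   \code{"rfe"}, \code{"mrmr"}, applied in order.
#' @param k target panel size for mi/rfe/mrmr stages.
#' @param tau variance threshold.
#' @param nBins MI bins.
#' @return A list of class \code{"SelectionConfig"}.
#' @export
selectionConfig <- function(chain = c("variance", "mrmr"), k = 50,
                            tau = 1e-10, nBins = 10) {
  stopIf(!all(chain %in% c("variance", "mi", "rfe", "mrmr")),
         "unknown selection stage")
  structure(list(chain = chain, k = k, tau = tau, nBins = nBins),
            class = "SelectionConfig")
}

# run a selection chain on (training) rows; returns the selected names and
# the per-stage SelectionResults
applySelection <- function(X, config, seed = 1L) {
  stopifnot(inherits(config, "SelectionConfig"))
  cur <- X
  results <- list()
  for (stage in config$chain) {
    k <- min(config$k, ncol(featureValues(cur)))
    res <- switch(stage,
      variance = varianceFilter(cur, config$tau),
      mi = {
        sc <- sort(miScores(cur, nBins = config$nBins), decreasing = TRUE)
        new("SelectionResult", selected = names(sc)[seq_len(k)],
            scores = sc[seq_len(k)], method = "mi", k = as.numeric(k))
      },
      rfe = rfeSelect(cur, nKeep = k, seed = seed),
      mrmr = mrmrSelect(cur, k = k, nBins = config$nBins))
    results[[stage]] <- res
    cur <- cur[, selectedFeatures(res)]
  }
  list(selected = featureNames(cur), stages = results)
}

#' Serialize a SelectionResult to a small JSON report
#'
#' @param res a \linkS4class{SelectionResult}.
#' @param path output path.
#' @export
writeSelectionResult <- function(res, path) {
  jsonlite::write_json(list(method = res@method, k = res@k,
                            selected = res@selected,
                            scores = as.list(res@scores)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
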