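# Validation schemes, the nested leakage-free protocol, epoch- and
# subject-level metrics, percentile bootstrap CIs, threshold analysis,
# paired fold tests and the k-fold-vs-LOSO leakage report.

#' Build a fold plan
#'
#' \code{random_split}: one stratified epoch-level train/test split
#' (\code{testFrac}, default 0.5). \code{kfold_epoch}: epoch-level k-fold
#' whose test sets partition the rows (the scheme that leaks subjects).
#' \code{loso}: leave-one-subject-out; each fold tests on all epochs of
#' exactly one subject.
#'
#' @param scheme \code{"random_split"}, \code{"kfold_epoch"} or
#'   \code{"loso"}.
#' @param subjectIds per-epoch subject ids.
#' @param labels per-epoch class labels (needed for stratification).
#' @param k number of folds for kfold_epoch (default 5).
#' @param testFrac test fraction for random_split (default 0.5).
#' @param seed integer seed.
#' @return A \linkS4class{FoldPlan}.
#' @examples
#' ids <- rep(c("a", "b", "c"), each = 4)
#' labs <- rep(c("control", "patient", "control"), each = 4)
#' makeFolds("loso", ids, labs)
#' @export
makeFolds <- function(scheme = c("random_split", "kfold_epoch", "loso"),
                      subjectIds, labels = NULL, k = 5, testFrac = 0.5,
                      seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(subjectIds)
  idx <- seq_len(n)
  folds <- switch(scheme,
    loso = {
      subs <- unique(subjectIds)
      stopIf(length(subs) < 2, "loso requires at least 2 subjects")
      lapply(subs, function(s)
        list(train = idx[subjectIds != s], test = idx[subjectIds == s]))
    },
    kfold_epoch = {
      stopIf(k > n, "k exceeds the number of epochs")
      stopIf(k < 2, "k must be at least 2")
      fid <- withSeed(seed, {
        f <- integer(n)
        strat <- if (is.null(labels)) rep("all", n) else labels
        for (cl in unique(strat)) {
          rows <- sample(idx[strat == cl])
          f[rows] <- rep_len(seq_len(k), length(rows))
        }
        f
      })
      lapply(seq_len(k), function(f)
        list(train = idx[fid != f], test = idx[fid == f]))
    },
    random_split = {
      stopIf(testFrac <= 0 || testFrac >= 1, "testFrac must be in (0,1)")
      stopIf(is.null(labels), "random_split needs labels for stratification")
      test <- withSeed(seed, {
        unlist(lapply(unique(labels), function(cl) {
          rows <- idx[labels == cl]
          sample(rows, round(length(rows) * testFrac))
        }))
      })
      list(list(train = setdiff(idx, test), test = sort(test)))
    })
  new("FoldPlan", scheme = scheme, folds = folds,
      params = list(k = k, testFrac = testFrac), seed = as.numeric(seed))
}

#' Macro / support-weighted averages and F1
#'
#' The averaging rules used for per-class metric summaries: \code{macroAverage}
#' is the unweighted mean over classes; \code{weightedAverage} weights each
#' class by its support; \code{f1Score} is the harmonic mean of precision
#' and recall.
#'
#' @param x per-class metric values.
#' @param support per-class supports (row counts).
#' @param precision,recall scalar or vector precision/recall.
#' @return Numeric scalar (or vector for \code{f1Score}).
#' @examples
#' macroAverage(c(0.738, 0.780))             # 0.759
#' f1Score(0.686, 0.680)                     # 0.683
#' @export
macroAverage <- function(x) mean(x)

#' @rdname macroAverage
#' @export
weightedAverage <- function(x, support) sum(x * support) / sum(support)

#' @rdname macroAverage
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

# rank-statistic ROC-AUC of the positive class
rocAUC <- function(yTrue, prob) {
  pos <- prob[yTrue == POSITIVE_CLASS]
  neg <- prob[yTrue == NEGATIVE_CLASS]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Binary classification metrics
#'
#' Accuracy, per-class precision/recall/F1 with supports, macro and
#' support-weighted averages, the confusion matrix, and (when
#' probabilities are supplied) the ROC-AUC of the positive (patient)
#' class. Control recall doubles as specificity.
#'
#' @param yTrue,yPred aligned label vectors (\code{control} / \code{patient}).
#' @param prob optional positive-class probabilities; when absent the AUC
#'   is omitted (not an error).
#' @return List with \code{accuracy}, \code{perClass} (data.frame),
#'   \code{macro}, \code{weighted}, \code{confusion}, \code{auc}, \code{n}.
#' @export
classificationMetrics <- function(yTrue, yPred, prob = NULL) {
  stopIf(length(yTrue) != length(yPred), "yTrue and yPred lengths differ")
  classes <- CLASS_LEVELS
  conf <- table(factor(yTrue, classes), factor(yPred, classes),
                dnn = c("true", "predicted"))
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(class = cl, precision = prec, recall = rec,
               f1 = f1Score(prec, rec), support = tp + fn)
  }))
  list(accuracy = sum(diag(conf)) / sum(conf),
       perClass = perClass,
       macro = c(precision = macroAverage(perClass$precision),
                 recall = macroAverage(perClass$recall),
                 f1 = macroAverage(perClass$f1)),
       weighted = c(
         precision = weightedAverage(perClass$precision, perClass$support),
         recall = weightedAverage(perClass$recall, perClass$support),
         f1 = weightedAverage(perClass$f1, perClass$support)),
       confusion = conf,
       auc = if (is.null(prob)) NULL else rocAUC(yTrue, prob),
       n = length(yTrue))
}

#' Aggregate epoch predictions to subject level
#'
#' A subject's score is the mean positive-class probability of their
#' epochs; the subject is predicted positive when the score is at least
#' the threshold (ties go to the positive class).
#'
#' @param prob per-epoch positive-class probabilities.
#' @param subjectIds aligned subject ids.
#' @param labels optional aligned true labels (carried into the output).
#' @param threshold decision threshold (default 0.5).
#' @return data.frame with subject_id, score, predicted and (when labels
#'   are given) label and correct.
#' @examples
#' aggregateSubjects(c(0.9, 0.8, 0.1), rep("s1", 3))   # score 0.6 -> patient
#' @export
aggregateSubjects <- function(prob, subjectIds, labels = NULL,
                              threshold = 0.5) {
  stopIf(length(prob) != length(subjectIds),
         "prob and subjectIds lengths differ")
  subs <- unique(subjectIds)
  score <- vapply(subs, function(s) mean(prob[subjectIds == s]), 0)
  out <- data.frame(subject_id = subs, score = score,
                    predicted = ifelse(score >= threshold, POSITIVE_CLASS,
                                       NEGATIVE_CLASS),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(labels)) {
    out$label <- vapply(subs, function(s)
      unique(labels[subjectIds == s])[1], "")
    out$correct <- out$predicted == out$label
  }
  out
}

#' Percentile bootstrap confidence interval for an accuracy
#'
#' Resamples the per-subject binary outcomes with replacement B times and
#' reports inverse-ECDF percentile bounds of the resampled accuracy, in
#' percent. Bounds are therefore exact multiples of 100/n.
#'
#' @param outcomes binary vector (1 = correct) of per-subject correctness.
#' @param B bootstrap iterations (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return List with \code{lower}, \code{upper} (percent), \code{level},
#'   \code{B}, \code{seed}, \code{n}.
#' @examples
#' bootstrapCI(c(rep(1, 23), rep(0, 5)), B = 2000, seed = 1)
#' @export
bootstrapCI <- function(outcomes, B = 2000, level = 0.95, seed = 1L) {
  outcomes <- as.numeric(outcomes)
  n <- length(outcomes)
  stopIf(n < 2, "need at least 2 outcomes")
  stopIf(!all(outcomes %in% c(0, 1)), "outcomes must be binary")
  accs <- withSeed(seed, vapply(seq_len(B), function(b)
    mean(outcomes[sample.int(n, n, replace = TRUE)]), 0))
  a <- (1 - level) / 2
  q <- stats::quantile(accs, c(a, 1 - a), type = 1, names = FALSE)
  list(lower = 100 * q[1], upper = 100 * q[2], level = level, B = B,
       seed = as.integer(seed), n = n)
}

#' Precision/recall/F1 threshold sweep
#'
#' Positive-class precision, recall and F1 at every threshold on a regular
#' grid; the reported optimum is the smallest threshold attaining the
#' maximum F1 (documented tie rule).
#'
#' @param prob positive-class probabilities.
#' @param yTrue aligned true labels; both classes must be present.
#' @param step grid step (default 0.001).
#' @return List with \code{curve} (data.frame threshold/precision/recall/
#'   f1) and \code{optimalThreshold}.
#' @export
thresholdSweep <- function(prob, yTrue, step = 0.001) {
  stopIf(length(unique(yTrue)) < 2, "both classes must be present")
  grid <- seq(0, 1, by = step)
  isPos <- yTrue == POSITIVE_CLASS
  nPos <- sum(isPos)
  # order once; tp/fp at threshold t = counts of prob >= t
  curve <- vapply(grid, function(t) {
    predPos <- prob >= t
    tp <- sum(predPos & isPos)
    fp <- sum(predPos & !isPos)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / nPos
    c(prec, rec, f1Score(prec, rec))
  }, numeric(3))
  df <- data.frame(threshold = grid, precision = curve[1, ],
                   recall = curve[2, ], f1 = curve[3, ])
  best <- df$threshold[which.max(df$f1)]   # which.max takes the first max
  list(curve = df, optimalThreshold = best, maxF1 = max(df$f1))
}

#' Paired Wilcoxon signed-rank tests over folds with BH correction
#'
#' Two-sided Wilcoxon signed-rank on the paired per-fold accuracy
#' differences for each comparison in the family (zero differences
#' discarded), with Benjamini-Hochberg adjustment across the family. The
#' reported W is the smaller of the two signed-rank sums, so W = 0 when
#' one method wins every fold.
#'
#' @param comparisons named list; each element is a list/data.frame with
#'   numeric vectors \code{a} and \code{b} of aligned per-fold accuracies.
#' @return data.frame with comparison, W, p, pBH.
#' @examples
#' pairedFoldTest(list(ens_vs_rf = list(a = c(.8, .9, .7, .85, .9, .8),
#'                                      b = c(.7, .8, .6, .75, .8, .7))))
#' @export
pairedFoldTest <- function(comparisons) {
  stopIf(length(comparisons) < 1, "need at least one comparison")
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    a <- cmp$a; b <- cmp$b
    stopIf(length(a) != length(b), "fold vectors must align (%s)", nm)
    nz <- (a - b) != 0
    if (!any(nz)) {
      warning(sprintf("all paired differences are zero (%s); p = 1", nm))
      return(data.frame(comparison = nm, W = NA_real_, p = 1))
    }
    d <- (a - b)[nz]
    r <- rank(abs(d))
    vPlus <- sum(r[d > 0])
    vMinus <- sum(r[d < 0])
    wt <- suppressWarnings(stats::wilcox.test(a[nz], b[nz], paired = TRUE))
    data.frame(comparison = nm, W = min(vPlus, vMinus), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$pBH <- stats::p.adjust(out$p, method = "BH")
  out
}

# ---- the protocol ---------------------------------------------------------

#' Run the full classification protocol over a fold plan
#'
#' Per fold, strictly on the training rows: selection chain (variance
#' filter, MRMR by default), then ensemble tuning and fitting; test rows
#' are only ever predicted. Out-of-fold predictions are pooled, epoch and
#' subject metrics computed, the subject-level bootstrap CI and the
#' threshold sweep derived. An audit log records the exact row sets each
#' fitting stage consumed; train/test disjointness is asserted for every
#' fold.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param plan a \linkS4class{FoldPlan} over the matrix rows.
#' @param selection a \code{\link{selectionConfig}}.
#' @param ensemble an \code{\link{ensembleConfig}}.
#' @param seed run seed; per-fold and per-model seeds are derived from it.
#' @param bootstrapB,level bootstrap settings for the subject-level CI.
#' @param thresholdStep grid step of the threshold sweep.
#' @return An \linkS4class{EvalReport}.
#' @export
runProtocol <- function(fm, plan, selection = selectionConfig(),
                        ensemble = ensembleConfig(), seed = 1L,
                        bootstrapB = 2000, level = 0.95,
                        thresholdStep = 0.001) {
  stopifnot(is(fm, "FeatureMatrix"), is(plan, "FoldPlan"))
  vals <- featureValues(fm)
  ids <- subjectIds(fm)
  labs <- classLabels(fm)
  n <- nrow(vals)
  pooledProb <- rep(NA_real_, n)
  pooledPred <- rep(NA_character_, n)
  foldAcc <- numeric(0)
  audit <- list()
  details <- list()
  for (fi in seq_along(plan@folds)) {
    f <- plan@folds[[fi]]
    stopIf(length(intersect(f$train, f$test)) > 0,
           "leakage: fold %d train and test rows overlap", fi)
    stopIf(max(c(f$train, f$test)) > n || min(c(f$train, f$test)) < 1,
           "fold %d indexes outside the matrix", fi)
    yTr <- labs[f$train]
    stopIf(length(unique(yTr)) < 2,
           "fold %d training set has a single class", fi)
    foldSeed <- deriveSeed(seed, 101, fi)
    sel <- tryCatch(
      applySelection(fm[f$train, ], selection, seed = foldSeed),
      error = function(e) stop(sprintf("fold %d selection: %s", fi,
                                       conditionMessage(e)), call. = FALSE))
    Xtr <- vals[f$train, sel$selected, drop = FALSE]
    Xte <- vals[f$test, sel$selected, drop = FALSE]
    ens <- tryCatch(
      fitEnsemble(Xtr, yTr, ensemble, seed = foldSeed),
      error = function(e) stop(sprintf("fold %d fitting: %s", fi,
                                       conditionMessage(e)), call. = FALSE))
    pr <- predictEnsemble(ens, Xte)
    pooledProb[f$test] <- pr$prob
    pooledPred[f$test] <- pr$label
    foldAcc <- c(foldAcc, mean(pr$label == labs[f$test]))
    audit[[fi]] <- list(fold = fi, trainRows = f$train, testRows = f$test)
    details[[fi]] <- list(
      fold = fi, nSelected = length(sel$selected),
      selected = sel$selected,
      hyperparameters = if (inherits(ens$model, "stackedModel")) NULL
        else lapply(ens$model, attr, which = "chosen"))
  }
  seen <- !is.na(pooledProb)
  pooled <- data.frame(epoch = which(seen), subjectId = ids[seen],
                       label = labs[seen], predicted = pooledPred[seen],
                       probPatient = pooledProb[seen],
                       stringsAsFactors = FALSE)
  em <- classificationMetrics(pooled$label, pooled$predicted,
                              pooled$probPatient)
  subj <- aggregateSubjects(pooled$probPatient, pooled$subjectId,
                            pooled$label)
  sm <- list(table = subj,
             accuracy = mean(subj$correct),
             metrics = classificationMetrics(subj$label, subj$predicted,
                                             subj$score))
  ci <- bootstrapCI(as.integer(subj$correct), B = bootstrapB, level = level,
                    seed = deriveSeed(seed, 103))
  sweep <- thresholdSweep(pooled$probPatient, pooled$label,
                          step = thresholdStep)
  new("EvalReport", scheme = plan@scheme, foldAccuracies = foldAcc,
      pooled = pooled, epochMetrics = em, subjectMetrics = sm,
      bootstrap = ci, thresholdCurve = sweep,
      details = list(folds = details, audit = audit, seed = seed))
}

#' Compare epoch-level k-fold with LOSO on identical configs
#'
#' Runs \code{\link{runProtocol}} under \code{kfold_epoch} and \code{loso}
#' with the same selection/ensemble configuration and seed, and reports
#' both reports plus the epoch- and subject-level accuracy gaps
#' (k-fold minus LOSO). A positive epoch-level gap quantifies the
#' optimism caused by subject leakage in epoch-level splits.
#'
#' @param fm a \linkS4class{FeatureMatrix} (>= 2 subjects per class).
#' @param selection,ensemble,seed,bootstrapB as in \code{\link{runProtocol}}.
#' @param k folds for the k-fold arm.
#' @return List with \code{kfold}, \code{loso} (EvalReports) and
#'   \code{gap} (named numeric).
#' @export
leakageReport <- function(fm, selection = selectionConfig(),
                          ensemble = ensembleConfig(), k = 5, seed = 1L,
                          bootstrapB = 2000) {
  ids <- subjectIds(fm)
  labs <- classLabels(fm)
  perClass <- table(unique(data.frame(ids, labs))$labs)
  stopIf(length(perClass) < 2 || any(perClass < 2),
         "need at least 2 subjects per class")
  kf <- runProtocol(fm, makeFolds("kfold_epoch", ids, labs, k = k,
                                  seed = seed),
                    selection, ensemble, seed = seed,
                    bootstrapB = bootstrapB)
  lo <- runProtocol(fm, makeFolds("loso", ids, labs, seed = seed),
                    selection, ensemble, seed = seed,
                    bootstrapB = bootstrapB)
  list(kfold = kf, loso = lo,
       gap = c(epoch = kf@epochMetrics$accuracy - lo@epochMetrics$accuracy,
               subject = kf@subjectMetrics$accuracy -
                 lo@subjectMetrics$accuracy))
}
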