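# Classifier registry, randomized hyperparameter search within training
# folds, and voting/stacking combination.
#
# Classifier internals are delegated to standard implementations (e1071,
# ranger, xgboost, rpart, nnet, class, stats::glm); this module's own
# computation is search orchestration, vote combination and the stacking
# cross-fit. A small SAMME AdaBoost over rpart stumps is implemented
# natively since no boosting package beyond xgboost is installed.

MODEL_FAMILIES <- c("svm_rbf", "knn", "gradient_boosting", "extra_trees",
                    "random_forest", "decision_tree", "logistic_regression",
                    "adaboost", "naive_bayes", "mlp")

# families whose inputs are standardized with train-fold mean/SD
SCALED_FAMILIES <- c("svm_rbf", "knn", "logistic_regression", "mlp")

defaultSearchSpace <- function(family) {
  switch(family,
    svm_rbf = list(cost = c(0.1, 1, 10, 100),
                   gamma = c(NA, 0.001, 0.01, 0.1)),  # NA = 1/p heuristic
    knn = list(k = c(3, 5, 7, 11, 15)),
    gradient_boosting = list(nrounds = c(100, 200),
                             max_depth = c(2, 3, 5),
                             eta = c(0.05, 0.1, 0.3)),
    extra_trees = list(num.trees = c(100, 300, 500),
                       max.depth = c(0, 5, 10)),
    random_forest = list(num.trees = c(100, 300, 500),
                         max.depth = c(0, 5, 10)),
    decision_tree = list(maxdepth = c(3, 5, 10, 30), cp = c(0.001, 0.01)),
    logistic_regression = list(dummy = 1),
    adaboost = list(nRounds = c(25, 50, 100), maxdepth = c(1, 2)),
    naive_bayes = list(laplace = c(0, 1)),
    mlp = list(size = c(5, 10, 20), decay = c(1e-4, 1e-3, 1e-2)))
}

#' Specify a classifier and its hyperparameter search space
#'
#' @param family one of svm_rbf, knn, gradient_boosting, extra_trees,
#'   random_forest, decision_tree, logistic_regression, adaboost,
#'   naive_bayes, mlp.
#' @param searchSpace named list of candidate values per hyperparameter
#'   (defaults per family; a space with a single point disables search).
#' @param seed integer seed for this model's randomness.
#' @return A list of class \code{"ModelSpec"}.
#' @examples
#' modelSpec("svm_rbf")
#' modelSpec("knn", searchSpace = list(k = c(3, 5)))
#' @export
modelSpec <- function(family, searchSpace = defaultSearchSpace(family),
                      seed = 1L) {
  stopIf(!family %in% MODEL_FAMILIES,
         "unknown model family '%s'", family)
  structure(list(family = family, searchSpace = searchSpace,
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

#' Ensemble configuration
#'
#' The default membership is the framework's base-learner set: RBF-SVM,
#' KNN, gradient boosting and extremely randomized trees, combined by soft
#' voting.
#'
#' @param members list of \code{\link{modelSpec}} objects (>= 1).
#' @param mode \code{"vote_soft"}, \code{"vote_hard"} or \code{"stack"}.
#' @param weights optional nonnegative per-member weights.
#' @param tuning list with \code{nIter} (randomized-search draws, default
#'   25; 0 disables tuning and uses each family's first candidate),
#'   \code{folds} (CV folds for tuning, default 5) and \code{seed}.
#' @return A list of class \code{"EnsembleConfig"}.
#' @export
ensembleConfig <- function(members = list(modelSpec("svm_rbf"),
                                          modelSpec("knn"),
                                          modelSpec("gradient_boosting"),
                                          modelSpec("extra_trees")),
                           mode = c("vote_soft", "vote_hard", "stack"),
                           weights = NULL,
                           tuning = list(nIter = 25, folds = 5, seed = 1L)) {
  mode <- match.arg(mode)
  stopIf(length(members) < 1, "need at least one ensemble member")
  for (m in members) stopifnot(inherits(m, "ModelSpec"))
  if (!is.null(weights)) {
    stopIf(length(weights) != length(members),
           "weights length must match the number of members")
    stopIf(any(weights < 0), "weights must be nonnegative")
  }
  tuning <- utils::modifyList(list(nIter = 25, folds = 5, seed = 1L), tuning)
  structure(list(members = members, mode = mode, weights = weights,
                 tuning = tuning),
            class = "EnsembleConfig")
}

# ---- fitting backends -----------------------------------------------------
# All return an object with class "fittedModel" carrying a predictProb
# closure: newdata matrix -> probability of the positive class.

fitFamily <- function(family, params, X, y, seed) {
  yf <- factor(y, levels = CLASS_LEVELS)
  stopIf(length(unique(y)) < 2, "training labels contain a single class")
  scaled <- family %in% SCALED_FAMILIES
  center <- NULL; scale <- NULL
  if (scaled) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  predictRaw <- switch(family,
    svm_rbf = {
      gamma <- if (is.null(params$gamma) || is.na(params$gamma))
        1 / ncol(X) else params$gamma
      fit <- withSeed(seed, e1071::svm(X, yf, kernel = "radial",
                                       cost = params$cost, gamma = gamma,
                                       probability = TRUE))
      function(nd) {
        pr <- attr(stats::predict(fit, nd, probability = TRUE),
                   "probabilities")
        pr[, POSITIVE_CLASS]
      }
    },
    knn = {
      k <- params$k
      trainX <- X; trainY <- yf
      function(nd) {
        pred <- withSeed(seed, class::knn(trainX, nd, trainY, k = k,
                                          prob = TRUE, use.all = TRUE))
        p <- attr(pred, "prob")
        ifelse(pred == POSITIVE_CLASS, p, 1 - p)
      }
    },
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(X, label = as.integer(yf == POSITIVE_CLASS))
      fit <- withSeed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = params$nrounds, verbose = 0))
      function(nd) stats::predict(fit, xgboost::xgb.DMatrix(nd))
    },
    extra_trees = ,
    random_forest = {
      fit <- ranger::ranger(
        x = X, y = yf, probability = TRUE,
        num.trees = params$num.trees,
        max.depth = if (params$max.depth == 0) NULL else params$max.depth,
        splitrule = if (family == "extra_trees") "extratrees" else "gini",
        num.random.splits = 1, seed = seed, num.threads = 1)
      function(nd)
        stats::predict(fit, data = nd,
                       num.threads = 1)$predictions[, POSITIVE_CLASS]
    },
    decision_tree = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      fit <- withSeed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = params$maxdepth,
                                       cp = params$cp)))
      function(nd)
        stats::predict(fit, newdata = data.frame(nd, check.names = FALSE),
                       type = "prob")[, POSITIVE_CLASS]
    },
    logistic_regression = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      function(nd) {
        p <- suppressWarnings(stats::predict(
          fit, newdata = data.frame(nd, check.names = FALSE),
          type = "response"))
        pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
      }
    },
    adaboost = fitAdaboost(X, yf, nRounds = params$nRounds,
                           maxdepth = params$maxdepth, seed = seed),
    naive_bayes = {
      fit <- e1071::naiveBayes(X, yf, laplace = params$laplace)
      function(nd) stats::predict(fit, nd, type = "raw")[, POSITIVE_CLASS]
    },
    mlp = {
      fit <- withSeed(seed, nnet::nnet(
        X, class.ind(yf), size = params$size, decay = params$decay,
        softmax = TRUE, maxit = 200, trace = FALSE, MaxNWts = 1e5))
      function(nd) stats::predict(fit, nd)[, POSITIVE_CLASS]
    })
  structure(list(family = family, params = params,
                 center = center, scale = scale,
                 predictRaw = predictRaw),
            class = "fittedModel")
}

class.ind <- function(f) {
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Positive-class probabilities from a fitted model
#'
#' @param model a fitted model returned by \code{\link{tuneModel}} or the
#'   internal fitting backends.
#' @param newdata numeric matrix of feature rows.
#' @return Numeric vector of probabilities of the positive (patient) class.
#' @export
predictProb <- function(model, newdata) {
  stopifnot(inherits(model, c("fittedModel", "stackedModel")))
  if (inherits(model, "stackedModel")) return(predictStacked(model, newdata))
  if (!is.null(model$center))
    newdata <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  p <- as.numeric(model$predictRaw(newdata))
  pmin(pmax(p, 0), 1)
}

# --- native SAMME AdaBoost over rpart stumps -------------------------------
fitAdaboost <- function(X, yf, nRounds, maxdepth, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- yf
  stumps <- list(); alphas <- numeric(0)
  withSeed(seed, {
    for (m in seq_len(nRounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = 0, minsplit = 2,
                            xval = 0))
      pred <- stats::predict(fit, df, type = "class")
      err <- sum(w * (pred != yf)) / sum(w)
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err)
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * (pred != yf))
      w <- w / sum(w)
      if (err < 1e-9) break
    }
  })
  function(nd) {
    ndf <- data.frame(nd, check.names = FALSE)
    score <- rep(0, nrow(ndf))
    for (m in seq_along(stumps)) {
      pred <- stats::predict(stumps[[m]], ndf, type = "class")
      score <- score + alphas[m] * ifelse(pred == POSITIVE_CLASS, 1, -1)
    }
    tot <- sum(alphas)
    if (tot == 0) return(rep(0.5, nrow(ndf)))
    1 / (1 + exp(-2 * score / tot))   # squash the margin to [0,1]
  }
}

# ---- tuning ---------------------------------------------------------------

stratifiedFolds <- function(y, k, seed) {
  idx <- seq_along(y)
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      rows <- sample(idx[y == cl])
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

sampleSpace <- function(space, nIter, seed) {
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  attr(grid, "out.attrs") <- NULL
  if (nIter <= 0 || nIter >= nrow(grid)) {
    if (nIter <= 0) grid <- grid[1, , drop = FALSE]
    return(grid)
  }
  withSeed(seed, grid[sample.int(nrow(grid), nIter), , drop = FALSE])
}

# one candidate row as a clean named list (no data.frame attributes)
rowParams <- function(cand, i) {
  p <- lapply(as.list(cand[i, , drop = FALSE]), unname)
  attributes(p) <- list(names = names(p))
  p
}

#' Tune and fit one classifier on training rows
#'
#' Randomized search over the spec's hyperparameter space, scored by
#' stratified k-fold accuracy on the given rows, then refit on all rows
#' with the best draw. Deterministic given the seeds. A single-point space
#' (or \code{nIter = 0}) skips the search.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param X numeric training matrix (rows = epochs).
#' @param y training labels.
#' @param nIter number of random draws (default 25).
#' @param folds CV folds used for scoring (default 5).
#' @param seed integer seed.
#' @return A fitted model (class \code{"fittedModel"}) with attributes
#'   \code{chosen} (the selected hyperparameters) and \code{cvAccuracy}.
#' @export
tuneModel <- function(spec, X, y, nIter = 25, folds = 5, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  stopIf(length(unique(y)) < 2, "training labels contain a single class")
  cand <- sampleSpace(spec$searchSpace, nIter, deriveSeed(seed, 11))
  best <- NULL; bestAcc <- -Inf
  if (nrow(cand) > 1) {
    foldId <- stratifiedFolds(y, folds, deriveSeed(seed, 13))
    for (i in seq_len(nrow(cand))) {
      params <- rowParams(cand, i)
      accs <- vapply(seq_len(folds), function(f) {
        tr <- foldId != f; te <- !tr
        if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
        fit <- fitFamily(spec$family, params, X[tr, , drop = FALSE], y[tr],
                         deriveSeed(seed, 17, i, f))
        mean((predictProb(fit, X[te, , drop = FALSE]) >= 0.5) ==
               (y[te] == POSITIVE_CLASS))
      }, 0)
      acc <- mean(accs, na.rm = TRUE)
      if (acc > bestAcc + 1e-12) { bestAcc <- acc; best <- params }
    }
  } else {
    best <- rowParams(cand, 1)
  }
  fit <- fitFamily(spec$family, best, X, y, deriveSeed(seed, 19))
  attr(fit, "chosen") <- best
  attr(fit, "cvAccuracy") <- if (is.finite(bestAcc)) bestAcc else NA_real_
  fit
}

# ---- vote combination -----------------------------------------------------

#' Soft-vote combination of member probabilities
#'
#' Weighted arithmetic mean of the members' class-probability rows,
#' renormalized to sum 1.
#'
#' @param memberProbs list of numeric matrices (rows = epochs, columns =
#'   classes) or of positive-class probability vectors.
#' @param weights optional nonnegative member weights (default equal).
#' @return Combined matrix (or vector, matching the input form).
#' @examples
#' softVote(list(c(0.8), c(0.6)))            # 0.7
#' softVote(list(c(0.8), c(0.6)), c(2, 1))   # (1.6 + 0.6)/3
#' @export
softVote <- function(memberProbs, weights = NULL) {
  stopIf(length(memberProbs) < 1, "need at least one member")
  asMat <- is.matrix(memberProbs[[1]])
  dims <- lapply(memberProbs, function(p) dim(as.matrix(p)))
  stopIf(length(unique(vapply(dims, paste, "", collapse = "x"))) != 1,
         "member probability shapes differ")
  if (is.null(weights)) weights <- rep(1, length(memberProbs))
  stopIf(length(weights) != length(memberProbs),
         "weights length must match members")
  stopIf(any(weights < 0) || sum(weights) == 0,
         "weights must be nonnegative and not all zero")
  acc <- 0
  for (i in seq_along(memberProbs))
    acc <- acc + weights[i] * as.matrix(memberProbs[[i]])
  acc <- acc / sum(weights)
  if (asMat) acc / rowSums(acc) else as.numeric(acc)
}

#' Hard-vote combination of member labels
#'
#' Weighted plurality vote. Ties are broken by the members' summed soft
#' probabilities when available, then in favour of the positive class.
#'
#' @param memberPreds list of aligned label vectors.
#' @param weights optional nonnegative member weights.
#' @param memberProbs optional list of positive-class probability vectors
#'   used for tie-breaking.
#' @return Character vector of combined labels.
#' @export
hardVote <- function(memberPreds, weights = NULL, memberProbs = NULL) {
  stopIf(length(memberPreds) < 1, "need at least one member")
  n <- length(memberPreds[[1]])
  stopIf(!all(vapply(memberPreds, length, 0L) == n),
         "member prediction lengths differ")
  if (is.null(weights)) weights <- rep(1, length(memberPreds))
  posVotes <- rep(0, n); negVotes <- rep(0, n)
  for (i in seq_along(memberPreds)) {
    isPos <- memberPreds[[i]] == POSITIVE_CLASS
    posVotes <- posVotes + weights[i] * isPos
    negVotes <- negVotes + weights[i] * !isPos
  }
  out <- ifelse(posVotes > negVotes, POSITIVE_CLASS, NEGATIVE_CLASS)
  tie <- posVotes == negVotes
  if (any(tie)) {
    if (!is.null(memberProbs)) {
      score <- Reduce(`+`, memberProbs)
      out[tie] <- ifelse(score[tie] >= 0.5 * length(memberProbs),
                         POSITIVE_CLASS, NEGATIVE_CLASS)
    } else out[tie] <- POSITIVE_CLASS
  }
  out
}

# ---- stacking -------------------------------------------------------------

#' Fit a stacking ensemble
#'
#' Meta-features are cross-fitted member probabilities (stratified k-fold
#' within the given rows); a logistic-regression meta-classifier is fitted
#' on them, and the members are refit on all rows.
#'
#' @param members list of \code{\link{modelSpec}} objects.
#' @param X training matrix.
#' @param y training labels.
#' @param config an \code{\link{ensembleConfig}} (tuning settings are used).
#' @return A \code{"stackedModel"}: members, meta-coefficients and the
#'   cross-fit fold assignment.
#' @export
fitStacking <- function(members, X, y, config = ensembleConfig(members)) {
  tun <- config$tuning
  k <- min(tun$folds, min(table(y)))
  stopIf(k < 2, "stacking needs at least 2 rows per class")
  foldId <- stratifiedFolds(y, k, deriveSeed(tun$seed, 23))
  meta <- matrix(NA_real_, nrow(X), length(members))
  for (f in seq_len(k)) {
    tr <- foldId != f; te <- !tr
    for (m in seq_along(members)) {
      fit <- tuneModel(members[[m]], X[tr, , drop = FALSE], y[tr],
                       nIter = tun$nIter, folds = max(2, k - 1),
                       seed = deriveSeed(tun$seed, 29, m, f))
      meta[te, m] <- predictProb(fit, X[te, , drop = FALSE])
    }
  }
  df <- data.frame(meta)
  names(df) <- paste0("m", seq_along(members))
  df$.y <- factor(y, levels = CLASS_LEVELS)
  metaFit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
  finalMembers <- lapply(seq_along(members), function(m)
    tuneModel(members[[m]], X, y, nIter = tun$nIter, folds = k,
              seed = deriveSeed(tun$seed, 31, m)))
  structure(list(members = finalMembers, metaFit = metaFit,
                 foldId = foldId, metaFeatures = meta),
            class = "stackedModel")
}

predictStacked <- function(model, newdata) {
  meta <- vapply(model$members, function(m) predictProb(m, newdata),
                 numeric(nrow(newdata)))
  if (!is.matrix(meta)) meta <- matrix(meta, nrow = 1)
  df <- data.frame(meta)
  names(df) <- paste0("m", seq_along(model$members))
  as.numeric(suppressWarnings(stats::predict(model$metaFit, newdata = df,
                                             type = "response")))
}

#' Fit an ensemble on training rows
#'
#' Tunes and fits every member, then combines per \code{config$mode}.
#'
#' @param X training matrix.
#' @param y training labels.
#' @param config an \code{\link{ensembleConfig}}.
#' @param seed integer seed (overrides \code{config$tuning$seed}).
#' @return An \code{"ensembleModel"}: fitted members, mode and weights.
#' @export
fitEnsemble <- function(X, y, config = ensembleConfig(), seed = NULL) {
  stopifnot(inherits(config, "EnsembleConfig"))
  tun <- config$tuning
  if (!is.null(seed)) tun$seed <- seed
  if (config$mode == "stack") {
    cfg <- config; cfg$tuning <- tun
    model <- fitStacking(config$members, X, y, cfg)
    return(structure(list(mode = "stack", model = model,
                          weights = config$weights),
                     class = "ensembleModel"))
  }
  fits <- lapply(seq_along(config$members), function(m)
    tuneModel(config$members[[m]], X, y, nIter = tun$nIter,
              folds = tun$folds, seed = deriveSeed(tun$seed, 37, m)))
  structure(list(mode = config$mode, model = fits,
                 weights = config$weights),
            class = "ensembleModel")
}

#' Ensemble probabilities and labels for new rows
#'
#' @param ens an \code{"ensembleModel"} from \code{\link{fitEnsemble}}.
#' @param newdata numeric matrix.
#' @return List with \code{prob} (positive-class probability) and
#'   \code{label}.
#' @export
predictEnsemble <- function(ens, newdata) {
  stopifnot(inherits(ens, "ensembleModel"))
  if (ens$mode == "stack") {
    p <- predictStacked(ens$model, newdata)
  } else {
    probs <- lapply(ens$model, predictProb, newdata = newdata)
    if (ens$mode == "vote_soft") {
      p <- softVote(probs, ens$weights)
    } else {
      labels <- lapply(probs, function(pr)
        ifelse(pr >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS))
      lab <- hardVote(labels, ens$weights, memberProbs = probs)
      # probabilities still reported (mean), labels from the hard vote
      p <- softVote(probs, ens$weights)
      return(list(prob = p, label = lab))
    }
  }
  list(prob = p, label = ifelse(p >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS))
}
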