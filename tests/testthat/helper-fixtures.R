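# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive brute-force implementations, independent of the package's code
# paths.

quickParams <- function(...) {
  args <- utils::modifyList(
    list(nControl = 3, nPatient = 3, duration = 16, nChannels = 3, seed = 7),
    list(...))
  do.call(synthParams, args)
}

quickEnsemble <- function(members = c("svm_rbf", "extra_trees"), seed = 1L,
                          mode = "vote_soft") {
  ensembleConfig(members = lapply(members, modelSpec), mode = mode,
                 tuning = list(nIter = 0, folds = 3, seed = seed))
}

# feature matrix with a planted class effect in the first nInf columns
plantedMatrix <- function(nPerClass = 30, p = 20, nInf = 5, effect = 1.5,
                          nSubjects = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  labs <- rep(c("control", "patient"), each = nPerClass)
  vals <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  vals[labs == "patient", seq_len(nInf)] <-
    vals[labs == "patient", seq_len(nInf)] + effect
  ids <- paste0(substr(labs, 1, 1),
                rep_len(seq_len(nSubjects), n))
  FeatureMatrix(vals, ids, labs)
}

# brute-force confusion-matrix metrics
oracleMetrics <- function(yTrue, yPred) {
  classes <- c("control", "patient")
  out <- list()
  for (cl in classes) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    out[[cl]] <- c(precision = prec, recall = rec,
                   f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec)
                        else 0,
                   support = tp + fn)
  }
  out$accuracy <- mean(yTrue == yPred)
  out
}

# brute-force precision/recall/F1 at one threshold
oracleThresholdPoint <- function(prob, yTrue, t) {
  pred <- ifelse(prob >= t, "patient", "control")
  m <- oracleMetrics(yTrue, pred)
  c(precision = unname(m$patient["precision"]),
    recall = unname(m$patient["recall"]),
    f1 = unname(m$patient["f1"]))
}

# step-by-step exhaustive MRMR (MID variant) using the package's MI
# estimator primitives re-implemented naively
oracleDiscretize <- function(x, nBins = 10) {
  br <- unique(quantile(x, seq(0, 1, length.out = nBins + 1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

oracleMI <- function(a, b) {
  tab <- table(a, b) / length(a)
  tot <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j]
    if (p > 0) tot <- tot + p * log2(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  tot
}

oracleMrmr <- function(vals, y, k, nBins = 10) {
  disc <- apply(vals, 2, oracleDiscretize, nBins = nBins)
  nm <- colnames(vals)
  rel <- sapply(nm, function(f) oracleMI(disc[, f], y))
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(nm, sel)
    crit <- sapply(cand, function(f) {
      if (!length(sel)) rel[[f]]
      else rel[[f]] - mean(sapply(sel, function(s)
        oracleMI(disc[, f], disc[, s])))
    })
    ord <- order(-crit, cand)
    sel <- c(sel, cand[ord[1]])
  }
  sel
}

# mean alpha (8-13 Hz) band power of a recording across channels
meanAlphaPower <- function(rec) {
  mean(apply(signalData(rec), 1, function(x)
    bandPower(welchPSD(x, samplingRate(rec)), 8, 13)))
}
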