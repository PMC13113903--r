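# Fold plans, the leakage-free protocol, metrics, bootstrap, threshold
# sweep and paired tests.

test_that("fold plans satisfy their defining invariants", {
  set.seed(1)
  ids <- rep(sprintf("s%02d", 1:28), each = 5)
  labs <- rep(rep(c("control", "patient"), each = 14), each = 5)
  plan <- makeFolds("loso", ids, labs)
  expect_length(folds(plan), 28)
  for (f in folds(plan)) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(unique(ids[f$test]), 1)           # one subject per fold
    expect_false(unique(ids[f$test]) %in% ids[f$train])
  }
  # every subject tested exactly once
  testSubs <- vapply(folds(plan), function(f) unique(ids[f$test]), "")
  expect_setequal(testSubs, unique(ids))
  # k-fold partitions the rows
  kf <- makeFolds("kfold_epoch", rep("s", 10), rep(c("control", "patient"),
                                                   5), k = 5, seed = 2)
  sizes <- vapply(folds(kf), function(f) length(f$test), 0L)
  expect_equal(sizes, rep(2L, 5))
  expect_setequal(unlist(lapply(folds(kf), `[[`, "test")), 1:10)
  # random split: stratified at the requested fraction
  rs <- makeFolds("random_split", ids, labs, testFrac = 0.5, seed = 3)
  f1 <- folds(rs)[[1]]
  expect_equal(length(f1$test), 70)
  expect_equal(sum(labs[f1$test] == "patient"), 35)
  expect_error(makeFolds("loso", rep("one", 5), rep("control", 5)),
               "2 subjects")
})

test_that("randomized fold plans keep train and test disjoint", {
  set.seed(9)
  for (i in 1:20) {
    nSub <- sample(4:10, 1)
    perSub <- sample(3:8, 1)
    ids <- rep(paste0("s", seq_len(nSub)), each = perSub)
    labs <- rep(rep_len(c("control", "patient"), nSub), each = perSub)
    scheme <- sample(c("loso", "kfold_epoch"), 1)
    plan <- makeFolds(scheme, ids, labs, k = 3, seed = i)
    for (f in folds(plan))
      expect_length(intersect(f$train, f$test), 0)
    if (scheme == "kfold_epoch")
      expect_setequal(unlist(lapply(folds(plan), `[[`, "test")),
                      seq_along(ids))
  }
})

test_that("classification metrics match a brute-force oracle", {
  set.seed(7)
  for (i in 1:1000) {
    n <- 30
    yTrue <- sample(c("control", "patient"), n, replace = TRUE)
    yPred <- sample(c("control", "patient"), n, replace = TRUE)
    if (length(unique(yTrue)) < 2) next
    m <- classificationMetrics(yTrue, yPred)
    o <- oracleMetrics(yTrue, yPred)
    expect_equal(m$accuracy, o$accuracy)
    for (cl in c("control", "patient")) {
      row <- m$perClass[m$perClass$class == cl, ]
      expect_equal(row$precision, unname(o[[cl]]["precision"]))
      expect_equal(row$recall, unname(o[[cl]]["recall"]))
      expect_equal(row$f1, unname(o[[cl]]["f1"]))
    }
  }
  # perfect predictions
  m <- classificationMetrics(rep(c("control", "patient"), 5),
                             rep(c("control", "patient"), 5),
                             prob = rep(c(0.1, 0.9), 5))
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$macro["f1"]), 1)
  expect_equal(m$auc, 1)
})

test_that("the rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- sample(c("control", "patient"), 100, replace = TRUE)
  p <- runif(100)
  ours <- classificationMetrics(y, ifelse(p >= 0.5, "patient", "control"),
                                prob = p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p, levels = c("control", "patient"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("subject aggregation means probabilities with ties positive", {
  agg <- aggregateSubjects(c(0.9, 0.8, 0.1), rep("s1", 3))
  expect_equal(agg$score, 0.6)
  expect_equal(agg$predicted, "patient")
  expect_equal(aggregateSubjects(rep(0.5, 4), rep("s1", 4))$predicted,
               "patient")                        # tie rule
  # 23 of 28 correct -> 82.14%
  ids <- sprintf("s%02d", 1:28)
  labs <- rep(c("control", "patient"), each = 14)
  prob <- ifelse(labs == "patient", 0.9, 0.1)
  prob[1:5] <- 0.9                               # five controls misread
  agg2 <- aggregateSubjects(rep(prob, each = 3), rep(ids, each = 3),
                            labels = rep(labs, each = 3))
  expect_equal(round(100 * mean(agg2$correct), 2), 82.14)
})

test_that("bootstrap CIs are percentile-exact, seeded and monotone", {
  expect_identical(bootstrapCI(rep(1, 10), B = 500, seed = 1)[c("lower",
                                                                "upper")],
                   list(lower = 100, upper = 100))
  ci <- bootstrapCI(c(1, 1, 0, 0), B = 2000, seed = 2)
  expect_true(ci$lower %in% (100 * 0:4 / 4))   # quantized to 100/n
  same <- bootstrapCI(c(rep(1, 20), rep(0, 8)), B = 1000, seed = 5)
  again <- bootstrapCI(c(rep(1, 20), rep(0, 8)), B = 1000, seed = 5)
  expect_identical(same, again)
  # n = 4: percentile bounds match the exact binomial resampling law
  big <- bootstrapCI(c(1, 1, 0, 0), B = 100000, seed = 3)
  expect_equal(big$lower, 100 * qbinom(0.025, 4, 0.5) / 4)
  expect_equal(big$upper, 100 * qbinom(0.975, 4, 0.5) / 4)
  # bounds never decrease as successes increase (n = 28)
  bounds <- t(vapply(0:28, function(k) {
    ci <- bootstrapCI(c(rep(1, k), rep(0, 28 - k)), B = 2000, seed = 11)
    c(ci$lower, ci$upper)
  }, numeric(2)))
  expect_true(all(diff(bounds[, 1]) >= 0))
  expect_true(all(diff(bounds[, 2]) >= 0))
  expect_error(bootstrapCI(c(1)), "at least 2")
})

test_that("threshold sweep equals the per-threshold oracle", {
  # perfectly separated scores: max F1 = 1 at the smallest gap threshold
  prob <- c(runif(50, 0, 0.3), runif(50, 0.7, 1))
  yTrue <- rep(c("control", "patient"), each = 50)
  sw <- thresholdSweep(prob, yTrue)
  expect_equal(sw$maxF1, 1)
  expect_lte(sw$optimalThreshold, 0.301)
  expect_error(thresholdSweep(runif(10), rep("patient", 10)), "both classes")
  # random scores against the brute-force confusion oracle
  set.seed(13)
  prob <- runif(200)
  yTrue <- sample(c("control", "patient"), 200, replace = TRUE)
  sw <- thresholdSweep(prob, yTrue, step = 0.01)
  for (i in seq(1, nrow(sw$curve), by = 7)) {
    pt <- oracleThresholdPoint(prob, yTrue, sw$curve$threshold[i])
    expect_equal(sw$curve$precision[i], unname(pt["precision"]))
    expect_equal(sw$curve$recall[i], unname(pt["recall"]))
    expect_equal(sw$curve$f1[i], unname(pt["f1"]))
  }
})

test_that("paired fold tests report W and BH-adjusted p-values", {
  a <- seq(0.75, 0.85, length.out = 28)
  b <- a - runif(28, 0.01, 0.05)
  res <- pairedFoldTest(list(ens_vs_rf = list(a = a, b = b)))
  expect_equal(res$W, 0)                     # every fold favours a
  expect_lt(res$p, 0.001)
  expect_warning(res2 <- pairedFoldTest(list(same = list(a = a, b = a))),
                 "zero")
  expect_equal(res2$p, 1)
  # family-wise BH adjustment equals the hand-computed step-up procedure
  set.seed(4)
  fam <- list(strong = list(a = a, b = a - runif(28, 0.01, 0.03)),
              weak = list(a = a, b = a - rnorm(28, 0.002, 0.02)),
              none = list(a = a, b = a + rnorm(28, 0, 0.02)))
  res3 <- pairedFoldTest(fam)
  handBH <- function(p) {     # step-up: cummin over descending rank order
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    pmin(1, cummin(p[o] * n / (n:1)))[order(o)]
  }
  expect_equal(res3$pBH, handBH(res3$p))
  expect_true(all(res3$pBH >= res3$p))
})

test_that("the protocol is leakage-audited, pooled once, deterministic", {
  fm <- plantedMatrix(nPerClass = 30, p = 10, nInf = 4, effect = 1.5,
                      nSubjects = 6, seed = 21)
  sel <- selectionConfig(k = 6)
  ens <- quickEnsemble("svm_rbf")
  plan <- makeFolds("loso", subjectIds(fm), classLabels(fm))
  rep1 <- runProtocol(fm, plan, sel, ens, seed = 2, bootstrapB = 200)
  # pooled LOSO predictions cover every epoch exactly once
  expect_setequal(rep1@pooled$epoch, seq_len(nrow(featureValues(fm))))
  expect_equal(nrow(rep1@pooled), nrow(featureValues(fm)))
  # audit: no test row was consumed by a fitting stage
  for (a in rep1@details$audit)
    expect_length(intersect(a$trainRows, a$testRows), 0)
  # determinism
  rep2 <- runProtocol(fm, plan, sel, ens, seed = 2, bootstrapB = 200)
  expect_equal(rep1@pooled, rep2@pooled)
  expect_equal(rep1@foldAccuracies, rep2@foldAccuracies)
  # malformed plan (train = test) is rejected at construction
  expect_error(new("FoldPlan", scheme = "loso",
                   folds = list(list(train = 1:10, test = 1:10)),
                   params = list(), seed = 1),
               "overlap")
  bad2 <- plan
  bad2@folds[[1]]$train <- seq_len(nrow(featureValues(fm)))
  expect_error(runProtocol(fm, bad2, sel, ens, seed = 2), "[Ll]eakage")
  # single-class training fold is a configuration error
  tiny <- plantedMatrix(nPerClass = 6, p = 4, nInf = 2, nSubjects = 2,
                        seed = 3)
  onecls <- new("FoldPlan", scheme = "loso",
                folds = list(list(train = which(classLabels(tiny) ==
                                                  "control"),
                                  test = which(classLabels(tiny) ==
                                                 "patient"))),
                params = list(), seed = 1)
  expect_error(runProtocol(tiny, onecls, sel, ens, seed = 1),
               "single class")
})
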