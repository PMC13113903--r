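# Time-domain, Hjorth and spectral features; Welch PSD; feature matrix
# assembly.

test_that("time features match hand computations and conventions", {
  f <- timeFeatures(rep(2, 100))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["rms"]), 2)
  expect_equal(unname(f["sad"]), 0)
  expect_equal(unname(f["hjorth_mobility"]), 0)   # constant convention
  expect_equal(unname(f["hjorth_complexity"]), 0)
  f2 <- timeFeatures(c(0, 1, 2, 3))
  expect_equal(unname(f2["sad"]), 3)
  expect_equal(unname(f2["ptp"]), 3)
  expect_equal(unname(f2["mean"]), 1.5)
  expect_error(timeFeatures(c(1, 2)), "3 samples")
})

test_that("a pure sinusoid has RMS 1/sqrt(2) and complexity 1", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq_len(6 * fs) / fs)
  f <- timeFeatures(x)
  expect_lt(abs(f[["rms"]] - 1 / sqrt(2)), 0.01 / sqrt(2))
  expect_lt(abs(f[["hjorth_complexity"]] - 1), 0.05)
})

test_that("Welch PSD peaks at the driving frequency and obeys Parseval", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq_len(10 * fs) / fs)
  psd <- welchPSD(x, fs, segLen = 250)
  expect_lte(abs(psd$freqs[which.max(psd$power)] - 10), fs / 250)
  set.seed(4)
  w <- rnorm(100 * fs)
  pw <- welchPSD(w, fs)
  expect_lt(abs(bandPower(pw, 0, fs / 2) - 1), 0.1)
  zero <- welchPSD(numeric(500), fs)
  expect_true(all(zero$power == 0))
  expect_error(welchPSD(rnorm(100), fs, segLen = 250), "exceeds")
})

test_that("band power concentrates correctly and tiles additively", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq_len(12 * fs) / fs)
  psd <- welchPSD(x, fs)
  tot <- bandPower(psd, 0, fs / 2)
  expect_gte(bandPower(psd, 8, 13) / tot, 0.9)    # alpha holds the sine
  expect_lte(bandPower(psd, 13, 30) / tot, 0.05)  # beta nearly empty
  expect_equal(bandPower(psd, 0.5, 8),
               bandPower(psd, 0.5, 4) + bandPower(psd, 4, 8))
  expect_error(bandPower(psd, 100, 200), "outside")
})

test_that("spectral entropy spans [0, 1] with closed-form special cases", {
  mkpsd <- function(power) structure(
    list(freqs = 0:64, power = power, fs = 128, nSegments = 1,
         segLen = 128), class = "PSDEstimate")
  nBins <- sum(0:64 >= 0.5 & 0:64 <= 50)   # analysis bins: 1..50 Hz
  single <- rep(0, 65); single[11] <- 5
  expect_equal(spectralFeatures(mkpsd(single))[["spectral_entropy"]], 0)
  expect_equal(spectralFeatures(mkpsd(rep(3, 65)))[["spectral_entropy"]], 1)
  two <- rep(0, 65); two[c(11, 21)] <- 2
  expect_equal(spectralFeatures(mkpsd(two))[["spectral_entropy"]],
               1 / log2(nBins))
})

test_that("features scale (or stay invariant) correctly under amplitude", {
  set.seed(6)
  fs <- 128
  for (rep in 1:5) {
    x <- rnorm(768) + 3 * sin(2 * pi * 9 * seq_len(768) / fs)
    c0 <- timeFeatures(x)
    c1 <- timeFeatures(2.5 * x)
    for (nm in c("rms", "std", "ptp"))
      expect_equal(c1[[nm]], 2.5 * c0[[nm]], tolerance = 1e-8)
    for (nm in c("hjorth_mobility", "hjorth_complexity", "skewness",
                 "kurtosis"))
      expect_equal(c1[[nm]], c0[[nm]], tolerance = 1e-8)
    s0 <- spectralFeatures(welchPSD(x, fs))
    s1 <- spectralFeatures(welchPSD(2.5 * x, fs))
    expect_equal(s1[["spectral_entropy"]], s0[["spectral_entropy"]],
                 tolerance = 1e-8)
  }
})

test_that("the feature matrix has 21 named columns per channel", {
  p <- quickParams(nControl = 1, nPatient = 0, duration = 13, nChannels = 3)
  ep <- segmentEpochs(genCohort(p)[[1]])
  fm <- buildFeatureMatrix(ep)
  expect_equal(ncol(featureValues(fm)), 3 * 21)
  expect_true(all(grepl("^[A-Za-z0-9]+__[a-z_]+$", featureNames(fm))))
  # 19- and 16-channel montages give the documented widths
  expect_equal(19 * 21, 399)
  expect_equal(16 * 21, 336)
  # column order is deterministic across rebuilds
  fm2 <- buildFeatureMatrix(ep)
  expect_identical(featureNames(fm), featureNames(fm2))
  expect_identical(featureValues(fm), featureValues(fm2))
})

test_that("feature extraction never produces non-finite values", {
  p <- quickParams(nControl = 1, nPatient = 1, duration = 13, nChannels = 3,
                   seed = 19)
  cohort <- genCohort(p)
  cohort[[1]] <- injectArtifacts(cohort[[1]], blinkRate = 30, emgRate = 10,
                                 seed = 1)
  ep <- segmentCohort(cohort)
  d <- epochData(ep)
  d[2, 1, ] <- 7          # plant a constant channel epoch
  ep <- eegclass:::EpochSet(d, samplingRate(ep), channelNames(ep),
                            subjectIds(ep), classLabels(ep), 6, 2)
  fm <- buildFeatureMatrix(ep)
  expect_true(all(is.finite(featureValues(fm))))
})

test_that("feature tables round-trip through the delimited format", {
  p <- quickParams(nControl = 1, nPatient = 1, duration = 13, nChannels = 2)
  fm <- buildFeatureMatrix(segmentCohort(genCohort(p)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureMatrix(fm, tf)
  back <- readFeatureMatrix(tf)
  expect_equal(featureNames(back), featureNames(fm))
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-9)
  expect_equal(subjectIds(back), subjectIds(fm))
  expect_equal(classLabels(back), classLabels(fm))
})
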