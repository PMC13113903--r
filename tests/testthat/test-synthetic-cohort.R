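# Synthetic cohort generator: determinism, planted spectral effects,
# subject random effects, artifact injection.

test_that("recordings have the requested shape and are seed-deterministic", {
  p <- synthParams(nControl = 1, nPatient = 0, fs = 128, duration = 60,
                   nChannels = 2, seed = 5)
  rec <- genRecording(p, "s1", "control", seed = 5)
  expect_equal(nSamples(rec), 7680)     # 60 s at 128 Hz
  expect_equal(nChannels(rec), 2)
  rec2 <- genRecording(p, "s1", "control", seed = 5)
  expect_identical(signalData(rec), signalData(rec2))
  rec3 <- genRecording(p, "s1", "control", seed = 6)
  expect_false(identical(signalData(rec), signalData(rec3)))
  expect_error(synthParams(duration = -1), "positive")
  expect_error(synthParams(fs = 0), "positive")
})

test_that("cohorts have requested sizes, unique ids and per-subject gains", {
  p <- synthParams(nControl = 14, nPatient = 14, duration = 2,
                   nChannels = 2, seed = 1)
  cohort <- genCohort(p)
  expect_length(cohort, 28)
  labs <- vapply(cohort, classLabel, "")
  expect_equal(sum(labs == "control"), 14)
  expect_equal(sum(labs == "patient"), 14)
  ids <- vapply(cohort, subjectId, "")
  expect_false(anyDuplicated(ids) > 0)
  # identical params => bit-identical cohort
  cohort2 <- genCohort(p)
  expect_identical(lapply(cohort, signalData), lapply(cohort2, signalData))
  # single-subject cohort
  p1 <- synthParams(nControl = 0, nPatient = 1, duration = 2, nChannels = 2)
  expect_length(genCohort(p1), 1)
})

test_that("zero alpha amplitude leaves alpha power at the noise baseline", {
  base <- synthParams(nControl = 1, nPatient = 0, duration = 30,
                      nChannels = 2, seed = 21,
                      bandAmplitudes = c(delta = 0, theta = 0, alpha = 0,
                                         beta = 0),
                      subjectEffectSd = 0)
  noAlpha <- synthParams(nControl = 1, nPatient = 0, duration = 30,
                         nChannels = 2, seed = 21,
                         bandAmplitudes = c(delta = 20, theta = 10,
                                            alpha = 0, beta = 5),
                         subjectEffectSd = 0)
  # 4 s Welch segments: sub-Hz resolution, so the theta band's 8 Hz edge
  # is resolved instead of smeared into the alpha range
  alphaFine <- function(rec) mean(apply(signalData(rec), 1, function(x)
    bandPower(welchPSD(x, samplingRate(rec),
                       segLen = 4 * samplingRate(rec)), 8, 13)))
  aNoise <- alphaFine(genCohort(base)[[1]])
  aNoAlpha <- alphaFine(genCohort(noAlpha)[[1]])
  expect_lt(abs(aNoAlpha / aNoise - 1), 0.2)
})

test_that("planted alpha reduction is recovered in sign and magnitude", {
  m <- 0.6
  p <- synthParams(nControl = 20, nPatient = 20, duration = 20,
                   nChannels = 4, seed = 42,
                   patientMultipliers = c(delta = 1, theta = 1.4,
                                          alpha = m, beta = 1))
  cohort <- genCohort(p)
  labs <- vapply(cohort, classLabel, "")
  lp <- log(vapply(cohort, meanAlphaPower, 0))
  diff <- mean(lp[labs == "patient"]) - mean(lp[labs == "control"])
  se <- sqrt(var(lp[labs == "patient"]) / 20 + var(lp[labs == "control"]) / 20)
  expect_lt(diff, 0)                       # planted direction
  expect_lt(abs(diff - log(m^2)), 2 * se)  # approximate magnitude
})

test_that("between-subject variance grows with subjectEffectSd", {
  bv <- vapply(c(0, 0.25, 0.5), function(s) {
    p <- synthParams(nControl = 10, nPatient = 0, duration = 15,
                     nChannels = 2, subjectEffectSd = s, seed = 7)
    m <- vapply(genCohort(p), function(r) mean(signalData(r)^2), 0)
    var(log(m))
  }, 0)
  expect_true(all(diff(bv) > 0))
})

test_that("artifact injection is additive, seeded and rate-faithful", {
  p <- synthParams(nControl = 1, nPatient = 0, duration = 60,
                   nChannels = 2, seed = 3)
  clean <- genCohort(p)[[1]]
  # zero rates: identity
  expect_identical(signalData(injectArtifacts(clean, 0, 0, seed = 1)),
                   signalData(clean))
  # input unchanged by injection
  before <- signalData(clean)
  cont <- injectArtifacts(clean, blinkRate = 6, emgRate = 2, seed = 2)
  expect_identical(signalData(clean), before)
  expect_gt(mean((signalData(cont) - before)^2), 0)
  # blink count over 50 seeds: total events within the Poisson 99.8% band
  # (events counted as contiguous super-50-uV runs of the added frontal
  # signal; blinks at 6/min are far sparser than the template width)
  counts <- vapply(1:50, function(s) {
    added <- signalData(injectArtifacts(clean, 6, 0, seed = s))[1, ] -
      before[1, ]
    r <- rle(added > 50)
    sum(r$values)
  }, 0L)
  lam <- 50 * 6                      # 50 seeds x 6 events over 60 s
  expect_gte(sum(counts), qpois(0.001, lam))
  expect_lte(sum(counts), qpois(0.999, lam))
})

test_that("blink energy concentrates below 5 Hz", {
  p <- synthParams(nControl = 1, nPatient = 0, duration = 30,
                   nChannels = 4, seed = 5)
  clean <- genCohort(p)[[1]]
  cont <- injectArtifacts(clean, blinkRate = 10, emgRate = 0, seed = 6)
  added <- signalData(cont)[1, ] - signalData(clean)[1, ]
  psd <- welchPSD(added, samplingRate(clean))
  expect_gte(bandPower(psd, 0, 5) / bandPower(psd, 0, 64), 0.8)
})
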