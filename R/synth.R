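# Synthetic two-class EEG cohort generator.
#
# Each channel is a sum of narrowband oscillations (band-limited Gaussian
# noise, not pure sines, so spectra look realistic) over 1/f^k background
# noise. The patient class scales band amplitudes by per-band multipliers
# (reduced alpha, elevated theta by default); a log-normal per-subject gain
# shared across bands and channels creates the within-subject epoch
# correlation that makes epoch-level k-fold validation leak.

DEFAULT_CHANNELS_19 <- c("Fp2", "F8", "T4", "T6", "O2", "Fp1", "F7", "T3",
                         "T5", "O1", "F4", "C4", "P4", "F3", "C3", "P3",
                         "Fz", "Cz", "Pz")
DEFAULT_CHANNELS_16 <- c("F7", "F3", "F4", "F8", "T3", "C3", "Cz", "C4",
                         "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Parameters of the synthetic EEG cohort generator
#'
#' Defines a two-class cohort of multichannel resting-state EEG recordings:
#' band-limited oscillations over 1/f^k noise, class-dependent band-power
#' effects, a shared log-normal per-subject gain, and optional ocular/muscle
#' artifact injection.
#'
#' @param nControl,nPatient subjects per class.
#' @param fs sampling rate, Hz.
#' @param duration recording length per subject, seconds.
#' @param nChannels number of channels.
#' @param channelNames channel labels (10-20 montage names by default; blink
#'   artifacts target channels whose name starts with "Fp" or "F").
#' @param bandAmplitudes named numeric, RMS amplitude in microvolts of the
#'   delta, theta, alpha and beta oscillations for the control class.
#' @param patientMultipliers named numeric, dimensionless per-band amplitude
#'   multipliers applied in the patient class (default: reduced alpha 0.6,
#'   elevated theta 1.4).
#' @param subjectEffectSd log-scale SD of the per-subject gain (0 disables
#'   subject random effects).
#' @param noiseExponent k of the 1/f^k background noise.
#' @param noiseAmplitude RMS of the background noise, microvolts.
#' @param blinkRate,emgRate artifact event rates, events per minute
#'   (applied only by \code{\link{injectArtifacts}} / \code{\link{cmdSimulate}}).
#' @param seed base random seed of the cohort.
#' @return A validated list of class \code{"SynthParams"}.
#' @examples
#' p <- synthParams(nControl = 2, nPatient = 2, duration = 10)
#' cohort <- genCohort(p)
#' length(cohort)
#' @export
synthParams <- function(nControl = 14, nPatient = 14, fs = 128,
                        duration = 60, nChannels = 16,
                        channelNames = NULL,
                        bandAmplitudes = c(delta = 20, theta = 10,
                                           alpha = 20, beta = 5),
                        patientMultipliers = c(delta = 1, theta = 1.4,
                                               alpha = 0.6, beta = 1),
                        subjectEffectSd = 0.2,
                        noiseExponent = 1, noiseAmplitude = 10,
                        blinkRate = 0, emgRate = 0, seed = 1L) {
  if (is.null(channelNames)) {
    channelNames <- if (nChannels == 19) DEFAULT_CHANNELS_19
      else if (nChannels <= 16) DEFAULT_CHANNELS_16[seq_len(nChannels)]
      else paste0("ch", seq_len(nChannels))
  }
  stopIf(length(channelNames) != nChannels,
         "channelNames must have length nChannels")
  stopIf(!is.numeric(fs) || fs <= 0, "fs must be positive")
  stopIf(!is.numeric(duration) || duration <= 0, "duration must be positive")
  stopIf(any(bandAmplitudes < 0), "band amplitudes must be >= 0")
  stopIf(any(patientMultipliers < 0), "patient multipliers must be >= 0")
  stopIf(blinkRate < 0 || emgRate < 0, "artifact rates must be >= 0")
  stopIf(subjectEffectSd < 0, "subjectEffectSd must be >= 0")
  bands <- c("delta", "theta", "alpha", "beta")
  stopIf(!all(bands %in% names(bandAmplitudes)),
         "bandAmplitudes must name delta, theta, alpha, beta")
  stopIf(!all(bands %in% names(patientMultipliers)),
         "patientMultipliers must name delta, theta, alpha, beta")
  structure(list(nControl = nControl, nPatient = nPatient, fs = fs,
                 duration = duration, nChannels = nChannels,
                 channelNames = channelNames,
                 bandAmplitudes = bandAmplitudes[bands],
                 patientMultipliers = patientMultipliers[bands],
                 subjectEffectSd = subjectEffectSd,
                 noiseExponent = noiseExponent,
                 noiseAmplitude = noiseAmplitude,
                 blinkRate = blinkRate, emgRate = emgRate,
                 seed = as.integer(seed)),
            class = "SynthParams")
}

# 1/f^k noise of length n with RMS `amp`, via spectral shaping of white noise
pinkNoise <- function(n, k, amp) {
  if (amp <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # avoid the DC singularity
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  shape <- f^(-k / 2)
  shape[1] <- 0                        # zero-mean
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * amp
}

# band-limited Gaussian oscillation with RMS `amp`; the filter is applied
# twice so out-of-band leakage into neighbouring measurement bands is
# negligible
bandNoise <- function(n, fs, lo, hi, amp) {
  if (amp <= 0) return(numeric(n))
  hi <- min(hi, fs / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, signal::filtfilt(bf, stats::rnorm(n)))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * amp
}

#' Generate one synthetic EEG recording
#'
#' Per channel: sum over bands of amplitude x class multiplier x subject gain
#' x narrowband Gaussian oscillation (random phase), plus 1/f^k noise.
#' Deterministic for a fixed seed.
#'
#' @param params a \code{\link{synthParams}} object.
#' @param subjectId subject identifier.
#' @param label \code{"control"} or \code{"patient"}.
#' @param seed integer seed for this recording.
#' @param subjectGain optional fixed per-subject gain; drawn log-normally
#'   from the seed when missing.
#' @return An \linkS4class{EEGRecording}.
#' @export
genRecording <- function(params, subjectId, label = c("control", "patient"),
                         seed = params$seed, subjectGain = NULL) {
  stopifnot(inherits(params, "SynthParams"))
  label <- match.arg(label)
  stopIf(params$duration <= 0 || params$fs <= 0,
         "duration and fs must be positive")
  n <- round(params$duration * params$fs)
  bands <- defaultBands()
  mult <- if (label == "patient") params$patientMultipliers
          else stats::setNames(rep(1, 4), names(params$patientMultipliers))
  withSeed(seed, {
    gain <- if (is.null(subjectGain)) {
      if (params$subjectEffectSd > 0)
        exp(stats::rnorm(1, 0, params$subjectEffectSd)) else 1
    } else subjectGain
    data <- matrix(0, params$nChannels, n)
    for (ch in seq_len(params$nChannels)) {
      x <- pinkNoise(n, params$noiseExponent, params$noiseAmplitude)
      for (b in names(params$bandAmplitudes)) {
        amp <- params$bandAmplitudes[[b]] * mult[[b]] * gain
        bd <- bands[[b]]
        x <- x + bandNoise(n, params$fs, bd$lo, bd$hi, amp)
      }
      data[ch, ] <- x
    }
    EEGRecording(data, params$fs, params$channelNames, subjectId, label)
  })
}

#' Generate a two-class synthetic cohort
#'
#' Draws one log-normal gain per subject (shared across bands and channels)
#' and one recording per subject. Subject ids are \code{ctrl01..} and
#' \code{pat01..}; deterministic for a fixed \code{params$seed}.
#'
#' @param params a \code{\link{synthParams}} object.
#' @return A list of \linkS4class{EEGRecording} objects,
#'   controls first, then patients.
#' @export
genCohort <- function(params) {
  stopifnot(inherits(params, "SynthParams"))
  nTot <- params$nControl + params$nPatient
  stopIf(nTot < 1, "cohort must contain at least one subject")
  labels <- c(rep("control", params$nControl), rep("patient", params$nPatient))
  ids <- c(sprintf("ctrl%02d", seq_len(params$nControl)),
           sprintf("pat%02d", seq_len(params$nPatient)))
  gains <- withSeed(deriveSeed(params$seed, 777), {
    if (params$subjectEffectSd > 0)
      exp(stats::rnorm(nTot, 0, params$subjectEffectSd)) else rep(1, nTot)
  })
  lapply(seq_len(nTot), function(i)
    genRecording(params, ids[i], labels[i],
                 seed = deriveSeed(params$seed, i),
                 subjectGain = gains[i]))
}

# smooth blink template: Gaussian bump, width sigma seconds
blinkTemplate <- function(fs, amp = 100, sigma = 0.08, halfWidth = 0.5) {
  t <- seq(-halfWidth, halfWidth, by = 1 / fs)
  amp * exp(-t^2 / (2 * sigma^2))
}

#' Inject ocular and muscle artifacts into a recording
#'
#' Blinks are smooth high-amplitude (~100 microvolt) low-frequency transients
#' (energy concentrated below 5 Hz) applied at full amplitude to frontal
#' channels (names starting with "Fp" or "F") and attenuated elsewhere.
#' EMG events are short broadband bursts above 20 Hz on a random channel.
#' Event times are Poisson with the given rates. The input recording is
#' not modified.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param blinkRate,emgRate events per minute (>= 0).
#' @param seed integer seed.
#' @return A new \linkS4class{EEGRecording} with artifacts added.
#' @export
injectArtifacts <- function(rec, blinkRate = 6, emgRate = 2, seed = 1L) {
  stopifnot(is(rec, "EEGRecording"))
  stopIf(blinkRate < 0 || emgRate < 0, "artifact rates must be >= 0")
  if (blinkRate == 0 && emgRate == 0) return(rec)
  fs <- samplingRate(rec)
  n <- nSamples(rec)
  durMin <- n / fs / 60
  data <- signalData(rec)
  frontal <- grepl("^F", channelNames(rec)) # Fp* and F* channels
  if (!any(frontal)) frontal[1] <- TRUE     # fall back to the first channel
  withSeed(seed, {
    nBlink <- stats::rpois(1, blinkRate * durMin)
    if (nBlink > 0) {
      tpl <- blinkTemplate(fs)
      half <- (length(tpl) - 1L) %/% 2L
      centers <- sort(ceiling(stats::runif(nBlink, half + 1, n - half)))
      chScale <- ifelse(frontal, 1, 0.2)
      for (cen in centers) {
        idx <- (cen - half):(cen + half)
        keep <- idx >= 1 & idx <= n
        for (ch in seq_len(nrow(data)))
          data[ch, idx[keep]] <- data[ch, idx[keep]] +
            chScale[ch] * tpl[keep] * stats::runif(1, 0.8, 1.2)
      }
    }
    nEmg <- stats::rpois(1, emgRate * durMin)
    if (nEmg > 0) {
      hi <- signal::butter(4, min(20 / (fs / 2), 0.95), type = "high")
      for (j in seq_len(nEmg)) {
        len <- round(stats::runif(1, 0.2, 0.5) * fs)
        start <- ceiling(stats::runif(1, 1, max(1, n - len)))
        ch <- sample.int(nrow(data), 1)
        burst <- signal::filtfilt(hi, stats::rnorm(len + 2 * round(fs / 4)))
        burst <- burst[round(fs / 4) + seq_len(len)]
        win <- sin(pi * seq(0, 1, length.out = len))^2
        data[ch, start:(start + len - 1)] <-
          data[ch, start:(start + len - 1)] + 30 * win * burst / stats::sd(burst)
      }
    }
    EEGRecording(data, fs, channelNames(rec), subjectId(rec), classLabel(rec))
  })
}
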