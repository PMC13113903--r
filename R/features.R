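# Per-channel feature extraction: time-domain statistics and Hjorth
# parameters, Welch PSD, canonical band powers, spectral entropy and PSD
# moments. 13 time + 8 spectral = 21 features per channel.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz. The delta lower edge
#' is set at the usual high-pass corner; all edges are configurable by
#' passing a modified list wherever bands are accepted.
#'
#' @return Named list of \code{list(lo=, hi=)} band edges in Hz.
#' @export
defaultBands <- function() {
  list(delta = list(lo = 0.5, hi = 4), theta = list(lo = 4, hi = 8),
       alpha = list(lo = 8, hi = 13), beta = list(lo = 13, hi = 30))
}

TIME_FEATURES <- c("mean", "variance", "std", "ptp", "min", "max", "rms",
                   "sad", "skewness", "kurtosis", "hjorth_activity",
                   "hjorth_mobility", "hjorth_complexity")
SPECTRAL_FEATURES <- c("band_delta", "band_theta", "band_alpha", "band_beta",
                       "spectral_entropy", "psd_mean", "psd_skewness",
                       "psd_kurtosis")

# Fisher-Pearson standardized third moment / excess kurtosis; 0 on a
# constant vector so no NaN ever enters a feature matrix
sampleSkewness <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  n <- length(x)
  mean((x - mean(x))^3) / (sum((x - mean(x))^2) / n)^1.5
}

sampleKurtosis <- function(x) {
  v <- mean((x - mean(x))^2)
  if (!is.finite(v) || v == 0) return(0)
  mean((x - mean(x))^4) / v^2 - 3
}

#' Time-domain features of one channel epoch
#'
#' Statistical descriptors plus the Hjorth parameters. Activity is the
#' signal variance; mobility is \code{sqrt(var(diff(x)) / var(x))}
#' (an estimate of mean frequency, in cycles per sample scale); complexity
#' is \code{mobility(diff(x)) / mobility(x)} and equals 1 for a pure
#' sinusoid. A constant signal yields mobility = complexity = 0 by
#' convention, so downstream selection never sees missing values.
#'
#' @param x numeric vector, one channel of one epoch (length >= 3).
#' @return Named numeric vector of 13 features: mean, variance, std, ptp,
#'   min, max, rms, sad, skewness, kurtosis, hjorth_activity,
#'   hjorth_mobility, hjorth_complexity.
#' @examples
#' timeFeatures(sin(2 * pi * 10 * seq(0, 6, by = 1 / 250)))["rms"]
#' @export
timeFeatures <- function(x) {
  stopIf(length(x) < 3, "need at least 3 samples")
  v <- stats::var(x)
  dx <- diff(x)
  vd <- stats::var(dx)
  mob <- if (v > 0) sqrt(vd / v) else 0
  comp <- 0
  if (mob > 0 && vd > 0) {
    vdd <- stats::var(diff(dx))
    mobD <- sqrt(vdd / vd)
    comp <- mobD / mob
  }
  c(mean = mean(x), variance = v, std = sqrt(v),
    ptp = max(x) - min(x), min = min(x), max = max(x),
    rms = sqrt(mean(x^2)), sad = sum(abs(dx)),
    skewness = sampleSkewness(x), kurtosis = sampleKurtosis(x),
    hjorth_activity = v, hjorth_mobility = mob, hjorth_complexity = comp)
}

#' Welch power spectral density
#'
#' Averaged windowed periodograms over overlapping segments, one-sided
#' density scaling (power integrates to the signal variance). Each segment
#' is mean-detrended and windowed before the FFT.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param segLen segment length in samples (default \code{fs}, i.e. 1 s /
#'   1 Hz resolution, giving >= 5 averaged segments per 6 s epoch).
#' @param overlapFrac fractional segment overlap in [0, 1) (default 0.5).
#' @param window \code{"hann"} or \code{"rect"}.
#' @return List of class \code{"PSDEstimate"}: \code{freqs} (Hz, 0..fs/2),
#'   \code{power} (uV^2/Hz), \code{fs}, \code{nSegments}, \code{segLen}.
#' @export
welchPSD <- function(x, fs, segLen = round(fs), overlapFrac = 0.5,
                     window = c("hann", "rect")) {
  window <- match.arg(window)
  segLen <- as.integer(segLen)
  stopIf(segLen > length(x), "segment length exceeds signal length")
  stopIf(overlapFrac < 0 || overlapFrac >= 1, "overlapFrac must be in [0,1)")
  hop <- max(1L, as.integer(round(segLen * (1 - overlapFrac))))
  starts <- seq(1L, length(x) - segLen + 1L, by = hop)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, segLen - 1) / (segLen - 1))
  else rep(1, segLen)
  u <- sum(w^2)
  nf <- segLen %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLen - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided: double all bins except DC (and Nyquist when segLen even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (segLen %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  structure(list(freqs = seq(0, nf - 1) * fs / segLen,
                 power = acc / length(starts), fs = fs,
                 nSegments = length(starts), segLen = segLen),
            class = "PSDEstimate")
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the PSD over [lo, hi).
#'
#' @param psd a \code{\link{welchPSD}} result.
#' @param lo,hi band edges, Hz (must lie within the PSD grid).
#' @return Band power in uV^2.
#' @export
bandPower <- function(psd, lo, hi) {
  stopIf(lo < 0 || hi > max(psd$freqs) + 1e-9 || lo >= hi,
         "band [%g, %g) outside the PSD grid", lo, hi)
  f <- psd$freqs
  p <- psd$power
  # interpolate the edges onto the grid so adjacent bands tile exactly
  grid <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  pg <- stats::approx(f, p, xout = grid)$y
  sum(diff(grid) * (utils::head(pg, -1) + utils::tail(pg, -1)) / 2)
}

#' Spectral features from a PSD
#'
#' Band powers for delta/theta/alpha/beta, spectral entropy (Shannon
#' entropy, base-2, of the PSD normalized to sum 1 over the analysis range,
#' divided by log2 of the number of bins, so 0 = a single spectral line and
#' 1 = a flat spectrum), and mean/skewness/kurtosis of the PSD values over
#' the analysis range.
#'
#' @param psd a \code{\link{welchPSD}} result.
#' @param bands band definition list (see \code{\link{defaultBands}}).
#' @param range analysis range in Hz for entropy and PSD moments
#'   (default c(0.5, 50), clipped to the grid).
#' @return Named numeric vector of 8 features.
#' @export
spectralFeatures <- function(psd, bands = defaultBands(),
                             range = c(0.5, 50)) {
  hi <- min(range[2], max(psd$freqs))
  sel <- psd$freqs >= range[1] & psd$freqs <= hi
  p <- psd$power[sel]
  bp <- vapply(bands, function(b)
    bandPower(psd, b$lo, min(b$hi, max(psd$freqs))), 0)
  names(bp) <- paste0("band_", names(bands))
  tot <- sum(p)
  ent <- 0
  if (tot > 0 && length(p) > 1) {
    q <- p / tot
    q <- q[q > 0]
    ent <- -sum(q * log2(q)) / log2(length(p))
  }
  c(bp, spectral_entropy = ent, psd_mean = mean(p),
    psd_skewness = sampleSkewness(p), psd_kurtosis = sampleKurtosis(p))
}

#' Build the named feature matrix of an epoch set
#'
#' For every epoch x channel, concatenates 13 time-domain and 8
#' frequency-domain features; columns are named \code{CHANNEL__FEATURE}
#' in deterministic order (channels in recording order, features in the
#' documented order).
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param bands band definitions (see \code{\link{defaultBands}}).
#' @param segLen,overlapFrac Welch parameters (defaults: 1 s segments,
#'   50\% overlap).
#' @return A \linkS4class{FeatureMatrix} with
#'   \code{21 * nChannels} columns.
#' @examples
#' p <- synthParams(nControl = 1, nPatient = 1, duration = 15, nChannels = 4)
#' ep <- segmentCohort(genCohort(p))
#' fm <- buildFeatureMatrix(ep)
#' dim(featureValues(fm))
#' @export
buildFeatureMatrix <- function(ep, bands = defaultBands(),
                               segLen = round(samplingRate(ep)),
                               overlapFrac = 0.5) {
  stopifnot(is(ep, "EpochSet"))
  d <- dim(epochData(ep))
  stopIf(d[1] == 0, "empty EpochSet")
  chn <- channelNames(ep)
  featNames <- as.vector(vapply(chn, function(ch)
    paste0(ch, "__", c(TIME_FEATURES, SPECTRAL_FEATURES)),
    character(21)))
  out <- matrix(0, d[1], length(featNames),
                dimnames = list(NULL, featNames))
  data <- epochData(ep)
  for (i in seq_len(d[1])) {
    row <- numeric(0)
    for (ch in seq_len(d[2])) {
      x <- data[i, ch, ]
      tf <- tryCatch(timeFeatures(x), error = function(e)
        stop(sprintf("epoch %d, channel %s: %s", i, chn[ch],
                     conditionMessage(e)), call. = FALSE))
      psd <- welchPSD(x, samplingRate(ep), segLen = segLen,
                      overlapFrac = overlapFrac)
      sf <- spectralFeatures(psd, bands)
      row <- c(row, tf, sf)
    }
    out[i, ] <- row
  }
  FeatureMatrix(out, subjectIds(ep), classLabels(ep))
}

#' Write / read a feature matrix as a delimited table
#'
#' Tab-separated with a header of feature names plus \code{subject_id} and
#' \code{label} columns; reads back losslessly.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path file path.
#' @export
writeFeatureMatrix <- function(fm, path) {
  df <- data.frame(subject_id = subjectIds(fm), label = classLabels(fm),
                   featureValues(fm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  stopIf(!file.exists(path), "feature table not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  stopIf(!all(c("subject_id", "label") %in% names(df)),
         "feature table must have subject_id and label columns")
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                       drop = FALSE])
  FeatureMatrix(vals, df$subject_id, df$label)
}
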