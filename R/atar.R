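# Tunable wavelet-packet artifact suppression (ATAR).
#
# Each channel is processed in windows: full wavelet-packet decomposition
# (periodized Daubechies filters), a robust data-driven magnitude threshold
# scaled by the aggressiveness parameter beta, attenuation of
# super-threshold coefficients, reconstruction. Smaller beta gives a lower
# threshold and hence more aggressive suppression.

# db4 (8-tap Daubechies) decomposition low-pass filter
DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.187034811718881140,
                -0.027983769416983850, 0.630880767929590400,
                0.714846570552541500, 0.230377813308855230)

waveletFilters <- function(wavelet = "db4") {
  h <- switch(wavelet,
    db4 = DB4_DEC_LO,
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    haar = c(sqrt(0.5), sqrt(0.5)),
    stop(sprintf("unknown wavelet '%s'", wavelet), call. = FALSE))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(lo = h, hi = g)
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwtStep <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(flt$lo)
  a <- numeric(half); d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(L)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + flt$lo[k] * x[idx]
    d <- d + flt$hi[k] * x[idx]
  }
  list(a = a, d = d)
}

# Full wavelet-packet decomposition to `level`; returns a list of 2^level
# terminal coefficient vectors. Length of x must be divisible by 2^level.
wpdDecompose <- function(x, level, flt) {
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- dwtStep(nodes[[i]], flt)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    nodes <- nxt
  }
  nodes
}

wpdReconstruct <- function(nodes, flt) {
  while (length(nodes) > 1L) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(nxt))
      nxt[[i]] <- idwtStepExact(nodes[[2L * i - 1L]], nodes[[2L * i]], flt)
    nodes <- nxt
  }
  nodes[[1]]
}

# transpose of dwtStep, written out explicitly
idwtStepExact <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  L <- length(flt$lo)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(L)) {
    idx <- (base + (k - 1L)) %% n + 1L
    # base offsets are distinct modulo n for a fixed k, so plain indexed
    # addition accumulates correctly
    x[idx] <- x[idx] + flt$lo[k] * a + flt$hi[k] * d
  }
  x
}

#' ATAR parameters
#'
#' @param beta aggressiveness (> 0, default 0.1). The coefficient threshold
#'   scales linearly with beta, so smaller beta suppresses more.
#' @param wavelet discrete wavelet name: \code{"db4"} (default), \code{"db2"}
#'   or \code{"haar"}.
#' @param level wavelet-packet decomposition depth (default 5; reduced
#'   automatically, with a warning, when a window is too short).
#' @param mode attenuation of super-threshold coefficients:
#'   \code{"elastic"} (smooth tanh compression toward the threshold,
#'   default), \code{"soft"} (magnitude clipping at the threshold) or
#'   \code{"linear-attenuate"} (linear ramp to zero at twice the threshold).
#' @param windowLen processing window in seconds (default 6, the epoch
#'   length).
#' @param k1,k2 threshold constants, microvolts: the per-window threshold is
#'   \code{beta * (k1 + k2 * sigma)} with \code{sigma} the
#'   interquartile-range-based robust scale of the coefficient magnitudes.
#' @return A validated list of class \code{"AtarParams"}.
#' @export
atarParams <- function(beta = 0.1, wavelet = "db4", level = 5,
                       mode = c("elastic", "soft", "linear-attenuate"),
                       windowLen = 6, k1 = 1200, k2 = 10) {
  mode <- match.arg(mode)
  stopIf(beta <= 0, "beta must be > 0")
  stopIf(level < 1, "level must be >= 1")
  waveletFilters(wavelet)   # validates the name
  structure(list(beta = beta, wavelet = wavelet, level = as.integer(level),
                 mode = mode, windowLen = windowLen, k1 = k1, k2 = k2),
            class = "AtarParams")
}

attenuateCoefs <- function(w, theta, mode) {
  aw <- abs(w)
  over <- aw > theta
  if (mode == "elastic") {
    # smooth compression: identity well below theta, saturates at theta
    sign(w) * theta * tanh(aw / theta)
  } else if (mode == "soft") {
    w[over] <- sign(w[over]) * theta
    w
  } else { # linear-attenuate
    fac <- pmax(0, 1 - (aw - theta) / theta)
    w[over] <- w[over] * fac[over]
    w
  }
}

# clean one 1-d window
atarWindow <- function(x, params) {
  n <- length(x)
  level <- params$level
  while (2^level > n) level <- level - 1L
  if (level < params$level)
    warning(sprintf("window of %d samples too short for level %d; using %d",
                    n, params$level, level))
  if (level < 1L) return(x)
  flt <- waveletFilters(params$wavelet)
  block <- 2L^level
  # pad by reflection to a multiple of 2^level, transform, crop after
  pad <- (block - n %% block) %% block
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  nodes <- wpdDecompose(xp, level, flt)
  w <- unlist(nodes)
  sigma <- stats::IQR(abs(w)) / 1.349
  theta <- params$beta * (params$k1 + params$k2 * sigma)
  if (theta <= 0) return(x)
  at <- 0L
  for (i in seq_along(nodes)) {
    k <- length(nodes[[i]])
    nodes[[i]] <- attenuateCoefs(w[at + seq_len(k)], theta, params$mode)
    at <- at + k
  }
  wpdReconstruct(nodes, flt)[seq_len(n)]
}

atarMatrix <- function(data, fs, params) {
  n <- ncol(data)
  wlen <- max(2L^params$level, round(params$windowLen * fs))
  starts <- seq(1L, n, by = wlen)
  out <- data
  for (ch in seq_len(nrow(data))) {
    for (s in starts) {
      e <- min(s + wlen - 1L, n)
      if (e - s + 1L >= 2L) out[ch, s:e] <- atarWindow(data[ch, s:e], params)
    }
  }
  out
}

#' Tunable wavelet-packet artifact removal
#'
#' Suppresses high-magnitude wavelet-packet coefficients (ocular and muscle
#' transients) while preserving sub-threshold oscillatory content. Applied
#' per channel, in windows of \code{windowLen} seconds. Methods exist for
#' continuous \linkS4class{EEGRecording}s (the default place to clean,
#' before segmentation) and for \linkS4class{EpochSet}s.
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{EpochSet}.
#' @param params an \code{\link{atarParams}} object.
#' @return An object of the same class with artifacts suppressed.
#' @examples
#' p <- synthParams(nControl = 1, nPatient = 0, duration = 12)
#' rec <- injectArtifacts(genCohort(p)[[1]], blinkRate = 10, emgRate = 0,
#'                        seed = 7)
#' cleaned <- atarClean(rec, atarParams(beta = 0.1))
#' @export
setGeneric("atarClean", function(x, params = atarParams())
  standardGeneric("atarClean"))

#' @rdname atarClean
#' @export
setMethod("atarClean", "EEGRecording", function(x, params = atarParams()) {
  stopifnot(inherits(params, "AtarParams"))
  EEGRecording(atarMatrix(signalData(x), samplingRate(x), params),
               samplingRate(x), channelNames(x), subjectId(x), classLabel(x))
})

#' @rdname atarClean
#' @export
setMethod("atarClean", "EpochSet", function(x, params = atarParams()) {
  stopifnot(inherits(params, "AtarParams"))
  data <- epochData(x)
  d <- dim(data)
  ep <- params
  ep$windowLen <- x@epochLen   # one window per epoch
  for (i in seq_len(d[1]))
    data[i, , ] <- atarMatrix(matrix(data[i, , ], d[2], d[3]), x@fs, ep)
  EpochSet(data, x@fs, x@channelNames, x@subjectIds, x@labels,
           x@epochLen, x@overlap)
})
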