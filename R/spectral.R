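#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (designed with
#' `signal::butter`) forward and backward (`signal::filtfilt`), so
#' filtering is zero-phase and does not distort relative phase between
#' channels.  The alpha band 8-12 Hz is the default analysis band.
#'
#' @param ts a [TimeSeriesPanel-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < fsHz / 2`.
#' @return a filtered [TimeSeriesPanel-class] with the band recorded.
#' @export
bandpass <- function(ts, lowHz = 8, highHz = 12) {
  fs <- ts@fsHz
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(2, c(lowHz, highHz) / (fs / 2), type = "pass")
  b <- bf$b / bf$a[1L]
  a <- bf$a / bf$a[1L]
  v <- ts@values
  res <- .C("iir_filtfilt", x = as.double(v), as.integer(nrow(v)),
            as.integer(ncol(v)), as.double(b), as.double(a),
            as.integer(length(a)), PACKAGE = "hopfconn")
  out <- matrix(res$x, nrow(v), ncol(v))
  dimnames(out) <- dimnames(ts@values)
  new("TimeSeriesPanel", values = out, fsHz = fs, labels = ts@labels,
      band = c(lowHz, highHz))
}

# Analytic signal via the FFT construction, zero-padded to a 2-3-5-smooth
# length (mixed-radix FFT degrades badly on lengths with large prime
# factors); padding artefacts are confined to the edges, which callers
# trim before phase statistics.
analyticSignal <- function(m) {
  n <- nrow(m)
  nfft <- stats::nextn(n, c(2, 3, 5))
  pad <- rbind(m, matrix(0, nfft - n, ncol(m)))
  F <- stats::mvfft(pad)
  h <- numeric(nfft)
  h[1L] <- 1
  if (nfft %% 2L == 0L) {
    h[nfft / 2L + 1L] <- 1
    h[2L:(nfft / 2L)] <- 2
  } else {
    h[2L:((nfft + 1L) / 2L)] <- 2
  }
  a <- stats::mvfft(F * h, inverse = TRUE) / nfft
  a[seq_len(n), , drop = FALSE]
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the per-channel analytic signal (FFT construction of the
#' Hilbert transform) and returns its angle in (-pi, pi].
#'
#' @param ts a (typically band-passed) [TimeSeriesPanel-class] with at
#'   least 64 samples.
#' @return a [PhasePanel-class].
#' @export
instantaneousPhase <- function(ts) {
  v <- ts@values
  stopIfNot(nrow(v) >= 64L, "need at least 64 samples")
  degenerate <- apply(v, 2L, function(col) all(col == col[1L]))
  if (any(degenerate))
    stop("constant channel(s) have undefined phase: ",
         paste(ts@labels[degenerate], collapse = ", "), call. = FALSE)
  ph <- Arg(analyticSignal(v))
  dimnames(ph) <- dimnames(v)
  new("PhasePanel", phases = ph, fsHz = ts@fsHz, labels = ts@labels,
      band = ts@band)
}

#' @rdname accessors
setMethod("phaseValues", "PhasePanel", function(x) x@phases)
#' @rdname accessors
setMethod("samplingRate", "PhasePanel", function(x) x@fsHz)
#' @rdname accessors
setMethod("regionLabels", "PhasePanel", function(x) x@labels)
#' @rdname accessors
setMethod("regionCount", "PhasePanel", function(x) ncol(x@phases))

# Welch power spectral density: 2 s Hann segments, 50% overlap (0.5 Hz
# resolution at 1250 Hz).  Returns list(freqHz, psd) with psd a
# (nfreq x N) matrix.
welchPSD <- function(m, fsHz, segmentS = 2, overlap = 0.5) {
  T <- nrow(m)
  L <- round(segmentS * fsHz)
  stopIfNot(T >= L, "signal shorter than one Welch segment")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, T - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  psd <- matrix(0, nf, ncol(m))
  for (s in starts) {
    seg <- m[s:(s + L - 1L), , drop = FALSE] * w
    P <- Mod(stats::mvfft(seg))^2 / (fsHz * U)
    half <- P[seq_len(nf), , drop = FALSE]
    if (nf > 2L) half[2L:(nf - 1L), ] <- 2 * half[2L:(nf - 1L), ]
    psd <- psd + half
  }
  list(freqHz = (seq_len(nf) - 1L) * fsHz / L, psd = psd / length(starts))
}

#' Per-region spectral peak frequencies
#'
#' For each region: Welch power spectral density (2 s Hann segments, 50%
#' overlap); the candidate peak is the frequency above 4 Hz with the
#' highest density; the peak is accepted only if its density is at least
#' twice the background level, defined as the mean density over 4-48 Hz
#' excluding +/- 1 Hz around the candidate.
#'
#' @param ts a [TimeSeriesPanel-class] of duration >= 2 s.
#' @return a [SpectralPeakTable-class].
#' @export
peakFrequency <- function(ts) {
  fs <- ts@fsHz
  if (nrow(ts@values) < 2 * fs)
    stop("need at least 2 s of signal", call. = FALSE)
  sp <- welchPSD(ts@values, fs)
  f <- sp$freqHz
  cand <- f > 4
  stopIfNot(any(cand), "no frequencies above 4 Hz resolved")
  bgBand <- f >= 4 & f <= min(48, max(f))
  peakHz <- numeric(ncol(sp$psd))
  accepted <- logical(ncol(sp$psd))
  for (j in seq_len(ncol(sp$psd))) {
    p <- sp$psd[, j]
    iPeak <- which(cand)[which.max(p[cand])]
    peakHz[j] <- f[iPeak]
    bg <- bgBand & abs(f - f[iPeak]) > 1
    bgLevel <- mean(p[bg])
    accepted[j] <- is.finite(bgLevel) && p[iPeak] >= 2 * bgLevel
  }
  new("SpectralPeakTable", labels = ts@labels, peakHz = peakHz,
      accepted = accepted)
}

#' Median peak frequency per region across subjects/epochs
#'
#' Median over accepted peaks only; a region with no accepted peak in any
#' table falls back to the global median across regions (with a message).
#'
#' @param tables nonempty list of [SpectralPeakTable-class] objects with
#'   matching labels.
#' @return named numeric vector of per-region frequencies (Hz).
#' @export
medianPeakFrequencies <- function(tables) {
  stopIfNot(length(tables) > 0L, "need at least one peak table")
  labels <- tables[[1L]]@labels
  for (t in tables)
    stopIfNot(identical(t@labels, labels), "peak tables have mismatched labels")
  perRegion <- lapply(seq_along(labels), function(i) {
    v <- vapply(tables, function(t)
      if (t@accepted[i]) t@peakHz[i] else NA_real_, numeric(1))
    v[!is.na(v)]
  })
  med <- vapply(perRegion, function(v)
    if (length(v)) stats::median(v) else NA_real_, numeric(1))
  if (all(is.na(med)))
    stop("no accepted peak in any region", call. = FALSE)
  if (anyNA(med)) {
    message(sum(is.na(med)),
            " region(s) without accepted peaks fall back to the global median")
    med[is.na(med)] <- stats::median(med, na.rm = TRUE)
  }
  names(med) <- labels
  med
}

setMethod("show", "SpectralPeakTable", function(object) {
  cat("SpectralPeakTable:", sum(object@accepted), "of",
      length(object@labels), "regions with accepted peaks\n")
})
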