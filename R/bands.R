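#' Canonical EEG frequency bands
#'
#' Band edges used throughout the package: theta 4-8, alpha 8-13, beta
#' 13-30, gamma 30-45 Hz. The upper gamma edge matches the 4-45 Hz bandpass
#' of the preprocessed DEAP/SEED distributions. Bands are half-open
#' `[fLow, fHigh)` when integrating spectra, so consecutive bands partition
#' the 4-45 Hz range without double counting.
#'
#' @param bands optional replacement table (data.frame with columns `band`,
#'   `fLow`, `fHigh`); validated for ordering and non-overlap.
#' @return data.frame with columns `band`, `fLow`, `fHigh`.
#' @examples
#' frequencyBands()
#' @export
frequencyBands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      band = c("theta", "alpha", "beta", "gamma"),
      fLow = c(4, 8, 13, 30),
      fHigh = c(8, 13, 30, 45),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("band", "fLow", "fHigh") %in% names(bands)))
  if (any(bands$fLow <= 0) || any(bands$fHigh <= bands$fLow))
    stop("invalid band: need 0 < fLow < fHigh")
  if (nrow(bands) > 1 && any(diff(bands$fLow) <= 0))
    stop("bands must be ordered by increasing frequency")
  if (nrow(bands) > 1 && any(bands$fLow[-1] < bands$fHigh[-nrow(bands)]))
    stop("bands must not overlap")
  bands
}

.bandRow <- function(band, bands = frequencyBands()) {
  if (is.character(band)) {
    i <- match(band, bands$band)
    if (is.na(i)) stop("unknown band: ", band)
    bands[i, ]
  } else band
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each column of `x` with a Butterworth band-pass (design order
#' `order`, default 4) applied forward and backward (`signal::filtfilt`),
#' so the output has no group delay. Used to isolate per-band content
#' before computing differential entropy.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param fs sampling rate (Hz).
#' @param band band name (see [frequencyBands()]) or a one-row band table.
#' @param bands band table used to resolve `band` by name.
#' @param order Butterworth design order.
#' @return Filtered signal, same shape as `x`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:127) / 128)   # 10 Hz: inside alpha
#' y <- bandpassFilter(x, 128, "alpha")
#' var(y) / var(x)                          # close to 1
#' @export
bandpassFilter <- function(x, fs, band, bands = frequencyBands(), order = 4) {
  b <- .bandRow(band, bands)
  if (b$fHigh >= fs / 2)
    stop("invalid band: upper edge ", b$fHigh, " Hz is at or above Nyquist (fs = ", fs, ")")
  bf <- signal::butter(order, c(b$fLow, b$fHigh) / (fs / 2), type = "pass")
  # the mean is removed first (an ideal band-pass has zero DC gain) and the
  # signal is odd-reflection padded: both tame the forward-backward edge
  # transients, which matter for 1-second windows
  filt1 <- function(v) {
    n <- length(v)
    v <- v - mean(v)
    p <- min(n - 1L, max(3L * (2L * order + 1L), as.integer(fs %/% 2)))
    vp <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[n] - v[(n - 1):(n - p)])
    as.numeric(signal::filtfilt(bf, vp))[(p + 1):(p + n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else filt1(x)
}

#' Welch power spectral density estimate
#'
#' One-sided Welch estimate: the signal is cut into segments of
#' `segLength` samples with fractional `overlap`, each segment is
#' Hann-windowed and its periodogram scaled to density units
#' (microvolts squared per Hz); segment periodograms are averaged. With the
#' default segment length of min(n, 256) a 1-second window yields a single
#' Hann periodogram.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param segLength samples per Welch segment.
#' @param overlap fractional overlap between consecutive segments.
#' @param demean subtract the segment mean before windowing (default TRUE;
#'   EEG features are driven by fluctuation power, not DC offset).
#' @return list with `freq` (Hz, 0..fs/2) and `psd` (density).
#' @export
welchPsd <- function(x, fs, segLength = min(length(x), 256L), overlap = 0.5,
                     demean = TRUE) {
  n <- length(x)
  segLength <- as.integer(segLength)
  if (segLength < 2L || segLength > n)
    stop("window shorter than one Welch segment")
  step <- max(1L, as.integer(round(segLength * (1 - overlap))))
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / segLength)  # Hann
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(segLength)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)]
    if (demean) seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w))^2 * scale
  }
  p2 <- acc / length(starts)
  half <- floor(segLength / 2)
  psd <- p2[1:(half + 1)]
  # fold the negative frequencies into the one-sided estimate
  if (segLength %% 2 == 0) {
    psd[2:half] <- psd[2:half] + rev(p2[(half + 2):segLength])
  } else {
    psd[2:(half + 1)] <- psd[2:(half + 1)] + rev(p2[(half + 2):segLength])
  }
  list(freq = (0:half) * fs / segLength, psd = psd)
}

#' Band power from the Welch estimate
#'
#' Integrates the one-sided Welch spectral density over `[fLow, fHigh)`
#' (rectangle rule over frequency bins), returning power in microvolts
#' squared. This band-integrated power is the "PSD" feature of the model.
#'
#' @param x numeric vector, or a samples-by-channels matrix together with
#'   `channel`.
#' @param fs sampling rate (Hz).
#' @param band band name or one-row band table.
#' @param channel channel name when `x` is a matrix.
#' @param bands band table.
#' @param ... passed to [welchPsd()].
#' @return nonnegative scalar power.
#' @examples
#' t <- (0:127) / 128
#' welchBandPower(sin(2 * pi * 10 * t), 128, "alpha")  # ~ 0.5 (A^2/2)
#' @export
welchBandPower <- function(x, fs, band, channel = NULL,
                           bands = frequencyBands(), ...) {
  if (is.matrix(x)) {
    if (is.null(channel)) stop("channel must be given for matrix input")
    i <- match(toupper(channel), toupper(colnames(x)))
    if (is.na(i)) stop("unknown channel: ", channel)
    x <- x[, i]
  }
  b <- .bandRow(band, bands)
  est <- welchPsd(x, fs, ...)
  df <- est$freq[2] - est$freq[1]
  sel <- est$freq >= b$fLow & est$freq < b$fHigh
  sum(est$psd[sel]) * df
}
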