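#' Differential entropy of a Gaussian signal from its variance
#'
#' Under a Gaussian assumption the differential entropy of a band-limited
#' EEG segment is `0.5 * log(2 * pi * e * variance)` nats. The natural
#' logarithm is used throughout (the `2*pi*e` form presumes it).
#'
#' @param variance signal variance (microvolts squared), strictly positive.
#' @return differential entropy in nats.
#' @examples
#' deFromVariance(1)            # 0.5 * log(2 * pi * e) ~ 1.41894
#' deFromVariance(1 / (2 * pi * exp(1)))  # 0
#' @export
deFromVariance <- function(variance) {
  if (any(!is.finite(variance)) || any(variance <= 0))
    stop("degenerate signal: variance must be positive to compute differential entropy")
  0.5 * log(2 * pi * exp(1) * variance)
}

#' Band differential entropy of one channel
#'
#' Band-pass filters the window (zero phase) and applies
#' [deFromVariance()] to the sample variance of the filtered channel.
#'
#' @param x samples-by-channels matrix (one 1-s window) or numeric vector.
#' @param fs sampling rate (Hz).
#' @param band band name or one-row band table.
#' @param channel channel name when `x` is a matrix.
#' @param bands band table.
#' @return differential entropy in nats.
#' @export
bandDE <- function(x, fs, band, channel = NULL, bands = frequencyBands()) {
  if (is.matrix(x)) {
    if (is.null(channel)) stop("channel must be given for matrix input")
    i <- match(toupper(channel), toupper(colnames(x)))
    if (is.na(i)) stop("unknown channel: ", channel)
    x <- x[, i]
  }
  y <- bandpassFilter(x, fs, band, bands)
  deFromVariance(stats::var(y))
}

#' Emotion valence index (theta log power ratio)
#'
#' Log ratio of theta-band power between two channels; reflects
#' inter-hemispheric asymmetry of frontal theta rhythm power. Antisymmetric
#' under swapping the channels.
#'
#' @param thetaPower1,thetaPower2 theta-band powers (positive).
#' @return `log(thetaPower1 / thetaPower2)`.
#' @examples
#' evi(exp(1) * 2, 2)   # 1
#' @export
evi <- function(thetaPower1, thetaPower2) {
  if (any(thetaPower1 <= 0) || any(thetaPower2 <= 0))
    stop("degenerate signal: EVI requires positive band powers")
  log(thetaPower1 / thetaPower2)
}

#' Asymmetry index (normalized band power difference)
#'
#' `(p1 - p2) / (p1 + p2)` for the band powers of two channels; bounded in
#' \[-1, 1\] and antisymmetric under swapping the channels.
#'
#' @param p1,p2 band powers (nonnegative, not both zero).
#' @return asymmetry index in \[-1, 1\].
#' @examples
#' asi(3, 1)   # 0.5
#' @export
asi <- function(p1, p2) {
  if (any(p1 < 0) || any(p2 < 0) || any(p1 + p2 == 0))
    stop("degenerate signal: ASI requires nonnegative powers with positive sum")
  (p1 - p2) / (p1 + p2)
}

#' Channel pairs for the asymmetry features
#'
#' The four pairs used for the theta EVI features, reused for the
#' alpha/beta/gamma ASI features: FP1-FP2, AF3-AF4, FP1-AF4, AF3-FP2
#' (homologous left-right pairs and the two diagonals).
#'
#' @return data.frame with columns `ch1`, `ch2`.
#' @export
channelPairs <- function() {
  data.frame(ch1 = c("FP1", "AF3", "FP1", "AF3"),
             ch2 = c("FP2", "AF4", "AF4", "FP2"),
             stringsAsFactors = FALSE)
}

#' Canonical names of the 48 window features
#'
#' Ordering inside each 16-feature block is band-major (theta, alpha, beta,
#' gamma) and channel/pair-minor. The spatial block holds the four theta
#' EVI values first, then alpha/beta/gamma ASI values over the same pairs.
#'
#' @param bands band table.
#' @param pairs pair table (see [channelPairs()]).
#' @return character vector of length 48.
#' @export
featureNames <- function(bands = frequencyBands(), pairs = channelPairs()) {
  ch <- frontalChannels()
  pairLab <- paste0(pairs$ch1, ".", pairs$ch2)
  c(
    as.vector(t(outer(bands$band, ch, function(b, c) paste0("de_", b, "_", c)))),
    as.vector(t(outer(bands$band, ch, function(b, c) paste0("psd_", b, "_", c)))),
    paste0("evi_", bands$band[1], "_", pairLab),
    as.vector(t(outer(bands$band[-1], pairLab, function(b, p) paste0("asi_", b, "_", p))))
  )
}

#' Extract the 48 features of one 1-second window
#'
#' Computes, for the four frontal channels: 16 differential entropy values
#' (4 bands x 4 channels, from zero-phase band-filtered variance), 16 Welch
#' band powers, 4 theta EVI values over the canonical pairs and 12 ASI
#' values (alpha/beta/gamma x pairs). Feature order is the canonical order
#' of [featureNames()].
#'
#' @param window samples-by-channels matrix (n = fs x 1 s) with the four
#'   frontal channels named in its columns.
#' @param fs sampling rate (Hz).
#' @param bands band table.
#' @param pairs pair table.
#' @return named numeric vector of length 48.
#' @export
extractFeatures <- function(window, fs, bands = frequencyBands(),
                            pairs = channelPairs()) {
  ch <- frontalChannels()
  idx <- match(ch, toupper(colnames(window)))
  if (anyNA(idx)) stop("window must contain channels FP1, FP2, AF3, AF4")
  x <- window[, idx, drop = FALSE]
  colnames(x) <- ch
  nb <- nrow(bands)

  de <- matrix(NA_real_, nb, 4)
  psd <- matrix(NA_real_, nb, 4)
  for (bi in seq_len(nb)) {
    filt <- bandpassFilter(x, fs, bands[bi, ], bands)
    de[bi, ] <- apply(filt, 2, function(v) deFromVariance(stats::var(v)))
    psd[bi, ] <- vapply(ch, function(cc)
      welchBandPower(x, fs, bands[bi, ], channel = cc, bands = bands), 0)
  }
  p1 <- psd[, match(pairs$ch1, ch)]
  p2 <- psd[, match(pairs$ch2, ch)]
  # vapply over bands gives a (pair x band) matrix; column-major flattening
  # yields the canonical band-major, pair-minor order
  spatial <- c(
    evi(p1[1, ], p2[1, ]),
    as.vector(vapply(2:nb, function(bi) asi(p1[bi, ], p2[bi, ]),
                     numeric(nrow(pairs))))
  )
  stats::setNames(c(as.vector(t(de)), as.vector(t(psd)), spatial),
                  featureNames(bands, pairs))
}

#' Per-window features of a whole trial
#'
#' Cuts the trial into consecutive non-overlapping 1-second windows (the
#' leading `baselineSeconds` are tagged as baseline windows) and computes
#' the 48 features of every window. For efficiency and to avoid per-window
#' filter edge artifacts, band filtering is applied once to the full trial
#' (`filterScope = "trial"`, the default); `filterScope = "window"`
#' reproduces the strictly window-wise [extractFeatures()] path.
#'
#' @param trial an [EEGTrial-class].
#' @param bands,pairs band and pair tables.
#' @param windowSeconds window length in seconds.
#' @param filterScope `"trial"` (filter once, then window) or `"window"`.
#' @return a [FeatureSet-class] (48 features x windows).
#' @export
windowFeatures <- function(trial, bands = frequencyBands(),
                           pairs = channelPairs(), windowSeconds = 1,
                           filterScope = c("trial", "window")) {
  filterScope <- match.arg(filterScope)
  fs <- trial@fs
  wlen <- as.integer(round(fs * windowSeconds))
  sp <- splitBaseline(trial, windowSeconds)
  allWin <- c(sp$baseline, sp$experimental)
  nWin <- length(allWin)
  isBase <- c(rep(TRUE, length(sp$baseline)), rep(FALSE, length(sp$experimental)))

  ch <- frontalChannels()
  x <- trial@samples[, match(ch, toupper(colnames(trial@samples))), drop = FALSE]
  colnames(x) <- ch
  nb <- nrow(bands)
  starts <- vapply(allWin, function(w) attr(w, "start"), 0L)

  feat <- matrix(NA_real_, 48L, nWin,
                 dimnames = list(featureNames(bands, pairs), NULL))
  if (filterScope == "window") {
    for (k in seq_len(nWin)) feat[, k] <- extractFeatures(allWin[[k]], fs, bands, pairs)
  } else {
    # variance of each band-filtered window (DE input), trial-level filtering
    de <- array(NA_real_, c(nb, 4, nWin))
    for (bi in seq_len(nb)) {
      filt <- bandpassFilter(x, fs, bands[bi, ], bands)
      for (k in seq_len(nWin)) {
        seg <- filt[starts[k]:(starts[k] + wlen - 1L), , drop = FALSE]
        v <- apply(seg, 2, stats::var)
        if (any(v <= 0)) stop("degenerate signal: zero-variance window")
        de[bi, , k] <- 0.5 * log(2 * pi * exp(1) * v)
      }
    }
    # Welch band powers per window (single Hann segment per 1-s window)
    psd <- array(NA_real_, c(nb, 4, nWin))
    for (k in seq_len(nWin)) {
      seg <- x[starts[k]:(starts[k] + wlen - 1L), , drop = FALSE]
      for (cc in seq_len(4)) {
        est <- welchPsd(seg[, cc], fs)
        df <- est$freq[2] - est$freq[1]
        for (bi in seq_len(nb)) {
          sel <- est$freq >= bands$fLow[bi] & est$freq < bands$fHigh[bi]
          psd[bi, cc, k] <- sum(est$psd[sel]) * df
        }
      }
    }
    i1 <- match(pairs$ch1, ch); i2 <- match(pairs$ch2, ch)
    for (k in seq_len(nWin)) {
      spatial <- c(evi(psd[1, i1, k], psd[1, i2, k]),
                   as.vector(vapply(2:nb, function(bi)
                     asi(psd[bi, i1, k], psd[bi, i2, k]), numeric(length(i1)))))
      feat[, k] <- c(as.vector(t(de[, , k])), as.vector(t(psd[, , k])), spatial)
    }
  }

  cd <- S4Vectors::DataFrame(
    trialId = trial@trialId,
    subjectId = trial@subjectId,
    windowIndex = c(seq_along(sp$baseline), seq_along(sp$experimental)),
    isBaseline = isBase,
    label = trial@label
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat), colData = cd)
  methods::new("FeatureSet", se)
}

#' Combine the FeatureSets of many trials
#'
#' @param featureSets list of [FeatureSet-class] objects (one per trial).
#' @return a single [FeatureSet-class].
#' @export
bindFeatureSets <- function(featureSets) {
  stopifnot(length(featureSets) >= 1)
  out <- do.call(BiocGenerics::cbind, featureSets)
  methods::new("FeatureSet", out)
}

#' Export a feature table as a data.frame (CSV-ready)
#'
#' Columns: trialId, subjectId, windowIndex, isBaseline, label, then the 48
#' named features of the chosen assay.
#'
#' @param featureSet a [FeatureSet-class].
#' @param assay assay name (`"features"` or `"corrected"`).
#' @return data.frame with one row per window.
#' @export
featureTable <- function(featureSet, assay = "features") {
  cd <- as.data.frame(SummarizedExperiment::colData(featureSet))
  cbind(cd, as.data.frame(t(SummarizedExperiment::assay(featureSet, assay))))
}
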