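#' Split a trial into baseline and experimental 1-second windows
#'
#' The leading `baselineSeconds` (3 s in the DEAP/SEED layouts) are cut
#' into consecutive windows of `windowSeconds`; the remainder is cut into
#' consecutive full windows (any trailing partial window is dropped). A
#' 63-second DEAP trial yields 3 baseline and 60 experimental windows.
#'
#' @param trial an [EEGTrial-class].
#' @param windowSeconds window length (seconds).
#' @return list with elements `baseline` and `experimental`, each a list of
#'   samples-by-channels matrices carrying a `start` attribute (sample
#'   index within the trial).
#' @examples
#' x <- matrix(rnorm(4 * 128 * 63), ncol = 4,
#'             dimnames = list(NULL, frontalChannels()))
#' sp <- splitBaseline(EEGTrial(x, 128))
#' lengths(sp)   # 3 and 60
#' @export
splitBaseline <- function(trial, windowSeconds = 1) {
  fs <- trial@fs
  wlen <- as.integer(round(fs * windowSeconds))
  nBase <- as.integer(round(fs * trial@baselineSeconds))
  n <- nrow(trial@samples)
  if (n <= nBase)
    stop("malformed trial: shorter than its ", trial@baselineSeconds, " s baseline")
  if (nBase %% wlen != 0)
    stop("malformed trial: baseline is not a whole number of windows")
  cut <- function(from, to) {
    starts <- seq(from, to - wlen + 1L, by = wlen)
    lapply(starts, function(s) {
      w <- trial@samples[s:(s + wlen - 1L), , drop = FALSE]
      attr(w, "start") <- as.integer(s)
      w
    })
  }
  baseline <- cut(1L, nBase)
  if (n - nBase < wlen)
    stop("malformed trial: no full experimental window after the baseline")
  experimental <- cut(nBase + 1L, n)
  list(baseline = baseline, experimental = experimental)
}

#' Mean of a feature over the baseline windows
#'
#' @param baselineValues numeric vector of per-window values of one feature.
#' @return arithmetic mean.
#' @examples
#' baselineMean(c(0.2, 0.4, 0.6))  # 0.4
#' @export
baselineMean <- function(baselineValues) {
  if (length(baselineValues) == 0)
    stop("malformed trial: no baseline windows")
  mean(baselineValues)
}

#' Fit per-feature min-max normalization on a training split
#'
#' Records the minimum and maximum of every feature over the supplied
#' windows only. Features with zero range are flagged degenerate (a
#' warning) and later map to 0.
#'
#' @param features a [FeatureSet-class], or a features-by-windows matrix.
#' @param fittedOn identifier of the split (kept for leakage audits).
#' @return a [NormalizationState-class].
#' @export
fitMinMax <- function(features, fittedOn = "training") {
  m <- if (methods::is(features, "SummarizedExperiment"))
    SummarizedExperiment::assay(features, "features") else features
  if (ncol(m) < 2) stop("need at least 2 windows to fit normalization")
  fmin <- apply(m, 1, min)
  fmax <- apply(m, 1, max)
  ndeg <- sum(fmax == fmin)
  if (ndeg > 0)
    warning(ndeg, " degenerate (constant) feature column(s); they will map to 0")
  methods::new("NormalizationState", fmin = fmin, fmax = fmax,
               fittedOn = as.character(fittedOn))
}

#' Apply fitted min-max scaling
#'
#' `(F - Fmin) / (Fmax - Fmin)`, clipped to \[0, 1\] so windows outside the
#' fitted (training) range cannot leave the unit interval. Degenerate
#' features (zero fitted range) map to 0.
#'
#' @param x numeric vector (one feature), or a features-by-windows matrix
#'   whose rows align with the state.
#' @param state a [NormalizationState-class]; alternatively give `fmin`
#'   and `fmax` directly.
#' @param fmin,fmax scalar range when `x` is a single feature vector.
#' @return scaled values in \[0, 1\], same shape as `x`.
#' @examples
#' applyMinMax(5, fmin = 0, fmax = 10)    # 0.5
#' applyMinMax(12, fmin = 0, fmax = 10)   # 1 (clipped)
#' @export
applyMinMax <- function(x, state = NULL, fmin = NULL, fmax = NULL) {
  if (!is.null(state)) {
    fmin <- state@fmin
    fmax <- state@fmax
  }
  rng <- fmax - fmin
  if (is.matrix(x)) {
    stopifnot(nrow(x) == length(fmin))
    out <- (x - fmin) / ifelse(rng == 0, 1, rng)
    out[rng == 0, ] <- 0
  } else {
    out <- ifelse(rng == 0, 0, (x - fmin) / ifelse(rng == 0, 1, rng))
  }
  pmin(pmax(out, 0), 1)
}

#' Baseline subtraction of a normalized feature
#'
#' `F' - Fbar`: both arguments must be normalized with the same
#' [NormalizationState-class]; the result lies in \[-1, 1\].
#'
#' @param feature normalized experimental feature value(s).
#' @param baselineMean normalized baseline mean of the same feature.
#' @return corrected feature value(s).
#' @examples
#' correctFeature(0.7, 0.4)  # 0.3
#' @export
correctFeature <- function(feature, baselineMean) {
  feature - baselineMean
}

#' Individual-difference correction of a feature set
#'
#' Full correction stage: every window's features are min-max scaled with
#' `state`; per trial, the mean of the scaled baseline windows is
#' subtracted from the scaled experimental windows. Baseline windows exist
#' only to supply the per-trial baseline mean — the returned set contains
#' the experimental windows only, with a `"corrected"` assay in \[-1, 1\]
#' next to the raw `"features"` assay.
#'
#' @param featureSet a [FeatureSet-class] containing baseline and
#'   experimental windows of one or more trials.
#' @param state a [NormalizationState-class] (fit it on the training split).
#' @return a [FeatureSet-class] of experimental windows with assays
#'   `features` and `corrected`.
#' @export
correctFeatureSet <- function(featureSet, state) {
  cd <- SummarizedExperiment::colData(featureSet)
  raw <- SummarizedExperiment::assay(featureSet, "features")
  norm <- applyMinMax(raw, state)
  corrected <- matrix(NA_real_, nrow(norm), ncol(norm))
  for (tid in unique(cd$trialId)) {
    inTrial <- cd$trialId == tid
    base <- inTrial & cd$isBaseline
    if (!any(base)) stop("malformed trial: no baseline windows for trial ", tid)
    fbar <- rowMeans(norm[, base, drop = FALSE])
    exp_ <- which(inTrial & !cd$isBaseline)
    corrected[, exp_] <- norm[, exp_, drop = FALSE] - fbar
  }
  keep <- which(!cd$isBaseline)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = raw[, keep, drop = FALSE],
                  corrected = corrected[, keep, drop = FALSE]),
    colData = cd[keep, ])
  rownames(se) <- rownames(featureSet)
  methods::new("FeatureSet", se)
}

#' Serialize / restore a NormalizationState as JSON
#'
#' @param state a [NormalizationState-class].
#' @param path JSON file path.
#' @return `readNormalizationState` returns the restored state.
#' @export
writeNormalizationState <- function(state, path) {
  jsonlite::write_json(
    list(fittedOn = state@fittedOn,
         features = data.frame(feature = names(state@fmin),
                               min = unname(state@fmin),
                               max = unname(state@fmax))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormalizationState
#' @export
readNormalizationState <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("NormalizationState",
               fmin = stats::setNames(obj$features$min, obj$features$feature),
               fmax = stats::setNames(obj$features$max, obj$features$feature),
               fittedOn = obj$fittedOn)
}
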