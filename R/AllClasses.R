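#' @import methods
#' @importFrom stats fft rnorm runif var setNames sd
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib emoKAN, .registration = TRUE
NULL

#' The four frontal electrodes used throughout the package
#'
#' Sparse-channel montage: the two prefrontal (FP1, FP2) and two
#' anterior-frontal (AF3, AF4) electrodes of the 10-20 system.
#'
#' @return Character vector of the four channel names, in canonical order.
#' @export
frontalChannels <- function() c("FP1", "FP2", "AF3", "AF4")

#' EEGTrial: one multichannel EEG trial
#'
#' Container for a single trial: a samples-by-channels matrix (microvolts)
#' at a given sampling rate, with a leading baseline segment recorded before
#' the stimulus, a class label and trial/subject identifiers. Channel
#' columns must be named and contain FP1, FP2, AF3 and AF4 exactly once.
#'
#' @slot samples numeric matrix, n_samples x 4, column names are channels.
#' @slot fs sampling rate in Hz.
#' @slot baselineSeconds length of the leading baseline segment (seconds).
#' @slot label class label of the trial.
#' @slot trialId,subjectId identifiers.
#' @export
setClass("EEGTrial",
  representation(
    samples = "matrix",
    fs = "numeric",
    baselineSeconds = "numeric",
    label = "character",
    trialId = "character",
    subjectId = "character"
  )
)

setValidity("EEGTrial", function(object) {
  msg <- character()
  ch <- colnames(object@samples)
  req <- frontalChannels()
  if (is.null(ch) || !all(req %in% toupper(ch)) ||
      any(table(toupper(ch))[req] != 1)) {
    msg <- c(msg, "samples must have the channels FP1, FP2, AF3, AF4 exactly once each")
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (nrow(object@samples) <= object@fs * object@baselineSeconds) {
    msg <- c(msg, "trial must be longer than its baseline segment")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGTrial
#'
#' @param samples numeric matrix (n_samples x channels) with named columns.
#' @param fs sampling rate (Hz).
#' @param baselineSeconds baseline length in seconds (default 3, the leading
#'   pre-stimulus segment of the DEAP/SEED layouts).
#' @param label trial class label.
#' @param trialId,subjectId identifiers.
#' @return An [EEGTrial-class] object.
#' @examples
#' x <- matrix(rnorm(4 * 128 * 5), ncol = 4,
#'             dimnames = list(NULL, frontalChannels()))
#' EEGTrial(x, fs = 128, label = "HVHA", trialId = "t1")
#' @export
EEGTrial <- function(samples, fs, baselineSeconds = 3, label = NA_character_,
                     trialId = "trial1", subjectId = "s1") {
  colnames(samples) <- toupper(colnames(samples))
  new("EEGTrial", samples = samples, fs = as.numeric(fs),
      baselineSeconds = as.numeric(baselineSeconds),
      label = as.character(label), trialId = as.character(trialId),
      subjectId = as.character(subjectId))
}

#' @describeIn EEGTrial number of samples in the trial
#' @param x,object an EEGTrial
#' @export
setMethod("length", "EEGTrial", function(x) nrow(x@samples))

#' @rdname EEGTrial
#' @export
samplingRate <- function(x) x@fs

#' @rdname EEGTrial
#' @export
trialLabel <- function(x) x@label

#' @rdname EEGTrial
#' @export
trialSamples <- function(x) x@samples

setMethod("show", "EEGTrial", function(object) {
  cat(sprintf(
    "EEGTrial '%s' (subject %s): %.1f s at %g Hz, %d channels, baseline %g s, label %s\n",
    object@trialId, object@subjectId, nrow(object@samples) / object@fs,
    object@fs, ncol(object@samples), object@baselineSeconds, object@label))
})

#' FeatureSet: per-window feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are the 48
#' named features (16 DE, 16 band power, 4 EVI + 12 ASI) and whose columns
#' are 1-second windows. Column metadata carries `trialId`, `windowIndex`,
#' `isBaseline`, `label` and `subjectId`. After correction an assay
#' `"corrected"` is added alongside the raw `"features"` assay.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setMethod("show", "FeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "FeatureSet: %d features x %d windows (%d baseline, %d experimental), %d trial(s)\n",
    nrow(object), ncol(object), sum(cd$isBaseline), sum(!cd$isBaseline),
    length(unique(cd$trialId))))
  cat("assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' NormalizationState: fitted per-feature min-max ranges
#'
#' Per-feature minimum and maximum fitted on a training split, used to scale
#' features to [0, 1] before baseline subtraction. Carries the identity of
#' the split it was fitted on so cross-validation leakage can be audited.
#'
#' @slot fmin,fmax named numeric vectors (one entry per feature).
#' @slot fittedOn identifier of the split the ranges were fitted on.
#' @export
setClass("NormalizationState",
  representation(fmin = "numeric", fmax = "numeric", fittedOn = "character"))

setValidity("NormalizationState", function(object) {
  if (length(object@fmin) != length(object@fmax))
    return("fmin and fmax must have equal length")
  if (any(object@fmax < object@fmin))
    return("fmax must be >= fmin for every feature")
  TRUE
})

setMethod("show", "NormalizationState", function(object) {
  cat(sprintf("NormalizationState: %d features, fitted on '%s' (%d degenerate)\n",
              length(object@fmin), object@fittedOn,
              sum(object@fmax == object@fmin)))
})

#' ModelConfig: architecture configuration
#'
#' Describes one of the four ablation variants: a three-block convolutional
#' backbone (3x3 kernels, same padding, batch norm, per-block dropout),
#' optionally a frequency-channel attention (F2CA) block after the third
#' convolution, a 256-unit dense layer, and a variant-specific head.
#'
#' @slot variant one of `"cnn"`, `"cnn_fcn"`, `"cnn_kan"`, `"cnn_kan_f2ca"`.
#' @slot numClasses number of emotion classes.
#' @slot convFilters filter counts of the three conv blocks.
#' @slot dropoutConv,dropoutFc dropout rates.
#' @slot l2 L2 penalty coefficient on weight matrices.
#' @slot f2caRatio bottleneck ratio of the attention block.
#' @slot groupSize,fusion sample-group fusion settings (see [fuseGroup()]).
#' @slot kan list with `gridSize`, `splineOrder`, `hidden`, `gridLo`, `gridHi`.
#' @export
setClass("ModelConfig",
  representation(
    variant = "character", numClasses = "integer",
    convFilters = "integer", dropoutConv = "numeric", dropoutFc = "numeric",
    l2 = "numeric", f2caRatio = "integer",
    groupSize = "integer", fusion = "character", kan = "list"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@variant %in% c("cnn", "cnn_fcn", "cnn_kan", "cnn_kan_f2ca"))
    msg <- c(msg, "unknown variant")
  if (object@numClasses < 2L) msg <- c(msg, "numClasses must be >= 2")
  if (length(object@convFilters) != 3L || any(object@convFilters < 1L))
    msg <- c(msg, "convFilters must be three positive counts")
  if (object@convFilters[3L] %% object@f2caRatio != 0L)
    msg <- c(msg, "third conv filter count must be divisible by f2caRatio")
  if (object@groupSize < 1L) msg <- c(msg, "groupSize must be >= 1")
  if (!object@fusion %in% c("mean", "concat")) msg <- c(msg, "fusion must be mean or concat")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults follow the published architecture: conv filters (32, 64, 64),
#' conv dropout (0.5, 0.4, 0.3), dense dropout 0.5, L2 0.001, attention
#' ratio 8, sample groups of 12.
#'
#' @param variant architecture variant; `"cnn_kan_f2ca"` is the full model.
#' @param numClasses number of classes (4 for valence-arousal quadrants,
#'   2 for a binary task, 3 for positive/neutral/negative).
#' @param convFilters,dropoutConv,dropoutFc,l2,f2caRatio,groupSize,fusion
#'   see [ModelConfig-class].
#' @param kan KAN head settings: `hidden` output width (128), `gridSize`
#'   spline grid intervals (5), `splineOrder` polynomial order (3), grid
#'   span `gridLo`/`gridHi` (-1, 1 — inputs are bounded by the correction
#'   stage).
#' @return A [ModelConfig-class] object.
#' @export
modelConfig <- function(variant = c("cnn_kan_f2ca", "cnn", "cnn_fcn", "cnn_kan"),
                        numClasses = 4L,
                        convFilters = c(32L, 64L, 64L),
                        dropoutConv = c(0.5, 0.4, 0.3),
                        dropoutFc = 0.5,
                        l2 = 0.001,
                        f2caRatio = 8L,
                        groupSize = 12L,
                        fusion = c("mean", "concat"),
                        kan = list()) {
  kanDefaults <- list(hidden = 128L, gridSize = 5L, splineOrder = 3L,
                      gridLo = -1, gridHi = 1)
  kanDefaults[names(kan)] <- kan
  new("ModelConfig", variant = match.arg(variant),
      numClasses = as.integer(numClasses),
      convFilters = as.integer(convFilters),
      dropoutConv = as.numeric(dropoutConv), dropoutFc = as.numeric(dropoutFc),
      l2 = as.numeric(l2), f2caRatio = as.integer(f2caRatio),
      groupSize = as.integer(groupSize), fusion = match.arg(fusion),
      kan = kanDefaults)
}

#' EmotionNet: an assembled model
#'
#' Holds a [ModelConfig-class] together with the named list of parameter
#' arrays (convolution kernels, batch-norm parameters and moving statistics,
#' dense/KAN/attention weights). Use [countParams()] for the total size,
#' [layerSummary()] for a per-layer audit, [trainFold()] to fit and
#' [predictProba()] for class probabilities.
#'
#' @slot config the architecture configuration.
#' @slot params named list of numeric arrays.
#' @slot trained logical.
#' @slot classes class labels seen during training (empty until trained).
#' @export
setClass("EmotionNet",
  representation(config = "ModelConfig", params = "list", trained = "logical",
                 classes = "character"))

setMethod("show", "EmotionNet", function(object) {
  cat(sprintf("EmotionNet variant '%s', %d classes, %s, %s parameters\n",
              object@config@variant, object@config@numClasses,
              if (object@trained) "trained" else "initialized",
              format(countParams(object), big.mark = ",")))
  print(layerSummary(object))
})

#' @rdname EmotionNet-class
#' @param model an EmotionNet
#' @export
modelParams <- function(model) model@params

#' @rdname EmotionNet-class
#' @export
modelVariant <- function(model) model@config@variant
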