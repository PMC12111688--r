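#' Default class gain tables of the synthetic generator
#'
#' Amplitude multipliers (band x channel) that encode the four
#' valence-arousal quadrant classes. Each class carries a distinct
#' signature: a lateralized band (gain 3 on the left or right of a pair,
#' driving EVI/ASI asymmetry) plus a globally raised band (gain 2, driving
#' band power and DE). Neutral gain is 1 everywhere.
#'
#' @return named list of 4x4 matrices (rows theta/alpha/beta/gamma,
#'   columns FP1/FP2/AF3/AF4).
#' @export
defaultClassGains <- function() {
  g <- function(...) {
    m <- matrix(1, 4, 4, dimnames = list(frequencyBands()$band, frontalChannels()))
    mods <- list(...)
    for (mod in mods) m[mod$band, mod$ch] <- mod$gain
    m
  }
  list(
    HVHA = g(list(band = "alpha", ch = c("FP1", "AF3"), gain = 3),
             list(band = "beta", ch = frontalChannels(), gain = 2)),
    HVLA = g(list(band = "alpha", ch = c("FP2", "AF4"), gain = 3),
             list(band = "theta", ch = frontalChannels(), gain = 2)),
    LVHA = g(list(band = "beta", ch = c("FP1", "AF3"), gain = 3),
             list(band = "gamma", ch = frontalChannels(), gain = 2)),
    LVLA = g(list(band = "theta", ch = c("FP2", "AF4"), gain = 3))
  )
}

#' Configuration of the synthetic 4-channel EEG generator
#'
#' The generator emulates the DEAP trial layout: `trialSeconds` of signal
#' at `fs` Hz, the first `baselineSeconds` being a pre-stimulus baseline.
#' Each channel is a sum of band-limited oscillations (band-passed Gaussian
#' noise at the canonical band edges, base amplitudes `oscAmp` microvolts
#' RMS) and a 1/f^`noiseExponent` background (RMS `noiseSd`, band-limited
#' to 4-45 Hz). During the experimental segment the oscillation amplitudes
#' are multiplied by the class gain table; the baseline segment always uses
#' neutral gains. Per-trial lognormal amplitude jitter (`jitterSd`) and a
#' per-subject global scale (`subjectSd`) emulate trial-to-trial and
#' individual variability (the latter is what baseline correction removes).
#'
#' @param fs sampling rate (Hz, default 128 as in DEAP).
#' @param trialSeconds trial length (default 63: 3 s baseline + 60 s).
#' @param baselineSeconds baseline length (default 3).
#' @param classes class labels; must name entries of `classGains`.
#' @param classGains named list of band x channel gain matrices.
#' @param oscAmp per-band RMS amplitudes (microvolts) at neutral gain.
#' @param noiseSd RMS of the 1/f background (microvolts).
#' @param noiseExponent spectral slope of the background.
#' @param jitterSd lognormal sd of per-trial band/channel amplitude jitter.
#' @param subjectSd lognormal sd of the per-subject global amplitude scale.
#' @param nSubjects number of simulated subjects to cycle over.
#' @return list of class `synthConfig`.
#' @export
synthConfig <- function(fs = 128, trialSeconds = 63, baselineSeconds = 3,
                        classes = names(defaultClassGains()),
                        classGains = defaultClassGains(),
                        oscAmp = c(theta = 4, alpha = 5, beta = 3.5, gamma = 2.5),
                        noiseSd = 12, noiseExponent = 1,
                        jitterSd = 0.1, subjectSd = 0.2, nSubjects = 8L) {
  stopifnot(fs >= 128, trialSeconds > baselineSeconds,
            all(classes %in% names(classGains)),
            all(vapply(classGains, function(m) all(m > 0), TRUE)),
            all(oscAmp > 0), noiseSd >= 0)
  structure(list(fs = fs, trialSeconds = trialSeconds,
                 baselineSeconds = baselineSeconds, classes = classes,
                 classGains = classGains, oscAmp = oscAmp, noiseSd = noiseSd,
                 noiseExponent = noiseExponent, jitterSd = jitterSd,
                 subjectSd = subjectSd, nSubjects = as.integer(nSubjects)),
            class = "synthConfig")
}

#' Class-neutral generator configuration
#'
#' All class gains 1: classes differ in label only, so every spatial
#' feature is zero-mean and a classifier should perform at chance. Used
#' for generator realism checks and permutation nulls.
#'
#' @param ... passed to [synthConfig()].
#' @return a `synthConfig`.
#' @export
neutralSynthConfig <- function(...) {
  gains <- defaultClassGains()
  for (i in seq_along(gains)) gains[[i]][] <- 1
  synthConfig(classGains = gains, ...)
}

# band-limited 1/f background, RMS = sd, support 4-45 Hz
.pinkNoise <- function(n, fs, sd, exponent) {
  if (sd <= 0) return(numeric(n))
  f <- (0:(n - 1)) * fs / n
  fFold <- pmin(f, fs - f)
  amp <- ifelse(fFold >= 4 & fFold <= 45, fFold^(-exponent / 2), 0)
  ph <- stats::runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::fft(spec, inverse = TRUE))
  x * sd / stats::sd(x)
}

# unit-RMS band-limited oscillation (band-passed white noise)
.bandOsc <- function(n, fs, band) {
  x <- bandpassFilter(stats::rnorm(n + 2 * fs), fs, band)
  x <- x[(fs + 1):(fs + n)]     # drop filter edges
  x / stats::sd(x)
}

#' Simulate one 4-channel EEG trial
#'
#' Deterministic given `(classLabel, seed)`. See [synthConfig()] for the
#' signal model. The global RNG state is left untouched.
#'
#' @param classLabel one of `config$classes`.
#' @param config a [synthConfig()].
#' @param seed integer seed.
#' @param subjectId subject identifier; the per-subject amplitude scale is
#'   derived deterministically from it.
#' @param trialId trial identifier.
#' @return an [EEGTrial-class].
#' @export
simulateTrial <- function(classLabel, config = synthConfig(), seed = 1L,
                          subjectId = "s01", trialId = NULL) {
  if (!classLabel %in% config$classes)
    stop("unknown class: ", classLabel)
  if (is.null(trialId)) trialId <- sprintf("%s_seed%d", classLabel, seed)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))

  fs <- config$fs
  n <- round(config$trialSeconds * fs)
  nBase <- round(config$baselineSeconds * fs)
  bands <- frequencyBands()
  ch <- frontalChannels()
  gains <- config$classGains[[classLabel]]

  # subject scale: deterministic in the subject id, independent of the trial
  set.seed(1000003L + sum(utf8ToInt(subjectId)))
  subjScale <- exp(stats::rnorm(1, 0, config$subjectSd))

  set.seed(seed)
  x <- matrix(0, n, 4, dimnames = list(NULL, ch))
  seg <- c(rep(1, nBase), rep(0, n - nBase))   # 1 = baseline portion
  for (bi in seq_len(nrow(bands))) {
    for (ci in seq_len(4)) {
      osc <- .bandOsc(n, fs, bands[bi, ])
      jitter <- exp(stats::rnorm(1, 0, config$jitterSd))
      amp <- config$oscAmp[[bands$band[bi]]] * jitter
      gain <- gains[bands$band[bi], ch[ci]]
      x[, ci] <- x[, ci] + osc * amp * (seg + (1 - seg) * gain)
    }
  }
  for (ci in seq_len(4)) {
    x[, ci] <- x[, ci] + .pinkNoise(n, fs, config$noiseSd, config$noiseExponent)
  }
  x <- x * subjScale
  EEGTrial(x, fs, baselineSeconds = config$baselineSeconds,
           label = classLabel, trialId = trialId, subjectId = subjectId)
}

#' Simulate a balanced multi-trial dataset
#'
#' `nTrialsPerClass` trials per class with distinct seeds, subjects cycling
#' over `config$nSubjects` to emulate a merged multi-subject dataset.
#'
#' @param config a [synthConfig()].
#' @param nTrialsPerClass trials per class.
#' @param seed base seed; trial k of the dataset uses `seed + k`.
#' @return list of [EEGTrial-class] objects.
#' @export
simulateDataset <- function(config = synthConfig(), nTrialsPerClass = 10L,
                            seed = 2024L) {
  if (nTrialsPerClass < 1) stop("nTrialsPerClass must be positive")
  trials <- list()
  k <- 0L
  for (cl in config$classes) {
    for (i in seq_len(nTrialsPerClass)) {
      k <- k + 1L
      subj <- sprintf("s%02d", (k - 1L) %% config$nSubjects + 1L)
      trials[[k]] <- simulateTrial(cl, config, seed = seed + k,
                                   subjectId = subj,
                                   trialId = sprintf("t%03d_%s", k, cl))
    }
  }
  trials
}

#' Extract window features for a list of trials
#'
#' Convenience wrapper: [windowFeatures()] per trial, bound into one
#' [FeatureSet-class].
#'
#' @param trials list of [EEGTrial-class].
#' @param ... passed to [windowFeatures()].
#' @return a [FeatureSet-class].
#' @export
datasetFeatures <- function(trials, ...) {
  bindFeatureSets(lapply(trials, windowFeatures, ...))
}

# ----------------------------------------------------------------- adapters

#' Channel names of the DEAP 32-channel (Geneva) montage
#' @return character vector of length 32.
#' @export
deapChannelNames <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

#' Channel names of the SEED 62-channel montage
#' @return character vector of length 62.
#' @export
seedChannelNames <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ",
    "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2",
    "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4",
    "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
    "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ",
    "O2", "CB2")
}

#' Load one subject of the DEAP preprocessed MATLAB release
#'
#' Reads the per-subject file (variables `data` 40 x 40 x 8064 and
#' `labels` 40 x 4), extracts the four frontal channels by name from the
#' Geneva montage, and assigns labels: binary high/low on one rating
#' dimension (rating > `threshold` is high) or the four valence-arousal
#' quadrants (`HVHA`, `HVLA`, `LVHA`, `LVLA`).
#'
#' @param path s01.mat-style file.
#' @param task `"quadrant"`, `"valence"` or `"arousal"`.
#' @param threshold rating cut (default 5; a rating of exactly 5 is low).
#' @param subjectId identifier stored in the trials.
#' @return list of 40 [EEGTrial-class] objects (fs = 128, 3 s baseline).
#' @export
readDeapSubject <- function(path, task = c("quadrant", "valence", "arousal"),
                            threshold = 5, subjectId = NULL) {
  task <- match.arg(task)
  vars <- readMat5(path)
  if (is.null(vars$data) || is.null(vars$labels))
    stop("malformed DEAP file: variables 'data' and 'labels' expected")
  d <- vars$data
  if (length(dim(d)) != 3 || dim(d)[2] < 32 || dim(d)[3] < 128 * 4)
    stop("malformed DEAP file: 'data' must be trials x channels x samples")
  idx <- match(toupper(frontalChannels()), toupper(deapChannelNames()))
  if (anyNA(idx)) stop("missing frontal channels in the DEAP montage")
  lab <- vars$labels
  if (is.null(subjectId))
    subjectId <- sub("\\.mat$", "", basename(path))
  lapply(seq_len(dim(d)[1]), function(t) {
    x <- t(d[t, idx, ])
    colnames(x) <- frontalChannels()
    v <- lab[t, 1]; a <- lab[t, 2]
    label <- switch(task,
      valence = if (v > threshold) "high" else "low",
      arousal = if (a > threshold) "high" else "low",
      quadrant = paste0(if (v > threshold) "HV" else "LV",
                        if (a > threshold) "HA" else "LA"))
    EEGTrial(x, fs = 128, baselineSeconds = 3, label = label,
             trialId = sprintf("%s_trial%02d", subjectId, t),
             subjectId = subjectId)
  })
}

#' Write a synthetic fixture in the DEAP on-disk layout
#'
#' Inverse of [readDeapSubject()] for round-trip tests: `data` is
#' trials x 40 channels x samples, `labels` trials x 4.
#'
#' @param data numeric array (trials x channels x samples).
#' @param labels numeric matrix (trials x 4 ratings).
#' @param path output .mat path.
#' @export
writeDeapFixture <- function(data, labels, path) {
  writeMat5(list(data = data, labels = labels), path)
}

#' Load one SEED session
#'
#' Reads every `*_eeg<k>` variable of a session file (62 x samples at
#' 200 Hz), selects the four frontal channels by name, applies the 4-45 Hz
#' band-pass used for this montage, and attaches the labels from the
#' companion label file (variable `label`, values -1/0/1 mapped to
#' negative/neutral/positive).
#'
#' @param path session .mat file.
#' @param labelsPath label.mat file (required; no silent default).
#' @param bandpass apply the 4-45 Hz filter on load (default TRUE).
#' @param subjectId identifier stored in the trials.
#' @return list of [EEGTrial-class] objects (fs = 200, 3 s baseline).
#' @export
readSeedSession <- function(path, labelsPath, bandpass = TRUE,
                            subjectId = NULL) {
  if (missing(labelsPath) || is.null(labelsPath) || !file.exists(labelsPath))
    stop("SEED label file is required and was not found")
  vars <- readMat5(path)
  eegNames <- grep("_eeg[0-9]+$", names(vars), value = TRUE)
  if (length(eegNames) == 0) stop("malformed SEED file: no *_eeg<k> variables")
  ord <- order(as.integer(sub(".*_eeg", "", eegNames)))
  eegNames <- eegNames[ord]
  labVars <- readMat5(labelsPath)
  if (is.null(labVars$label)) stop("malformed SEED label file: variable 'label' expected")
  labels <- as.numeric(labVars$label)
  if (length(labels) < length(eegNames))
    stop("label file has fewer entries than the session has trials")
  labelMap <- c("-1" = "negative", "0" = "neutral", "1" = "positive")
  idx <- match(toupper(frontalChannels()), toupper(seedChannelNames()))
  if (is.null(subjectId))
    subjectId <- sub("\\.mat$", "", basename(path))
  band <- data.frame(band = "broad", fLow = 4, fHigh = 45)
  lapply(seq_along(eegNames), function(t) {
    m <- vars[[eegNames[t]]]
    if (is.null(dim(m)) || nrow(m) < 62)
      stop("malformed SEED trial '", eegNames[t], "': expected 62 x samples")
    x <- t(m[idx, , drop = FALSE])
    colnames(x) <- frontalChannels()
    if (bandpass) x <- bandpassFilter(x, 200, band[1, ], band)
    lbl <- labelMap[as.character(labels[t])]
    if (is.na(lbl)) stop("unknown SEED label value: ", labels[t])
    EEGTrial(x, fs = 200, baselineSeconds = 3, label = lbl,
             trialId = sprintf("%s_trial%02d", subjectId, t),
             subjectId = subjectId)
  })
}

#' Write a synthetic fixture pair in the SEED on-disk layout
#'
#' @param trials list of numeric 62 x samples matrices.
#' @param labels numeric vector in \{-1, 0, 1\}.
#' @param path session .mat path.
#' @param labelsPath label .mat path.
#' @export
writeSeedFixture <- function(trials, labels, path, labelsPath) {
  vars <- stats::setNames(trials, sprintf("syn_eeg%d", seq_along(trials)))
  writeMat5(vars, path)
  writeMat5(list(label = as.numeric(labels)), labelsPath)
  invisible(path)
}
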