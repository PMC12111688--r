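test_that("baseline splitting follows the 3 s + 1 s window layout", {
  tr63 <- randomTrial(seconds = 63, seed = 1)
  sp <- splitBaseline(tr63)
  expect_length(sp$baseline, 3)
  expect_length(sp$experimental, 60)
  expect_identical(attr(sp$baseline[[1]], "start"), 1L)
  expect_identical(attr(sp$experimental[[1]], "start"), 3L * 128L + 1L)

  tr4 <- randomTrial(seconds = 4, seed = 2)
  sp4 <- splitBaseline(tr4)
  expect_length(sp4$baseline, 3)
  expect_length(sp4$experimental, 1)

  # a 2-s trial cannot hold its 3-s baseline
  x <- matrix(rnorm(2 * 128 * 4), ncol = 4,
              dimnames = list(NULL, frontalChannels()))
  expect_error(splitBaseline(EEGTrial(x, 128)), "baseline")
})

test_that("baseline mean is the arithmetic mean and rejects empties", {
  expect_equal(baselineMean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(baselineMean(rep(3.7, 5)), 3.7)
  set.seed(8)
  v <- rnorm(3)
  expect_equal(baselineMean(v), sum(v) / 3)
  expect_error(baselineMean(numeric(0)), "malformed")
})

test_that("min-max fit records column ranges and flags degenerate features", {
  set.seed(4)
  m <- matrix(rnorm(48 * 10), 48, 10, dimnames = list(featureNames(), NULL))
  st <- fitMinMax(m)
  expect_equal(st@fmin, apply(m, 1, min))
  expect_equal(st@fmax, apply(m, 1, max))

  m2 <- m
  m2[5, ] <- 1.5
  expect_warning(st2 <- fitMinMax(m2), "degenerate")
  expect_equal(unname(st2@fmin[5]), unname(st2@fmax[5]))
  expect_error(fitMinMax(m[, 1, drop = FALSE]), "at least 2")
})

test_that("min-max application scales, clips and zeroes degenerate columns", {
  expect_equal(applyMinMax(5, fmin = 0, fmax = 10), 0.5)
  expect_equal(applyMinMax(0, fmin = 0, fmax = 10), 0)
  expect_equal(applyMinMax(10, fmin = 0, fmax = 10), 1)
  expect_equal(applyMinMax(12, fmin = 0, fmax = 10), 1)   # clipped
  expect_equal(applyMinMax(-3, fmin = 0, fmax = 10), 0)   # clipped
  expect_equal(applyMinMax(7, fmin = 2, fmax = 2), 0)     # degenerate

  m <- matrix(c(0, 5, 10, 3, 3, 3), 2, 3, byrow = TRUE)
  out <- applyMinMax(m, fmin = c(0, 3), fmax = c(10, 3))
  expect_equal(out[1, ], c(0, 0.5, 1))
  expect_equal(out[2, ], c(0, 0, 0))
})

test_that("baseline subtraction and the corrected range hold end to end", {
  expect_equal(correctFeature(0.7, 0.4), 0.3)
  expect_equal(correctFeature(0.123, 0.123), 0)

  # the per-trial baseline mean rests on 3 windows, so its sampling noise
  # only averages out across many trials
  cfg <- neutralSynthConfig(trialSeconds = 13)
  trials <- lapply(1:48, function(k)
    simulateTrial("HVHA", cfg, seed = 400 + k, trialId = paste0("n", k)))
  fs <- datasetFeatures(trials)
  st <- fitMinMax(fs)
  corr <- correctFeatureSet(fs, st)
  cm <- SummarizedExperiment::assay(corr, "corrected")
  expect_true(all(cm >= -1 & cm <= 1))
  # trials statistically identical to their baselines: corrected ~ 0
  expect_lt(max(abs(rowMeans(cm))), 0.05)
})

test_that("corrected features are invariant to a constant offset within range", {
  tr <- randomTrial(seconds = 8, seed = 21)
  fs1 <- windowFeatures(tr)
  # offsetting every sample leaves band-limited features untouched (the
  # filters and demeaned Welch estimates remove DC), hence also the
  # corrected features after a refit
  tr2 <- EEGTrial(trialSamples(tr) + 40, samplingRate(tr), label = trialLabel(tr),
                  trialId = "t21b")
  fs2 <- windowFeatures(tr2)
  st1 <- fitMinMax(fs1)
  st2 <- fitMinMax(fs2)
  c1 <- SummarizedExperiment::assay(correctFeatureSet(fs1, st1), "corrected")
  c2 <- SummarizedExperiment::assay(correctFeatureSet(fs2, st2), "corrected")
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("normalization state survives a JSON round trip", {
  set.seed(2)
  m <- matrix(rnorm(48 * 6), 48, 6, dimnames = list(featureNames(), NULL))
  st <- fitMinMax(m, fittedOn = "fold03-train")
  path <- tempfile(fileext = ".json")
  writeNormalizationState(st, path)
  st2 <- readNormalizationState(path)
  expect_equal(st2@fmin, st@fmin)
  expect_equal(st2@fmax, st@fmax)
  expect_identical(st2@fittedOn, "fold03-train")
})
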