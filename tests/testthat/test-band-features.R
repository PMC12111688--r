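test_that("bandpass filter is linear, band-selective and rejects bad bands", {
  fs <- 128
  expect_equal(bandpassFilter(numeric(fs), fs, "alpha"), numeric(fs))

  x <- sineWindow(10, fs)                      # 10 Hz sits inside alpha
  inBand <- bandpassFilter(x, fs, "alpha")
  oracle <- dftBandVariance(x, fs, 8, 13)
  expect_lt(abs(var(inBand) - oracle) / oracle, 0.05)

  outBand <- bandpassFilter(x, fs, "gamma")
  expect_lt(var(outBand) / var(x), 0.01)
  expect_lt(dftBandVariance(x, fs, 30, 45) / var(x), 0.01)  # oracle agrees

  expect_error(bandpassFilter(x, fs, data.frame(band = "hf", fLow = 50, fHigh = 70)),
               "Nyquist")
})

test_that("Welch band power matches Parseval oracles", {
  fs <- 128
  zero <- numeric(fs)
  for (b in frequencyBands()$band)
    expect_equal(welchBandPower(zero, fs, b), 0)

  # unit sine at 10 Hz: power A^2/2, within Welch/Hann leakage
  x <- sineWindow(10, fs)
  expect_lt(abs(welchBandPower(x, fs, "alpha") - 0.5) / 0.5, 0.15)

  # white noise: total band power over a partition of [0, fs/2] ~ variance,
  # and the 4-45 Hz share is its frequency fraction (Monte Carlo, 100 draws)
  set.seed(7)
  broadband <- data.frame(band = "all", fLow = 4, fHigh = 45)
  ratio <- replicate(100, {
    v <- rnorm(fs)
    welchBandPower(v, fs, broadband[1, ], bands = broadband) / var(v)
  })
  expect_lt(abs(mean(ratio) - (45 - 4) / (fs / 2)), 0.1 * (45 - 4) / (fs / 2))

  expect_error(welchBandPower(noiseWindow(), fs, "alpha", channel = "Cz"),
               "unknown channel")
})

test_that("differential entropy follows the Gaussian closed form", {
  expect_equal(deFromVariance(1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(deFromVariance(1 / (2 * pi * exp(1))), 0)
  v <- 0.37
  expect_equal(deFromVariance(4 * v) - deFromVariance(v), log(2))
  expect_error(deFromVariance(0), "degenerate")
  expect_error(deFromVariance(-1), "degenerate")
})

test_that("band DE composes filter variance and the entropy form", {
  fs <- 128
  w <- read.csv(test_path("fixtures", "noise128.csv"))
  x <- as.matrix(w)
  colnames(x) <- frontalChannels()

  # independent two-step composition
  for (b in c("theta", "beta")) {
    filtered <- bandpassFilter(x[, "FP1"], fs, b)
    expect_equal(bandDE(x, fs, b, channel = "FP1"),
                 deFromVariance(var(filtered)), tolerance = 1e-12)
  }

  # amplitude doubling raises DE by ln 2 in every band
  for (b in frequencyBands()$band) {
    expect_equal(bandDE(2 * x, fs, b, channel = "AF3") -
                   bandDE(x, fs, b, channel = "AF3"),
                 log(2), tolerance = 1e-9)
  }
  expect_error(bandDE(matrix(0, fs, 4,
                             dimnames = list(NULL, frontalChannels())),
                      fs, "alpha", channel = "FP1"),
               "degenerate")
})

test_that("EVI and ASI satisfy their identities and bounds", {
  p <- 2.3
  expect_equal(evi(p, p), 0)
  expect_equal(evi(exp(1) * p, p), 1)
  expect_equal(asi(p, p), 0)
  expect_equal(asi(3 * p, p), 0.5)
  expect_equal(asi(p, 0), 1)
  set.seed(11)
  for (i in 1:25) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10)
    expect_equal(evi(a, b), -evi(b, a))
    expect_equal(asi(a, b), -asi(b, a))
    expect_true(abs(asi(a, b)) <= 1)
  }
  expect_error(evi(0, 1), "degenerate")
  expect_error(asi(0, 0), "degenerate")
})

test_that("extractFeatures yields 48 canonically ordered features", {
  fs <- 128
  w <- noiseWindow(seed = 3)
  f <- extractFeatures(w, fs)
  expect_length(f, 48)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), featureNames())

  # identical waveform on all channels: all 16 spatial features vanish
  v <- as.vector(noiseWindow(seed = 4)[, 1])
  same <- matrix(v, fs, 4, dimnames = list(NULL, frontalChannels()))
  fSame <- extractFeatures(same, fs)
  expect_equal(unname(fSame[33:48]), rep(0, 16), tolerance = 1e-10)

  # alpha amplitude 3x on FP1 vs FP2: ASI equals the asi() of the measured powers
  set.seed(5)
  alpha <- bandpassFilter(rnorm(fs * 3), fs, "alpha")[fs + 1:fs]
  x <- noiseWindow(seed = 6, sd = 0.05)
  x[, "FP1"] <- x[, "FP1"] + 3 * alpha
  x[, "FP2"] <- x[, "FP2"] + alpha
  f2 <- extractFeatures(x, fs)
  pows <- vapply(c("FP1", "FP2"), function(ch)
    welchBandPower(x, fs, "alpha", channel = ch), 0)
  expect_equal(unname(f2["asi_alpha_FP1.FP2"]), unname(asi(pows[1], pows[2])),
               tolerance = 1e-10)
  expect_gt(f2["asi_alpha_FP1.FP2"], 0.4)

  # every spatial slot holds the asi/evi of its named band and pair
  for (b in c("alpha", "beta", "gamma")) {
    for (pr in list(c("FP1", "FP2"), c("AF3", "AF4"), c("AF3", "FP2"))) {
      pw <- vapply(pr, function(ch) welchBandPower(x, fs, b, channel = ch), 0)
      expect_equal(unname(f2[paste0("asi_", b, "_", pr[1], ".", pr[2])]),
                   unname(asi(pw[1], pw[2])), tolerance = 1e-10)
    }
  }
  pwT <- vapply(c("FP1", "AF4"), function(ch)
    welchBandPower(x, fs, "theta", channel = ch), 0)
  expect_equal(unname(f2["evi_theta_FP1.AF4"]), unname(evi(pwT[1], pwT[2])),
               tolerance = 1e-10)

  # channel relabeling equivariance: values identical, positions follow names
  perm <- c("AF4", "FP1", "AF3", "FP2")
  wPerm <- w[, perm]
  expect_equal(extractFeatures(wPerm, fs), f)
})

test_that("windowFeatures builds a tagged FeatureSet over the trial", {
  tr <- randomTrial(seconds = 6, seed = 9)
  fs <- windowFeatures(tr)
  expect_s4_class(fs, "FeatureSet")
  cd <- SummarizedExperiment::colData(fs)
  expect_identical(dim(fs), c(48L, 6L))
  expect_identical(sum(cd$isBaseline), 3L)
  m <- SummarizedExperiment::assay(fs)
  expect_true(all(is.finite(m)))
  expect_identical(rownames(fs), featureNames())

  # window-scope filtering reproduces extractFeatures exactly
  fsW <- windowFeatures(tr, filterScope = "window")
  sp <- splitBaseline(tr)
  ref <- extractFeatures(sp$experimental[[2]], 128)
  expect_equal(SummarizedExperiment::assay(fsW)[, 5], ref, tolerance = 1e-12)
})
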