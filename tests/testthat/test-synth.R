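test_that("trial simulation is deterministic and correctly shaped", {
  cfg <- synthConfig()
  t1 <- simulateTrial("HVHA", cfg, seed = 5)
  t2 <- simulateTrial("HVHA", cfg, seed = 5)
  expect_identical(trialSamples(t1), trialSamples(t2))
  expect_identical(dim(trialSamples(t1)), c(63L * 128L, 4L))
  expect_identical(colnames(trialSamples(t1)), frontalChannels())
  expect_identical(trialLabel(t1), "HVHA")
  t3 <- simulateTrial("HVHA", cfg, seed = 6)
  expect_false(identical(trialSamples(t1), trialSamples(t3)))
  expect_error(simulateTrial("joy", cfg, seed = 1), "unknown class")
})

test_that("simulated datasets are balanced with distinct trials", {
  cfg <- synthConfig(trialSeconds = 5)
  trials <- simulateDataset(cfg, nTrialsPerClass = 3L, seed = 7L)
  expect_length(trials, 12)
  labs <- vapply(trials, trialLabel, "")
  expect_identical(as.integer(table(labs)), rep(3L, 4))
  sigs <- vapply(trials, function(t) sum(trialSamples(t)[1:100, 1]), 0)
  expect_identical(anyDuplicated(sigs), 0L)
  subj <- vapply(trials, function(t) t@subjectId, "")
  expect_gt(length(unique(subj)), 1)
})

test_that("a DEAP-shaped trial yields 3 baseline and 60 experimental windows", {
  tr <- simulateTrial("LVLA", synthConfig(), seed = 8)
  sp <- splitBaseline(tr)
  expect_length(sp$baseline, 3)
  expect_length(sp$experimental, 60)
})

test_that("a 3x alpha gain drives the measured asymmetry into its band", {
  cfg <- synthConfig()
  fsets <- lapply(1:5, function(k)
    windowFeatures(simulateTrial("HVHA", cfg, seed = 80 + k,
                                 trialId = paste0("a", k))))
  fs <- bindFeatureSets(fsets)
  cd <- SummarizedExperiment::colData(fs)
  m <- SummarizedExperiment::assay(fs)
  asiMean <- mean(m["asi_alpha_FP1.FP2", !cd$isBaseline])
  expect_gt(asiMean, 0.3)
  expect_lt(asiMean, 0.7)
  # the homologous AF pair carries the same lateralization
  expect_gt(mean(m["asi_alpha_AF3.AF4", !cd$isBaseline]), 0.3)
})

test_that("class-neutral configurations have zero-mean spatial features", {
  # per-trial in-band spectral share fluctuates (a few % for 63-s trials),
  # so the check needs both long trials and enough of them
  cfg <- neutralSynthConfig()
  fsets <- lapply(1:40, function(k)
    windowFeatures(simulateTrial(cfg$classes[(k %% 4) + 1], cfg, seed = 200 + k,
                                 trialId = paste0("n", k))))
  fs <- bindFeatureSets(fsets)
  cd <- SummarizedExperiment::colData(fs)
  m <- SummarizedExperiment::assay(fs)[33:48, !cd$isBaseline]
  expect_gte(ncol(m), 200)
  expect_lt(max(abs(rowMeans(m))), 0.05)
})

test_that("MAT5 numeric arrays survive a bit-level round trip", {
  set.seed(30)
  vars <- list(
    a = matrix(rnorm(12), 3, 4),
    longname_variable = array(rnorm(24), c(2, 3, 4)),
    v = rnorm(5)
  )
  path <- tempfile(fileext = ".mat")
  writeMat5(vars, path)
  back <- readMat5(path)
  expect_identical(names(back), names(vars))
  expect_identical(back$a, vars$a)
  expect_identical(back$longname_variable, vars$longname_variable)
  expect_identical(back$v, vars$v)
  junk <- tempfile()
  writeLines("not a mat file, just text padding to reach a header", junk)
  expect_error(readMat5(junk), "MAT")
})

test_that("the DEAP adapter inverts its fixture writer and codes labels", {
  set.seed(31)
  nTr <- 6; nS <- 128 * 4
  data <- array(rnorm(nTr * 40 * nS, sd = 5), c(nTr, 40, nS))
  # ratings: cover all four quadrants plus the 5.0 boundary
  labels <- rbind(c(9, 9, 5, 5), c(9, 2, 5, 5), c(2, 9, 5, 5),
                  c(2, 2, 5, 5), c(5, 5, 5, 5), c(6, 4, 1, 1))
  path <- tempfile(fileext = ".mat")
  writeDeapFixture(data, labels, path)
  trials <- readDeapSubject(path, task = "quadrant")
  expect_length(trials, nTr)
  expect_identical(vapply(trials, trialLabel, ""),
                   c("HVHA", "HVLA", "LVHA", "LVLA", "LVLA", "HVLA"))
  # bit-level round trip of the extracted channels (Fp1 is montage index 1)
  expect_identical(trialSamples(trials[[1]])[, "FP1"], data[1, 1, ])
  expect_identical(trialSamples(trials[[1]])[, "AF4"], data[1, 18, ])
  expect_identical(samplingRate(trials[[1]]), 128)

  valence <- readDeapSubject(path, task = "valence")
  expect_identical(trialLabel(valence[[5]]), "low")   # rating 5.0 with ">5"
  expect_identical(trialLabel(valence[[1]]), "high")
  expect_error(readDeapSubject(tempfile(fileext = ".mat")), "")
})

test_that("the SEED adapter inverts its fixture writer and maps labels", {
  set.seed(32)
  nS <- 200 * 4
  trialsRaw <- lapply(1:3, function(k) matrix(rnorm(62 * nS, sd = 5), 62, nS))
  labels <- c(-1, 0, 1)
  path <- tempfile(fileext = ".mat")
  labPath <- tempfile(fileext = ".mat")
  writeSeedFixture(trialsRaw, labels, path, labPath)
  trials <- readSeedSession(path, labPath, bandpass = FALSE)
  expect_length(trials, 3)
  expect_identical(vapply(trials, trialLabel, ""),
                   c("negative", "neutral", "positive"))
  expect_identical(samplingRate(trials[[1]]), 200)
  # channel selection by name: FP1 row 1, AF4 row 5 of the montage
  expect_identical(trialSamples(trials[[2]])[, "FP1"], trialsRaw[[2]][1, ])
  expect_identical(trialSamples(trials[[2]])[, "AF4"], trialsRaw[[2]][5, ])

  filt <- readSeedSession(path, labPath, bandpass = TRUE)
  expect_false(identical(trialSamples(filt[[1]]), trialSamples(trials[[1]])))

  expect_error(readSeedSession(path, tempfile()), "label file")
})
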