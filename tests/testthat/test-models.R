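# analytic per-layer parameter formulas, written independently of the code
analyticCount <- function(variant, numClasses = 4L,
                          filters = c(32L, 64L, 64L), ratio = 8L,
                          kanHidden = 128L, grid = 5L, k = 3L) {
  conv <- 9 * 3 * filters[1] + filters[1] +
    9 * filters[1] * filters[2] + filters[2] +
    9 * filters[2] * filters[3] + filters[3]
  bn <- 4 * sum(filters)
  dense <- 16 * filters[3] * 256 + 256
  head <- switch(variant,
    cnn = 256 * numClasses + numClasses,
    cnn_fcn = 256 * 128 + 128 + 128 * numClasses + numClasses,
    cnn_kan = 256 * kanHidden * (2 + grid + k) + kanHidden * numClasses + numClasses,
    cnn_kan_f2ca = 256 * kanHidden * (2 + grid + k) + kanHidden * numClasses + numClasses)
  att <- if (variant == "cnn_kan_f2ca")
    filters[3] * (filters[3] / ratio) + filters[3] / ratio +
      (filters[3] / ratio) * filters[3] + filters[3]
  else 0
  conv + bn + dense + head + att
}

test_that("the published ablation parameter totals are reproduced", {
  expect_identical(countParams(buildModel(modelConfig("cnn"))), 320388L)
  expect_identical(countParams(buildModel(modelConfig("cnn_fcn"))), 352772L)
  # audit against the printed decomposition
  audit <- layerSummary(buildModel(modelConfig("cnn")))
  byLayer <- setNames(audit$params, audit$layer)
  expect_identical(unname(byLayer["conv1_W"] + byLayer["conv1_b"]), 896L)
  expect_identical(unname(byLayer["conv2_W"] + byLayer["conv2_b"]), 18496L)
  expect_identical(unname(byLayer["conv3_W"] + byLayer["conv3_b"]), 36928L)
  expect_identical(unname(sum(byLayer[grep("^bn", names(byLayer))])), 640L)
  expect_identical(unname(byLayer["dense_W"] + byLayer["dense_b"]), 262400L)
  expect_identical(unname(byLayer["out_W"] + byLayer["out_b"]), 1028L)
})

test_that("every variant count equals the analytic per-layer sum", {
  for (v in c("cnn", "cnn_fcn", "cnn_kan", "cnn_kan_f2ca")) {
    for (nc in c(2L, 3L, 4L)) {
      m <- buildModel(modelConfig(v, numClasses = nc))
      expect_identical(countParams(m), as.integer(analyticCount(v, nc)),
                       info = paste(v, nc))
    }
  }
})

test_that("inserting the attention block adds exactly 1,096 parameters", {
  for (nc in c(2L, 4L)) {
    d <- countParams(buildModel(modelConfig("cnn_kan_f2ca", numClasses = nc))) -
      countParams(buildModel(modelConfig("cnn_kan", numClasses = nc)))
    expect_identical(d, 1096L)
  }
  expect_identical(f2caParamCount(64, 8), 1096L)
})

test_that("group fusion averages or concatenates embeddings", {
  v <- rnorm(6)
  g <- matrix(rep(v, each = 12), 12, 6)
  expect_equal(fuseGroup(g, "mean"), v)
  one <- matrix(v, 1, 6)
  expect_equal(fuseGroup(one, "mean"), v)
  expect_equal(fuseGroup(one, "concat"), v)
  set.seed(3)
  g2 <- matrix(rnorm(36), 6, 6)
  expect_equal(fuseGroup(g2, "mean"), colMeans(g2))
  expect_equal(fuseGroup(g2, "concat"), as.vector(t(g2)))
  expect_error(fuseGroup(list(1, 2), "mean"), "matrix")
})

test_that("inference yields deterministic simplex outputs", {
  m <- buildModel(modelConfig("cnn_kan_f2ca"), seed = 2)
  x <- randomBatch(5, seed = 4)
  p <- predictProba(m, x)
  expect_identical(dim(p), c(5L, 4L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)

  # duplicated rows give identical outputs; permutation permutes rows
  xdup <- x[c(1, 1, 2, 3, 2), , , , drop = FALSE]
  pd <- predictProba(m, xdup)
  expect_equal(pd[1, ], pd[2, ])
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predictProba(m, x[perm, , , , drop = FALSE]), p[perm, ],
               tolerance = 1e-7)
  expect_equal(predictProba(m, x), p)   # repeated call identical
})

test_that("the compiled forward pass matches the pure-R reference", {
  x <- randomBatch(6, seed = 5)
  for (v in c("cnn", "cnn_fcn", "cnn_kan", "cnn_kan_f2ca")) {
    m <- buildModel(modelConfig(v), seed = 6)
    expect_lt(max(abs(predictProba(m, x) - emoKAN:::.referenceForward(m, x))),
              5e-6)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(modelConfig("cnn", numClasses = 1), "numClasses")
  expect_error(modelConfig("cnn", convFilters = c(32L, 64L, 60L)), "divisible")
  expect_error(new("ModelConfig", variant = "mlp", numClasses = 4L,
                   convFilters = c(32L, 64L, 64L), dropoutConv = rep(0.5, 3),
                   dropoutFc = 0.5, l2 = 1e-3, f2caRatio = 8L, groupSize = 12L,
                   fusion = "mean", kan = list()), "variant")
})
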