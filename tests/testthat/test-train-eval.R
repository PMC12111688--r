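test_that("k-fold splitting is a seeded balanced partition", {
  f <- kfoldSplit(100, 10, seed = 2024)
  expect_identical(as.integer(table(f)), rep(10L, 10))
  expect_identical(kfoldSplit(100, 10, seed = 2024), f)     # deterministic
  expect_false(identical(kfoldSplit(100, 10, seed = 2025), f))
  f2 <- kfoldSplit(23, 4, seed = 1)
  expect_true(all(table(f2) %in% c(5L, 6L)))
  expect_identical(sort(unique(f2)), 1:4)
  expect_error(kfoldSplit(5, 10), "at least")
})

test_that("metrics match hand computation and the one-vs-rest oracle", {
  perfect <- computeMetrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)

  # binary counts TP=3, FP=1, FN=1, TN=5 for class "pos"
  yTrue <- c(rep("pos", 4), rep("neg", 6))
  yPred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m <- computeMetrics(yTrue, yPred)
  pos <- m$perClass[m$perClass$class == "pos", ]
  expect_equal(pos[, c("TP", "FP", "FN", "TN")],
               data.frame(TP = 3L, FP = 1L, FN = 1L, TN = 5L),
               ignore_attr = TRUE)
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.75)
  expect_equal(pos$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  # random 3-class problem vs brute-force one-vs-rest loop
  set.seed(60)
  yT <- sample(c("x", "y", "z"), 60, replace = TRUE)
  yP <- sample(c("x", "y", "z"), 60, replace = TRUE)
  got <- computeMetrics(yT, yP, classes = c("x", "y", "z"))
  brute <- sapply(c("x", "y", "z"), function(cl) {
    tp <- sum(yT == cl & yP == cl); fp <- sum(yT != cl & yP == cl)
    fn <- sum(yT == cl & yP != cl)
    prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    c(prec = prec, rec = rec,
      f1 = ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec)),
      support = tp + fn)
  })
  w <- brute["support", ] / sum(brute["support", ])
  expect_equal(got$precision, sum(w * brute["prec", ]))
  expect_equal(got$recall, sum(w * brute["rec", ]))
  expect_equal(got$f1, sum(w * brute["f1", ]))

  # identities: weighted recall == accuracy; label permutation invariance
  expect_equal(got$recall, got$accuracy)
  map <- c(x = "z", y = "x", z = "y")
  got2 <- computeMetrics(map[yT], map[yP])
  expect_equal(got2$accuracy, got$accuracy)
  expect_equal(got2$f1, got$f1)

  expect_error(computeMetrics(character(0), character(0)), "empty")
  expect_error(computeMetrics(c("a"), c("a", "b")), "mismatch")
})

test_that("training is seeded, and a zero learning rate freezes the weights", {
  x <- randomBatch(64, seed = 8)
  set.seed(9)
  y <- sample(c("p", "q"), 64, replace = TRUE)
  m <- buildModel(modelConfig("cnn", numClasses = 2), seed = 10)

  frozen <- trainFold(m, x, y, trainConfig(epochs = 2, batchSize = 32, lr = 0))
  for (nm in names(m@params)) {
    if (grepl("^bn._(mean|var)$", nm)) next      # moving stats still track
    expect_equal(modelParams(frozen)[[nm]], m@params[[nm]],
                 tolerance = 1e-7, ignore_attr = TRUE)
  }

  f1 <- trainFold(m, x, y, trainConfig(epochs = 3, batchSize = 32, seed = 5))
  f2 <- trainFold(m, x, y, trainConfig(epochs = 3, batchSize = 32, seed = 5))
  expect_identical(attr(f1, "history")$loss, attr(f2, "history")$loss)
  h <- attr(f1, "history")
  expect_identical(nrow(h), 3L)
  expect_true(all(is.finite(h$loss)))
})

test_that("a linearly separable two-class problem is learned quickly", {
  set.seed(11)
  n <- 240
  x <- randomBatch(n, seed = 12) * 0.2
  y <- rep(c("lo", "hi"), each = n / 2)
  x[y == "hi", , , 1] <- x[y == "hi", , , 1] + 0.8   # strong DE-plane offset
  m <- buildModel(modelConfig("cnn", numClasses = 2), seed = 13)
  fit <- trainFold(m, x, y, trainConfig(epochs = 30, batchSize = 32, seed = 14))
  h <- attr(fit, "history")
  expect_gt(h$accuracy[30], 0.95)
  expect_lt(h$loss[30], h$loss[1])
})

# double-precision replica of the engine's training-mode forward (cnn),
# used as the independent oracle for the compiled gradients
cnnLossR <- function(p, xm, y, l2, filters = c(4L, 8L, 8L)) {
  n <- ncol(xm)
  f <- filters
  neigh <- matrix(-1L, 16, 9)
  for (i in 0:3) for (j in 0:3) for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    if (ii >= 0 && ii < 4 && jj >= 0 && jj < 4)
      neigh[i + 4 * j + 1, (di + 1) + 3 * (dj + 1) + 1] <- ii + 4 * jj
  }
  conv <- function(A, W, b, cin, cout) {
    out <- matrix(0, cout, 16 * n)
    for (s in seq_len(n)) for (p0 in 1:16) {
      col <- numeric(9 * cin)
      for (o in 1:9) {
        q <- neigh[p0, o]
        if (q >= 0) col[((o - 1) * cin + 1):((o - 1) * cin + cin)] <-
            A[, (s - 1) * 16 + q + 1]
      }
      out[, (s - 1) * 16 + p0] <- as.vector(t(W) %*% col) + b
    }
    out
  }
  bnT <- function(A, g, be) {
    mu <- rowMeans(A); A <- A - mu
    va <- rowMeans(A^2)
    (A / sqrt(va + 1e-3)) * g + be
  }
  A <- pmax(bnT(conv(matrix(xm, 3, 16 * n), p$conv1_W, p$conv1_b, 3, f[1]),
                p$bn1_gamma, p$bn1_beta), 0)
  A <- pmax(bnT(conv(A, p$conv2_W, p$conv2_b, f[1], f[2]),
                p$bn2_gamma, p$bn2_beta), 0)
  A <- pmax(bnT(conv(A, p$conv3_W, p$conv3_b, f[2], f[3]),
                p$bn3_gamma, p$bn3_beta), 0)
  Xf <- matrix(A, 16 * f[3], n)
  H <- pmax(t(Xf) %*% p$dense_W + rep(p$dense_b, each = n), 0)
  Z <- H %*% p$out_W + rep(p$out_b, each = n)
  E <- exp(Z - apply(Z, 1, max)); P <- E / rowSums(E)
  -mean(log(P[cbind(seq_len(n), y + 1L)])) +
    l2 * (sum(p$conv1_W^2) + sum(p$conv2_W^2) + sum(p$conv3_W^2) +
          sum(p$dense_W^2) + sum(p$out_W^2))
}

test_that("compiled training gradients match a double-precision oracle", {
  set.seed(3)
  cfg <- modelConfig("cnn", numClasses = 3, convFilters = c(4L, 8L, 8L))
  m <- buildModel(cfg, seed = 5)
  n <- 7
  x <- randomBatch(n, seed = 15)
  xm <- emoKAN:::.batchToEngine(x)
  y <- sample(0:2, n, replace = TRUE)
  res <- emoKAN:::engine_loss_grad(m@params, emoKAN:::.engineConfig(cfg), xm, y)
  expect_equal(res$loss, cnnLossR(m@params, xm, y, cfg@l2), tolerance = 1e-5)
  eps <- 1e-5
  set.seed(16)
  for (nm in c("conv2_W", "bn1_beta", "bn3_gamma", "dense_W", "out_b")) {
    for (i in sample(length(m@params[[nm]]), 3)) {
      p1 <- m@params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m@params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (cnnLossR(p1, xm, y, cfg@l2) - cnnLossR(p2, xm, y, cfg@l2)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], fd, tolerance = 1e-3,
                   info = paste(nm, i))
    }
  }
})

test_that("cross-validation runs per-fold normalization without leakage", {
  cfg <- synthConfig(trialSeconds = 8)
  trials <- simulateDataset(cfg, nTrialsPerClass = 3L, seed = 50L)
  fs <- datasetFeatures(trials)
  cv <- runCV(fs, modelConfig("cnn"), trainConfig(epochs = 2, folds = 3,
                                                  batchSize = 16, seed = 99))
  expect_identical(nrow(cv$folds), 3L)
  expect_identical(sum(cv$folds$n), 4L * 3L * 5L)   # every window tested once
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_identical(cv$summary$metric, c("accuracy", "precision", "recall", "f1"))
  # weighted recall equals accuracy per fold
  expect_equal(cv$folds$recall, cv$folds$accuracy)
})
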