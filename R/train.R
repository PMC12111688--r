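#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.0005,
#' batch size 512, 200 epochs, L2 coefficient 0.001, seed 2024 and 10-fold
#' cross-validation. Desk-scale runs typically lower `epochs`.
#'
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs (no early stopping).
#' @param l2 L2 penalty coefficient.
#' @param seed seed driving data shuffling and weight initialization.
#' @param folds number of cross-validation folds.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(lr = 5e-4, batchSize = 512L, epochs = 200L,
                        l2 = 0.001, seed = 2024L, folds = 10L) {
  stopifnot(lr >= 0, batchSize >= 1, epochs >= 1, l2 >= 0, folds >= 2)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), l2 = l2,
                 seed = as.integer(seed), folds = as.integer(folds)),
            class = "trainConfig")
}

#' Seeded k-fold partition
#'
#' Shuffles the sample indices with the given seed and deals them into
#' `folds` folds whose sizes differ by at most one; every sample is
#' assigned to exactly one test fold.
#'
#' @param nSamples number of samples.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of length `nSamples` with fold labels 1..folds.
#' @export
kfoldSplit <- function(nSamples, folds = 10L, seed = 2024L) {
  if (nSamples < folds) stop("need at least as many samples as folds")
  set.seed(seed)
  ord <- sample.int(nSamples)
  fold <- integer(nSamples)
  fold[ord] <- rep(seq_len(folds), length.out = nSamples)
  fold
}

#' Train a model on one fold
#'
#' Minimizes categorical cross-entropy plus the L2 penalty with Adam,
#' shuffling each epoch. Training is deterministic given
#' `config$seed`. A non-finite loss aborts with a divergence error.
#'
#' @param model an initialized [EmotionNet-class].
#' @param x training batch, array (N, 4, 4, 3).
#' @param y training labels (character/factor, length N).
#' @param config a [trainConfig()].
#' @param valX,valY optional validation batch for per-epoch monitoring.
#' @param classes class-label ordering; defaults to sorted unique labels.
#' @return the trained [EmotionNet-class]; per-epoch history (loss,
#'   accuracy, and validation metrics when supplied) is attached as
#'   `attr(model, "history")`.
#' @export
trainFold <- function(model, x, y, config = trainConfig(), valX = NULL,
                      valY = NULL, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes) - 1L
  if (anyNA(yi)) stop("labels outside the class set")
  if (length(yi) == 0) stop("empty training data")
  xm <- .batchToEngine(x)
  vX <- if (!is.null(valX)) .batchToEngine(valX) else NULL
  vY <- if (!is.null(valY)) match(as.character(valY), classes) - 1L else NULL
  res <- engine_train(model@params, .engineConfig(model@config), xm, yi,
                      list(lr = config$lr, batchSize = config$batchSize,
                           epochs = config$epochs, seed = config$seed),
                      vX, vY)
  out <- methods::new("EmotionNet", config = model@config, params = res$params,
                      trained = TRUE, classes = classes)
  h <- res$history
  attr(out, "history") <- data.frame(
    epoch = seq_along(h$loss), loss = h$loss, accuracy = h$accuracy,
    valLoss = h$valLoss, valAccuracy = h$valAccuracy)
  out
}

#' Classification metrics with support-weighted averaging
#'
#' Accuracy plus per-class one-vs-rest precision, recall and F1, aggregated
#' by support-weighted averaging. For single-label multiclass problems the
#' weighted recall equals the accuracy (each sample contributes its own
#' class's recall).
#'
#' @param yTrue,yPred label vectors of equal length.
#' @param classes class ordering (default: sorted union).
#' @return list with `accuracy`, `precision`, `recall`, `f1` (weighted),
#'   `perClass` (data.frame with per-class counts and metrics) and
#'   `confusion` (table, rows = truth).
#' @examples
#' computeMetrics(c("a", "a", "b"), c("a", "b", "b"))$accuracy
#' @export
computeMetrics <- function(yTrue, yPred, classes = NULL) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) == 0) stop("empty input")
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (is.null(classes)) classes <- sort(unique(c(yTrue, yPred)))
  n <- length(yTrue)
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, support = tp + fn, TP = tp, FP = fp, FN = fn,
               TN = tn, precision = prec, recall = rec, f1 = f1)
  }))
  w <- perClass$support / sum(perClass$support)
  conf <- table(factor(yTrue, classes), factor(yPred, classes),
                dnn = c("truth", "prediction"))
  list(accuracy = mean(yTrue == yPred),
       precision = sum(w * perClass$precision),
       recall = sum(w * perClass$recall),
       f1 = sum(w * perClass$f1),
       perClass = perClass,
       confusion = conf)
}

#' 10-fold cross-validation over a window feature set
#'
#' Full protocol on a [FeatureSet-class] of raw (uncorrected) windows:
#' windows are shuffled and partitioned at the window level (`folds` folds,
#' seeded); within each fold the min-max normalization is fitted on the
#' training windows only, every trial's baseline mean is computed under
#' that state, corrected features are mapped to pseudo-RGB tensors, the
#' model is trained on the training windows and evaluated on the held-out
#' fold. Normalization can instead be fitted once on all windows
#' (`normalization = "global"`, the merged-dataset parity mode).
#'
#' @param featureSet raw [FeatureSet-class] including baseline windows.
#' @param config a [ModelConfig-class].
#' @param train a [trainConfig()].
#' @param normalization `"fold"` (no leakage) or `"global"`.
#' @param shuffleLabels permute trial labels before splitting (permutation
#'   null; expected accuracy is chance).
#' @param verbose print per-fold progress.
#' @return list with `folds` (data.frame: fold, n, accuracy, precision,
#'   recall, f1), `summary` (mean and sd of each metric), `perFold` (full
#'   metric objects) and `classes`.
#' @export
runCV <- function(featureSet, config = modelConfig(), train = trainConfig(),
                  normalization = c("fold", "global"), shuffleLabels = FALSE,
                  verbose = FALSE) {
  normalization <- match.arg(normalization)
  cd <- SummarizedExperiment::colData(featureSet)

  if (shuffleLabels) {
    # permutation null at the window level — the exchangeability unit of a
    # window classifier. (Permuting whole-trial labels instead leaves each
    # trial's windows label-consistent, and window-level folds then measure
    # trial memorization rather than chance.)
    set.seed(train$seed + 1L)
    wi <- which(!cd$isBaseline)
    cd$label[wi] <- cd$label[sample(wi)]
    SummarizedExperiment::colData(featureSet)$label <- cd$label
  }

  expIdx <- which(!cd$isBaseline)
  nExp <- length(expIdx)
  fold <- kfoldSplit(nExp, train$folds, train$seed)
  classes <- sort(unique(as.character(cd$label[expIdx])))

  globalState <- if (normalization == "global")
    fitMinMax(featureSet[, expIdx], fittedOn = "global") else NULL

  foldRows <- list()
  perFold <- list()
  for (f in seq_len(train$folds)) {
    testIdx <- expIdx[fold == f]
    trainIdx <- expIdx[fold != f]
    state <- if (is.null(globalState))
      fitMinMax(featureSet[, trainIdx], fittedOn = sprintf("fold%02d-train", f))
    else globalState
    corrected <- correctFeatureSet(featureSet, state)
    # corrected columns align with expIdx (experimental windows, same order)
    pos <- seq_len(nExp)
    batch <- featureSetToBatch(corrected, "corrected")
    xTest <- batch$x[pos[fold == f], , , , drop = FALSE]
    xTrain <- batch$x[pos[fold != f], , , , drop = FALSE]
    yTest <- batch$label[pos[fold == f]]
    yTrain <- batch$label[pos[fold != f]]

    model <- buildModel(config, seed = train$seed + f)
    cfgF <- train
    cfgF$seed <- train$seed + 1000L * f
    fitted <- trainFold(model, xTrain, yTrain, cfgF, classes = classes)
    pred <- predictClass(fitted, xTest)
    m <- computeMetrics(yTest, pred, classes)
    foldRows[[f]] <- data.frame(fold = f, n = length(yTest),
                                accuracy = m$accuracy, precision = m$precision,
                                recall = m$recall, f1 = m$f1)
    perFold[[f]] <- m
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.4f", f, train$folds, m$accuracy))
  }
  folds <- do.call(rbind, foldRows)
  summary <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1"),
    mean = vapply(c("accuracy", "precision", "recall", "f1"),
                  function(k) mean(folds[[k]]), 0),
    sd = vapply(c("accuracy", "precision", "recall", "f1"),
                function(k) stats::sd(folds[[k]]), 0),
    row.names = NULL)
  list(folds = folds, summary = summary, perFold = perFold, classes = classes)
}

#' Write cross-validation results to disk
#'
#' Per-fold metrics as CSV plus a JSON summary.
#'
#' @param cv result of [runCV()].
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @export
writeCVResults <- function(cv, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) utils::write.csv(cv$folds, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(summary = cv$summary, classes = cv$classes),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(cv)
}
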