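#' @rdname countParams
#' @export
setGeneric("countParams", function(model) standardGeneric("countParams"))

#' @rdname predictProba
#' @export
setGeneric("predictProba", function(model, x) standardGeneric("predictProba"))

.glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# conv kernels are stored as (9 * Cin) x Cout matrices; row index encodes
# (cin, di, dj) with cin fastest and (di, dj) in {-1,0,1}^2, dj slowest.
.convW <- function(cin, cout) {
  w <- .glorot(9 * cin, 9 * cout, c(9 * cin, cout))
  attr(w, "kernel") <- c(3L, 3L, cin, cout)
  w
}

#' Assemble one of the four ablation architectures
#'
#' Backbone: three 3x3 same-padding convolutions (32, 64, 64 filters), each
#' followed by batch normalization, ReLU and dropout (0.5, 0.4, 0.3); the
#' full variant inserts a frequency-channel attention block after the third
#' convolution. The 4x4x64 map is flattened (1024) into a 256-unit dense
#' layer with dropout 0.5, then the variant head: `cnn` a softmax dense
#' layer; `cnn_fcn` dense 128 + softmax dense; `cnn_kan` and
#' `cnn_kan_f2ca` a KAN(256 -> 128) layer + softmax dense.
#'
#' @param config a [ModelConfig-class].
#' @param seed optional integer seed for the weight initialization.
#' @return an [EmotionNet-class] with freshly initialized parameters.
#' @examples
#' countParams(buildModel(modelConfig("cnn")))       # 320388
#' countParams(buildModel(modelConfig("cnn_fcn")))   # 352772
#' @export
buildModel <- function(config, seed = NULL) {
  stopifnot(methods::is(config, "ModelConfig"))
  if (!is.null(seed)) set.seed(seed)
  f <- config@convFilters
  C <- config@numClasses
  flat <- 16L * f[3]

  bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                         mean = rep(0, c), var = rep(1, c))
  p <- list(
    conv1_W = .convW(3L, f[1]), conv1_b = rep(0, f[1]),
    conv2_W = .convW(f[1], f[2]), conv2_b = rep(0, f[2]),
    conv3_W = .convW(f[2], f[3]), conv3_b = rep(0, f[3])
  )
  for (i in 1:3) {
    b <- bn(f[i])
    p[[paste0("bn", i, "_gamma")]] <- b$gamma
    p[[paste0("bn", i, "_beta")]] <- b$beta
    p[[paste0("bn", i, "_mean")]] <- b$mean
    p[[paste0("bn", i, "_var")]] <- b$var
  }
  if (config@variant == "cnn_kan_f2ca") {
    h <- f[3] %/% config@f2caRatio
    p$f2ca_W1 <- .glorot(f[3], h, c(h, f[3]))
    p$f2ca_b1 <- rep(0, h)
    p$f2ca_W2 <- .glorot(h, f[3], c(f[3], h))
    p$f2ca_b2 <- rep(0, f[3])
  }
  p$dense_W <- .glorot(flat, 256L, c(flat, 256L))
  p$dense_b <- rep(0, 256L)

  if (config@variant == "cnn") {
    p$out_W <- .glorot(256L, C, c(256L, C)); p$out_b <- rep(0, C)
  } else if (config@variant == "cnn_fcn") {
    p$fc2_W <- .glorot(256L, 128L, c(256L, 128L)); p$fc2_b <- rep(0, 128L)
    p$out_W <- .glorot(128L, C, c(128L, C)); p$out_b <- rep(0, C)
  } else {
    kc <- config@kan
    ki <- kanInit(256L, kc$hidden, kc$gridSize, kc$splineOrder,
                  kc$gridLo, kc$gridHi)
    p$kan_Wbase <- ki$Wbase
    p$kan_Wspline <- ki$Wspline
    p$kan_scaler <- ki$scaler
    p$out_W <- .glorot(kc$hidden, C, c(kc$hidden, C)); p$out_b <- rep(0, C)
  }
  methods::new("EmotionNet", config = config, params = p, trained = FALSE,
               classes = character())
}

#' Per-layer parameter audit
#'
#' One row per parameter array: name, shape and size. Batch-norm moving
#' statistics are included (the convention under which the `cnn` variant
#' totals 320,388: 896 + 18,496 + 36,928 convolutions, 640 batch norm,
#' 262,400 + 1,028 dense).
#'
#' @param model an [EmotionNet-class].
#' @return data.frame with columns `layer`, `shape`, `params`.
#' @export
layerSummary <- function(model) {
  p <- model@params
  data.frame(
    layer = names(p),
    shape = vapply(p, function(a) paste(if (is.null(dim(a))) length(a) else dim(a),
                                        collapse = "x"), ""),
    params = vapply(p, length, 0L),
    row.names = NULL
  )
}

#' Total parameter count
#'
#' Sum over all parameter arrays, batch-norm moving statistics included.
#'
#' @param model an [EmotionNet-class].
#' @return integer total.
#' @export
setMethod("countParams", "EmotionNet", function(model) {
  sum(vapply(model@params, length, 0L))
})

#' Write an architecture summary as JSON
#'
#' @param model an [EmotionNet-class].
#' @param path output path.
#' @export
writeModelSummary <- function(model, path) {
  jsonlite::write_json(
    list(variant = model@config@variant,
         numClasses = model@config@numClasses,
         totalParams = countParams(model),
         layers = layerSummary(model)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fuse the embeddings of a sample group
#'
#' The network processes windows in groups of 12 that share a trial label;
#' their per-window embeddings can be fused into a single vector before the
#' classification head — `mean` averages them (length d), `concat`
#' concatenates them (length groupSize * d).
#'
#' @param group groupSize x d numeric matrix (one row per window embedding).
#' @param mode `"mean"` or `"concat"`.
#' @return numeric vector.
#' @export
fuseGroup <- function(group, mode = c("mean", "concat")) {
  mode <- match.arg(mode)
  if (!is.matrix(group)) stop("group must be a matrix of stacked embeddings")
  if (mode == "mean") colMeans(group) else as.vector(t(group))
}

.engineConfig <- function(config) {
  list(
    variant = match(config@variant, c("cnn", "cnn_fcn", "cnn_kan", "cnn_kan_f2ca")) - 1L,
    filters = as.integer(config@convFilters),
    numClasses = as.integer(config@numClasses),
    dropoutConv = as.numeric(config@dropoutConv),
    dropoutFc = as.numeric(config@dropoutFc),
    l2 = as.numeric(config@l2),
    ratio = as.integer(config@f2caRatio),
    kanHidden = as.integer(config@kan$hidden),
    kanGridSize = as.integer(config@kan$gridSize),
    kanOrder = as.integer(config@kan$splineOrder),
    kanLo = as.numeric(config@kan$gridLo),
    kanHi = as.numeric(config@kan$gridHi)
  )
}

# (batch, 4, 4, 3) array -> 48 x N matrix in engine order
# (channel fastest, then row, then column)
.batchToEngine <- function(x) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 4L, all(dim(x)[2:4] == c(4, 4, 3)))
  m <- aperm(x, c(4, 2, 3, 1))
  dim(m) <- c(48L, dim(x)[1])
  m
}

#' Class probabilities for a batch of pseudo-RGB images
#'
#' Inference-mode forward pass (dropout off, batch norm uses moving
#' statistics); rows lie on the probability simplex.
#'
#' @param model a built (and usually trained) [EmotionNet-class].
#' @param x array of shape (N, 4, 4, 3), or a single 4x4x3 image.
#' @return N x numClasses matrix of probabilities; columns are named after
#'   the training classes when the model has been trained.
#' @export
setMethod("predictProba", "EmotionNet", function(model, x) {
  xm <- .batchToEngine(x)
  probs <- engine_forward(model@params, .engineConfig(model@config), xm)
  if (length(model@classes)) colnames(probs) <- model@classes
  probs
})

#' Predicted class labels
#'
#' @param model a trained [EmotionNet-class].
#' @param x batch array (N, 4, 4, 3).
#' @return character (or integer index) vector of argmax classes.
#' @export
predictClass <- function(model, x) {
  probs <- predictProba(model, x)
  idx <- max.col(probs, ties.method = "first")
  if (length(model@classes)) model@classes[idx] else idx
}

# Pure-R inference-mode forward pass; slow, used to cross-check the
# compiled engine on small batches.
.referenceForward <- function(model, x) {
  cfg <- model@config
  p <- model@params
  f <- cfg@convFilters
  xm <- .batchToEngine(x)           # 48 x N
  n <- ncol(xm)
  eps <- 1e-3

  # neighbor index per position p0 = i + 4j and offset o = (di+1) + 3(dj+1)
  neigh <- matrix(-1L, 16, 9)
  for (i in 0:3) for (j in 0:3) for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    if (ii >= 0 && ii < 4 && jj >= 0 && jj < 4)
      neigh[i + 4 * j + 1, (di + 1) + 3 * (dj + 1) + 1] <- ii + 4 * jj
  }
  conv <- function(A, W, b, cin, cout) {
    # A: cin x (16 n); returns cout x (16 n)
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
  bnRelu <- function(A, i) {
    g <- p[[paste0("bn", i, "_gamma")]]; be <- p[[paste0("bn", i, "_beta")]]
    mu <- p[[paste0("bn", i, "_mean")]]; va <- p[[paste0("bn", i, "_var")]]
    pmax((A - mu) / sqrt(va + eps) * g + be, 0)
  }
  A0 <- matrix(xm, 3L, 16L * n)     # channels x (position, sample)
  A <- bnRelu(conv(A0, p$conv1_W, p$conv1_b, 3L, f[1]), 1)
  A <- bnRelu(conv(A, p$conv2_W, p$conv2_b, f[1], f[2]), 2)
  A <- bnRelu(conv(A, p$conv3_W, p$conv3_b, f[2], f[3]), 3)
  if (cfg@variant == "cnn_kan_f2ca") {
    for (s in seq_len(n)) {
      cols <- ((s - 1) * 16 + 1):((s - 1) * 16 + 16)
      v1 <- rowMeans(A[, cols, drop = FALSE])
      sW <- excite(fourierDescriptor(v1), p$f2ca_W1, p$f2ca_b1, p$f2ca_W2, p$f2ca_b2)
      A[, cols] <- A[, cols] * sW
    }
  }
  Xf <- matrix(A, 16L * f[3], n)    # flatten: channel fastest, then position
  H <- pmax(t(Xf) %*% p$dense_W + rep(p$dense_b, each = n), 0)
  if (cfg@variant == "cnn") {
    Z <- H %*% p$out_W + rep(p$out_b, each = n)
  } else if (cfg@variant == "cnn_fcn") {
    H2 <- pmax(H %*% p$fc2_W + rep(p$fc2_b, each = n), 0)
    Z <- H2 %*% p$out_W + rep(p$out_b, each = n)
  } else {
    kp <- list(Wbase = p$kan_Wbase, Wspline = p$kan_Wspline,
               scaler = p$kan_scaler,
               grid = kanGrid(cfg@kan$gridSize, cfg@kan$splineOrder,
                              cfg@kan$gridLo, cfg@kan$gridHi),
               k = cfg@kan$splineOrder)
    H2 <- kanForward(pmin(pmax(H, cfg@kan$gridLo), cfg@kan$gridHi), kp)
    Z <- H2 %*% p$out_W + rep(p$out_b, each = n)
  }
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}
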