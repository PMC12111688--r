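#' Knot vector for the KAN spline grid
#'
#' Uniform knots spanning `[lo, hi]` with `gridSize` intervals, extended by
#' `k` knots on each side so that `gridSize + k` B-spline basis functions
#' of order `k` are supported on the span.
#'
#' @param gridSize number of grid intervals (default 5).
#' @param k spline polynomial order (default 3, cubic).
#' @param lo,hi grid span (default \[-1, 1\]: corrected features are bounded).
#' @return numeric knot vector of length `gridSize + 2k + 1`.
#' @export
kanGrid <- function(gridSize = 5L, k = 3L, lo = -1, hi = 1) {
  if (gridSize < 1L || k < 0L || hi <= lo) stop("invalid spline grid configuration")
  h <- (hi - lo) / gridSize
  lo + h * seq(-k, gridSize + k)
}

#' B-spline basis values at a point (Cox-de Boor recursion)
#'
#' Evaluates all `length(grid) - k - 1` basis functions of order `k` on the
#' knot vector `grid` at each value of `x`. For the canonical KAN grid this
#' is `gridSize + k` functions; inside the span they sum to 1 (partition of
#' unity). Points outside the span are clamped to it first (avoids
#' zero-basis dead zones).
#'
#' @param x numeric vector of evaluation points.
#' @param grid non-decreasing knot vector.
#' @param k spline order (k = 0 gives indicator functions).
#' @return matrix, `length(x)` rows x `length(grid) - k - 1` columns.
#' @export
bsplineBasis <- function(x, grid, k) {
  if (any(diff(grid) < 0)) stop("invalid spline grid: knots must be non-decreasing")
  nb <- length(grid) - k - 1L
  if (nb < 1L) stop("invalid spline grid: too few knots for order ", k)
  lo <- grid[k + 1L]
  hi <- grid[length(grid) - k]
  x <- pmin(pmax(x, lo), hi)
  n <- length(x)
  # order 0: half-open indicator on [t_j, t_{j+1}), closed at the top span end
  B <- matrix(0, n, length(grid) - 1L)
  for (j in seq_len(length(grid) - 1L)) {
    B[, j] <- as.numeric(x >= grid[j] & x < grid[j + 1L])
  }
  topCell <- max(which(grid < hi))
  B[x == hi, ] <- 0
  B[x == hi, topCell] <- 1
  if (k > 0) {
    for (ord in seq_len(k)) {
      nbo <- length(grid) - ord - 1L
      Bn <- matrix(0, n, nbo)
      for (j in seq_len(nbo)) {
        d1 <- grid[j + ord] - grid[j]
        d2 <- grid[j + ord + 1L] - grid[j + 1L]
        t1 <- if (d1 > 0) (x - grid[j]) / d1 * B[, j] else 0
        t2 <- if (d2 > 0) (grid[j + ord + 1L] - x) / d2 * B[, j + 1L] else 0
        Bn[, j] <- t1 + t2
      }
      B <- Bn
    }
  }
  B[, seq_len(nb), drop = FALSE]
}

.silu <- function(x) x / (1 + exp(-x))

#' Base path of the KAN layer
#'
#' `SiLU(X) %*% Wbase`: a SiLU-activated linear map that carries the smooth
#' global trend of the layer, in parallel with the spline path.
#'
#' @param X batch x dIn matrix.
#' @param Wbase dIn x dOut weight matrix.
#' @return batch x dOut matrix.
#' @export
baseOutput <- function(X, Wbase) {
  if (ncol(X) != nrow(Wbase)) stop("shape mismatch between X and Wbase")
  .silu(X) %*% Wbase
}

#' Initialize KAN layer parameters
#'
#' @param dIn,dOut layer dimensions.
#' @param gridSize,k,lo,hi spline grid settings (see [kanGrid()]).
#' @param baseSd,splineSd init scales for the base weights and spline
#'   coefficients; the spline scaler starts at 1.
#' @return list with `Wbase` (dIn x dOut), `Wspline` (dIn x dOut x nCoef),
#'   `scaler` (dIn x dOut), `grid`, `k`.
#' @export
kanInit <- function(dIn, dOut, gridSize = 5L, k = 3L, lo = -1, hi = 1,
                    baseSd = sqrt(2 / (dIn + dOut)), splineSd = 0.1) {
  nCoef <- gridSize + k
  list(
    Wbase = matrix(stats::rnorm(dIn * dOut, sd = baseSd), dIn, dOut),
    Wspline = array(stats::rnorm(dIn * dOut * nCoef, sd = splineSd),
                    c(dIn, dOut, nCoef)),
    scaler = matrix(1, dIn, dOut),
    grid = kanGrid(gridSize, k, lo, hi),
    k = as.integer(k)
  )
}

#' Spline path of the KAN layer
#'
#' For every (input, output) edge, a learnable univariate spline
#' `sum_k B_k(x_i) * Wspline[i, o, k]`, scaled by the per-edge adaptive
#' scaler and summed over inputs.
#'
#' @param X batch x dIn matrix.
#' @param params KAN parameter list (see [kanInit()]).
#' @return batch x dOut matrix.
#' @export
splineOutput <- function(X, params) {
  dIn <- dim(params$Wspline)[1]
  dOut <- dim(params$Wspline)[2]
  nCoef <- dim(params$Wspline)[3]
  if (ncol(X) != dIn) stop("shape mismatch between X and Wspline")
  out <- matrix(0, nrow(X), dOut)
  for (i in seq_len(dIn)) {
    B <- bsplineBasis(X[, i], params$grid, params$k)      # batch x nCoef
    W <- matrix(params$Wspline[i, , ], dOut, nCoef)        # dOut x nCoef
    out <- out + (B %*% t(W)) * rep(params$scaler[i, ], each = nrow(X))
  }
  out
}

#' KAN layer forward pass
#'
#' Sum of the SiLU base path and the scaled spline path:
#' `SiLU(X) %*% Wbase + splineOutput(X)`.
#'
#' @param X batch x dIn matrix.
#' @param params KAN parameter list.
#' @return batch x dOut matrix.
#' @export
kanForward <- function(X, params) {
  baseOutput(X, params$Wbase) + splineOutput(X, params)
}

#' Analytic gradients of the KAN layer
#'
#' Returns the gradient of `sum(kanForward(X, params) * dOut)` with respect
#' to X, Wbase, Wspline and the scaler; used for gradient-correctness
#' checks of the training engine.
#'
#' @param X batch x dIn matrix.
#' @param params KAN parameter list.
#' @param dOut upstream gradient, batch x dOut matrix.
#' @return list with `dX`, `dWbase`, `dWspline`, `dScaler`.
#' @export
kanGradient <- function(X, params, dOut) {
  dIn <- dim(params$Wspline)[1]
  dOutDim <- dim(params$Wspline)[2]
  nCoef <- dim(params$Wspline)[3]
  k <- params$k
  grid <- params$grid
  lo <- grid[k + 1L]; hi <- grid[length(grid) - k]

  sig <- 1 / (1 + exp(-X))
  siluX <- X * sig
  dSilu <- sig * (1 + X * (1 - sig))
  dWbase <- t(siluX) %*% dOut
  dX <- (dOut %*% t(params$Wbase)) * dSilu

  dWspline <- array(0, c(dIn, dOutDim, nCoef))
  dScaler <- matrix(0, dIn, dOutDim)
  inSpan <- X > lo & X < hi   # clamp kills the derivative outside the span
  for (i in seq_len(dIn)) {
    B <- bsplineBasis(X[, i], grid, k)
    Bl <- bsplineBasis(X[, i], grid, k - 1L)               # one order lower
    dB <- matrix(0, nrow(X), nCoef)
    for (j in seq_len(nCoef)) {
      d1 <- grid[j + k] - grid[j]
      d2 <- grid[j + k + 1L] - grid[j + 1L]
      if (d1 > 0) dB[, j] <- dB[, j] + k / d1 * Bl[, j]
      if (d2 > 0) dB[, j] <- dB[, j] - k / d2 * Bl[, j + 1L]
    }
    W <- matrix(params$Wspline[i, , ], dOutDim, nCoef)
    sc <- params$scaler[i, ]
    g <- dOut * rep(sc, each = nrow(X))                    # batch x dOut
    dWspline[i, , ] <- t(g) %*% B
    S <- B %*% t(W)                                        # batch x dOut
    dScaler[i, ] <- colSums(dOut * S)
    dX[, i] <- dX[, i] + ((g %*% W) * dB) %*% rep(1, nCoef) * inSpan[, i]
  }
  list(dX = dX, dWbase = dWbase, dWspline = dWspline, dScaler = dScaler)
}

#' Parameter count of a KAN layer
#'
#' Base weights + spline coefficients + adaptive scaler:
#' `dIn * dOut * (2 + gridSize + k)`.
#'
#' @param dIn,dOut layer dimensions.
#' @param gridSize,k spline grid settings.
#' @return integer.
#' @examples
#' kanParamCount(256, 128, 5, 3)   # 327680
#' @export
kanParamCount <- function(dIn, dOut, gridSize = 5L, k = 3L) {
  if (dIn < 1 || dOut < 1 || gridSize < 1 || k < 0) stop("arguments must be positive")
  as.integer(dIn * dOut * (2 + gridSize + k))
}
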