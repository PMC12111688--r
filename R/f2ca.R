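#' Global average pooling over the spatial axes
#'
#' @param map H x W x C activation array.
#' @return numeric vector of length C (per-channel spatial mean).
#' @export
globalAveragePool <- function(map) {
  stopifnot(length(dim(map)) == 3)
  apply(map, 3, mean)
}

#' Fourier descriptor of a channel vector
#'
#' Real part of the full-length discrete Fourier transform of the pooled
#' channel vector (length preserved: C in, C out; unnormalized transform).
#' Replacing the identity on the pooled vector with this descriptor is what
#' distinguishes the frequency-channel attention block from plain
#' squeeze-and-excitation: it mixes all channels into each descriptor
#' entry, exposing global variation patterns across the channel axis.
#'
#' @param v1 numeric vector of length C.
#' @return numeric vector of length C.
#' @examples
#' fourierDescriptor(rep(2, 8))   # 16 0 0 0 0 0 0 0
#' @export
fourierDescriptor <- function(v1) {
  Re(stats::fft(v1))
}

#' Excitation: bottleneck MLP with sigmoid gate
#'
#' `sigmoid(W2 %*% relu(W1 %*% freg + b1) + b2)`: compresses the C-length
#' descriptor by the ratio r, restores it, and gates with a sigmoid so each
#' attention weight lies in (0, 1).
#'
#' @param freg descriptor vector (length C).
#' @param W1 (C/r) x C weight matrix, `b1` its bias (length C/r).
#' @param W2 C x (C/r) weight matrix, `b2` its bias (length C).
#' @return attention weights in (0,1), length C.
#' @export
excite <- function(freg, W1, b1, W2, b2) {
  if (ncol(W1) != length(freg) || ncol(W2) != nrow(W1) ||
      length(b1) != nrow(W1) || length(b2) != nrow(W2))
    stop("excitation weight dimensions are inconsistent")
  h <- pmax(as.vector(W1 %*% freg) + b1, 0)
  z <- as.vector(W2 %*% h) + b2
  1 / (1 + exp(-z))
}

#' Re-weight an activation map by per-channel attention
#'
#' `y[i,j,c] = x[i,j,c] * s[c]` (broadcast multiply over the channel axis).
#'
#' @param map H x W x C array.
#' @param s attention weights, length C.
#' @return array of the same shape.
#' @export
reweight <- function(map, s) {
  d <- dim(map)
  if (length(s) != d[3]) stop("attention length must equal the channel count")
  sweep(map, 3, s, `*`)
}

#' Full frequency-channel attention block
#'
#' Composition pool -> Fourier descriptor -> excitation -> re-weight on an
#' H x W x C activation map.
#'
#' @param map H x W x C array.
#' @param params list with `W1`, `b1`, `W2`, `b2` (see [excite()]).
#' @return re-weighted map of the same shape.
#' @export
f2caForward <- function(map, params) {
  v1 <- globalAveragePool(map)
  s <- excite(fourierDescriptor(v1), params$W1, params$b1, params$W2, params$b2)
  reweight(map, s)
}

#' Parameter count of the attention block
#'
#' Two biased dense layers C -> C/r -> C:
#' `(C*(C/r) + C/r) + ((C/r)*C + C)`. For C = 64, r = 8 this is 1,096.
#'
#' @param C channel count.
#' @param r bottleneck ratio (C must be divisible by r).
#' @return integer parameter count.
#' @examples
#' f2caParamCount(64, 8)   # 1096
#' @export
f2caParamCount <- function(C, r = 8) {
  if (C %% r != 0) stop("C must be divisible by r")
  h <- C %/% r
  as.integer(C * h + h + h * C + C)
}
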