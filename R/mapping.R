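#' Arrange one 16-feature block as a 4x4 plane
#'
#' Row-major fill of the canonical block order: rows are the four bands
#' (theta, alpha, beta, gamma), columns the four channels (DE/PSD planes)
#' or the four channel pairs (spatial plane, whose theta row holds the EVI
#' values and remaining rows the ASI values).
#'
#' @param block numeric vector of exactly 16 values in canonical order.
#' @return 4x4 numeric matrix.
#' @examples
#' buildPlane(0:15)[1, ]   # 0 1 2 3
#' @export
buildPlane <- function(block) {
  if (length(block) != 16L)
    stop("plane block must have exactly 16 values, got ", length(block))
  matrix(as.numeric(block), nrow = 4, ncol = 4, byrow = TRUE)
}

#' Stack the three feature planes into a pseudo-RGB image
#'
#' @param dePlane,psdPlane,spatialPlane 4x4 matrices.
#' @return 4x4x3 array; plane order along the third axis is
#'   (DE, PSD, EVI-ASI).
#' @export
stackPseudoRGB <- function(dePlane, psdPlane, spatialPlane) {
  planes <- list(dePlane, psdPlane, spatialPlane)
  if (!all(vapply(planes, function(p) is.matrix(p) && all(dim(p) == c(4, 4)), TRUE)))
    stop("each plane must be a 4x4 matrix")
  array(c(dePlane, psdPlane, spatialPlane), dim = c(4, 4, 3),
        dimnames = list(frequencyBands()$band, NULL, c("de", "psd", "spatial")))
}

#' Map a 48-feature vector to its pseudo-RGB image
#'
#' @param features named numeric vector in canonical [featureNames()] order.
#' @return 4x4x3 array.
#' @export
pseudoRGB <- function(features) {
  if (length(features) != 48L) stop("expected 48 features")
  stackPseudoRGB(buildPlane(features[1:16]),
                 buildPlane(features[17:32]),
                 buildPlane(features[33:48]))
}

#' The feature-to-tensor layout map
#'
#' Bijection between the 48 canonical feature names and pseudo-RGB tensor
#' coordinates (row, col, plane). `featureLayout()[i, ]` locates
#' `featureNames()[i]`.
#'
#' @return data.frame with columns `feature`, `row`, `col`, `plane`.
#' @export
featureLayout <- function() {
  nm <- featureNames()
  idx <- seq_len(48L) - 1L
  block <- idx %/% 16L          # 0 de, 1 psd, 2 spatial
  within <- idx %% 16L
  data.frame(feature = nm,
             row = within %/% 4L + 1L,
             col = within %% 4L + 1L,
             plane = block + 1L,
             stringsAsFactors = FALSE)
}

#' Batch pseudo-RGB images into a 4D tensor
#'
#' @param windows list of 4x4x3 arrays.
#' @return array of shape (batch, 4, 4, 3), input order preserved.
#' @export
batchTensors <- function(windows) {
  if (length(windows) == 0) stop("empty batch")
  ok <- vapply(windows, function(w) length(dim(w)) == 3 && all(dim(w) == c(4, 4, 3)), TRUE)
  if (!all(ok)) stop("every window must be a 4x4x3 array")
  out <- array(NA_real_, c(length(windows), 4, 4, 3))
  for (k in seq_along(windows)) out[k, , , ] <- windows[[k]]
  out
}

#' Build the model input tensor from a corrected FeatureSet
#'
#' @param featureSet a [FeatureSet-class] with the chosen assay.
#' @param assay assay to map (default `"corrected"`).
#' @return list with `x` (N x 4 x 4 x 3 array), `label`, `trialId` (vectors
#'   aligned with the batch axis).
#' @export
featureSetToBatch <- function(featureSet, assay = "corrected") {
  m <- SummarizedExperiment::assay(featureSet, assay)
  cd <- SummarizedExperiment::colData(featureSet)
  n <- ncol(m)
  x <- array(NA_real_, c(n, 4, 4, 3))
  lay <- featureLayout()
  for (i in seq_len(48L)) x[, lay$row[i], lay$col[i], lay$plane[i]] <- m[i, ]
  list(x = x, label = as.character(cd$label), trialId = as.character(cd$trialId))
}
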