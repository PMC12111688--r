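# Minimal MATLAB level-5 (.mat) reader/writer for plain numeric arrays.
# Covers what the DEAP and SEED MATLAB releases contain (double/single/int
# N-d arrays); cell arrays, structs, sparse and character data are skipped
# with a warning. Compressed elements are inflated with memDecompress when
# the zlib stream is readable, otherwise a clear error asks for an
# uncompressed export.

.mi <- list(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
            UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
            UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L)

.readNum <- function(raw, off, type, nbytes) {
  n <- switch(as.character(type),
    "1" = nbytes, "2" = nbytes, "3" = nbytes / 2, "4" = nbytes / 2,
    "5" = nbytes / 4, "6" = nbytes / 4, "7" = nbytes / 4,
    "9" = nbytes / 8, "12" = nbytes / 8, "13" = nbytes / 8,
    "16" = nbytes,
    stop("unsupported MAT data type ", type))
  what <- if (type %in% c(7L, 9L)) "double" else "integer"
  size <- switch(as.character(type), "1" = 1, "2" = 1, "3" = 2, "4" = 2,
                 "5" = 4, "6" = 4, "7" = 4, "9" = 8, "12" = 8, "13" = 8,
                 "16" = 1)
  signed <- type %in% c(1L, 3L, 5L, 12L)
  vals <- readBin(raw[(off + 1):(off + nbytes)], what, n = n, size = size,
                  signed = if (size < 4) signed else TRUE,
                  endian = "little")
  vals
}

# parse one tagged sub-element starting at offset; returns list(type,
# nbytes, dataOffset, next) with 8-byte alignment handled
.readTag <- function(raw, off) {
  word <- readBin(raw[(off + 1):(off + 4)], "integer", 1, 4, endian = "little")
  small <- bitwAnd(word, -65536L) != 0L
  if (small) {
    type <- bitwAnd(word, 65535L)
    nbytes <- bitwShiftR(bitwAnd(word, -65536L), 16)
    list(type = type, nbytes = nbytes, dataOffset = off + 4L,
         nxt = off + 8L)
  } else {
    nbytes <- readBin(raw[(off + 5):(off + 8)], "integer", 1, 4, endian = "little")
    pad <- (8 - nbytes %% 8) %% 8
    list(type = word, nbytes = nbytes, dataOffset = off + 8L,
         nxt = off + 8L + nbytes + pad)
  }
}

.parseMatrix <- function(raw) {
  off <- 0L
  flags <- .readTag(raw, off)
  cls <- bitwAnd(.readNum(raw, flags$dataOffset, flags$type, 4)[1], 255L)
  off <- flags$nxt
  dimsEl <- .readTag(raw, off)
  dims <- .readNum(raw, dimsEl$dataOffset, dimsEl$type, dimsEl$nbytes)
  off <- dimsEl$nxt
  nameEl <- .readTag(raw, off)
  nm <- if (nameEl$nbytes > 0)
    rawToChar(raw[(nameEl$dataOffset + 1):(nameEl$dataOffset + nameEl$nbytes)])
  else ""
  off <- nameEl$nxt
  if (!cls %in% 6:13) {
    return(list(name = nm, value = NULL, skipped = TRUE))
  }
  dataEl <- .readTag(raw, off)
  vals <- .readNum(raw, dataEl$dataOffset, dataEl$type, dataEl$nbytes)
  vals <- as.numeric(vals)
  if (length(dims) > 2 || (length(dims) == 2 && !all(dims == c(1, length(vals))))) {
    dim(vals) <- dims
  } else if (length(dims) == 2 && dims[1] == 1) {
    # keep 1 x n as a plain vector
  } else {
    dim(vals) <- dims
  }
  list(name = nm, value = vals, skipped = FALSE)
}

#' Read numeric variables from a MATLAB v5 .mat file
#'
#' Supports the plain numeric N-d arrays used by the DEAP and SEED MATLAB
#' releases. Non-numeric variables are skipped with a warning; compressed
#' elements are inflated when possible.
#'
#' @param path .mat file path.
#' @return named list of numeric vectors/arrays.
#' @export
readMat5 <- function(path) {
  if (!file.exists(path)) stop("not a MAT-file: '", path, "' does not exist")
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) stop("not a MAT-file: too short")
  magic <- rawToChar(raw[1:4])
  if (!startsWith(magic, "MATL")) stop("not a MATLAB level-5 file")
  out <- list()
  off <- 128L
  while (off + 8 <= length(raw)) {
    tag <- .readTag(raw, off)
    if (tag$nbytes == 0) { off <- tag$nxt; next }
    body <- raw[(tag$dataOffset + 1):(tag$dataOffset + tag$nbytes)]
    type <- tag$type
    if (type == .mi$COMPRESSED) {
      body <- tryCatch(
        memDecompress(body, type = "gzip"),
        error = function(e) stop(
          "compressed MAT element could not be inflated; re-save the file ",
          "uncompressed (e.g. scipy.io.savemat(..., do_compression=False) ",
          "or MATLAB save -v6)", call. = FALSE))
      inner <- .readTag(body, 0L)
      type <- inner$type
      body <- body[(inner$dataOffset + 1):(inner$dataOffset + inner$nbytes)]
    }
    if (type == .mi$MATRIX) {
      el <- .parseMatrix(body)
      if (el$skipped) {
        warning("skipping non-numeric MAT variable '", el$name, "'")
      } else {
        out[[el$name]] <- el$value
      }
    }
    off <- tag$nxt
  }
  out
}

.padRaw <- function(r) {
  pad <- (8 - length(r) %% 8) %% 8
  c(r, raw(pad))
}

.matElement <- function(name, value) {
  dims <- dim(value)
  if (is.null(dims)) dims <- c(1L, length(value))
  flags <- c(writeBin(c(6L, 8L), raw(), 4, endian = "little"),
             writeBin(c(6L, 0L), raw(), 4, endian = "little"))
  dimsEl <- c(writeBin(c(5L, 4L * length(dims)), raw(), 4, endian = "little"),
              .padRaw(writeBin(as.integer(dims), raw(), 4, endian = "little")))
  nb <- charToRaw(name)
  nameEl <- c(writeBin(c(1L, length(nb)), raw(), 4, endian = "little"),
              .padRaw(nb))
  dataEl <- c(writeBin(c(9L, 8L * length(value)), raw(), 4, endian = "little"),
              .padRaw(writeBin(as.numeric(value), raw(), 8, endian = "little")))
  body <- c(flags, dimsEl, nameEl, dataEl)
  c(writeBin(c(14L, length(body)), raw(), 4, endian = "little"), body)
}

#' Write numeric variables as an uncompressed MATLAB v5 .mat file
#'
#' Inverse of [readMat5()] for double arrays; used to build synthetic
#' fixtures in the DEAP/SEED on-disk layouts.
#'
#' @param vars named list of numeric vectors/arrays.
#' @param path output path.
#' @export
writeMat5 <- function(vars, path) {
  stopifnot(length(names(vars)) == length(vars))
  hdrText <- sprintf("MATLAB 5.0 MAT-file, written by emoKAN %s",
                     format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(hdrText)
  hdr <- c(hdr, rep(charToRaw(" "), 124 - length(hdr)))
  hdr <- c(hdr, as.raw(c(0x00, 0x01)), charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (nm in names(vars)) writeBin(.matElement(nm, vars[[nm]]), con)
  invisible(path)
}
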