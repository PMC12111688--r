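# shared fixtures, all generated in code

sineWindow <- function(freq, fs = 128, seconds = 1, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, by = 1 / fs, length.out = fs * seconds) + phase)
}

# a 1-s 4-channel window with named channels
noiseWindow <- function(fs = 128, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(fs * 4, sd = sd), fs, 4,
         dimnames = list(NULL, frontalChannels()))
}

randomTrial <- function(seconds = 10, fs = 128, seed = 1, label = "x") {
  set.seed(seed)
  x <- matrix(rnorm(seconds * fs * 4), ncol = 4,
              dimnames = list(NULL, frontalChannels()))
  EEGTrial(x, fs, label = label, trialId = paste0("t", seed))
}

# band power by direct DFT masking of the exact samples (oracle)
dftBandVariance <- function(x, fs, fLow, fHigh) {
  n <- length(x)
  X <- fft(x - mean(x))
  f <- (0:(n - 1)) * fs / n
  fFold <- pmin(f, fs - f)
  keep <- fFold >= fLow & fFold < fHigh
  sum(Mod(X[keep])^2) / n^2
}

# independent recursive de Boor evaluation of a single basis function
deBoorRef <- function(x, grid, j, k) {
  if (k == 0) {
    inTop <- grid[j + 1] == max(grid) && x == grid[j + 1]
    return(as.numeric((x >= grid[j] && x < grid[j + 1]) || inTop))
  }
  d1 <- grid[j + k] - grid[j]
  d2 <- grid[j + k + 1] - grid[j + 1]
  t1 <- if (d1 > 0) (x - grid[j]) / d1 * deBoorRef(x, grid, j, k - 1) else 0
  t2 <- if (d2 > 0) (grid[j + k + 1] - x) / d2 * deBoorRef(x, grid, j + 1, k - 1) else 0
  t1 + t2
}

# small pseudo-RGB batch with bounded entries
randomBatch <- function(n, seed = 1) {
  set.seed(seed)
  array(runif(n * 48, -1, 1), c(n, 4, 4, 3))
}
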