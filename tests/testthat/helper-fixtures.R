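# Shared fixtures, all generated in code.

# solid digital ball in a logical array
digital_ball <- function(dims, center, radius) {
  arr <- array(FALSE, dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  arr[d2 <= radius^2] <- TRUE
  arr
}

# filled digital disk in a logical matrix
digital_disk <- function(dims, center, radius) {
  m <- matrix(FALSE, dims[1], dims[2])
  idx <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2
  m[d2 <= radius^2] <- TRUE
  m
}

# brute-force Euclidean distance transform oracle (tiny volumes only)
edt_brute <- function(mask) {
  d <- dim(mask)
  idx <- arrayInd(seq_len(prod(d)), d)
  bg <- idx[!mask, , drop = FALSE]
  out <- array(0, d)
  fg <- which(mask)
  for (p in fg) {
    q <- idx[p, ]
    out[p] <- sqrt(min((bg[, 1] - q[1])^2 + (bg[, 2] - q[2])^2 +
                         (bg[, 3] - q[3])^2))
  }
  out
}

# one small rendered acquisition + analysis, shared across test files
.fixture_env <- new.env(parent = emptyenv())
cached_small_analysis <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- phantom_spec(size_cm = c(depth = 1.4, width = 1.1, length = 2.2))
    prof <- scan_profile(n_frames = 40, coverage_cm = 1.3)
    sim <- simulate_acquisition(spec, prof, seed = 7)
    a <- suppressWarnings(analyze(sim$volume))
    .fixture_env$small <- list(sim = sim, analysis = a)
  }
  .fixture_env$small
}
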