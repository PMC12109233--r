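# Independent brute-force oracles used to cross-check the implementation.

# exhaustive alternating extrema scan on a raw (unsmoothed) wave: strict
# local minima (last sample of a flat run) and maxima (first sample of a
# flat run), paired into trough-peak-trough cycles, small swings merged with
# the same 10% prominence rule
oracle_cycles <- function(x, fs) {
  n <- length(x)
  troughs <- integer(); peaks <- integer()
  dir <- 0L
  for (i in 2:n) {
    if (x[i] > x[i - 1]) {
      if (dir <= 0L) troughs <- c(troughs, i - 1L)
      dir <- 1L
    } else if (x[i] < x[i - 1]) {
      if (dir > 0L) peaks <- c(peaks, i - 1L)
      if (dir == 0L && i > 2L) peaks <- c(peaks, i - 1L)
      dir <- -1L
    }
  }
  peaks <- peaks[peaks > troughs[1]]
  k <- min(length(peaks), length(troughs) - 1L)
  repeat {
    depths <- x[peaks[seq_len(k)]] - x[troughs[seq_len(k)]]
    keep <- depths >= 0.1 * stats::median(depths)
    if (all(keep)) break
    drop <- which(!keep)[1]
    peaks <- peaks[-drop]
    troughs <- troughs[-(drop + 1L)]
    k <- k - 1L
  }
  data.frame(insp_onset = (troughs[seq_len(k)] - 1) / fs,
             exp_onset = (peaks[seq_len(k)] - 1) / fs,
             end = (troughs[seq_len(k) + 1L] - 1) / fs)
}

# plain-R dynamic programming DTW (full cost matrix), unit steps, diagonal
# preferred on ties; independent of the compiled path
oracle_dtw <- function(A, B, metric = "cosine") {
  A <- log1p(A); B <- log1p(B)
  if (metric == "cosine") {
    nz <- function(m) { s <- sqrt(colSums(m^2)); s[s == 0] <- 1
                        sweep(m, 2, s, "/") }
    A <- nz(A); B <- nz(B)
    dloc <- function(i, j) max(0, 1 - sum(A[, i] * B[, j]))
  } else {
    dloc <- function(i, j) sqrt(sum((A[, i] - B[, j])^2))
  }
  n <- ncol(A); m <- ncol(B)
  D <- matrix(Inf, n, m)
  D[1, 1] <- dloc(1, 1)
  for (j in 2:m) D[1, j] <- D[1, j - 1] + dloc(1, j)
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + dloc(i, 1)
    for (j in 2:m)
      D[i, j] <- dloc(i, j) + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
  }
  # traceback
  path <- matrix(c(n, m), 1)
  i <- n; j <- m
  while (i > 1 || j > 1) {
    if (i == 1) j <- j - 1
    else if (j == 1) i <- i - 1
    else {
      opts <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      w <- which.min(opts)  # which.min takes the first: diagonal preferred
      if (w == 1) { i <- i - 1; j <- j - 1 }
      else if (w == 2) i <- i - 1
      else j <- j - 1
    }
    path <- rbind(c(i, j), path)
  }
  list(path = path, cost = D[n, m])
}

# brute-force hit count: literal double loop over events and onsets
oracle_hits <- function(onsets, events, tol, directional = FALSE) {
  sum(vapply(events, function(e) {
    if (directional) any(onsets >= e - tol & onsets <= e)
    else any(abs(onsets - e) <= tol)
  }, logical(1)))
}

make_quiet <- function(seed, duration = 120, noise_sd = 0.02, ...) {
  generate_quiet_breathing(
    quiet_breathing_params(noise_sd = noise_sd, seed = seed, ...), duration)
}

segment_classify <- function(trace, thresholds = classifier_thresholds()) {
  classify_breaths(
    compute_cycle_features(segment_breaths(trace), trace), thresholds)
}

# piecewise-linear tempo curve through the given knots/slopes
tempo_curve_pl <- function(knots, slopes) {
  vals <- c(0, cumsum(slopes * diff(knots)))
  function(t) stats::approx(knots, vals, xout = t, rule = 2)$y
}
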