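# Shared fixtures and independent oracles for the test suite.

# Random valid formant track for property tests: smooth log-contour from
# a few cosine components around a random centre.
random_track <- function(n_frames = 200, center = NULL, excursion = NULL) {
  if (is.null(center)) center <- runif(1, 300, 2500)
  if (is.null(excursion)) excursion <- runif(1, 0.05, 0.4)
  t <- seq_len(n_frames) / n_frames
  dev <- rowSums(vapply(1:3, function(k)
    runif(1, 0.2, 1) * cos(2 * pi * runif(1, 1, 4) * t + runif(1, 0, 2 * pi)),
    numeric(n_frames)))
  dev <- dev / max(abs(dev)) * excursion
  formant_track(center * exp(dev), runif(n_frames, 0, 1))
}

# Log-sinusoidal contour with an exact number of full modulation cycles,
# used as the ground-truth input for the cycle estimator.
log_sinusoid_track <- function(g, n_cycles, duration, depth = 0.2,
                               frame_period = 0.001) {
  n <- round(duration / frame_period)
  t <- (seq_len(n) - 1) * frame_period
  formant_track(g * exp(depth * sin(2 * pi * n_cycles * t / duration)),
                frame_period = frame_period)
}

# Exhaustive brute-force minimum-cost alignment: enumerates every
# order-preserving set of matched (ref, hyp) index pairs and minimizes
# substitution + insertion + deletion cost directly. Independent of the
# dynamic-programming implementation.
brute_force_alignment_cost <- function(ref, hyp,
                                       costs = c(sub = 10, ins = 7,
                                                 del = 7)) {
  n <- length(ref)
  m <- length(hyp)
  best <- n * costs[["del"]] + m * costs[["ins"]]  # k = 0 alignment
  for (k in seq_len(min(n, m))) {
    ref_sets <- utils::combn(n, k, simplify = FALSE)
    hyp_sets <- utils::combn(m, k, simplify = FALSE)
    for (a in ref_sets) {
      for (b in hyp_sets) {
        mism <- sum(ref[a] != hyp[b])
        cost <- mism * costs[["sub"]] +
          (n - k) * costs[["del"]] + (m - k) * costs[["ins"]]
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# All strings of length 0..max_len over an alphabet, as a list of
# character vectors.
all_strings <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(i) as.character(grid[i, ])))
  }
  out
}
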