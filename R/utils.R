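# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible integer seed from a base seed and string keys
#'
#' Stimulus construction draws random quantities (triangle-wave starting
#' phase, synthetic-contour components) per sentence and per condition. To
#' keep every stimulus reproducible from a single corpus seed, sub-seeds are
#' derived deterministically by hashing the base seed together with string
#' identifiers (e.g. sentence id, condition id) into a 31-bit integer.
#'
#' @param base integer base seed.
#' @param ... character or numeric keys mixed into the hash.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "s001", "C4")
derive_seed <- function(base, ...) {
  stopifnot(is.numeric(base), length(base) == 1, is.finite(base))
  m <- 2147483647
  h <- as.numeric(base) %% m
  for (key in list(...)) {
    for (code in utf8ToInt(paste0("|", paste(as.character(key),
                                             collapse = ",")))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Linear per-sample interpolation of a frame-sampled contour (frame k holds
# the value at time (k-1)*frame_period); constant extrapolation at the ends.
interp_frames_to_samples <- function(values, frame_period, n_samples,
                                     sample_rate) {
  if (length(values) == 1L) return(rep(values, n_samples))
  frame_t <- (seq_along(values) - 1) * frame_period
  sample_t <- (seq_len(n_samples) - 1) / sample_rate
  stats::approx(frame_t, values, xout = sample_t, rule = 2)$y
}

rms <- function(x) sqrt(mean(x^2))

db_to_amp <- function(db) 10^(db / 20)
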