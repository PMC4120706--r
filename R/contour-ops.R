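# Algebra on formant-frequency and amplitude contours. All frequency
# manipulations operate on a log scale about the geometric mean of the
# contour, which is the natural pivot for formant-frequency variation.

#' Geometric mean frequency of a formant track
#'
#' The geometric mean `g = exp(mean(log f))` over all frames, unweighted.
#' It is the pivot used for depth scaling and spectral inversion.
#'
#' @param x a [formant_track()] or a positive numeric vector of
#'   frequencies.
#' @return The geometric mean frequency in Hz.
#' @export
#' @examples
#' geometric_mean(formant_track(c(400, 900)))  # 600
geometric_mean <- function(x) {
  f <- if (is_formant_track(x)) x$freqs else as.numeric(x)
  if (length(f) < 1L) stop("empty frequency contour", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("all frequencies must be finite and > 0", call. = FALSE)
  exp(mean(log(f)))
}

#' Scale the depth of formant-frequency variation (formant squash)
#'
#' Rescales a formant-frequency contour about its geometric mean `g` on a
#' log scale: per frame, `log s = log g + x * log(f / g)`, with
#' `0 <= x <= 1`. `x = 1` leaves the contour unchanged; `x = 0` flattens
#' it to a constant at `g`. Amplitudes are never adjusted.
#'
#' @param track a [formant_track()].
#' @param x proportional scale factor in `[0, 1]`.
#' @return A new [formant_track()] with rescaled frequencies.
#' @export
#' @examples
#' scale_depth(formant_track(c(200, 800)), 0.5)$freqs  # 282.8, 565.7
scale_depth <- function(track, x) {
  stopifnot(is_formant_track(track))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("scale factor x must be a single number in [0, 1]", call. = FALSE)
  g <- geometric_mean(track)
  formant_track(g * (track$freqs / g)^x, track$amps,
                track$frame_period, track$label)
}

#' Invert a formant-frequency contour about its geometric mean
#'
#' Reflects the contour about its geometric mean on a log scale:
#' `log s = log g - log(f / g)`, i.e. `s = g^2 / f` per frame. Inversion
#' preserves the rate and depth of frequency variation, producing a
#' speech-plausible but phonetically uninformative contour; it is an
#' involution. Amplitudes are unchanged.
#'
#' @param track a [formant_track()].
#' @return A new [formant_track()] with the inverted contour.
#' @export
invert_about_gmean <- function(track) {
  stopifnot(is_formant_track(track))
  g <- geometric_mean(track)
  formant_track(g^2 / track$freqs, track$amps,
                track$frame_period, track$label)
}

#' Smooth a contour by non-overlapping block averaging
#'
#' Down-samples a frame contour by averaging consecutive non-overlapping
#' blocks (default 40 frames, i.e. low-pass filtering a 1-ms-frame contour
#' at 25 Hz). A trailing partial block is averaged over its own length.
#'
#' @param freqs numeric contour (one value per frame).
#' @param block block length in frames (>= 1).
#' @return Numeric vector of block means, in frame order.
#' @export
#' @examples
#' block_smooth(1:80, 40)  # 20.5, 60.5
block_smooth <- function(freqs, block = 40) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 1L) stop("empty contour", call. = FALSE)
  if (!is.numeric(block) || length(block) != 1L || block < 1)
    stop("block must be >= 1", call. = FALSE)
  block <- as.integer(block)
  idx <- (seq_along(freqs) - 1L) %/% block
  as.numeric(tapply(freqs, idx, mean))
}

#' Estimate the modulation cycle count of a smoothed formant contour
#'
#' Counts the number of times the (already smoothed) contour crosses the
#' geometric mean frequency `g`, as sign changes of `value - g` between
#' successive samples (a sample exactly at `g` counts as positive). The
#' number of half-cycles of modulation is the crossing count plus one;
#' the cycle count keeps half-cycle precision, and the modulation period
#' is the track duration divided by the cycle count.
#'
#' @param smoothed numeric contour, typically the output of
#'   [block_smooth()].
#' @param g geometric mean frequency in Hz (> 0).
#' @param duration track duration in seconds (> 0).
#' @return An object of class `cycle_estimate`: list with `half_cycles`,
#'   `cycles` and `period_T` (seconds).
#' @export
estimate_cycles <- function(smoothed, g, duration) {
  smoothed <- as.numeric(smoothed)
  if (length(smoothed) < 1L) stop("empty contour", call. = FALSE)
  stopifnot(is.numeric(g), length(g) == 1L, g > 0,
            is.numeric(duration), length(duration) == 1L, duration > 0)
  s <- ifelse(smoothed - g >= 0, 1L, -1L)
  crossings <- if (length(s) > 1L) sum(s[-1L] != s[-length(s)]) else 0L
  half_cycles <- crossings + 1L
  cycles <- half_cycles / 2
  structure(list(half_cycles = half_cycles, cycles = cycles,
                 period_T = duration / cycles),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat(sprintf("<cycle_estimate: %d half-cycles (%.1f cycles), T = %.4f s>\n",
              x$half_cycles, x$cycles, x$period_T))
  invisible(x)
}

# Analytic peak of the 4-odd-harmonic triangle series, attained at phase 0:
# (8/pi^2) * (1 + 1/9 + 1/25 + 1/49). Used to normalize the series to +-1
# exactly, independent of frame phase.
triangle_peak <- function() (8 / pi^2) * sum(1 / c(1, 3, 5, 7)^2)

#' Parameters of a band-limited triangle-wave frequency contour
#'
#' Describes a competitor contour that is triangular on a log-frequency
#' scale, built from the first four odd harmonics (1, 3, 5, 7) of the
#' triangle-wave Fourier series. The truncation leaves peaks and troughs
#' slightly rounded, avoiding synthesis artifacts from abrupt resonator
#' frequency changes.
#'
#' @param g geometric mean pivot in Hz (> 0).
#' @param r half the log-range (natural log units) of the target F2
#'   contour (>= 0).
#' @param period_T modulation period in seconds (> 0).
#' @param start_phase starting phase as a fraction of one period, in
#'   `[0, 1)`.
#' @param scale_x depth scale factor in `[0, 1]`.
#' @return An object of class `triangle_spec`.
#' @export
triangle_spec <- function(g, r, period_T, start_phase = 0, scale_x = 1) {
  stopifnot(is.numeric(g), length(g) == 1L, g > 0,
            is.numeric(r), length(r) == 1L, r >= 0,
            is.numeric(period_T), length(period_T) == 1L, period_T > 0)
  if (!is.numeric(start_phase) || length(start_phase) != 1L ||
      start_phase < 0 || start_phase >= 1)
    stop("start_phase must be in [0, 1)", call. = FALSE)
  if (!is.numeric(scale_x) || length(scale_x) != 1L ||
      scale_x < 0 || scale_x > 1)
    stop("scale_x must be in [0, 1]", call. = FALSE)
  structure(list(g = g, r = r, period_T = period_T,
                 start_phase = start_phase, scale_x = scale_x,
                 harmonics = c(1, 3, 5, 7)),
            class = "triangle_spec")
}

#' Generate a triangle-wave formant-frequency contour
#'
#' Evaluates the band-limited triangle wave
#' `a(t) = (8/pi^2) * sum_{n in 1,3,5,7} cos(2 pi n (t + phi T) / T) / n^2`,
#' normalizes it by its analytic peak so it spans exactly \[-1, 1\], and
#' maps it to frequency multiplicatively on a log scale:
#' `f(t) = g * exp(x * r * a_hat(t))`. The resulting contour is centred on
#' `g` with a log peak-to-trough range of `2 x r`. Amplitudes are set to 1
#' as a placeholder; competitor amplitude flattening is applied downstream.
#'
#' @param spec a [triangle_spec()].
#' @param duration contour duration in seconds (>= `frame_period`).
#' @param frame_period frame spacing in seconds (default 0.001).
#' @return A [formant_track()] labelled `"F2C"`.
#' @export
#' @examples
#' sp <- triangle_spec(g = 1200, r = log(4 / 3), period_T = 0.5)
#' triangle_contour(sp, duration = 1)$freqs[1]  # 1600 at phase 0
triangle_contour <- function(spec, duration, frame_period = 0.001) {
  stopifnot(inherits(spec, "triangle_spec"))
  if (!is.numeric(duration) || length(duration) != 1L ||
      duration < frame_period)
    stop("duration must be at least one frame period", call. = FALSE)
  n_frames <- round(duration / frame_period)
  t <- (seq_len(n_frames) - 1) * frame_period
  a <- numeric(n_frames)
  for (h in spec$harmonics) {
    a <- a + cos(2 * pi * h * (t + spec$start_phase * spec$period_T) /
                   spec$period_T) / h^2
  }
  a_hat <- (8 / pi^2) * a / triangle_peak()
  formant_track(spec$g * exp(spec$scale_x * spec$r * a_hat),
                frame_period = frame_period, label = "F2C")
}

#' Flatten a track's amplitude contour to its RMS power
#'
#' Replaces every frame amplitude with the constant root-mean-square of
#' the amplitude contour, leaving frequencies untouched. Competitor
#' formants are always presented with a constant amplitude matched to the
#' RMS power of the target F2's amplitude contour.
#'
#' @param track a [formant_track()].
#' @return A new [formant_track()] with constant amplitudes. A track whose
#'   amplitudes are all zero is returned unchanged with a warning (it
#'   would synthesize to silence).
#' @export
flatten_amplitude <- function(track) {
  stopifnot(is_formant_track(track))
  level <- rms(track$amps)
  if (level == 0)
    warning("amplitude contour is all zero; degenerate (silent) stimulus",
            call. = FALSE)
  formant_track(track$freqs, rep(level, length(track$amps)),
                track$frame_period, track$label)
}

#' Find frames where two tracks approach closer than a frequency limit
#'
#' Competitor contours must keep a minimum nominal-frequency separation
#' from F1 at every moment (80 Hz by default) to prevent track crossovers
#' and audible interactions between harmonics exciting different formants.
#'
#' @param a,b [formant_track()] objects with equal frame counts and frame
#'   periods.
#' @param min_hz minimum allowed separation in Hz (default 80).
#' @return Integer vector of frame indices where
#'   `|a$freqs - b$freqs| < min_hz`; empty if the constraint holds
#'   everywhere.
#' @export
check_min_separation <- function(a, b, min_hz = 80) {
  stopifnot(is_formant_track(a), is_formant_track(b))
  if (length(a$freqs) != length(b$freqs) ||
      a$frame_period != b$frame_period)
    stop("tracks must share frame count and frame period", call. = FALSE)
  which(abs(a$freqs - b$freqs) < min_hz)
}
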