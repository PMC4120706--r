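# Parallel-formant synthesis: a glottal-pulse source drives time-varying
# second-order resonators, one per formant, whose outputs are weighted by
# the formant amplitude contours and summed.

#' Excitation source specification
#'
#' A monotonous (constant-F0) train of Rosenberg-style glottal pulses is
#' the voiced excitation for all stimuli; F0 = 140 Hz by default. The
#' pulse is the classic polynomial glottal-flow shape: a cubic rise over
#' the open phase followed by a quadratic fall over the closing phase,
#' zero during closure.
#'
#' @param f0 fundamental-frequency contour in Hz: a scalar or one value
#'   per 1-ms frame. Must be positive and below `sample_rate / 4`.
#' @param open_fraction fraction of the glottal period occupied by the
#'   opening phase (default 0.6).
#' @param closing_fraction fraction occupied by the closing phase
#'   (default 0.2); `open + closing <= 1`.
#' @param sample_rate output sample rate in Hz (default 22050).
#' @param frame_period frame spacing of `f0` when it is a contour
#'   (default 0.001 s).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(f0 = 140, open_fraction = 0.6,
                        closing_fraction = 0.2, sample_rate = 22050,
                        frame_period = 0.001) {
  f0 <- as.numeric(f0)
  stopifnot(length(f0) >= 1L, all(is.finite(f0)))
  if (any(f0 <= 0) || any(f0 >= sample_rate / 4))
    stop("f0 must satisfy 0 < f0 < sample_rate / 4", call. = FALSE)
  if (open_fraction <= 0 || closing_fraction <= 0 ||
      open_fraction + closing_fraction > 1)
    stop("open and closing fractions must be in (0, 1) with sum <= 1",
         call. = FALSE)
  structure(list(f0 = f0, open_fraction = open_fraction,
                 closing_fraction = closing_fraction,
                 sample_rate = sample_rate, frame_period = frame_period),
            class = "source_spec")
}

#' Resonator specification
#'
#' Constant 3-dB bandwidths for the parallel formant resonators: 50, 70
#' and 90 Hz for F1, F2 and F3; competitor formants use 70 Hz (matching
#' the target F2).
#'
#' @param bandwidths named numeric vector of 3-dB bandwidths in Hz.
#' @param sample_rate sample rate in Hz (default 22050).
#' @return An object of class `resonator_spec`.
#' @export
resonator_spec <- function(bandwidths = c(F1 = 50, F2 = 70, F3 = 90,
                                          F2C = 70),
                           sample_rate = 22050) {
  stopifnot(all(bandwidths > 0), all(bandwidths < sample_rate / 2))
  structure(list(bandwidths = bandwidths, sample_rate = sample_rate),
            class = "resonator_spec")
}

bandwidth_for_label <- function(res, label) {
  if (label %in% names(res$bandwidths)) res$bandwidths[[label]]
  else res$bandwidths[["F2C"]]
}

#' Generate a Rosenberg-style glottal pulse train
#'
#' Accumulates instantaneous phase from the (per-sample interpolated) F0
#' contour and evaluates the pulse shape at the fractional position within
#' each glottal cycle, so fractional periods (e.g. 157.5 samples per cycle
#' at 140 Hz and 22.05 kHz) are honoured on average: cycle lengths
#' alternate between the neighbouring integer sample counts. By default
#' the returned excitation is the first difference of the glottal flow —
#' the flow derivative — which folds in the +6 dB/octave lip-radiation
#' characteristic as is conventional in source-filter synthesis and keeps
#' formant-region harmonics from being swamped by the fundamental. The
#' output is mean-removed.
#'
#' @param spec a [source_spec()].
#' @param duration duration in seconds (>= 0).
#' @param derivative if `TRUE` (default) return the glottal-flow
#'   derivative; if `FALSE`, the raw flow pulse train.
#' @return Numeric waveform of `round(duration * sample_rate)` samples.
#' @export
glottal_source <- function(spec = source_spec(), duration,
                           derivative = TRUE) {
  stopifnot(inherits(spec, "source_spec"),
            is.numeric(duration), length(duration) == 1L, duration >= 0)
  fs <- spec$sample_rate
  n <- round(duration * fs)
  if (n == 0L) return(numeric(0))
  f0 <- interp_frames_to_samples(spec$f0, spec$frame_period, n, fs)
  # phase[i] = cycles completed before sample i; first sample at phase 0
  phase <- c(0, cumsum(f0 / fs))[seq_len(n)]
  u <- phase %% 1
  op <- spec$open_fraction
  cl <- spec$closing_fraction
  w <- numeric(n)
  rising <- u < op
  w[rising] <- 3 * (u[rising] / op)^2 - 2 * (u[rising] / op)^3
  falling <- !rising & u < op + cl
  w[falling] <- 1 - ((u[falling] - op) / cl)^2
  if (derivative) w <- diff(c(0, w))
  w - mean(w)
}

# Count glottal cycle onsets in a phase-accumulated source (internal, used
# by tests through the exported source itself): onsets are phase wraps.
glottal_cycle_onsets <- function(spec, duration) {
  fs <- spec$sample_rate
  n <- round(duration * fs)
  f0 <- interp_frames_to_samples(spec$f0, spec$frame_period, n, fs)
  phase <- c(0, cumsum(f0 / fs))[seq_len(n)]
  which(diff(floor(phase)) >= 1) + 1L
}

#' Magnitude response of the designed two-pole resonator
#'
#' Evaluates `|H(e^{j 2 pi f / fs})|` for the resonator with centre
#' frequency `centre` and 3-dB bandwidth `bandwidth` as designed by
#' [resonate()]: pole radius `exp(-pi B / fs)`, pole angle
#' `2 pi F / fs`, gain normalized to unity at the centre frequency.
#'
#' @param freq_hz frequencies at which to evaluate the response (Hz).
#' @param centre resonator centre frequency (Hz).
#' @param bandwidth 3-dB bandwidth (Hz).
#' @param sample_rate sample rate (Hz).
#' @return Numeric vector of magnitude gains.
#' @export
resonator_gain <- function(freq_hz, centre, bandwidth,
                           sample_rate = 22050) {
  r <- exp(-pi * bandwidth / sample_rate)
  theta <- 2 * pi * centre / sample_rate
  c1 <- 2 * r * cos(theta)
  c2 <- r^2
  denom_at <- function(w) abs(1 - c1 * exp(-1i * w) + c2 * exp(-2i * w))
  a0 <- denom_at(theta)
  a0 / denom_at(2 * pi * freq_hz / sample_rate)
}

#' Filter a waveform through a time-varying two-pole resonator
#'
#' Standard synthesizer formulation: poles at radius `exp(-pi B / fs)` and
#' angle `2 pi F / fs`, difference equation
#' `y[n] = A[n] x[n] + c1[n] y[n-1] - c2 y[n-2]`, with the input gain
#' `A[n]` normalized so the magnitude response is unity at the
#' instantaneous centre frequency. The centre-frequency contour is given
#' per 1-ms frame and linearly interpolated per sample; coefficients are
#' recomputed every sample.
#'
#' @param source mono input waveform.
#' @param freq_contour centre-frequency contour in Hz, one value per
#'   frame; all values must be positive and below Nyquist.
#' @param bandwidth constant 3-dB bandwidth in Hz.
#' @param sample_rate sample rate in Hz.
#' @param frame_period frame spacing of `freq_contour` in seconds.
#' @return Filtered waveform, same length as `source`.
#' @export
resonate <- function(source, freq_contour, bandwidth,
                     sample_rate = 22050, frame_period = 0.001) {
  freq_contour <- as.numeric(freq_contour)
  if (any(!is.finite(freq_contour)) || any(freq_contour <= 0) ||
      any(freq_contour >= sample_rate / 2))
    stop("centre frequencies must lie in (0, Nyquist)", call. = FALSE)
  stopifnot(bandwidth > 0, bandwidth < sample_rate / 2)
  n <- length(source)
  if (n == 0L) return(numeric(0))
  f <- interp_frames_to_samples(freq_contour, frame_period, n, sample_rate)
  r <- exp(-pi * bandwidth / sample_rate)
  theta <- 2 * pi * f / sample_rate
  c1 <- 2 * r * cos(theta)
  c2 <- r^2
  # unity gain at the instantaneous centre frequency
  A <- abs(1 - c1 * exp(-1i * theta) + c2 * exp(-2i * theta))
  y <- numeric(n)
  y1 <- 0
  y2 <- 0
  for (i in seq_len(n)) {
    yi <- A[i] * source[i] + c1[i] * y1 - c2 * y2
    y2 <- y1
    y1 <- yi
    y[i] <- yi
  }
  y
}

#' Synthesize a set of formant tracks to a mono waveform
#'
#' Each track's frequency contour drives one resonator excited by the
#' common glottal source; the resonator output is weighted by the track's
#' per-sample-interpolated amplitude contour, and the weighted outputs are
#' summed. By default adjacent formants are summed with alternating
#' polarity (+, -, +, ...) to avoid deep spectral zeros between formant
#' peaks.
#'
#' @param tracks list of [formant_track()] objects with equal durations
#'   and frame periods.
#' @param source a [source_spec()].
#' @param res a [resonator_spec()]; per-track bandwidths are looked up by
#'   track label (unknown labels get the competitor bandwidth, 70 Hz).
#' @param polarity `"alternating"` (default) or `"uniform"` summation.
#' @param normalize if `TRUE` (default), scale the summed output so its
#'   peak equals `headroom`; silent output is returned as-is.
#' @param headroom peak level after normalization (default 0.9).
#' @return Mono waveform of `round(duration * sample_rate)` samples.
#' @export
synthesize_formants <- function(tracks, source = source_spec(),
                                res = resonator_spec(),
                                polarity = c("alternating", "uniform"),
                                normalize = TRUE, headroom = 0.9) {
  polarity <- match.arg(polarity)
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, is_formant_track,
                                             logical(1))))
  n_frames <- length(tracks[[1]]$freqs)
  fp <- tracks[[1]]$frame_period
  for (tr in tracks) {
    if (length(tr$freqs) != n_frames || tr$frame_period != fp)
      stop("all tracks must share frame count and frame period",
           call. = FALSE)
  }
  fs <- source$sample_rate
  duration <- n_frames * fp
  src <- glottal_source(source, duration)
  n <- length(src)
  out <- numeric(n)
  sign <- 1
  for (tr in tracks) {
    bw <- bandwidth_for_label(res, tr$label)
    y <- resonate(src, tr$freqs, bw, fs, fp)
    a <- interp_frames_to_samples(tr$amps, fp, n, fs)
    out <- out + sign * y * a
    if (polarity == "alternating") sign <- -sign
  }
  if (normalize) {
    peak <- max(abs(out))
    if (peak > 0) out <- out * (headroom / peak)
  }
  out
}

#' Apply raised-cosine onset and offset ramps
#'
#' Multiplies the first and last `ramp` seconds of a waveform by a
#' raised-cosine window `(1 - cos(pi t / ramp)) / 2` and its mirror, so
#' the first and last samples are exactly zero. Default ramp is 10 ms.
#'
#' @param wave mono waveform.
#' @param ramp ramp duration in seconds (default 0.010).
#' @param sample_rate sample rate in Hz.
#' @return The ramped waveform.
#' @export
apply_ramps <- function(wave, ramp = 0.010, sample_rate = 22050) {
  nr <- round(ramp * sample_rate)
  if (length(wave) < 2 * nr)
    stop("waveform shorter than two ramps", call. = FALSE)
  if (nr < 1L) return(wave)
  t <- (seq_len(nr) - 1) / sample_rate
  env <- (1 - cos(pi * t / ramp)) / 2
  n <- length(wave)
  wave[seq_len(nr)] <- wave[seq_len(nr)] * env
  wave[n - seq_len(nr) + 1] <- wave[n - seq_len(nr) + 1] * env
  wave
}

#' Two-channel stimulus container
#'
#' @param left,right numeric waveforms of equal length, samples in
#'   `[-1, 1]`.
#' @param sample_rate sample rate in Hz.
#' @param meta named list of condition metadata (condition id, per-ear
#'   formant lists, level offsets, seeds).
#' @return An object of class `stereo_stimulus`.
#' @export
stereo_stimulus <- function(left, right, sample_rate = 22050,
                            meta = list()) {
  if (length(left) != length(right))
    stop("channels must have equal length", call. = FALSE)
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("samples must be finite", call. = FALSE)
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 sample_rate = sample_rate, meta = meta),
            class = "stereo_stimulus")
}

#' @export
print.stereo_stimulus <- function(x, ...) {
  cat(sprintf("<stereo_stimulus: %.3f s @ %d Hz%s>\n",
              length(x$left) / x$sample_rate, x$sample_rate,
              if (!is.null(x$meta$condition))
                paste0(", condition ", x$meta$condition) else ""))
  invisible(x)
}

#' Assemble a dichotic stimulus from per-ear formant track sets
#'
#' Each ear is synthesized independently ([synthesize_formants()] without
#' normalization), ramped, and scaled so its long-term RMS level equals
#' `reference_dbfs + offset` dB re full scale. Absolute SPL is not
#' reproducible in software: `reference_dbfs` is the digital level that
#' stands for the experiment's reference SPL, and all condition levels are
#' offsets from it. An empty ear is silent.
#'
#' @param left_tracks,right_tracks lists of [formant_track()] objects (an
#'   empty list gives a silent channel; at least one ear must be
#'   non-empty).
#' @param level_offsets_db numeric length-2 vector `c(left, right)` of dB
#'   offsets from the reference level.
#' @param source a [source_spec()].
#' @param res a [resonator_spec()].
#' @param reference_dbfs digital RMS level (dB re full scale) mapped to
#'   the reference SPL (default -25).
#' @param ramp onset/offset ramp in seconds (default 0.010).
#' @param auto_normalize if the scaled stimulus would clip, rescale both
#'   channels jointly instead of raising an error.
#' @param meta named list merged into the stimulus metadata.
#' @return A [stereo_stimulus()].
#' @export
assemble_dichotic <- function(left_tracks, right_tracks,
                              level_offsets_db = c(0, 0),
                              source = source_spec(),
                              res = resonator_spec(),
                              reference_dbfs = -25, ramp = 0.010,
                              auto_normalize = FALSE, meta = list()) {
  stopifnot(length(level_offsets_db) == 2L)
  if (length(left_tracks) == 0L && length(right_tracks) == 0L)
    stop("at least one ear must carry a formant", call. = FALSE)
  fs <- source$sample_rate
  synth_ear <- function(tracks, offset_db) {
    if (length(tracks) == 0L) return(NULL)
    w <- synthesize_formants(tracks, source, res, normalize = FALSE)
    w <- apply_ramps(w, ramp, fs)
    level <- rms(w)
    if (level == 0) return(w)
    w * (db_to_amp(reference_dbfs + offset_db) / level)
  }
  left <- synth_ear(left_tracks, level_offsets_db[1])
  right <- synth_ear(right_tracks, level_offsets_db[2])
  if (is.null(left)) left <- numeric(length(right))
  if (is.null(right)) right <- numeric(length(left))
  peak <- max(abs(c(left, right)))
  scaled_by <- 1
  if (peak > 1) {
    if (!auto_normalize)
      stop(sprintf(paste0("stimulus clips after level offsets ",
                          "(peak %.3f); lower reference_dbfs or enable ",
                          "auto_normalize"), peak), call. = FALSE)
    scaled_by <- 0.999 / peak
    left <- left * scaled_by
    right <- right * scaled_by
  }
  meta <- utils::modifyList(
    list(level_offsets_db = level_offsets_db,
         reference_dbfs = reference_dbfs,
         left_formants = vapply(left_tracks, function(t) t$label, ""),
         right_formants = vapply(right_tracks, function(t) t$label, ""),
         auto_scaled_by = scaled_by),
    meta)
  stereo_stimulus(left, right, fs, meta)
}

#' Write a stereo stimulus to a 16-bit PCM WAV file
#'
#' Plain RIFF/WAVE, 16-bit signed PCM, two channels. Samples are clipped
#' to `[-1, 1]` and quantized to the nearest of 32767 steps, so a
#' write-read round trip agrees with the original within one least
#' significant bit.
#'
#' @param stim a [stereo_stimulus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(stim, path) {
  stopifnot(inherits(stim, "stereo_stimulus"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(stim$left)
  fs <- as.integer(stim$sample_rate)
  n_channels <- 2L
  bits <- 16L
  block_align <- n_channels * bits %/% 8L
  data_bytes <- n * block_align
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  quant <- function(x) as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  interleaved <- integer(2L * n)
  interleaved[seq(1L, 2L * n, by = 2L)] <- quant(stim$left)
  interleaved[seq(2L, 2L * n, by = 2L)] <- quant(stim$right)
  writeBin(interleaved, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_wav()]
#'
#' Minimal reader for the canonical 44-byte-header RIFF layout this
#' package writes (16-bit PCM, one or two channels).
#'
#' @param path input file path.
#' @return A [stereo_stimulus()]; a mono file is returned with identical
#'   channels.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sample_rate <- NULL
  n_channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || !nzchar(id))
      stop("no data chunk found", call. = FALSE)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM supported", call. = FALSE)
      n_channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  x <- samples / 32767
  if (n_channels == 2L) {
    stereo_stimulus(x[seq(1, length(x), by = 2)],
                    x[seq(2, length(x), by = 2)], sample_rate)
  } else {
    stereo_stimulus(x, x, sample_rate)
  }
}
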