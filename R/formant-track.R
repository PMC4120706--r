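#' Frame-sampled formant track
#'
#' A formant track is the frame-by-frame description of one formant: a
#' frequency contour (Hz) and a linear amplitude contour, sampled at a
#' uniform frame period (1 ms by default, the analysis frame used
#' throughout this package).
#'
#' @param freqs numeric vector of frequencies in Hz, one per frame; all > 0.
#' @param amps numeric vector of linear amplitudes (>= 0), one per frame.
#'   Defaults to 1 for every frame.
#' @param frame_period frame spacing in seconds (default 0.001).
#' @param label free-text label, e.g. `"F2"`.
#' @return An object of class `formant_track`: a list with elements
#'   `freqs`, `amps`, `frame_period`, `label`.
#' @export
#' @examples
#' tr <- formant_track(c(400, 900), label = "F2")
#' geometric_mean(tr)
formant_track <- function(freqs, amps = rep(1, length(freqs)),
                          frame_period = 0.001, label = "") {
  freqs <- as.numeric(freqs)
  amps <- as.numeric(amps)
  if (length(freqs) < 1L)
    stop("a formant track needs at least one frame", call. = FALSE)
  if (length(freqs) != length(amps))
    stop("freqs and amps must have the same length", call. = FALSE)
  if (!all(is.finite(freqs)) || any(freqs <= 0))
    stop("all frequencies must be finite and > 0", call. = FALSE)
  if (!all(is.finite(amps)) || any(amps < 0))
    stop("all amplitudes must be finite and >= 0", call. = FALSE)
  if (!is.numeric(frame_period) || length(frame_period) != 1L ||
      frame_period <= 0)
    stop("frame_period must be a single positive number", call. = FALSE)
  structure(list(freqs = freqs, amps = amps,
                 frame_period = as.numeric(frame_period),
                 label = as.character(label)),
            class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf("<formant_track %s: %d frames @ %g ms, %.0f-%.0f Hz>\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$freqs), 1000 * x$frame_period,
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Duration of a formant track in seconds
#'
#' @param track a [formant_track()].
#' @return Duration in seconds (`n_frames * frame_period`).
#' @export
track_duration <- function(track) {
  stopifnot(inherits(track, "formant_track"))
  length(track$freqs) * track$frame_period
}

is_formant_track <- function(x) inherits(x, "formant_track")

#' Sentence-level bundle of formant tracks and reference transcripts
#'
#' Bundles the F1-F3 tracks of one sentence with its scoring references:
#' the designated keywords and the reference phoneme sequence.
#'
#' @param id sentence identifier.
#' @param f1,f2,f3 [formant_track()] objects of equal duration and frame
#'   period.
#' @param keywords character vector of designated keywords (>= 1).
#' @param phonemes character vector of reference phoneme symbols (may be
#'   empty if phoneme scoring is not wanted).
#' @return An object of class `sentence_tracks`.
#' @export
sentence_tracks <- function(id, f1, f2, f3, keywords, phonemes = character()) {
  stopifnot(is_formant_track(f1), is_formant_track(f2), is_formant_track(f3))
  n <- length(f1$freqs)
  if (length(f2$freqs) != n || length(f3$freqs) != n ||
      f1$frame_period != f2$frame_period ||
      f1$frame_period != f3$frame_period)
    stop("f1, f2, f3 must share frame count and frame period", call. = FALSE)
  keywords <- as.character(keywords)
  if (length(keywords) < 1L)
    stop("a sentence needs at least one keyword", call. = FALSE)
  structure(list(id = as.character(id), f1 = f1, f2 = f2, f3 = f3,
                 keywords = keywords, phonemes = as.character(phonemes)),
            class = "sentence_tracks")
}

#' @export
print.sentence_tracks <- function(x, ...) {
  cat(sprintf("<sentence_tracks %s: %.3f s, %d keywords>\n",
              x$id, track_duration(x$f1), length(x$keywords)))
  invisible(x)
}

#' Write formant tracks of a sentence to a delimited text file
#'
#' The on-disk format is a plain-text table with a header row and columns
#' `time_s, f1_hz, a1, f2_hz, a2, f3_hz, a3`, one row per 1-ms frame.
#'
#' @param sentence a [sentence_tracks()] object.
#' @param path output file path.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_formant_tracks <- function(sentence, path, sep = "\t") {
  stopifnot(inherits(sentence, "sentence_tracks"))
  n <- length(sentence$f1$freqs)
  df <- data.frame(
    time_s = (seq_len(n) - 1) * sentence$f1$frame_period,
    f1_hz = sentence$f1$freqs, a1 = sentence$f1$amps,
    f2_hz = sentence$f2$freqs, a2 = sentence$f2$amps,
    f3_hz = sentence$f3$freqs, a3 = sentence$f3$amps)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read formant tracks of a sentence from a delimited text file
#'
#' Reads the format written by [write_formant_tracks()] (comma- or
#' tab-delimited, autodetected) and validates that frame times are
#' monotone and uniformly spaced.
#'
#' @param path input file path.
#' @param id sentence id to attach; defaults to the file name without
#'   extension.
#' @param keywords,phonemes scoring references to attach (the track file
#'   itself carries only acoustics).
#' @return A [sentence_tracks()] object.
#' @export
read_formant_tracks <- function(path, id = NULL,
                                keywords = "unknown",
                                phonemes = character()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time_s", "f1_hz", "a1", "f2_hz", "a2", "f3_hz", "a3")
  if (!all(need %in% names(df)))
    stop("track file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 2L)
    stop("track file must contain at least two frames", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9)
    stop("frame times must be uniformly spaced", call. = FALSE)
  fp <- dt[1]
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  sentence_tracks(
    id = id,
    f1 = formant_track(df$f1_hz, df$a1, fp, "F1"),
    f2 = formant_track(df$f2_hz, df$a2, fp, "F2"),
    f3 = formant_track(df$f3_hz, df$a3, fp, "F3"),
    keywords = keywords, phonemes = phonemes)
}
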