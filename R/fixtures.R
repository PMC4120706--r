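# Synthetic-data generation: plausible formant-track corpora standing in
# for a recorded-sentence corpus, and simulated listener responses, so the
# whole pipeline is testable with no external data.

#' Specification for one synthetic sentence
#'
#' Synthetic formant contours are band-limited sums of random-phase
#' cosines on a log-frequency scale, centred on the nominal formant
#' frequencies of a standard adult male vocal tract (F1 = 500, F2 = 1500,
#' F3 = 2500 Hz), with modulation components in the 2-6 Hz band typical
#' of articulator movement. Amplitude contours are raised-cosine syllabic
#' envelopes. Because the contours are analytic, their log-ranges and
#' cycle counts are known exactly, which makes them usable as test
#' oracles.
#'
#' @param duration sentence duration in seconds; `NULL` (default) draws
#'   uniformly from 1.5-2.5 s.
#' @param formant_centers strictly increasing Hz vector of F1-F3 centres.
#' @param log_excursion per-formant half log-ranges (natural log units).
#' @param modulation_rate_band Hz range for the random contour
#'   components.
#' @param syllable_rate amplitude-modulation rate in Hz.
#' @param n_keywords keywords per sentence; `NULL` draws 2-5.
#' @param rng_seed integer seed; every draw is deterministic given it.
#' @return An object of class `synthetic_sentence_spec`.
#' @export
synthetic_sentence_spec <- function(duration = NULL,
                                    formant_centers = c(500, 1500, 2500),
                                    log_excursion = c(0.18, 0.22, 0.12),
                                    modulation_rate_band = c(2, 6),
                                    syllable_rate = 4,
                                    n_keywords = NULL,
                                    rng_seed = 1) {
  stopifnot(length(formant_centers) == 3L,
            all(diff(formant_centers) > 0),
            length(log_excursion) == 3L, all(log_excursion >= 0),
            length(modulation_rate_band) == 2L,
            modulation_rate_band[1] > 0,
            diff(modulation_rate_band) > 0,
            syllable_rate > 0)
  if (!is.null(duration)) stopifnot(duration > 0)
  structure(list(duration = duration, formant_centers = formant_centers,
                 log_excursion = log_excursion,
                 modulation_rate_band = modulation_rate_band,
                 syllable_rate = syllable_rate, n_keywords = n_keywords,
                 rng_seed = rng_seed),
            class = "synthetic_sentence_spec")
}

# Pseudo-word and phoneme-string generation for scoring fixtures: CV(C)
# syllables over a small inventory; phoneme symbols are the letters.
make_pseudo_words <- function(n) {
  consonants <- c("b", "d", "g", "k", "l", "m", "n", "p", "s", "t")
  vowels <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    n_syll <- sample(1:2, 1)
    paste(vapply(seq_len(n_syll), function(j) {
      paste0(sample(consonants, 1), sample(vowels, 1),
             if (stats::runif(1) < 0.5) sample(consonants, 1) else "")
    }, ""), collapse = "")
  }, "")
}

#' Generate the formant tracks of one synthetic sentence
#'
#' Per formant, the log-frequency contour is the centre log frequency
#' plus a sum of 3-5 random-amplitude, random-phase cosines with rates in
#' the modulation band, rescaled and centred so the half log-range equals
#' the spec's excursion exactly. The construction is validated to keep
#' `F1 < F2 < F3` at every frame with `F2 - F1 >= 200` Hz. Amplitude
#' contours are raised-cosine syllabic envelopes scaled so F1 dominates
#' (as in natural speech). Frames are 1 ms; everything is deterministic
#' given the spec's seed.
#'
#' @param spec a [synthetic_sentence_spec()].
#' @param id sentence id (default `"syn"`).
#' @return A [sentence_tracks()] object with pseudo-word keywords and a
#'   matching reference phoneme string.
#' @export
make_tracks <- function(spec = synthetic_sentence_spec(), id = "syn") {
  stopifnot(inherits(spec, "synthetic_sentence_spec"))
  with_seed(spec$rng_seed, {
    duration <- if (is.null(spec$duration)) stats::runif(1, 1.5, 2.5)
                else spec$duration
    fp <- 0.001
    n <- round(duration / fp)
    t <- (seq_len(n) - 1) * fp
    band <- spec$modulation_rate_band
    one_contour <- function(center, excursion) {
      k <- sample(3:5, 1)
      rates <- stats::runif(k, band[1], band[2])
      phases <- stats::runif(k, 0, 2 * pi)
      amps <- stats::runif(k, 0.3, 1)
      dev <- rowSums(vapply(seq_len(k), function(j)
        amps[j] * cos(2 * pi * rates[j] * t + phases[j]), numeric(n)))
      mid <- (max(dev) + min(dev)) / 2
      half <- (max(dev) - min(dev)) / 2
      dev <- if (half > 0) (dev - mid) * (excursion / half) else dev * 0
      center * exp(dev)
    }
    centers <- spec$formant_centers
    exc <- spec$log_excursion
    f1 <- one_contour(centers[1], exc[1])
    f2 <- one_contour(centers[2], exc[2])
    f3 <- one_contour(centers[3], exc[3])
    if (any(f2 - f1 < 200) || any(f3 <= f2))
      stop("infeasible synthetic-contour constraints: formant bands ",
           "overlap; reduce log_excursion or separate the centres",
           call. = FALSE)
    syll_env <- function(phase) {
      env <- (1 - cos(2 * pi * spec$syllable_rate * t + phase)) / 2
      0.05 + 0.95 * env
    }
    rel <- c(1, 0.4, 0.15)  # F1 dominates, as in natural speech spectra
    amps <- lapply(1:3, function(k) rel[k] * syll_env(stats::runif(1, 0,
                                                                   2 * pi)))
    n_kw <- if (is.null(spec$n_keywords)) sample(2:5, 1) else spec$n_keywords
    keywords <- make_pseudo_words(n_kw)
    phonemes <- unlist(strsplit(keywords, ""))
    sentence_tracks(
      id = id,
      f1 = formant_track(f1, amps[[1]], fp, "F1"),
      f2 = formant_track(f2, amps[[2]], fp, "F2"),
      f3 = formant_track(f3, amps[[3]], fp, "F3"),
      keywords = keywords, phonemes = phonemes)
  })
}

#' Generate a synthetic sentence corpus
#'
#' Builds `n` synthetic sentences with per-sentence seeds derived from a
#' single base seed; optionally writes each sentence's tracks to the
#' standard delimited text format.
#'
#' @param n number of sentences (>= 1).
#' @param base_seed integer corpus seed.
#' @param spec a [synthetic_sentence_spec()] used as the template (its
#'   `rng_seed` is replaced per sentence).
#' @param dir optional output directory for track files
#'   (`<id>.tsv` per sentence).
#' @return A list of [sentence_tracks()], ids `s001`, `s002`, ...
#' @export
make_corpus <- function(n, base_seed = 1,
                        spec = synthetic_sentence_spec(), dir = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("s%03d", i)
    spec_i <- spec
    spec_i$rng_seed <- derive_seed(base_seed, id)
    out[[i]] <- make_tracks(spec_i, id = id)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_formant_tracks(out[[i]], file.path(dir, paste0(id, ".tsv")))
    }
  }
  out
}

#' Simulate listener keyword outcomes under a psychometric model
#'
#' Each keyword of each planned trial is reported correctly with
#' independent probability `Psi(x)`, where `x` is the trial's condition
#' covariate (e.g. the scale factor in percent) and `Psi` the supplied
#' Weibull function. No lexical confusion structure is modelled.
#'
#' @param plan data frame with one row per sentence presentation and
#'   columns `condition` (id), `x` (covariate) and `n_keywords`.
#' @param psychometric a [weibull_params()].
#' @param n_listeners number of simulated listeners (default 1).
#' @param rng_seed integer seed.
#' @return `plan` replicated per listener with columns `listener` and
#'   `n_correct` added.
#' @export
simulate_responses <- function(plan, psychometric, n_listeners = 1,
                               rng_seed = 1) {
  stopifnot(is.data.frame(plan),
            all(c("condition", "x", "n_keywords") %in% names(plan)),
            nrow(plan) >= 1L,
            inherits(psychometric, "weibull_params"),
            n_listeners >= 1)
  p <- weibull_eval(plan$x, psychometric)
  with_seed(rng_seed, {
    out <- do.call(rbind, lapply(seq_len(n_listeners), function(l) {
      df <- plan
      df$listener <- l
      df$n_correct <- stats::rbinom(nrow(plan), plan$n_keywords, p)
      df
    }))
    rownames(out) <- NULL
    out
  })
}
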