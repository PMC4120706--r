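# Experiment construction: condition tables for the three experiments,
# counterbalanced sentence rotation, competitor generation under the
# F1-proximity constraint, and per-condition stimulus assembly.

#' Competitor specification
#'
#' Describes how a second-formant competitor (F2C) is derived from the
#' target F2: by spectral inversion about the geometric mean (speech-like),
#' as a band-limited triangle wave matched to F2's average rate and depth
#' of variation (not speech-like), or as a constant at the geometric mean.
#' The competitor's nominal frequency must stay at least
#' `min_separation_hz` from F1 at every frame; triangle competitors redraw
#' their random starting phase (up to `max_phase_redraws` times) when the
#' initial draw would violate this.
#'
#' @param kind one of `"inverted"`, `"triangle"`, `"constant"`.
#' @param scale_x depth scale factor in `[0, 1]`, relative to the
#'   unscaled target F2.
#' @param min_separation_hz minimum F2C-F1 separation in Hz (default 80).
#' @param max_phase_redraws redraw budget for triangle phases
#'   (default 100).
#' @param rng_seed integer seed for the phase draw (`NULL` uses the
#'   current RNG state).
#' @return An object of class `competitor_spec`.
#' @export
competitor_spec <- function(kind = c("inverted", "triangle", "constant"),
                            scale_x = 1, min_separation_hz = 80,
                            max_phase_redraws = 100, rng_seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(scale_x) || length(scale_x) != 1L ||
      scale_x < 0 || scale_x > 1)
    stop("scale_x must be in [0, 1]", call. = FALSE)
  stopifnot(min_separation_hz >= 0, max_phase_redraws >= 1)
  structure(list(kind = kind, scale_x = scale_x,
                 min_separation_hz = min_separation_hz,
                 max_phase_redraws = max_phase_redraws,
                 rng_seed = rng_seed),
            class = "competitor_spec")
}

#' Build the condition table for one experiment
#'
#' Returns the full stimulus-condition table:
#' * `exp1` — 11 diotic conditions differing only in the common scale
#'   factor applied to all three target formants (100% down to 0% in 10%
#'   steps), no competitor.
#' * `exp2` — 7 dichotic conditions, target formants at 50% depth. C1 is
#'   the control (left F1+F2C, right F3 only; inverted F2C at 100%);
#'   C2-C6 add an inverted F2C at 0-100% depth in 25% steps; C7 is the
#'   dichotic reference (left F1, right F2+F3, no competitor).
#' * `exp3` — 8 dichotic conditions, target formants at 50% depth. C1 is
#'   the control (right ear F2+F3 only, left silent); C2-C6 use
#'   triangle-wave F2Cs at 0-100% depth in 25% steps; C7 uses an inverted
#'   F2C at 100%; C8 is the dichotic reference.
#'
#' Dichotic conditions carry level offsets of +3 dB (left) and -7 dB
#' (right) relative to the diotic reference level: the overall reference
#' is raised 3 dB to compensate for splitting the formants between the
#' ears, and the right ear (F2+F3) sits about 10 dB below the left
#' (F1-dominated) ear.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @return A data frame with one row per condition and columns
#'   `experiment`, `id`, `left`, `right` (comma-separated formant sets),
#'   `target_scale_x`, `f2c_kind`, `f2c_scale_x`, `level_left_db`,
#'   `level_right_db`.
#' @export
#' @examples
#' build_condition_table("exp2")
build_condition_table <- function(experiment = c("exp1", "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    scales <- seq(100, 0, by = -10)
    return(data.frame(
      experiment = "exp1",
      id = sprintf("S%d", scales),
      left = "F1,F2,F3", right = "F1,F2,F3",
      target_scale_x = scales / 100,
      f2c_kind = NA_character_, f2c_scale_x = NA_real_,
      level_left_db = 0, level_right_db = 0,
      stringsAsFactors = FALSE))
  }
  if (experiment == "exp2") {
    df <- data.frame(
      experiment = "exp2",
      id = paste0("C", 1:7),
      left = c("F1,F2C", rep("F1,F2C", 5), "F1"),
      right = c("F3", rep("F2,F3", 5), "F2,F3"),
      target_scale_x = 0.5,
      f2c_kind = c(rep("inverted", 6), NA_character_),
      f2c_scale_x = c(1, 0, 0.25, 0.5, 0.75, 1, NA_real_),
      level_left_db = 3, level_right_db = -7,
      stringsAsFactors = FALSE)
    return(df)
  }
  data.frame(
    experiment = "exp3",
    id = paste0("C", 1:8),
    left = c("", rep("F1,F2C", 6), "F1"),
    right = c("F2,F3", rep("F2,F3", 6), "F2,F3"),
    target_scale_x = 0.5,
    f2c_kind = c(NA_character_, rep("triangle", 5), "inverted",
                 NA_character_),
    f2c_scale_x = c(NA_real_, 0, 0.25, 0.5, 0.75, 1, 1, NA_real_),
    level_left_db = 3, level_right_db = -7,
    stringsAsFactors = FALSE)
}

parse_formant_set <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Allocate sentences to conditions by counterbalanced rotation
#'
#' Splits the sentence list into equal consecutive blocks, one per
#' condition, and assigns block `b` to condition
#' `((b - 1 + rotation) mod n_conditions) + 1`. Across a full cycle of
#' rotations every sentence appears in every condition exactly once;
#' rotation `n_conditions` reproduces rotation 0.
#'
#' @param sentence_ids character vector of sentence ids; its length must
#'   be divisible by `n_conditions`.
#' @param n_conditions number of conditions.
#' @param rotation non-negative rotation index (default 0).
#' @return A list of length `n_conditions`; element `j` holds the
#'   sentence ids assigned to condition `j`.
#' @export
allocate_sentences <- function(sentence_ids, n_conditions, rotation = 0) {
  n <- length(sentence_ids)
  stopifnot(n_conditions >= 1, rotation >= 0)
  if (n %% n_conditions != 0)
    stop("number of sentences must be divisible by the number of ",
         "conditions", call. = FALSE)
  per <- n %/% n_conditions
  out <- vector("list", n_conditions)
  for (b in seq_len(n_conditions)) {
    cond <- ((b - 1 + rotation) %% n_conditions) + 1
    out[[cond]] <- sentence_ids[((b - 1) * per + 1):(b * per)]
  }
  out
}

#' Build a second-formant competitor track
#'
#' Derives an F2C frequency contour from the target F2 according to the
#' competitor kind, flattens its amplitude to the RMS power of F2's
#' amplitude contour, and enforces the minimum-separation constraint
#' against F1:
#' * `constant` — fixed at the geometric mean of F2.
#' * `inverted` — F2 inverted about its geometric mean on a log scale,
#'   then depth-scaled by `scale_x` (inversion and scaling share the
#'   pivot, so their order is unobservable).
#' * `triangle` — the modulation period is estimated from the 40-frame
#'   block-smoothed F2 contour ([estimate_cycles()]); the contour is a
#'   band-limited triangle wave centred on F2's geometric mean with half
#'   log-range `r` equal to half the raw F2 log-range, depth-scaled by
#'   `scale_x`, with a random starting phase. If the drawn phase violates
#'   the separation constraint a new phase is drawn, up to the redraw
#'   budget.
#'
#' Inverted and constant contours that violate the constraint raise an
#' error naming the worst frame (such sentences must be excluded or
#' regenerated upstream); only triangle phases can be redrawn.
#'
#' @param f2 the target F2 [formant_track()] (unscaled).
#' @param f1 the F1 [formant_track()] as presented (i.e. depth-scaled),
#'   same duration as `f2`.
#' @param spec a [competitor_spec()].
#' @return A [formant_track()] labelled `"F2C"`, with attributes
#'   `start_phase` (triangle kind) and `n_redraws`.
#' @export
make_competitor <- function(f2, f1, spec) {
  stopifnot(is_formant_track(f2), is_formant_track(f1),
            inherits(spec, "competitor_spec"))
  if (length(f2$freqs) != length(f1$freqs) ||
      f2$frame_period != f1$frame_period)
    stop("f1 and f2 must share frame count and frame period",
         call. = FALSE)
  g <- geometric_mean(f2)
  amp <- rms(f2$amps)
  n <- length(f2$freqs)
  fp <- f2$frame_period
  separation_error <- function(track) {
    bad <- check_min_separation(track, f1, spec$min_separation_hz)
    gap <- abs(track$freqs - f1$freqs)
    worst <- which.min(gap)
    stop(errorCondition(
      sprintf(paste0("competitor violates the %g-Hz separation ",
                     "constraint at %d frame(s); worst at frame %d ",
                     "(gap %.1f Hz)"),
              spec$min_separation_hz, length(bad), worst, gap[worst]),
      class = c("f2c_separation_error", "error", "condition")))
  }
  finish <- function(freqs, start_phase = NA_real_, n_redraws = 0L) {
    tr <- formant_track(freqs, rep(amp, n), fp, "F2C")
    attr(tr, "start_phase") <- start_phase
    attr(tr, "n_redraws") <- n_redraws
    tr
  }
  if (spec$kind == "constant") {
    tr <- finish(rep(g, n))
    if (length(check_min_separation(tr, f1, spec$min_separation_hz)) > 0)
      separation_error(tr)
    return(tr)
  }
  if (spec$kind == "inverted") {
    inv <- scale_depth(invert_about_gmean(f2), spec$scale_x)
    tr <- finish(inv$freqs)
    if (length(check_min_separation(tr, f1, spec$min_separation_hz)) > 0)
      separation_error(tr)
    return(tr)
  }
  # triangle
  sm <- block_smooth(f2$freqs, 40)
  ce <- estimate_cycles(sm, g, track_duration(f2))
  r <- (max(log(f2$freqs)) - min(log(f2$freqs))) / 2
  draw <- function() {
    phase <- stats::runif(1)
    tsp <- triangle_spec(g, r, ce$period_T, phase, spec$scale_x)
    list(phase = phase,
         track = triangle_contour(tsp, track_duration(f2), fp))
  }
  build <- function() {
    for (k in seq_len(spec$max_phase_redraws)) {
      cand <- draw()
      if (length(check_min_separation(cand$track, f1,
                                      spec$min_separation_hz)) == 0) {
        return(finish(cand$track$freqs, cand$phase, k - 1L))
      }
      last <- cand
    }
    separation_error(last$track)
  }
  if (is.null(spec$rng_seed)) build() else with_seed(spec$rng_seed, build())
}

#' Build the stereo stimulus for one sentence in one condition
#'
#' Applies the condition's common depth scale factor to the three target
#' formants, builds the competitor (if the condition has one) from the
#' *unscaled* target F2 — competitor depth is specified relative to the
#' natural F2 — routes the formants to the ears given by the condition,
#' and synthesizes both channels.
#'
#' @param sentence a [sentence_tracks()] object.
#' @param cond one row of a [build_condition_table()] data frame.
#' @param rng_seed base integer seed; the per-competitor seed is derived
#'   from it together with the sentence and condition ids, so a corpus is
#'   reproducible from a single seed.
#' @param source a [source_spec()].
#' @param res a [resonator_spec()].
#' @param ... further arguments passed to [assemble_dichotic()].
#' @return A [stereo_stimulus()] whose metadata records the condition id,
#'   sentence id, seed, and triangle phase (if any).
#' @export
build_stimulus <- function(sentence, cond, rng_seed = 1,
                           source = source_spec(),
                           res = resonator_spec(), ...) {
  stopifnot(inherits(sentence, "sentence_tracks"),
            is.data.frame(cond), nrow(cond) == 1L)
  x <- cond$target_scale_x
  scaled <- list(F1 = scale_depth(sentence$f1, x),
                 F2 = scale_depth(sentence$f2, x),
                 F3 = scale_depth(sentence$f3, x))
  comp <- NULL
  comp_seed <- NA_integer_
  if (!is.na(cond$f2c_kind)) {
    comp_seed <- derive_seed(rng_seed, sentence$id, cond$id)
    cspec <- competitor_spec(kind = cond$f2c_kind,
                             scale_x = cond$f2c_scale_x,
                             rng_seed = comp_seed)
    comp <- make_competitor(sentence$f2, scaled$F1, cspec)
  }
  pick <- function(names) {
    lapply(names, function(nm) {
      if (nm == "F2C") {
        if (is.null(comp))
          stop("condition routes F2C but specifies no competitor",
               call. = FALSE)
        comp
      } else scaled[[nm]]
    })
  }
  left <- pick(parse_formant_set(cond$left))
  right <- pick(parse_formant_set(cond$right))
  assemble_dichotic(
    left, right,
    level_offsets_db = c(cond$level_left_db, cond$level_right_db),
    source = source, res = res,
    meta = list(condition = cond$id, sentence = sentence$id,
                seed = comp_seed,
                start_phase = if (is.null(comp)) NA_real_
                              else attr(comp, "start_phase")),
    ...)
}

#' Synthesize and write all stimuli for one rotation of an experiment
#'
#' Allocates the corpus sentences to conditions by rotation, builds each
#' sentence's stimulus in its assigned condition, writes the WAV files,
#' and returns (and writes) a manifest.
#'
#' @param corpus list of [sentence_tracks()] objects; the corpus size
#'   must be divisible by the number of conditions.
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param rotation rotation index (default 0).
#' @param rng_seed base integer seed.
#' @param out_dir output directory for WAV files and the manifest
#'   (`manifest.tsv`); created if missing. `NULL` skips writing and only
#'   returns the manifest with in-memory stimuli.
#' @param ... passed to [build_stimulus()].
#' @return A data frame manifest: `sentence_id`, `condition`, `wav`,
#'   `seed`, `start_phase`, plus (when `out_dir` is `NULL`) a list column
#'   `stimulus`.
#' @export
make_stimuli <- function(corpus, experiment, rotation = 0, rng_seed = 1,
                         out_dir = NULL, ...) {
  conds <- build_condition_table(experiment)
  ids <- vapply(corpus, function(s) s$id, "")
  alloc <- allocate_sentences(ids, nrow(conds), rotation)
  rows <- list()
  stims <- list()
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, , drop = FALSE]
    for (sid in alloc[[ci]]) {
      sentence <- corpus[[match(sid, ids)]]
      stim <- build_stimulus(sentence, cond, rng_seed = rng_seed, ...)
      wav <- sprintf("%s_%s.wav", sid, cond$id)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_wav(stim, file.path(out_dir, wav))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = sid, condition = cond$id, wav = wav,
        seed = stim$meta$seed, start_phase = stim$meta$start_phase,
        stringsAsFactors = FALSE)
      stims[[length(stims) + 1L]] <- stim
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    manifest$stimulus <- stims
  }
  manifest
}

#' Audit competitor-F1 separation across a corpus
#'
#' Builds every competitor kind at every requested depth scale factor for
#' every sentence in a corpus (with seeded triangle phases and
#' redraw-on-violation) and records the minimum per-frame frequency gap
#' between each competitor and the F1 track as presented (i.e.
#' depth-scaled). Used to verify that generated stimuli respect the
#' minimum-separation constraint corpus-wide.
#'
#' @param corpus list of [sentence_tracks()] objects.
#' @param kinds competitor kinds to audit.
#' @param scale_factors depth scale factors to audit.
#' @param base_seed integer corpus seed for phase draws.
#' @param target_scale_x depth scale applied to the target formants
#'   (default 0.5, the depth at which targets are presented in the
#'   competitor experiments).
#' @param min_hz separation limit in Hz (default 80).
#' @return A data frame with columns `sentence_id`, `kind`, `scale_x`,
#'   `min_gap_hz`, `n_redraws`.
#' @export
competitor_separation_audit <- function(corpus,
                                        kinds = c("constant", "inverted",
                                                  "triangle"),
                                        scale_factors = c(0, 0.25, 0.5,
                                                          0.75, 1),
                                        base_seed = 1,
                                        target_scale_x = 0.5,
                                        min_hz = 80) {
  rows <- list()
  for (sentence in corpus) {
    f1 <- scale_depth(sentence$f1, target_scale_x)
    for (kind in kinds) {
      for (x in scale_factors) {
        spec <- competitor_spec(
          kind = kind, scale_x = x, min_separation_hz = min_hz,
          rng_seed = derive_seed(base_seed, sentence$id, kind, x))
        comp <- make_competitor(sentence$f2, f1, spec)
        rows[[length(rows) + 1L]] <- data.frame(
          sentence_id = sentence$id, kind = kind, scale_x = x,
          min_gap_hz = min(abs(comp$freqs - f1$freqs)),
          n_redraws = attr(comp, "n_redraws"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
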