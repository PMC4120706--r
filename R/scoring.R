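# Intelligibility scoring: tight keyword scoring with homonym acceptance,
# optimal phoneme alignment, pooled condition means, competitor efficacy.

#' Normalize a response transcript
#'
#' Case-folds, strips punctuation (keeping word-internal apostrophes),
#' collapses whitespace and tokenizes. No stemming: tight scoring demands
#' exact word forms.
#'
#' @param text character scalar.
#' @return Character vector of tokens.
#' @export
normalize_response <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9' ]+", " ", x)
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x)  # strip quoting apostrophes
  tokens <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  tokens[nzchar(tokens)]
}

#' Tight keyword score
#'
#' A keyword is scored correct only if its exact form — or a listed
#' homonym — appears among the response tokens. Matching consumes
#' response tokens one-to-one, so a single response word cannot satisfy
#' two keywords.
#'
#' @param ref_keywords character vector of designated keywords (>= 1).
#' @param response_text free-text listener response.
#' @param homonyms named list mapping a keyword to a character vector of
#'   accepted alternatives (e.g. `list(blew = "blue")`).
#' @return Percentage of keywords correct, in `[0, 100]`.
#' @export
#' @examples
#' tight_keyword_score(c("cat", "ran"), "the cat walked")  # 50
tight_keyword_score <- function(ref_keywords, response_text,
                                homonyms = list()) {
  ref_keywords <- tolower(as.character(ref_keywords))
  if (length(ref_keywords) < 1L)
    stop("keyword list must be non-empty", call. = FALSE)
  tokens <- normalize_response(response_text)
  used <- logical(length(tokens))
  correct <- 0L
  for (kw in ref_keywords) {
    accepted <- c(kw, tolower(as.character(homonyms[[kw]])))
    hit <- which(!used & tokens %in% accepted)
    if (length(hit) > 0L) {
      used[hit[1L]] <- TRUE
      correct <- correct + 1L
    }
  }
  100 * correct / length(ref_keywords)
}

#' Optimal phoneme alignment by dynamic programming
#'
#' Global minimum-cost alignment of a hypothesis phoneme sequence against
#' the reference, with insertions, deletions and substitutions. Default
#' costs are substitution 10, insertion 7, deletion 7 (so one
#' substitution, cost 10, is preferred over a deletion plus an insertion,
#' cost 14). Cost ties are broken preferring substitution/match, then
#' deletion. The returned counts satisfy
#' `hits + subs + dels = length(ref)`.
#'
#' @param ref,hyp character vectors of phoneme symbols, or single
#'   space-separated strings. May be empty.
#' @param costs named numeric vector `c(sub =, ins =, del =)`.
#' @return An object of class `phoneme_alignment`: list with `hits`,
#'   `subs`, `dels`, `ins`, `cost`, `ref_len`.
#' @export
#' @examples
#' align_phonemes(c("k", "ae", "t"), c("k", "ih", "t"))
align_phonemes <- function(ref, hyp, costs = c(sub = 10, ins = 7, del = 7)) {
  as_symbols <- function(x) {
    x <- as.character(x)
    if (length(x) == 1L && grepl(" ", x))
      x <- strsplit(trimws(x), "\\s+")[[1]]
    x[nzchar(x)]
  }
  ref <- as_symbols(ref)
  hyp <- as_symbols(hyp)
  stopifnot(all(c("sub", "ins", "del") %in% names(costs)))
  n <- length(ref)
  m <- length(hyp)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- (0:n) * costs[["del"]]
  D[1L, ] <- (0:m) * costs[["ins"]]
  # moves: 1 = diagonal (match/sub), 2 = up (deletion), 3 = left (insertion)
  move <- matrix(0L, n + 1L, m + 1L)
  move[-1L, 1L] <- 2L
  move[1L, -1L] <- 3L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag_cost <- D[i, j] + if (ref[i] == hyp[j]) 0 else costs[["sub"]]
      del_cost <- D[i, j + 1L] + costs[["del"]]
      ins_cost <- D[i + 1L, j] + costs[["ins"]]
      best <- min(diag_cost, del_cost, ins_cost)
      D[i + 1L, j + 1L] <- best
      move[i + 1L, j + 1L] <-
        if (diag_cost == best) 1L else if (del_cost == best) 2L else 3L
    }
  }
  hits <- 0L; subs <- 0L; dels <- 0L; ins <- 0L
  i <- n + 1L
  j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- move[i, j]
    if (mv == 1L) {
      if (ref[i - 1L] == hyp[j - 1L]) hits <- hits + 1L else subs <- subs + 1L
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      dels <- dels + 1L; i <- i - 1L
    } else {
      ins <- ins + 1L; j <- j - 1L
    }
  }
  structure(list(hits = hits, subs = subs, dels = dels, ins = ins,
                 cost = D[n + 1L, m + 1L], ref_len = n),
            class = "phoneme_alignment")
}

#' @export
print.phoneme_alignment <- function(x, ...) {
  cat(sprintf(
    "<phoneme_alignment: %d hits, %d subs, %d dels, %d ins (cost %g)>\n",
    x$hits, x$subs, x$dels, x$ins, x$cost))
  invisible(x)
}

#' Phonemic score from an alignment
#'
#' `100 * hits / ref_len`: the percentage of reference phonemes correctly
#' aligned. Insertions do not reduce the score.
#'
#' @param alignment a [align_phonemes()] result.
#' @param ref_len reference length; defaults to the alignment's.
#' @return Percentage in `[0, 100]`.
#' @export
phoneme_score <- function(alignment, ref_len = alignment$ref_len) {
  stopifnot(inherits(alignment, "phoneme_alignment"))
  if (!is.numeric(ref_len) || ref_len < 1)
    stop("reference must contain at least one phoneme", call. = FALSE)
  100 * alignment$hits / ref_len
}

#' Pooled keyword score for a condition
#'
#' Sentences contribute different numbers of keywords (typically 2-5), so
#' the condition mean pools over keywords — `100 * sum(correct) /
#' sum(keywords)` — giving equal weight to every keyword rather than to
#' every sentence.
#'
#' @param n_keywords integer vector, keywords per sentence (all >= 1).
#' @param n_correct integer vector, keywords correct per sentence
#'   (`0 <= n_correct <= n_keywords`).
#' @return Pooled percentage correct.
#' @export
#' @examples
#' pooled_condition_score(c(2, 5), c(2, 0))  # 28.57, not 50
pooled_condition_score <- function(n_keywords, n_correct) {
  if (length(n_keywords) < 1L) stop("empty outcome list", call. = FALSE)
  stopifnot(length(n_keywords) == length(n_correct),
            all(n_keywords >= 1), all(n_correct >= 0),
            all(n_correct <= n_keywords))
  100 * sum(n_correct) / sum(n_keywords)
}

#' Competitor efficacy
#'
#' The impact of adding a competitor, expressed relative to the dichotic
#' reference condition (no competitor; 0% efficacy) and the control
#' condition in which the competitor replaces the target F2 (100%
#' efficacy): `100 * (ref - cond) / (ref - control)`.
#'
#' @param cond_pct score (percent correct) for the condition of interest;
#'   may be a vector.
#' @param ref_pct score for the dichotic reference condition.
#' @param control_pct score for the control condition.
#' @return Efficacy in percent (vectorized over `cond_pct`).
#' @export
#' @examples
#' competitor_efficacy(40, ref_pct = 50, control_pct = 0)  # 20
competitor_efficacy <- function(cond_pct, ref_pct, control_pct) {
  stopifnot(is.numeric(cond_pct), is.numeric(ref_pct),
            is.numeric(control_pct))
  if (ref_pct <= control_pct)
    stop("efficacy is undefined unless the reference score exceeds the ",
         "control score", call. = FALSE)
  100 * (ref_pct - cond_pct) / (ref_pct - control_pct)
}
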