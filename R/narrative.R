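## Linguistic units: POS-based candidate extraction, stopword / task-word
## removal, per-image singleton removal, and narrative descriptive statistics.

#' Construct a narrative
#'
#' One observer's time-stamped, part-of-speech tagged spoken description of
#' one image.
#'
#' @param observer,image Identifiers.
#' @param tokens Data frame with columns `surface` (lowercased word), `pos`
#'   (Penn-style tag), `t_on`, `t_off` (seconds). Onsets must be
#'   non-decreasing and offsets must not precede onsets.
#' @export
narrative <- function(observer, image, tokens) {
  stopifnot(is.data.frame(tokens),
            all(c("surface", "pos", "t_on", "t_off") %in% names(tokens)))
  if (nrow(tokens)) {
    if (any(!nzchar(tokens$surface))) stop_fmt("empty token surface")
    if (any(tokens$t_on < 0) || any(tokens$t_off < tokens$t_on))
      stop_fmt("token times must satisfy 0 <= t_on <= t_off")
    if (is.unsorted(tokens$t_on)) stop_fmt("token onsets must be non-decreasing")
  }
  tokens$surface <- tolower(tokens$surface)
  structure(list(observer = as.character(observer), image = as.character(image),
                 tokens = as.data.frame(tokens, stringsAsFactors = FALSE)),
            class = "narrative")
}

#' @export
print.narrative <- function(x, ...) {
  cat(sprintf("<narrative> observer %s, image %s: %d tokens\n",
              x$observer, x$image, nrow(x$tokens)))
  invisible(x)
}

#' Default part-of-speech whitelist for linguistic units
#'
#' Adjectives, common and proper nouns (singular and plural), gerunds, and
#' foreign words - the word classes most likely to name image content.
#' @export
default_pos_whitelist <- function() {
  c("JJ", "JJR", "JJS", "NN", "NNS", "NNP", "NNPS", "VBG", "FW")
}

#' Extract candidate linguistic-unit tokens by part of speech
#'
#' @param narr A [narrative()].
#' @param pos_whitelist Tags to keep (default [default_pos_whitelist()]).
#' @return The token data frame restricted to whitelisted tags, order intact.
#' @export
extract_candidate_tokens <- function(narr, pos_whitelist = default_pos_whitelist()) {
  stopifnot(inherits(narr, "narrative"))
  tok <- narr$tokens
  if (nrow(tok) && any(is.na(tok$pos) | !nzchar(tok$pos)))
    stop_fmt("untagged token '%s' at %.2f s",
             tok$surface[which(is.na(tok$pos) | !nzchar(tok$pos))[1]],
             tok$t_on[which(is.na(tok$pos) | !nzchar(tok$pos))[1]])
  tok[tok$pos %in% pos_whitelist, , drop = FALSE]
}

#' Load the packaged English stopword list
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "gazealign"),
            warn = FALSE)
}

#' Remove stopwords and task-instruction words
#'
#' @param tokens Token data frame with a `surface` column.
#' @param stopwords Lowercased stopword list (default the packaged English
#'   list, which includes spoken-language fillers such as "okay" and "um").
#' @param task_words Words tied to the elicitation protocol rather than the
#'   image (default `"next"`, the instruction word for advancing stimuli).
#' @export
remove_stopwords <- function(tokens, stopwords = default_stopwords(),
                             task_words = "next") {
  drop <- tokens$surface %in% c(tolower(stopwords), tolower(task_words))
  tokens[!drop, , drop = FALSE]
}

#' Remove per-image singleton word forms
#'
#' A surface form uttered exactly once across all of an image's narratives is
#' removed everywhere: such words tend to be transcription errors or
#' idiosyncratic word choices that cannot be grounded reliably. Counting is
#' done on the token lists as given (i.e. after any upstream filtering).
#'
#' @param token_lists List of token data frames, one per narrative of a single
#'   image.
#' @return The list with singleton forms removed, order otherwise preserved.
#' @export
remove_singletons <- function(token_lists) {
  all_surfaces <- unlist(lapply(token_lists, function(t) t$surface))
  counts <- table(all_surfaces)
  singletons <- names(counts)[counts == 1L]
  lapply(token_lists, function(t) t[!(t$surface %in% singletons), , drop = FALSE])
}

#' Token, type, and type-token-ratio statistics for a narrative
#'
#' Computed on the raw tokenized narrative (before linguistic-unit filtering),
#' as a first-order measure of narrative length and lexical diversity.
#'
#' @param tokens Token data frame with a `surface` column.
#' @return List with `n_tokens`, `n_types`, `ttr` (`NA` when empty).
#' @export
narrative_stats <- function(tokens) {
  n <- nrow(tokens)
  ty <- length(unique(tokens$surface))
  list(n_tokens = n, n_types = ty, ttr = if (n > 0) ty / n else NA_real_)
}

#' Full linguistic-unit pipeline for one image
#'
#' POS filtering, stopword/task-word removal, then per-image singleton
#' removal, applied to all of an image's narratives together. The pipeline is
#' idempotent and preserves token order and onsets.
#'
#' @param narratives List of [narrative()] objects for one image.
#' @param pos_whitelist,stopwords,task_words See the individual steps.
#' @return Named list (by observer) of linguistic-unit data frames
#'   `(surface, t_on)`.
#' @export
linguistic_units <- function(narratives, pos_whitelist = default_pos_whitelist(),
                             stopwords = default_stopwords(),
                             task_words = "next") {
  toks <- lapply(narratives, function(n)
    remove_stopwords(extract_candidate_tokens(n, pos_whitelist),
                     stopwords, task_words))
  toks <- remove_singletons(toks)
  out <- lapply(toks, function(t)
    data.frame(surface = t$surface, t_on = t$t_on, stringsAsFactors = FALSE))
  names(out) <- vapply(narratives, function(n) n$observer, character(1))
  out
}
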