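# Compound terms are handled as word sequences. Every public function here
# accepts either a single string ("right upper lobe") or a character vector
# of words; strings are split on whitespace, and hyphenated words
# ("right-sided") count as one word throughout.

term_words <- function(term) {
  if (length(term) == 1 && grepl("[[:space:]]", term)) {
    term <- strsplit(normalize_term(term), " ", fixed = TRUE)[[1]]
  }
  tolower(term[nzchar(term)])
}

#' Count the words of a term
#'
#' @param term A string or character vector of terms (each counted on
#'   whitespace; hyphenated words count once).
#' @return Integer vector of word counts.
#' @export
#' @examples
#' word_count("right-sided ij central venous catheter")  # 5
word_count <- function(term) {
  if (length(term) == 0) return(integer())
  vapply(normalize_term(term),
         function(x) if (!nzchar(x)) 0L else length(strsplit(x, " ", fixed = TRUE)[[1]]),
         integer(1), USE.NAMES = FALSE)
}

#' Split a phrase at conjunctions
#'
#' Long coordinated phrases are divided at "and"/"or" so that each conjunct
#' is handled as its own compound term: "right pleural effusion and left
#' lung pneumothorax" becomes two segments. Conjunction tokens are
#' discarded; empty segments are dropped.
#'
#' @param phrase String or word vector.
#' @return Character vector of segment strings.
#' @export
#' @examples
#' split_on_conjunctions("abdomen and neck")
split_on_conjunctions <- function(phrase) {
  split_at(term_words(phrase), .pos_conj)
}

#' Split a phrase at prepositions
#'
#' "right upper lobe of lung base" becomes "right upper lobe" and
#' "lung base"; each segment is decomposed independently downstream. The
#' preposition itself is discarded.
#'
#' @param phrase String or word vector.
#' @return Character vector of segment strings.
#' @export
split_on_prepositions <- function(phrase) {
  split_at(term_words(phrase), .pos_prep)
}

#' Split a phrase at both conjunctions and prepositions
#'
#' @param phrase String or word vector.
#' @return Character vector of segment strings.
#' @export
split_phrase <- function(phrase) {
  split_at(term_words(phrase), c(.pos_conj, .pos_prep))
}

split_at <- function(words, breakers) {
  if (length(words) == 0) return(character())
  is_break <- words %in% breakers
  grp <- cumsum(is_break)
  segs <- split(words[!is_break], grp[!is_break])
  out <- vapply(segs, paste, character(1), collapse = " ")
  unname(out[nzchar(out)])
}

#' Identify the stem term of a segment
#'
#' The stem is the head of the compound term: its rightmost non-stop word.
#' In "right upper lobe" every word but "lobe" is a modifier, so the stem is
#' "lobe"; for a single-word segment the word is its own stem.
#'
#' @param segment String or word vector (one segment, already split at
#'   conjunctions/prepositions).
#' @param stopwords Stop-word list.
#' @return The stem word (length-1 character).
#' @export
#' @examples
#' identify_stem("right upper lobe")
identify_stem <- function(segment, stopwords = radterm_stopwords()) {
  words <- term_words(segment)
  keep <- !(words %in% tolower(stopwords))
  if (!any(keep)) {
    abort(paste0("no stem: segment consists only of stop words: '",
                 paste(words, collapse = " "), "'"))
  }
  words[max(which(keep))]
}

#' Generate all compound-term patterns of a segment
#'
#' An n-word compound term is annotated under *all* its patterns: the
#' suffixes of length 2..n, each ending at the stem. "right upper lobe"
#' yields "right upper lobe" and "upper lobe"; a 5-word term like
#' "right-sided ij central venous catheter" yields 4 patterns down to
#' "venous catheter". The bare stem is not a pattern (single terms are
#' excluded from the compound-term experiments), so a 1-word segment yields
#' an empty set. Trailing stop words are trimmed first so every pattern ends
#' at the stem.
#'
#' @param segment String or word vector (conjunction/preposition-free).
#' @param stopwords Stop-word list used to locate the stem.
#' @return Tibble with columns `segment`, `stem`, `pattern`, `n_words`,
#'   one row per pattern, longest first.
#' @export
#' @examples
#' generate_patterns("right upper lobe")
generate_patterns <- function(segment, stopwords = radterm_stopwords()) {
  words <- term_words(segment)
  keep <- !(words %in% tolower(stopwords))
  if (any(keep)) words <- words[seq_len(max(which(keep)))]
  n <- length(words)
  if (n < 2) {
    return(tibble(segment = character(), stem = character(),
                  pattern = character(), n_words = integer()))
  }
  stem <- identify_stem(words, stopwords)
  starts <- seq_len(n - 1)
  pats <- vapply(starts, function(i) paste(words[i:n], collapse = " "),
                 character(1))
  tibble(
    segment = paste(words, collapse = " "),
    stem = stem,
    pattern = pats,
    n_words = n - starts + 1L
  )
}

#' Decompose a free phrase into stems and patterns
#'
#' Convenience wrapper: splits at conjunctions and prepositions, then
#' generates the pattern set of each resulting segment. The returned table
#' matches the audit-dump layout `segment  stem  pattern`.
#'
#' @inheritParams generate_patterns
#' @param phrase String or word vector.
#' @return Tibble as in [generate_patterns()], rows for all segments.
#' @export
decompose_phrase <- function(phrase, stopwords = radterm_stopwords()) {
  segs <- split_phrase(phrase)
  purrr::map_dfr(segs, generate_patterns, stopwords = stopwords)
}
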