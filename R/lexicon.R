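#' Build a lookup lexicon
#'
#' A lexicon is the NER lookup table: a tibble with one row per
#' (surface, concept) pair. Surfaces are normalized to lowercase,
#' single-spaced form at construction, so lookup is exact string equality on
#' normalized text. Homonyms — the same surface mapped to several concepts,
#' possibly from different source dictionaries — are retained; a lookup may
#' legitimately return more than one concept and no disambiguation is
#' attempted.
#'
#' @param concept_id Character vector of concept identifiers.
#' @param semantic_class Character vector of top-class labels.
#' @param surface Character vector of (possibly multi-word) terms.
#' @param source Source dictionary tag, one of `"DEFAULT"`, `"RADLEX"`,
#'   `"GPD"`, `"CTED"`, `"SYNTHETIC"`; recycled.
#' @return A `radterm_lexicon` tibble with columns `concept_id`,
#'   `semantic_class`, `surface`, `source`, deduplicated on
#'   (`surface`, `concept_id`).
#' @export
#' @examples
#' lexicon("RID38666", "clinical finding", "Pleural  Effusion")
lexicon <- function(concept_id = character(), semantic_class = character(),
                    surface = character(), source = "DEFAULT") {
  df <- tibble(
    concept_id = as.character(concept_id),
    semantic_class = as.character(semantic_class),
    surface = normalize_term(as.character(surface)),
    source = as.character(source)
  )
  as_lexicon(df)
}

#' Coerce a data frame to a lexicon
#'
#' @param df Data frame with columns `concept_id`, `semantic_class`,
#'   `surface` and optionally `source`.
#' @return A `radterm_lexicon` tibble.
#' @export
as_lexicon <- function(df) {
  need <- c("concept_id", "semantic_class", "surface")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("lexicon is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"source" %in% names(df)) df$source <- "DEFAULT"
  out <- as_tibble(df)[, c("concept_id", "semantic_class", "surface", "source")]
  out$surface <- normalize_term(out$surface)
  bad <- !nzchar(out$surface) & nrow(out) > 0
  if (any(bad)) abort("lexicon surfaces must be nonempty.")
  out <- distinct(out, .data$surface, .data$concept_id, .keep_all = TRUE)
  class(out) <- c("radterm_lexicon", class(tibble()))
  out
}

#' Read a bar-separated-value (BSV) dictionary
#'
#' Dictionaries are exchanged as BSV: UTF-8 text, no header, one entry per
#' line with exactly three pipe-separated fields
#' `concept_id|semantic_class|surface`. Duplicate lines collapse to one
#' entry.
#'
#' @param path Path to a BSV file.
#' @param source Source tag to stamp on every entry (the BSV format itself
#'   does not carry the source dictionary).
#' @return A `radterm_lexicon` tibble.
#' @export
read_dictionary_bsv <- function(path, source = "DEFAULT") {
  if (!file.exists(path)) abort(paste0("no such dictionary file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warn(paste0("empty dictionary file: ", path))
    return(lexicon(source = character()))
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    bad <- idx[nf != 3][1]
    abort(paste0("malformed BSV line ", bad, " in ", path,
                 ": expected 3 pipe-separated fields, got ", nf[nf != 3][1]))
  }
  m <- do.call(rbind, fields)
  lexicon(concept_id = m[, 1], semantic_class = m[, 2], surface = m[, 3],
          source = source)
}

#' Write a lexicon to canonical BSV
#'
#' Canonical form: UTF-8, no header, lines sorted by (`surface`,
#' `concept_id`), fields pipe-separated. `read_dictionary_bsv()` of a written
#' file reproduces the lexicon (the `source` tag is supplied at read time and
#' is not serialized).
#'
#' @param lex A `radterm_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary_bsv <- function(lex, path) {
  lex <- as_lexicon(lex)
  ord <- order(lex$surface, lex$concept_id, method = "radix")
  lex <- lex[ord, ]
  lines <- paste(lex$concept_id, lex$semantic_class, lex$surface, sep = "|")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Combine dictionaries
#'
#' Set union of entries, mirroring the composition patterns used for the NER
#' experiments (base dictionary alone, base + domain ontology, base + domain
#' ontology + general-purpose dictionary). When the same surface arrives from
#' several sources all entries are kept — lookup may return several concepts —
#' and source tags are preserved. No source takes precedence over another.
#'
#' @param ... Lexicons, or a single list of lexicons.
#' @return A merged `radterm_lexicon`.
#' @export
#' @examples
#' a <- lexicon("X1", "anatomical entity", "upper lobe", "DEFAULT")
#' b <- lexicon("R1", "anatomical entity", "upper lobe", "RADLEX")
#' nrow(merge_lexicons(a, b))
merge_lexicons <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  if (length(parts) < 1) abort("merge_lexicons() needs at least one lexicon.")
  parts <- lapply(parts, as_lexicon)
  out <- bind_rows(parts)
  # union semantics on (surface, concept_id); first occurrence keeps its tag
  as_lexicon(distinct(out, .data$surface, .data$concept_id, .keep_all = TRUE))
}

#' Drop single-word entries
#'
#' The compound-term experiments remove single terms from every dictionary so
#' that only multi-word surfaces can match. Hyphenated words
#' ("right-sided") count as one word.
#'
#' @param lex A `radterm_lexicon`.
#' @return The lexicon restricted to entries with at least two words.
#' @export
filter_single_terms <- function(lex) {
  lex <- as_lexicon(lex)
  as_lexicon(lex[word_count(lex$surface) >= 2, ])
}

# Exact-match index: environment keyed by surface -> integer row ids.
# Built once per annotation run; amortized O(1) lookup.
lexicon_index <- function(lex) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(lex)))
  if (nrow(lex) > 0) {
    sp <- split(seq_len(nrow(lex)), lex$surface)
    for (s in names(sp)) assign(s, sp[[s]], envir = env)
  }
  max_words <- if (nrow(lex) > 0) max(word_count(lex$surface)) else 0L
  list(env = env, max_words = max_words)
}

#' @export
print.radterm_lexicon <- function(x, ...) {
  cat("<radterm lexicon: ", nrow(x), " entries, ",
      length(unique(x$surface)), " distinct surfaces>\n", sep = "")
  NextMethod()
}
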