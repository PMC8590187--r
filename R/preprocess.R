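# --- closed-class word lists --------------------------------------------
# A deliberately small, deterministic tagger: radiology-report NP chunking
# needs little more than "is this a modifier, a head-ish word, or glue".
# The lists are constants here; the stop-word list is user-replaceable.

.radterm_stopwords <- c(
  "a", "an", "the", "and", "or", "of", "in", "on", "at", "to", "for",
  "with", "without", "from", "by", "as", "is", "are", "was", "were", "be",
  "been", "no", "not", "there", "this", "that", "these", "those", "it",
  "its", "per"
)

.pos_prep <- c("of", "in", "on", "at", "to", "for", "with", "without",
               "from", "by", "into", "over", "under", "within", "near")
.pos_conj <- c("and", "or", "nor", "but")
.pos_det  <- c("a", "an", "the", "no", "this", "that", "these", "those",
               "any", "some", "each", "every")
.pos_verbish <- c("is", "are", "was", "were", "be", "been", "seen", "noted",
                  "identified", "demonstrated", "demonstrates", "shows",
                  "shown", "appears", "remains", "persists", "made",
                  "compared", "there", "not", "as", "it", "available")
.pos_adj_lexicon <- c("right", "left", "upper", "lower", "mild", "small",
                      "large", "severe", "acute", "chronic", "new", "stable",
                      "unchanged", "bilateral", "low", "high", "soft")
.pos_adj_suffix <- c("al", "ous", "ic", "ive", "ary", "ar", "ed", "ing")

#' Default stop-word list
#'
#' A compact English list (32 words) including the conjunctions and
#' prepositions that split compound terms ("and", "or", "of"). Stop words
#' are *flagged* on tokens, never deleted from text, so offsets stay valid;
#' dictionary matching then skips flagged tokens. The same list ships as
#' `system.file("extdata", "stopwords_en.txt", package = "radterm")` for the
#' pipeline's `stopwords` file option; any newline-separated word list can
#' replace it.
#'
#' @return Character vector of lowercase stop words.
#' @export
radterm_stopwords <- function() .radterm_stopwords

#' Tokenize raw text with character offsets
#'
#' Whitespace/punctuation tokenization. A hyphenated word ("right-sided")
#' stays a single token; every other non-alphanumeric character becomes its
#' own token. Offsets are 0-based, half-open, indexing the input string
#' exactly.
#'
#' @param text A single string.
#' @return Tibble with columns `text`, `start`, `end`, `sentence` (1-based
#'   sentence number; boundaries at `.`, `!`, `?` tokens).
#' @param abbreviations Lowercase words after which a period does not end a
#'   sentence.
#' @export
#' @examples
#' tokenize("right-sided ij central venous catheter")
tokenize <- function(text, abbreviations = c("dr", "mr", "ms", "vs", "e", "g", "i")) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(text = character(), start = integer(), end = integer(),
                  sentence = integer()))
  }
  m <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(text = character(), start = integer(), end = integer(),
                  sentence = integer()))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  toks <- substring(text, starts + 1L, starts + lens)
  sent <- integer(length(toks))
  cur <- 1L
  prev_word <- ""
  for (i in seq_along(toks)) {
    sent[i] <- cur
    if (grepl("^[.!?]$", toks[i]) && !(tolower(prev_word) %in% abbreviations)) {
      cur <- cur + 1L
    }
    if (grepl("^[A-Za-z0-9]", toks[i])) prev_word <- toks[i]
  }
  tibble(text = toks, start = starts, end = starts + lens, sentence = sent)
}

#' Tag tokens with coarse part-of-speech classes and stop-word flags
#'
#' A deterministic rule/lexicon tagger standing in for a full POS pipeline:
#' closed-class lists assign PREP, CONJ and DET; a short adjective lexicon
#' plus suffix heuristics (-al, -ous, -ic, ...) assign ADJ; a small
#' verb-like list and punctuation fall to OTHER; everything else defaults to
#' NOUN. Words can be swapped behind this contract without touching the
#' chunker.
#'
#' @param tokens Token tibble from [tokenize()].
#' @param stopwords Character vector of stop words to flag.
#' @return The tibble with `pos` and `is_stop` columns added.
#' @export
pos_tag <- function(tokens, stopwords = radterm_stopwords()) {
  lower <- tolower(tokens$text)
  pos <- rep("NOUN", length(lower))
  is_word <- grepl("^[A-Za-z0-9]", tokens$text)
  pos[!is_word] <- "OTHER"
  pos[lower %in% .pos_verbish] <- "OTHER"
  suffix_re <- paste0("(", paste(.pos_adj_suffix, collapse = "|"), ")$")
  adj <- is_word & (lower %in% .pos_adj_lexicon |
                      (nchar(lower) > 4 & grepl(suffix_re, lower)))
  pos[adj] <- "ADJ"
  pos[lower %in% .pos_det] <- "DET"
  pos[lower %in% .pos_conj] <- "CONJ"
  pos[lower %in% .pos_prep] <- "PREP"
  tokens$pos <- pos
  tokens$is_stop <- lower %in% tolower(stopwords)
  tokens
}

#' Identify noun-phrase chunks
#'
#' Extracts maximal runs of non-stop ADJ/NOUN tokens ending in a NOUN within
#' each sentence — the chunker behind all dictionary matching. With
#' `join_prepositions = TRUE`, two such runs separated by exactly one PREP
#' token are merged into one phrase; runs are never joined across a
#' conjunction, so "right pleural effusion and left lung pneumothorax"
#' always yields two phrases.
#'
#' @param tokens POS-tagged token tibble from [pos_tag()].
#' @param join_prepositions Join `NP PREP NP` into a single phrase?
#' @return Tibble with columns `start`, `end` (character offsets),
#'   `first_token`, `last_token` (row indices into `tokens`), `n_tokens`.
#' @export
chunk_noun_phrases <- function(tokens, join_prepositions = FALSE) {
  empty <- tibble(start = integer(), end = integer(),
                  first_token = integer(), last_token = integer(),
                  n_tokens = integer())
  if (nrow(tokens) == 0) return(empty)
  if (is.null(tokens$pos)) abort("tokens must be POS-tagged; see pos_tag().")

  in_run <- tokens$pos %in% c("ADJ", "NOUN") & !tokens$is_stop
  runs <- list()
  i <- 1
  n <- nrow(tokens)
  while (i <= n) {
    if (!in_run[i]) { i <- i + 1; next }
    j <- i
    while (j < n && in_run[j + 1] && tokens$sentence[j + 1] == tokens$sentence[i]) {
      j <- j + 1
    }
    # trim trailing non-NOUN so the chunk ends at its head
    k <- j
    while (k >= i && tokens$pos[k] != "NOUN") k <- k - 1
    if (k >= i) runs[[length(runs) + 1]] <- c(as.integer(i), as.integer(k))
    i <- j + 1
  }
  if (length(runs) == 0) return(empty)

  if (join_prepositions && length(runs) > 1) {
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- seq(last[2] + 1, r[1] - 1)
      if (length(gap) == 1 && tokens$pos[gap] == "PREP" &&
          tokens$sentence[gap] == tokens$sentence[r[1]]) {
        merged[[length(merged)]] <- c(last[1], r[2])
      } else {
        merged[[length(merged) + 1]] <- r
      }
    }
    runs <- merged
  }

  first <- vapply(runs, `[`, integer(1), 1)
  last <- vapply(runs, `[`, integer(1), 2)
  tibble(
    start = tokens$start[first],
    end = tokens$end[last],
    first_token = first,
    last_token = last,
    n_tokens = last - first + 1L
  )
}

#' Load a report corpus
#'
#' Reports arrive as a long TSV (or equivalent data frame) with columns
#' `doc_id`, `modality`, `section`, `text` — one row per section. Sections
#' are assembled per document, in row order, into `raw_text` joined with
#' single newlines; all downstream character offsets index this assembled
#' text. Section names outside `sections_use` are kept but flagged with a
#' warning. Alternatively `path` may be a directory of `.txt` files named
#' `<modality>_<id>.txt`, each loaded as a single `findings` section.
#'
#' @param path TSV path, data frame, or directory of plain-text reports.
#' @param sections_use Recognised section names.
#' @return Tibble with one row per report: `doc_id`, `modality`, `raw_text`,
#'   `sections` (named list of section texts), `n_sections`.
#' @export
load_reports <- function(path,
                         sections_use = c("findings", "interpretations",
                                          "impressions")) {
  if (is.data.frame(path)) {
    df <- as_tibble(path)
  } else if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    df <- purrr::map_dfr(files, function(f) {
      id <- sub("\\.txt$", "", basename(f))
      tibble(doc_id = id,
             modality = toupper(sub("_.*$", "", id)),
             section = "findings",
             text = paste(readLines(f, warn = FALSE), collapse = "\n"))
    })
  } else {
    if (!file.exists(path)) abort(paste0("no such corpus: ", path))
    df <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      colClasses = "character", quote = "",
                                      na.strings = NULL,
                                      fileEncoding = "UTF-8"))
  }
  need <- c("doc_id", "modality", "section", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(tibble(doc_id = character(), modality = character(),
                  raw_text = character(), sections = list(),
                  n_sections = integer()))
  }
  key <- paste(df$doc_id, df$section)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate doc_id + section: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  df$modality <- normalize_modality(df$modality)
  unknown <- setdiff(unique(df$section), sections_use)
  if (length(unknown) > 0) {
    warn(paste0("unrecognised section name(s) kept: ",
                paste(unknown, collapse = ", ")))
  }
  df %>%
    group_by(.data$doc_id) %>%
    summarise(
      modality = .data$modality[1],
      raw_text = paste(.data$text, collapse = "\n"),
      sections = list(setNames(as.list(.data$text), .data$section)),
      n_sections = dplyr::n(),
      .groups = "drop"
    )
}

normalize_modality <- function(x) {
  up <- toupper(gsub("[^A-Za-z]", "", x))
  up[up %in% c("XRAY", "XR", "RADIOGRAPHY")] <- "XRAY"
  ok <- c("CT", "MRI", "PET", "XRAY")
  bad <- setdiff(unique(up), ok)
  if (length(bad) > 0) {
    abort(paste0("unknown modality value(s): ", paste(bad, collapse = ", ")))
  }
  up
}

#' Write a corpus back to its long TSV form
#'
#' @param corpus Long-format tibble (`doc_id`, `modality`, `section`, `text`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  utils::write.table(corpus[, c("doc_id", "modality", "section", "text")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
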