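#' Annotate one document by dictionary lookup
#'
#' The core matcher. The text is lowercased (offsets preserved), tokenized,
#' tagged and chunked into noun phrases; inside each noun phrase every
#' contiguous window of *content* tokens (stop-flagged tokens are
#' transparent: skipped when joining, but spanned by the resulting offsets)
#' is joined with single spaces and looked up in the lexicon by exact string
#' equality. Each hit yields one annotation; with `policy = "all"` (the
#' default, matching a gold standard that contains every pattern of a
#' compound term) nested hits are all emitted, while `policy = "longest"`
#' keeps only hits not nested inside a longer hit. Duplicates by
#' (start, end, concept) collapse.
#'
#' @param text Raw report text (one document).
#' @param lex A `radterm_lexicon` (surfaces normalized).
#' @param doc_id Document identifier stamped on the annotations.
#' @param policy `"all"` or `"longest"`.
#' @param join_prepositions Passed to [chunk_noun_phrases()].
#' @param stopwords Stop-word list.
#' @return Annotation tibble: `doc_id`, `start`, `end`, `surface`,
#'   `concept_id`, `semantic_class`, `source`, ordered by (start, end).
#' @export
#' @examples
#' lex <- lexicon(c("L1", "L2"), "anatomical entity",
#'                c("right upper lobe", "upper lobe"))
#' annotate_text("There is scarring in the right upper lobe.", lex)
annotate_text <- function(text, lex, doc_id = "doc1", policy = c("all", "longest"),
                          join_prepositions = FALSE,
                          stopwords = radterm_stopwords()) {
  policy <- match.arg(policy)
  lex <- as_lexicon(lex)
  idx <- lexicon_index(lex)
  annotate_text_impl(text, lex, idx, doc_id, policy, join_prepositions,
                     stopwords)
}

annotate_text_impl <- function(text, lex, idx, doc_id, policy,
                               join_prepositions, stopwords) {
  empty <- tibble(doc_id = character(), start = integer(), end = integer(),
                  surface = character(), concept_id = character(),
                  semantic_class = character(), source = character())
  if (idx$max_words == 0) return(empty)
  toks <- pos_tag(tokenize(normalize_text(text)), stopwords = stopwords)
  nps <- chunk_noun_phrases(toks, join_prepositions = join_prepositions)
  if (nrow(nps) == 0) return(empty)

  hits <- list()
  for (r in seq_len(nrow(nps))) {
    rng <- seq(nps$first_token[r], nps$last_token[r])
    content <- rng[!toks$is_stop[rng]]
    k <- length(content)
    if (k == 0) next
    for (i in seq_len(k)) {
      jmax <- min(k, i + idx$max_words - 1)
      for (j in i:jmax) {
        surf <- paste(toks$text[content[i:j]], collapse = " ")
        rows <- idx$env[[surf]]
        if (is.null(rows)) next
        hits[[length(hits) + 1]] <- tibble(
          doc_id = doc_id,
          start = toks$start[content[i]],
          end = toks$end[content[j]],
          surface = surf,
          concept_id = lex$concept_id[rows],
          semantic_class = lex$semantic_class[rows],
          source = lex$source[rows]
        )
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- bind_rows(hits)
  out <- distinct(out, .data$start, .data$end, .data$concept_id,
                  .keep_all = TRUE)
  if (policy == "longest") out <- drop_nested(out)
  arrange(out, .data$start, .data$end, .data$concept_id)
}

# keep annotations whose span is not strictly contained in another's span
drop_nested <- function(ann) {
  if (nrow(ann) < 2) return(ann)
  spans <- distinct(ann, .data$start, .data$end)
  keep_span <- vapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    !any(spans$start <= s & spans$end >= e &
           (spans$start != s | spans$end != e))
  }, logical(1))
  kept <- spans[keep_span, ]
  dplyr::semi_join(ann, kept, by = c("start", "end"))
}

#' Annotate a whole corpus
#'
#' Applies [annotate_text()] per document; output is deterministic, ordered
#' by (doc_id, start, end).
#'
#' @param reports Report tibble from [load_reports()] (columns `doc_id`,
#'   `raw_text`), or a long corpus tibble/TSV accepted by [load_reports()].
#' @inheritParams annotate_text
#' @return Annotation tibble over all documents.
#' @export
annotate_corpus <- function(reports, lex, policy = c("all", "longest"),
                            join_prepositions = FALSE,
                            stopwords = radterm_stopwords()) {
  policy <- match.arg(policy)
  if (!("raw_text" %in% names(reports))) reports <- load_reports(reports)
  lex <- as_lexicon(lex)
  idx <- lexicon_index(lex)
  empty <- tibble(doc_id = character(), start = integer(), end = integer(),
                  surface = character(), concept_id = character(),
                  semantic_class = character(), source = character())
  if (nrow(reports) == 0) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(reports)), function(i) {
    annotate_text_impl(reports$raw_text[i], lex, idx, reports$doc_id[i],
                       policy, join_prepositions, stopwords)
  })
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$doc_id, .data$start, .data$end)
}

#' Write annotations to a standoff TSV
#'
#' Columns: `doc_id start end semantic_class concept_id surface source`.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(ann, path) {
  cols <- c("doc_id", "start", "end", "semantic_class", "concept_id",
            "surface", "source")
  cols <- intersect(cols, names(ann))
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotations (predicted or gold) from a standoff TSV
#'
#' @param path TSV with header; must contain `doc_id`, `start`, `end`,
#'   `surface`; `semantic_class`, `stem`, `concept_id`, `source` are kept
#'   when present.
#' @return Annotation tibble with integer offsets.
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such annotation file: ", path))
  df <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                    colClasses = "character", quote = "",
                                    na.strings = NULL,
                                    fileEncoding = "UTF-8"))
  need <- c("doc_id", "start", "end", "surface")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
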