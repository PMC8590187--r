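# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (brute force, enumeration) and never call
# the code paths they check.

# small hand-written ontology: root -> 2 top classes -> leaves
toy_ontology <- function() {
  ontology(tibble::tribble(
    ~concept_id, ~preferred_term, ~parent_id,
    "R0", "entity", "",
    "T1", "clinical finding", "R0",
    "T2", "anatomical entity", "R0",
    "C1", "effusion", "T1",
    "C2", "pleural effusion", "C1",
    "C3", "lobe", "T2",
    "C4", "shared concept", "T1",
    "C4", "shared concept", "T2"
  ))
}

random_lexicon <- function(n = 100, seed = 42) {
  set.seed(seed)
  words <- c("lobe", "effusion", "node", "upper", "right", "left", "pleural",
             "small", "lung", "base", "mass", "apex")
  surfaces <- replicate(n, paste(sample(words, sample(1:3, 1)), collapse = " "))
  lexicon(
    concept_id = sprintf("ID%04d", seq_len(n)),
    semantic_class = sample(c("clinical finding", "anatomical entity"), n,
                            replace = TRUE),
    surface = surfaces
  )
}

# independent window-scan NER oracle: lowercase, tokenize on the same rules,
# re-derive noun phrases straight from the tag sequence with a regex, then
# enumerate every contiguous window of non-stop tokens and test set
# membership of its joined text. No lexicon index, no chunker call.
oracle_annotate <- function(text, lex, doc_id = "doc1") {
  toks <- pos_tag(tokenize(tolower(text)))
  surfaces <- unique(lex$surface)
  # NP runs from the tag string, per sentence
  hits <- list()
  for (s in unique(toks$sentence)) {
    st <- toks[toks$sentence == s, ]
    ok <- st$pos %in% c("ADJ", "NOUN") & !st$is_stop
    tag <- paste(ifelse(ok, ifelse(st$pos == "NOUN", "N", "A"), "x"),
                 collapse = "")
    m <- gregexpr("[AN]+", tag)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      i0 <- as.integer(m[k])
      j0 <- i0 + attr(m, "match.length")[k] - 1
      while (j0 >= i0 && substr(tag, j0, j0) != "N") j0 <- j0 - 1
      if (j0 < i0) next
      rng <- i0:j0
      for (a in seq_along(rng)) for (b in a:length(rng)) {
        surf <- paste(st$text[rng[a:b]], collapse = " ")
        rows <- which(lex$surface == surf)
        for (rr in rows) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            doc_id = doc_id, start = st$start[rng[a]], end = st$end[rng[b]],
            surface = surf, concept_id = lex$concept_id[rr]
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(doc_id = character(), start = integer(),
                          end = integer(), surface = character(),
                          concept_id = character()))
  }
  out <- dplyr::distinct(dplyr::bind_rows(hits))
  dplyr::arrange(out, start, end, concept_id)
}

tiny_sim <- function(seed = 11, n = 2, coverage = 0.8) {
  generate_corpus(sim_config(seed = seed, n_reports_per_modality = n,
                             sentences_per_report = 8,
                             dictionary_coverage = coverage))
}
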