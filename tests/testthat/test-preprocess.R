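test_that("tokenizer keeps hyphenated words whole and offsets index the text", {
  t1 <- tokenize("right-sided ij central venous catheter")
  expect_equal(nrow(t1), 5)
  expect_equal(t1$text[1], "right-sided")

  t2 <- tokenize("no acute disease.")
  expect_equal(sum(grepl("^[a-z]", t2$text)), 3)
  expect_equal(t2$text[4], ".")

  # reconstruction oracle: substrings at offsets reproduce token texts,
  # and re-joining the tokens with the gaps reproduces the sentence
  s <- "there is a small right pleural effusion. no pneumothorax."
  tk <- tokenize(s)
  expect_identical(substring(s, tk$start + 1, tk$end), tk$text)
  rebuilt <- ""
  last <- 0
  for (i in seq_len(nrow(tk))) {
    rebuilt <- paste0(rebuilt, substring(s, last + 1, tk$start[i]), tk$text[i])
    last <- tk$end[i]
  }
  expect_identical(rebuilt, s)
  expect_equal(max(tk$sentence), 2)
})

test_that("lowercasing preserves length and offsets", {
  s <- "Right Upper Lobe"
  expect_identical(normalize_text(s), "right upper lobe")
  expect_identical(normalize_text(""), "")
  expect_equal(nchar(normalize_text(s)), nchar(s))
})

test_that("closed classes and defaults tag as specified", {
  tk <- pos_tag(tokenize("density of the effusion and edema"))
  tags <- setNames(tk$pos, tk$text)
  expect_equal(unname(tags["of"]), "PREP")
  expect_equal(unname(tags["and"]), "CONJ")
  expect_equal(unname(tags["the"]), "DET")
  expect_equal(unname(tags["effusion"]), "NOUN")  # default
  expect_true(tk$is_stop[tk$text == "of"])
  expect_false(tk$is_stop[tk$text == "effusion"])
})

test_that("coordinated phrases chunk into separate noun phrases", {
  tk <- pos_tag(tokenize("right pleural effusion and left lung pneumothorax"))
  nps <- chunk_noun_phrases(tk)
  expect_equal(nrow(nps), 2)
  expect_equal(nps$n_tokens, c(3L, 3L))
  expect_equal(chunk_noun_phrases(pos_tag(tokenize("")))$start, integer())
})

test_that("preposition joining merges exactly NP PREP NP", {
  tk <- pos_tag(tokenize("right upper lobe of lung base"))
  apart <- chunk_noun_phrases(tk, join_prepositions = FALSE)
  joined <- chunk_noun_phrases(tk, join_prepositions = TRUE)
  expect_equal(nrow(apart), 2)
  expect_equal(nrow(joined), 1)
  expect_equal(joined$start, min(apart$start))
  expect_equal(joined$end, max(apart$end))
})

test_that("chunk spans equal a brute-force regex over the tag sequence", {
  set.seed(5)
  vocab <- c("mild", "effusion", "lobe", "the", "of", "and", "is", "seen",
             "right", "pleural", "node", "no", ".")
  for (rep in 1:25) {
    s <- paste(sample(vocab, 12, replace = TRUE), collapse = " ")
    tk <- pos_tag(tokenize(s))
    nps <- chunk_noun_phrases(tk)
    # oracle: regex over the per-sentence tag string
    want <- list()
    for (sent in unique(tk$sentence)) {
      st <- tk[tk$sentence == sent, ]
      ok <- st$pos %in% c("ADJ", "NOUN") & !st$is_stop
      tag <- paste(ifelse(ok, ifelse(st$pos == "NOUN", "N", "A"), "x"),
                   collapse = "")
      m <- gregexpr("[AN]*N", tag)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        i <- as.integer(m[k]); j <- i + attr(m, "match.length")[k] - 1
        want[[length(want) + 1]] <- c(st$start[i], st$end[j])
      }
    }
    got <- unname(split(cbind(nps$start, nps$end), seq_len(nrow(nps))))
    got <- lapply(got, as.numeric)
    expect_equal(got, lapply(want, as.numeric), info = s)
    # invariants: sorted, non-overlapping, rightmost token is a NOUN
    if (nrow(nps) > 1) expect_true(all(diff(nps$start) > 0))
    expect_true(all(tk$pos[nps$last_token] == "NOUN"))
  }
})

test_that("corpus TSV loads into assembled reports with flags and errors", {
  df <- data.frame(
    doc_id = c("d1", "d1", "d1", "d1"),
    modality = "CT",
    section = c("findings", "interpretations", "impressions", "technique"),
    text = c("a.", "b.", "c.", "d."))
  expect_warning(reports <- load_reports(df), "technique")
  expect_equal(nrow(reports), 1)
  expect_equal(reports$raw_text, "a.\nb.\nc.\nd.")
  expect_equal(reports$n_sections, 4)

  expect_equal(nrow(load_reports(df[0, ])), 0)
  dup <- df[c(1, 1), ]
  expect_error(load_reports(dup), "duplicate")
  expect_error(load_reports(df[, -4]), "missing")

  sim <- generate_corpus(sim_config(seed = 2, n_reports_per_modality = 3,
                                    sentences_per_report = 5))
  expect_equal(nrow(sim$reports), 12)
  expect_equal(as.integer(table(sim$reports$modality)), rep(3L, 4))
})
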