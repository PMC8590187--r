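test_that("generated ontologies have the configured top-class structure", {
  g <- generate_ontology(sim_config(seed = 3), "radlex")
  expect_length(g$top_class_ids, 15)
  g2 <- generate_ontology(sim_config(seed = 3), "snomed")
  expect_length(g2$top_class_ids, 19)

  # degenerate config: one top class, no attached stems
  g3 <- generate_ontology(sim_config(seed = 3, top_classes = "only class",
                                     attach_prob = 0), "radlex")
  expect_length(g3$top_class_ids, 1)

  # tree mode: every attached stem leaf traces to exactly one top class
  leaves <- grep("^RIDL", g$concepts$concept_id, value = TRUE)
  expect_gt(length(leaves), 0)
  for (id in leaves) {
    expect_length(trace_top_class(g, id), 1)
  }
})

test_that("the same seed reproduces the whole study byte-for-byte", {
  s1 <- tiny_sim(seed = 77)
  s2 <- tiny_sim(seed = 77)
  expect_identical(s1$corpus, s2$corpus)
  expect_identical(s1$gold, s2$gold)
  expect_identical(s1$lexicon, s2$lexicon)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  s3 <- tiny_sim(seed = 78)
  expect_false(identical(s1$corpus, s3$corpus))
})

test_that("gold spans sit inside noun phrases and decode to their surfaces", {
  sim <- tiny_sim(seed = 41, n = 3)
  txt <- setNames(sim$reports$raw_text, sim$reports$doc_id)
  ext <- substr(txt[sim$gold$doc_id], sim$gold$start + 1, sim$gold$end)
  expect_identical(unname(tolower(ext)), sim$gold$surface)
  # containment in a chunked NP, per document
  for (d in sim$reports$doc_id) {
    toks <- pos_tag(tokenize(normalize_text(txt[[d]])))
    nps <- chunk_noun_phrases(toks)
    g <- sim$gold[sim$gold$doc_id == d, ]
    inside <- vapply(seq_len(nrow(g)), function(i) {
      any(nps$start <= g$start[i] & g$end[i] <= nps$end)
    }, logical(1))
    expect_true(all(inside), info = d)
  }
  # every gold surface's stem is its final word
  expect_equal(vapply(strsplit(sim$gold$surface, " "), function(w)
    w[length(w)], character(1)), sim$gold$stem)
})

test_that("planted word-length distribution follows the configured masses", {
  sc <- sim_config(seed = 63, n_reports_per_modality = 30,
                   sentences_per_report = 25)
  sim <- generate_corpus(sc)
  # longest pattern per planted term = the full term
  full <- sim$gold %>%
    dplyr::group_by(doc_id, end) %>%
    dplyr::summarise(n_words = max(word_count(surface)), .groups = "drop")
  expect_gte(nrow(full), 2000)
  obs <- table(factor(full$n_words, levels = names(sc$pattern_length_dist)))
  chisq <- suppressWarnings(
    stats::chisq.test(as.integer(obs), p = sc$pattern_length_dist))
  expect_gt(chisq$p.value, 0.01)
})

test_that("extreme dictionary coverage gives perfect or zero recall", {
  full <- generate_corpus(sim_config(seed = 5, n_reports_per_modality = 2,
                                     sentences_per_report = 8,
                                     dictionary_coverage = 1))
  m_full <- match_annotations(annotate_corpus(full$reports, full$lexicon),
                              full$gold)
  expect_equal(compute_metrics(m_full)$recall, 100)

  none <- generate_corpus(sim_config(seed = 5, n_reports_per_modality = 2,
                                     sentences_per_report = 8,
                                     dictionary_coverage = 0))
  m_none <- match_annotations(annotate_corpus(none$reports, none$lexicon),
                              none$gold)
  expect_equal(unname(m_none$counts["tp"]), 0L)
})

test_that("eval fixtures encode their own expected confusion counts", {
  fx <- generate_eval_fixture(sim_config(seed = 44, n_reports_per_modality = 2,
                                         sentences_per_report = 6),
                              n_missing = 0, n_spurious = 0, n_shifted = 0)
  m <- match_annotations(fx$pred, fx$gold)
  expect_equal(compute_metrics(m)$f_measure, 100)

  fx2 <- generate_eval_fixture(sim_config(seed = 44, n_reports_per_modality = 2,
                                          sentences_per_report = 6),
                               n_missing = 5, n_spurious = 0, n_shifted = 0)
  m2 <- match_annotations(fx2$pred, fx2$gold)
  expect_equal(unname(m2$counts["fn"]), 5L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(dictionary_coverage = 1.2), "coverage")
  expect_error(sim_config(pattern_length_dist = c(`2` = 0.5)), "sum to 1")
  expect_error(sim_config(stems = character()), "stem")
})
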