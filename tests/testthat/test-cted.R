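test_that("FN surfaces are added and FP surfaces removed, with provenance", {
  base <- lexicon(c("B1", "B2"), c("unclassified", "anatomical entity"),
                  c("related to", "upper lobe"))
  match <- structure(list(
    tp = tibble::tibble(doc_id = character(), start = integer(),
                        end = integer(), surface = character()),
    fp = tibble::tibble(doc_id = "d1", start = 0L, end = 10L,
                        surface = "related to", semantic_class = "unclassified"),
    fn = tibble::tibble(doc_id = c("d1", "d2"), start = c(5L, 9L),
                        end = c(21L, 25L), surface = "pleural effusion",
                        semantic_class = "clinical finding"),
    partial = NULL, counts = c(tp = 0L, fp = 1L, fn = 2L),
    mode = "exact", check_class = TRUE), class = "radterm_match")

  out <- build_cted(base, match, graph = toy_ontology())
  expect_equal(sum(out$delta$action == "add"), 1)
  expect_equal(sum(out$delta$action == "remove"), 1)
  add <- out$delta[out$delta$action == "add", ]
  # full surface exists in the ontology, so its concept id is reused and the
  # stem traces to clinical finding
  expect_equal(add$concept_id, "C2")
  expect_equal(add$semantic_class, "clinical finding")
  expect_setequal(add$docs[[1]], c("d1", "d2"))
  expect_false("related to" %in% out$lexicon$surface)
  expect_true("pleural effusion" %in% out$lexicon$surface)
  expect_true("upper lobe" %in% out$lexicon$surface)

  # minted ids are stable by sorted surface when not in the ontology
  match$fn$surface <- c("zz top finding", "aa base finding")
  out2 <- build_cted(base, match, graph = toy_ontology())
  add2 <- out2$delta[out2$delta$action == "add", ]
  expect_equal(add2$concept_id[order(add2$surface)], c("CTED:0001", "CTED:0002"))
  expect_true(all(add2$semantic_class == "unclassified"))
})

test_that("empty error sets leave the dictionary unchanged", {
  sim <- tiny_sim(seed = 6)
  pred <- annotate_corpus(sim$reports, sim$lexicon)
  perfect <- match_annotations(sim$gold, sim$gold)
  out <- build_cted(sim$lexicon, perfect)
  expect_equal(nrow(out$delta), 0)
  expect_equal(nrow(out$lexicon), nrow(sim$lexicon))
  expect_setequal(out$lexicon$surface, sim$lexicon$surface)
})

test_that("enhancement reaches a fixed point on its development corpus", {
  sim <- generate_corpus(sim_config(seed = 18, n_reports_per_modality = 3,
                                    sentences_per_report = 8,
                                    dictionary_coverage = 0.6))
  pred <- annotate_corpus(sim$reports, sim$lexicon)
  m <- match_annotations(pred, sim$gold)
  out <- build_cted(sim$lexicon, m, graph = sim$ontology)

  pred2 <- annotate_corpus(sim$reports, out$lexicon)
  m2 <- match_annotations(pred2, sim$gold)
  # recall 100% and zero FPs from removed surfaces when re-evaluated on the
  # development corpus itself
  expect_equal(unname(m2$counts[c("fp", "fn")]), c(0L, 0L))
  expect_gte(compute_metrics(m2)$recall, compute_metrics(m)$recall)
  removed <- out$delta$surface[out$delta$action == "remove"]
  expect_false(any(pred2$surface %in% removed))
  # second enhancement round finds nothing to change
  out2 <- build_cted(out$lexicon, m2, graph = sim$ontology)
  expect_equal(nrow(out2$delta), 0)
})

test_that("enhance_and_validate rejects overlapping corpora and improves F", {
  dev <- generate_corpus(sim_config(seed = 25, n_reports_per_modality = 4,
                                    sentences_per_report = 8,
                                    dictionary_coverage = 0.5))
  val <- generate_corpus(sim_config(seed = 26, n_reports_per_modality = 2,
                                    sentences_per_report = 8,
                                    dictionary_coverage = 0.5),
                         graph = dev$ontology, doc_prefix = "val")
  expect_error(enhance_and_validate(dev$lexicon, dev$reports, dev$gold,
                                    dev$reports, dev$gold), "overlap")
  rep <- enhance_and_validate(dev$lexicon, dev$reports, dev$gold,
                              val$reports, val$gold, graph = dev$ontology)
  gl <- glance(rep)
  expect_gte(gl$f_after, gl$f_before)
  expect_gt(gl$n_added, 0)
  td <- tidy(rep)
  expect_setequal(unique(td$stage), c("before", "after"))
})

test_that("before-enhancement recall tracks generator dictionary coverage", {
  for (c_target in c(0.2, 0.5, 0.8)) {
    sim <- generate_corpus(sim_config(seed = 1000 + round(100 * c_target),
                                      n_reports_per_modality = 5,
                                      dictionary_coverage = c_target))
    expect_gte(nrow(sim$gold), 500)
    pred <- annotate_corpus(sim$reports, sim$lexicon)
    rec <- compute_metrics(match_annotations(pred, sim$gold))$recall
    expect_lt(abs(rec - 100 * c_target), 5,
              label = paste0("recall ", rec, " at coverage ", c_target))
  }
})
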