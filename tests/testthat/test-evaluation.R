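test_that("identity and empty predictions give the degenerate counts", {
  sim <- tiny_sim(seed = 4)
  g <- sim$gold
  m_id <- match_annotations(g, g)
  expect_equal(unname(m_id$counts), c(nrow(g), 0L, 0L))

  m_none <- match_annotations(g[0, ], g)
  expect_equal(unname(m_none$counts["fn"]), nrow(g))
  expect_equal(unname(m_none$counts["tp"]), 0L)
})

test_that("perturbed gold matches the generator ledger and set-difference oracle", {
  fx <- generate_eval_fixture(sim_config(seed = 8, n_reports_per_modality = 2,
                                         sentences_per_report = 8),
                              n_missing = 7, n_spurious = 4, n_shifted = 3)
  m <- match_annotations(fx$pred, fx$gold, mode = "partial")
  expect_equal(unname(m$counts), unname(fx$expected))
  # conservation: every gold span is TP or FN; every unique prediction TP or FP
  expect_equal(nrow(m$tp) + nrow(m$fn), nrow(fx$gold))
  expect_equal(nrow(m$tp) + nrow(m$fp), nrow(dplyr::distinct(
    fx$pred, doc_id, start, end, semantic_class)))
  # each shifted span appears among the listed partial positives
  expect_gte(nrow(m$partial), fx$n_partial_expected)

  # brute-force set comparison oracle
  key <- function(df) paste(df$doc_id, df$start, df$end, df$semantic_class)
  expect_equal(nrow(m$tp), length(intersect(key(fx$pred), key(fx$gold))))
  expect_equal(nrow(m$fn), length(setdiff(key(fx$gold), key(fx$pred))))
  expect_equal(nrow(m$fp), length(setdiff(key(fx$pred), key(fx$gold))))
})

test_that("precision, recall and F follow the percent-scale formulas", {
  m <- compute_metrics(3, 1, 2)
  expect_equal(m$precision, 75.0)
  expect_equal(m$recall, 60.0)
  expect_equal(m$f_measure, 66.7)

  z <- compute_metrics(0, 0, 0)
  expect_true(z$degenerate)
  expect_equal(c(z$precision, z$recall, z$f_measure), c(0, 0, 0))
  expect_error(compute_metrics(-1, 0, 0), "non-negative")

  # F is symmetric and collapses to P when P == R
  expect_equal(f_measure(82.8, 51), f_measure(51, 82.8))
  expect_equal(f_measure(40, 40), 40)
})

test_that("tidy/glance views agree with the counts", {
  fx <- generate_eval_fixture(sim_config(seed = 9, n_reports_per_modality = 2,
                                         sentences_per_report = 6),
                              n_missing = 2, n_spurious = 2, n_shifted = 1)
  m <- match_annotations(fx$pred, fx$gold, mode = "partial")
  td <- tidy(m)
  expect_equal(as.integer(table(td$status)[c("tp", "fp", "fn")]),
               unname(m$counts))
  gl <- glance(m)
  expect_equal(gl$tp, unname(m$counts["tp"]))
  expect_equal(gl$n_partial, nrow(m$partial))
})

test_that("per-modality metrics pool counts into the All row", {
  sim <- generate_corpus(sim_config(seed = 14, n_reports_per_modality = 3,
                                    sentences_per_report = 6,
                                    dictionary_coverage = 0.6))
  pred <- annotate_corpus(sim$reports, sim$lexicon)
  tab <- per_modality_metrics(pred, sim$gold, sim$reports)
  all_row <- tab[tab$modality == "All", ]
  by_mod <- tab[tab$modality != "All", ]
  expect_equal(all_row$tp, sum(by_mod$tp))
  expect_equal(all_row$fp, sum(by_mod$fp))
  expect_equal(all_row$fn, sum(by_mod$fn))
  # pooling oracle: the All row equals matching on the whole corpus at once
  whole <- compute_metrics(match_annotations(pred, sim$gold))
  expect_equal(all_row$precision, whole$precision)
  expect_equal(all_row$f_measure, whole$f_measure)

  # single-modality corpus: one row plus identical All row
  ct <- sim$reports[sim$reports$modality == "CT", ]
  ct_pred <- pred[pred$doc_id %in% ct$doc_id, ]
  ct_gold <- sim$gold[sim$gold$doc_id %in% ct$doc_id, ]
  t2 <- per_modality_metrics(ct_pred, ct_gold, ct)
  expect_equal(nrow(t2), 2)
  expect_equal(t2$f_measure[1], t2$f_measure[2])

  expect_error(per_modality_metrics(
    data.frame(doc_id = "ghost", start = 0L, end = 1L,
               semantic_class = "x"), sim$gold, sim$reports), "unknown")
})
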