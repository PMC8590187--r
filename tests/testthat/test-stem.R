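test_that("stem extraction counts one occurrence per annotation", {
  reports <- tibble::tibble(doc_id = c("x1", "x2"), modality = "XRAY",
                            raw_text = "", sections = list(NULL, NULL),
                            n_sections = 0L)
  ann <- tibble::tibble(
    doc_id = c("x1", "x1", "x2", "x2"),
    surface = c("pleural effusion", "small pleural effusion",
                "pleural effusion", "of the"),
    category = "FN")
  expect_warning(st <- extract_stems(ann, reports), "skipped")
  expect_equal(nrow(st), 3)
  expect_true(all(st$stem == "effusion"))
  expect_equal(attr(st, "n_skipped"), 1L)
  expect_equal(nrow(extract_stems(ann[0, ], reports)), 0)
})

test_that("occurrence ratios normalize to 100 within each cell", {
  stems <- tibble::tibble(
    modality = c(rep("CT", 5), rep("PET", 3)),
    category = c(rep("TP", 5), rep("FN", 3)),
    stem = c("lobe", "lobe", "effusion", "node", "node",
             "uptake", "uptake", "node"))
  or_tab <- compute_or(stems)
  sums <- or_tab %>%
    dplyr::group_by(modality, category) %>%
    dplyr::summarise(s = sum(occurrences / total * 100), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
  expect_equal(or_tab$or_percent[or_tab$stem == "uptake"], 66.67)
  # a cell with a single distinct stem scores 100
  one <- compute_or(tibble::tibble(modality = "MRI", category = "TP",
                                   stem = "artery"))
  expect_equal(one$or_percent, 100)
  # invariant to input ordering
  expect_equal(compute_or(stems[sample(nrow(stems)), ]), or_tab)
  # type counting collapses repeats
  types <- compute_or(stems, count = "types")
  expect_true(all(types$occurrences == 1))
})

test_that("matching ratios split matched, over-two-categories and N/A", {
  g <- toy_ontology()
  stems <- tibble::tibble(
    modality = "CT", category = "FN",
    stem = c("effusion", "effusion", "lobe", "shared concept", "mystery"))
  mr <- compute_mr(stems, list(RADLEX = g))
  rl <- mr[mr$ontology == "RADLEX", ]
  expect_equal(rl$occurrences[rl$class_label == "clinical finding"], 2)
  expect_equal(rl$occurrences[rl$class_label == "anatomical entity"], 1)
  expect_equal(rl$occurrences[rl$class_label == "Over two categories"], 1)
  expect_equal(rl$occurrences[rl$class_label == "N/A"], 1)
  expect_equal(sum(rl$occurrences), nrow(stems))  # matched + N/A == total

  # no ontologies: everything N/A
  mr0 <- compute_mr(stems)
  expect_equal(mr0$class_label, "N/A")
  expect_equal(mr0$mr_percent, 100)
})

test_that("combined matching equals the brute-force union of ontologies", {
  set.seed(31)
  sc <- sim_config(seed = 55, attach_prob = 0.6)
  g1 <- generate_ontology(sc, "radlex")
  g2 <- generate_ontology(sc, "snomed")
  stems <- tibble::tibble(modality = "CT", category = "FN",
                          stem = sample(sc$stems, 200, replace = TRUE))
  mr <- compute_mr(stems, list(DEFAULT = g2, RADLEX = g1))
  in1 <- stems$stem %in% g1$concepts$preferred_term
  in2 <- stems$stem %in% g2$concepts$preferred_term
  comb <- mr[mr$ontology == "COMBINED", ]
  expect_equal(comb$occurrences[comb$class_label == "matched"], sum(in1 | in2))
  expect_equal(comb$occurrences[comb$class_label == "N/A"], sum(!(in1 | in2)))

  # monotonicity: combined MR at least each single-ontology matched share,
  # at most their sum
  mr_single <- function(ont) {
    blk <- mr[mr$ontology == ont & mr$class_label != "N/A", ]
    sum(blk$occurrences) / nrow(stems) * 100
  }
  mr_comb <- comb$mr_percent[comb$class_label == "matched"]
  expect_gte(mr_comb, max(mr_single("DEFAULT"), mr_single("RADLEX")) - 1e-9)
  expect_lte(mr_comb, mr_single("DEFAULT") + mr_single("RADLEX") + 1e-9)
})

test_that("word-length profiles count and percentage each bin", {
  ann <- tibble::tibble(surface = c("upper lobe", "right upper lobe",
                                    "upper lobe", "effusion"))
  p <- word_length_profile(ann)
  expect_equal(sum(p$count), 4)
  expect_equal(p$count[p$n_words == 2], 2)
  expect_equal(sum(p$percent), 100)
  expect_equal(word_length_profile("upper lobe")$percent, 100)
  expect_equal(word_length_share(p, 2, 3), 75)
})
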