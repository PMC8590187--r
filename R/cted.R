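#' Build a compound-terms-enhanced dictionary (CtED)
#'
#' Error-driven dictionary enhancement: every distinct multi-word surface of
#' the false-negative gold annotations is *added* to the dictionary, and
#' every entry whose surface produced a false-positive prediction is
#' *removed* (globally, from all source dictionaries). Added entries are
#' tagged `source = "CTED"`; their concept ids are minted in a reserved
#' `CTED:NNNN` namespace, numbered by sorted surface so a rebuild is
#' reproducible, unless the full surface already names a concept in the
#' supplied ontology, in which case that concept id is reused. Their
#' semantic class comes from tracing the surface's stem to its ontology top
#' class when the stem is an ontology term (and traces to a single class);
#' otherwise `"unclassified"`.
#'
#' @param base The lexicon the evaluation ran with.
#' @param match A `radterm_match` from [match_annotations()] of predictions
#'   made with `base` against `gold`.
#' @param graph Optional `radterm_ontology` used to resolve concept ids and
#'   semantic classes of added terms.
#' @param class_assigner Optional function `stem -> class label` overriding
#'   the ontology-trace default.
#' @param stopwords Stop-word list for stem identification.
#' @return List with `lexicon` (the enhanced `radterm_lexicon`) and `delta`,
#'   a tibble `action` (`"add"`/`"remove"`), `surface`, `concept_id`,
#'   `semantic_class`, `docs` (list of originating doc ids).
#' @export
build_cted <- function(base, match, graph = NULL, class_assigner = NULL,
                       stopwords = radterm_stopwords()) {
  stopifnot(inherits(match, "radterm_match"))
  base <- as_lexicon(base)

  fn_surfaces <- unique(normalize_term(match$fn$surface))
  fn_surfaces <- fn_surfaces[word_count(fn_surfaces) >= 2]
  fn_surfaces <- sort(fn_surfaces, method = "radix")
  fp_surfaces <- unique(normalize_term(match$fp$surface))

  # surfaces to add that survive the FP purge (a surface in both sets is
  # removed, keeping added and removed disjoint)
  fn_surfaces <- setdiff(fn_surfaces, fp_surfaces)

  term_idx <- if (!is.null(graph)) ontology_term_index(graph) else list()
  assign_class <- class_assigner %||% function(stem) {
    ids <- term_idx[[stem]]
    if (is.null(ids)) return("unclassified")
    labs <- unique(unlist(lapply(ids, trace_top_class, graph = graph)))
    if (length(labs) == 1) labs else "unclassified"
  }

  added <- NULL
  if (length(fn_surfaces) > 0) {
    minted <- sprintf("CTED:%04d", seq_along(fn_surfaces))
    cid <- vapply(seq_along(fn_surfaces), function(i) {
      ids <- term_idx[[fn_surfaces[i]]]
      if (is.null(ids)) minted[i] else ids[[1]]
    }, character(1))
    stems <- vapply(fn_surfaces, identify_stem, character(1),
                    stopwords = stopwords, USE.NAMES = FALSE)
    cls <- vapply(stems, function(s) assign_class(s)[[1]], character(1),
                  USE.NAMES = FALSE)
    added <- lexicon(cid, cls, fn_surfaces, source = "CTED")
  }

  removed <- base[base$surface %in% fp_surfaces, , drop = FALSE]
  kept <- base[!(base$surface %in% fp_surfaces), , drop = FALSE]
  enhanced <- if (is.null(added)) as_lexicon(kept)
              else merge_lexicons(as_lexicon(kept), added)

  docs_for <- function(surfaces, src) {
    lapply(surfaces, function(s) {
      sort(unique(src$doc_id[normalize_term(src$surface) == s]))
    })
  }
  delta <- bind_rows(
    if (!is.null(added)) tibble(
      action = "add", surface = added$surface, concept_id = added$concept_id,
      semantic_class = added$semantic_class,
      docs = docs_for(added$surface, match$fn)
    ),
    if (nrow(removed) > 0) tibble(
      action = "remove", surface = removed$surface,
      concept_id = removed$concept_id,
      semantic_class = removed$semantic_class,
      docs = docs_for(removed$surface, match$fp)
    )
  )
  if (is.null(delta)) {
    delta <- tibble(action = character(), surface = character(),
                    concept_id = character(), semantic_class = character(),
                    docs = list())
  }
  list(lexicon = enhanced, delta = delta)
}

#' Write a CtED delta audit table
#'
#' Columns `action  surface  concept_id  class  docs` (doc ids
#' comma-joined).
#'
#' @param delta Delta tibble from [build_cted()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cted_delta_tsv <- function(delta, path) {
  out <- tibble(
    action = delta$action, surface = delta$surface,
    concept_id = delta$concept_id, class = delta$semantic_class,
    docs = vapply(delta$docs, paste, character(1), collapse = ",")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Enhance a dictionary on a development corpus and validate on held-out
#' reports
#'
#' The full enhancement experiment: annotate the development corpus with the
#' base dictionary, classify errors against the development gold, build the
#' CtED from them, then evaluate the base and enhanced dictionaries on a
#' disjoint validation corpus. Single-word entries are dropped from the base
#' first (the experiments concern compound terms) unless
#' `compound_only = FALSE`.
#'
#' @param base Base lexicon (before enhancement).
#' @param dev_reports,val_reports Report tibbles from [load_reports()];
#'   their `doc_id` sets must be disjoint.
#' @param dev_gold,val_gold Gold annotation tibbles for the two corpora.
#' @param policy,join_prepositions,stopwords Passed to [annotate_corpus()].
#' @param check_class Passed to [match_annotations()].
#' @param graph Optional ontology for CtED class assignment.
#' @param compound_only Drop single-word base entries first?
#' @return A `radterm_enhance_report`: list with `before` and `after`
#'   per-modality metric tibbles (validation corpus), `dev_metrics`
#'   (development corpus, base dictionary), `delta`, and the two lexicons.
#' @export
enhance_and_validate <- function(base, dev_reports, dev_gold,
                                 val_reports, val_gold,
                                 policy = "all", check_class = TRUE,
                                 join_prepositions = FALSE,
                                 stopwords = radterm_stopwords(),
                                 graph = NULL, compound_only = TRUE) {
  overlap <- intersect(dev_reports$doc_id, val_reports$doc_id)
  if (length(overlap) > 0) {
    abort(paste0("development and validation corpora overlap: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  base <- as_lexicon(base)
  if (compound_only) base <- filter_single_terms(base)

  dev_pred <- annotate_corpus(dev_reports, base, policy = policy,
                              join_prepositions = join_prepositions,
                              stopwords = stopwords)
  dev_match <- match_annotations(dev_pred, dev_gold, check_class = check_class)
  cted <- build_cted(base, dev_match, graph = graph, stopwords = stopwords)

  eval_with <- function(lex, reports, gold) {
    pred <- annotate_corpus(reports, lex, policy = policy,
                            join_prepositions = join_prepositions,
                            stopwords = stopwords)
    per_modality_metrics(pred, gold, reports, check_class = check_class)
  }
  structure(
    list(
      before = eval_with(base, val_reports, val_gold),
      after = eval_with(cted$lexicon, val_reports, val_gold),
      dev_metrics = compute_metrics(dev_match),
      delta = cted$delta,
      base_lexicon = base,
      enhanced_lexicon = cted$lexicon
    ),
    class = "radterm_enhance_report"
  )
}

#' @export
print.radterm_enhance_report <- function(x, ...) {
  b <- x$before[x$before$modality == "All", ]
  a <- x$after[x$after$modality == "All", ]
  cat("<radterm enhancement report>\n")
  cat("  delta: +", sum(x$delta$action == "add"), " / -",
      sum(x$delta$action == "remove"), " entries\n", sep = "")
  cat(sprintf("  validation F: %.1f -> %.1f (P %.1f -> %.1f, R %.1f -> %.1f)\n",
              b$f_measure, a$f_measure, b$precision, a$precision,
              b$recall, a$recall))
  invisible(x)
}

#' @describeIn enhance_and_validate `tidy()` returns the per-modality
#'   metrics in long form with a `stage` column (`"before"`/`"after"`).
#' @param x A `radterm_enhance_report`.
#' @method tidy radterm_enhance_report
#' @export
tidy.radterm_enhance_report <- function(x, ...) {
  bind_rows(
    mutate(x$before, stage = "before", .before = 1),
    mutate(x$after, stage = "after", .before = 1)
  )
}

#' @describeIn enhance_and_validate `glance()` returns one row with pooled
#'   before/after scores and delta sizes.
#' @method glance radterm_enhance_report
#' @export
glance.radterm_enhance_report <- function(x, ...) {
  b <- x$before[x$before$modality == "All", ]
  a <- x$after[x$after$modality == "All", ]
  tibble(
    f_before = b$f_measure, f_after = a$f_measure,
    precision_before = b$precision, precision_after = a$precision,
    recall_before = b$recall, recall_after = a$recall,
    n_added = sum(x$delta$action == "add"),
    n_removed = sum(x$delta$action == "remove")
  )
}
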