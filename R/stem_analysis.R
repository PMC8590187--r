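#' Extract stem-term occurrences from annotation sets
#'
#' Each annotation (typically a true-positive or false-negative record)
#' contributes one stem occurrence: the rightmost non-stop word of its
#' surface. Occurrences — not unique types — are counted, so a stem
#' appearing in 3 annotations contributes 3. Surfaces consisting only of
#' stop words cannot be decomposed; they are skipped with a warning and
#' their count is attached as the `n_skipped` attribute.
#'
#' @param ann Annotation tibble with `doc_id`, `surface` and optionally a
#'   `category` column; if absent, `category` labels all rows.
#' @param reports Report tibble from [load_reports()] supplying `modality`
#'   per `doc_id`.
#' @param category Default category label (e.g. `"TP"`, `"FN"`) when `ann`
#'   has no `category` column.
#' @param stopwords Stop-word list.
#' @return Tibble with one row per stem occurrence: `modality`, `category`,
#'   `stem`.
#' @export
extract_stems <- function(ann, reports, category = "TP",
                          stopwords = radterm_stopwords()) {
  mods <- setNames(reports$modality, reports$doc_id)
  unknown <- setdiff(unique(ann$doc_id), names(mods))
  if (length(unknown) > 0) {
    abort(paste0("annotations reference unknown doc_id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(ann) == 0) {
    out <- tibble(modality = character(), category = character(),
                  stem = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  cat_col <- if ("category" %in% names(ann)) ann$category else
    rep(category, nrow(ann))
  stems <- vapply(normalize_term(ann$surface), function(s) {
    w <- term_words(s)
    keep <- !(w %in% tolower(stopwords))
    if (!any(keep)) NA_character_ else w[max(which(keep))]
  }, character(1), USE.NAMES = FALSE)
  skipped <- is.na(stems)
  if (any(skipped)) {
    warn(paste0(sum(skipped),
                " annotation(s) with stop-word-only surfaces skipped."))
  }
  out <- tibble(
    modality = unname(mods[ann$doc_id[!skipped]]),
    category = cat_col[!skipped],
    stem = stems[!skipped]
  )
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Stem-term occurrence ratios
#'
#' For each (modality, category) cell, the occurrence ratio of a stem is its
#' share of all stem occurrences in that cell, in percent:
#' `OR = occurrences / total * 100`. A high OR in the true positives means
#' compound terms with that head are captured well; a high OR in the false
#' negatives flags heads whose compound terms the dictionary still misses.
#' Within each cell the unrounded ratios sum to 100.
#'
#' @param stems Stem-occurrence tibble from [extract_stems()] (columns
#'   `modality`, `category`, `stem`).
#' @param count `"occurrences"` (default) counts every annotation;
#'   `"types"` counts each distinct stem once per cell.
#' @param digits Decimal places for `or_percent`.
#' @return Tibble `modality`, `category`, `stem`, `occurrences`, `total`,
#'   `or_percent`, sorted by descending ratio within cell.
#' @export
compute_or <- function(stems, count = c("occurrences", "types"), digits = 2) {
  count <- match.arg(count)
  if (nrow(stems) == 0) {
    return(tibble(modality = character(), category = character(),
                  stem = character(), occurrences = integer(),
                  total = integer(), or_percent = numeric()))
  }
  df <- if (count == "types") distinct(stems, .data$modality, .data$category,
                                       .data$stem) else stems
  df %>%
    count(.data$modality, .data$category, .data$stem, name = "occurrences") %>%
    group_by(.data$modality, .data$category) %>%
    mutate(total = sum(.data$occurrences),
           or_percent = ratio_percent(.data$occurrences, .data$total,
                                      digits = digits)) %>%
    ungroup() %>%
    arrange(.data$modality, .data$category, dplyr::desc(.data$occurrences),
            .data$stem)
}

#' Stem-term matching ratios against reference ontologies
#'
#' For false-negative stem occurrences, the matching ratio of an ontology is
#' the share of occurrences whose stem *exactly matches* (lowercased string
#' equality) a term of that ontology: `MR = matched / total * 100`. Matched
#' stems are profiled by their top class via [trace_top_class()]; a stem
#' tracing to more than one top class falls in the `"Over two categories"`
#' bucket, and unmatched stems in `"N/A"`. A `COMBINED` block counts
#' occurrences matched by at least one of the supplied ontologies, split
#' into `"matched"` and `"N/A"`.
#'
#' @param fn_stems Stem-occurrence tibble (typically the `FN` rows from
#'   [extract_stems()]).
#' @param ontologies Named list of `radterm_ontology` objects (e.g.
#'   `list(DEFAULT = ..., RADLEX = ...)`).
#' @param digits Decimal places for `mr_percent`.
#' @return Tibble `ontology`, `class_label`, `occurrences`, `total`,
#'   `mr_percent`; one block per ontology plus `COMBINED`.
#' @export
compute_mr <- function(fn_stems, ontologies = list(), digits = 2) {
  total <- nrow(fn_stems)
  if (total == 0) {
    return(tibble(ontology = character(), class_label = character(),
                  occurrences = integer(), total = integer(),
                  mr_percent = numeric()))
  }
  if (length(ontologies) == 0) {
    return(tibble(ontology = "COMBINED", class_label = "N/A",
                  occurrences = total, total = total,
                  mr_percent = ratio_percent(total, total, digits)))
  }
  if (is.null(names(ontologies)) || any(!nzchar(names(ontologies)))) {
    names(ontologies) <- paste0("ONTOLOGY", seq_along(ontologies))
  }

  stems <- fn_stems$stem
  uniq <- unique(stems)
  matched_any <- rep(FALSE, length(stems))
  blocks <- list()
  for (nm in names(ontologies)) {
    g <- ontologies[[nm]]
    idx <- ontology_term_index(g)
    # classify each distinct stem once, then spread over occurrences
    label_of <- vapply(uniq, function(s) {
      ids <- idx[[s]]
      if (is.null(ids)) return("N/A")
      labs <- unique(unlist(lapply(ids, trace_top_class, graph = g)))
      if (length(labs) == 0) return("N/A")
      if (length(labs) > 1) "Over two categories" else labs
    }, character(1))
    occ_label <- unname(label_of[match(stems, uniq)])
    matched_any <- matched_any | occ_label != "N/A"
    blocks[[nm]] <- tibble(ontology = nm, class_label = occ_label)
  }
  per_ont <- bind_rows(blocks) %>%
    count(.data$ontology, .data$class_label, name = "occurrences") %>%
    mutate(total = total,
           mr_percent = ratio_percent(.data$occurrences, total, digits))
  combined <- tibble(
    ontology = "COMBINED",
    class_label = c("matched", "N/A"),
    occurrences = c(sum(matched_any), sum(!matched_any)),
    total = total
  )
  combined$mr_percent <- ratio_percent(combined$occurrences, total, digits)
  out <- bind_rows(per_ont, combined)
  arrange(out, .data$ontology, dplyr::desc(.data$occurrences))
}

#' Word-length profile of compound-term annotations
#'
#' Histogram of annotation surfaces by word count, with per-bin percentages.
#' Useful for showing how heavily compound terms concentrate on 2-4 words.
#'
#' @param ann Annotation tibble with a `surface` column, or a character
#'   vector of surfaces.
#' @param digits Decimal places for percentages.
#' @return Tibble `n_words`, `count`, `percent`, ordered by `n_words`.
#' @export
word_length_profile <- function(ann, digits = 2) {
  surfaces <- if (is.character(ann)) ann else ann$surface
  if (length(surfaces) == 0) {
    return(tibble(n_words = integer(), count = integer(),
                  percent = numeric()))
  }
  wc <- word_count(surfaces)
  tb <- table(wc)
  tibble(
    n_words = as.integer(names(tb)),
    count = as.integer(tb),
    percent = ratio_percent(as.integer(tb), length(surfaces), digits)
  )
}

#' Share of a word-length range
#'
#' Percentage of annotations whose word count falls in `[min_words,
#' max_words]`, computed from a [word_length_profile()] table.
#'
#' @param profile Profile tibble.
#' @param min_words,max_words Inclusive range bounds.
#' @param digits Decimal places.
#' @return A single percentage.
#' @export
word_length_share <- function(profile, min_words = 2, max_words = 4,
                              digits = 2) {
  total <- sum(profile$count)
  inside <- profile$n_words >= min_words & profile$n_words <= max_words
  ratio_percent(sum(profile$count[inside]), total, digits)
}
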