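#' Compare predicted annotations with a gold standard
#'
#' Span-level exact matching: a prediction and a gold annotation match iff
#' they agree on document and on both character offsets — and, by default,
#' on semantic class. Matching is 1:1: predictions are first reduced to
#' unique (doc, span, class) keys, then paired greedily against gold, so the
#' counts always satisfy `tp + fn == |gold|` and `tp + fp == |unique
#' predictions|`. *Partial positives* — same class, overlapping but unequal
#' span — are additionally listed when `mode = "partial"`, but stay counted
#' as FN (and their predictions as FP), which is how they are treated in
#' the headline scores.
#'
#' @param pred Predicted annotation tibble (`doc_id`, `start`, `end`,
#'   `semantic_class`, ...).
#' @param gold Gold annotation tibble (same span columns, plus `surface`,
#'   optionally `stem`).
#' @param mode `"exact"` (default) or `"partial"` to also enumerate partial
#'   positives.
#' @param check_class Require semantic-class agreement for a true positive?
#' @return A `radterm_match` object: list with tibbles `tp`, `fp`, `fn`,
#'   `partial` and integer `counts` (tp, fp, fn).
#' @export
match_annotations <- function(pred, gold, mode = c("exact", "partial"),
                              check_class = TRUE) {
  mode <- match.arg(mode)
  pred <- as_tibble(pred)
  gold <- as_tibble(gold)
  if (nrow(pred) > 0 && (!"semantic_class" %in% names(pred)) && check_class) {
    abort("predictions lack a semantic_class column; set check_class = FALSE.")
  }
  key_of <- function(df) {
    if (nrow(df) == 0) return(character())
    base <- paste(df$doc_id, df$start, df$end, sep = "\r")
    if (check_class) paste(base, normalize_term(df$semantic_class), sep = "\r")
    else base
  }
  pred_u <- if (nrow(pred) > 0) pred[!duplicated(key_of(pred)), ] else pred
  pk <- key_of(pred_u)
  gk <- key_of(gold)
  if (anyDuplicated(gk)) gold <- gold[!duplicated(gk), , drop = FALSE]
  gk <- key_of(gold)

  tp <- gold[gk %in% pk, , drop = FALSE]
  fn <- gold[!(gk %in% pk), , drop = FALSE]
  fp <- pred_u[!(pk %in% gk), , drop = FALSE]

  partial <- tibble(doc_id = character(), pred_start = integer(),
                    pred_end = integer(), gold_start = integer(),
                    gold_end = integer(), semantic_class = character(),
                    gold_surface = character())
  if (mode == "partial" && nrow(fp) > 0 && nrow(fn) > 0) {
    partial <- find_partials(fp, fn, check_class)
  }

  structure(
    list(tp = tp, fp = fp, fn = fn, partial = partial,
         counts = c(tp = nrow(tp), fp = nrow(fp), fn = nrow(fn)),
         mode = mode, check_class = check_class),
    class = "radterm_match"
  )
}

find_partials <- function(fp, fn, check_class) {
  rows <- list()
  for (i in seq_len(nrow(fp))) {
    cand <- fn[fn$doc_id == fp$doc_id[i] &
                 fn$start < fp$end[i] & fp$start[i] < fn$end, , drop = FALSE]
    if (check_class && nrow(cand) > 0) {
      cand <- cand[normalize_term(cand$semantic_class) ==
                     normalize_term(fp$semantic_class[i]), , drop = FALSE]
    }
    for (j in seq_len(nrow(cand))) {
      rows[[length(rows) + 1]] <- tibble(
        doc_id = fp$doc_id[i],
        pred_start = fp$start[i], pred_end = fp$end[i],
        gold_start = cand$start[j], gold_end = cand$end[j],
        semantic_class = if ("semantic_class" %in% names(cand))
          cand$semantic_class[j] else NA_character_,
        gold_surface = cand$surface[j]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(doc_id = character(), pred_start = integer(),
                  pred_end = integer(), gold_start = integer(),
                  gold_end = integer(), semantic_class = character(),
                  gold_surface = character()))
  }
  bind_rows(rows)
}

#' F-measure from precision and recall
#'
#' The harmonic mean on the percent scale:
#' `F = 2 * P * R / (P + R)`; defined as 0 when both are 0.
#'
#' @param precision,recall Percentages (0-100); vectorized.
#' @param digits Decimal places (`NULL` for none).
#' @return Percentage vector.
#' @export
#' @examples
#' f_measure(82.8, 51)  # 63.1
f_measure <- function(precision, recall, digits = 1) {
  out <- ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Precision, recall and F-measure from TP/FP/FN counts
#'
#' Percent-scale scores:
#' `P = TP / (TP + FP) * 100`, `R = TP / (TP + FN) * 100`,
#' `F = 2 P R / (P + R)`. Degenerate cells (zero denominator) score 0 and
#' are flagged.
#'
#' @param tp Either the TP count, or a `radterm_match` object.
#' @param fp,fn FP / FN counts (ignored when `tp` is a match object).
#' @param digits Decimal places for the three scores (`NULL` for none).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure`, `degenerate`.
#' @export
#' @examples
#' compute_metrics(3, 1, 2)
compute_metrics <- function(tp, fp = NULL, fn = NULL, digits = 1) {
  if (inherits(tp, "radterm_match")) {
    cts <- tp$counts
    tp <- cts[["tp"]]; fp <- cts[["fp"]]; fn <- cts[["fn"]]
  }
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative.")
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp) * 100
  r <- if (tp + fn == 0) 0 else tp / (tp + fn) * 100
  f <- f_measure(p, r, digits = NULL)
  if (!is.null(digits)) {
    p <- round(p, digits); r <- round(r, digits); f <- round(f, digits)
  }
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = p, recall = r, f_measure = f, degenerate = degenerate)
}

#' Per-modality evaluation table
#'
#' Evaluates each imaging modality's documents separately and adds an
#' `"All"` row that *pools the counts* over modalities (it is not an average
#' of the per-modality scores).
#'
#' @inheritParams match_annotations
#' @param reports Report tibble from [load_reports()] providing `doc_id` and
#'   `modality`.
#' @param digits Decimal places for scores.
#' @return Tibble with one row per modality plus `"All"`, columns as in
#'   [compute_metrics()].
#' @export
per_modality_metrics <- function(pred, gold, reports, check_class = TRUE,
                                 digits = 1) {
  mods <- setNames(reports$modality, reports$doc_id)
  unknown <- setdiff(unique(c(pred$doc_id, gold$doc_id)), names(mods))
  if (length(unknown) > 0) {
    abort(paste0("annotations reference unknown doc_id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  rows <- purrr::map_dfr(sort(unique(reports$modality)), function(m) {
    docs <- names(mods)[mods == m]
    mres <- match_annotations(pred[pred$doc_id %in% docs, , drop = FALSE],
                              gold[gold$doc_id %in% docs, , drop = FALSE],
                              check_class = check_class)
    mutate(compute_metrics(mres, digits = digits), modality = m,
           .before = 1)
  })
  all_row <- mutate(
    compute_metrics(sum(rows$tp), sum(rows$fp), sum(rows$fn), digits = digits),
    modality = "All", .before = 1)
  bind_rows(rows, all_row)
}

#' @export
print.radterm_match <- function(x, ...) {
  m <- compute_metrics(x)
  cat("<radterm match: TP=", m$tp, " FP=", m$fp, " FN=", m$fn,
      " | P=", m$precision, " R=", m$recall, " F=", m$f_measure, ">\n",
      sep = "")
  if (x$mode == "partial") {
    cat("  partial positives listed: ", nrow(x$partial), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn match_annotations `tidy()` returns one row per annotation with
#'   its match `status` (`"tp"`, `"fp"`, `"fn"`).
#' @param x A `radterm_match`.
#' @method tidy radterm_match
#' @export
tidy.radterm_match <- function(x, ...) {
  bind_rows(
    mutate(x$tp, status = "tp"),
    mutate(x$fp, status = "fp"),
    mutate(x$fn, status = "fn")
  )
}

#' @describeIn match_annotations `glance()` returns the one-row metric
#'   summary.
#' @method glance radterm_match
#' @export
glance.radterm_match <- function(x, ...) {
  m <- compute_metrics(x)
  m$n_partial <- nrow(x$partial)
  m
}
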