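# Seedable generator of toy ontologies, dictionaries and radiology-style
# corpora. Everything is template-based: sentences are fixed token frames
# with slots for planted compound terms, so character offsets of every gold
# annotation are known exactly and every downstream stage can be tested
# against generator ground truth.

#' Fifteen RadLex-style top classes
#' @return Character vector of 15 class labels.
#' @export
radlex_top_classes <- function() {
  c("anatomical entity", "clinical finding", "imaging modality",
    "imaging observation", "nonanatomical substance", "object", "procedure",
    "process step", "process", "property", "radlex descriptor",
    "radlex nonanatomical set", "report", "report content",
    "temporary entity")
}

#' Nineteen SNOMED-style top classes
#' @return Character vector of 19 class labels.
#' @export
snomed_top_classes <- function() {
  c("body structure", "clinical finding", "environment or geographical location",
    "event", "observable entity", "organism",
    "pharmaceutical or biologic product", "physical force", "physical object",
    "procedure", "qualifier value", "record artifact",
    "situation with explicit context", "snomed ct model component",
    "social context", "special concept", "specimen", "staging and scales",
    "substance")
}

default_stems <- function() {
  c("lobe", "effusion", "node", "artery", "hemorrhage", "change",
    "collection", "lesion", "evidence", "sinus", "matter", "body",
    "enhancement", "study", "gland", "nodule", "disease", "uptake",
    "avidity", "tube", "edema", "lung", "opacity", "pneumothorax", "line",
    "catheter", "mass", "fracture")
}

default_modifiers <- function() {
  c("right", "left", "upper", "lower", "pleural", "central", "venous",
    "small", "large", "mild", "severe", "acute", "chronic", "bilateral",
    "focal", "diffuse", "new", "interval", "soft", "lymph", "hilar",
    "apical", "basilar", "frontal")
}

# modality-specific stem weighting (multiplicative over a base weight of 1):
# PET leans on metabolic terms, x-ray on effusions/support devices, etc.
default_stem_boosts <- function() {
  list(
    CT   = c(change = 4, collection = 3, lesion = 3, lobe = 3, effusion = 2,
             evidence = 2, node = 2, hemorrhage = 2, artery = 1.5),
    MRI  = c(artery = 5, change = 4, enhancement = 4, lesion = 3,
             evidence = 2, study = 2, sinus = 2, matter = 2, lobe = 2),
    PET  = c(uptake = 12, node = 6, avidity = 4, disease = 3, lesion = 2,
             lobe = 2, gland = 2, nodule = 2),
    XRAY = c(effusion = 8, tube = 5, opacity = 4, pneumothorax = 4,
             line = 3, lung = 3, edema = 2, lobe = 2)
  )
}

default_distractors <- function() {
  list(c("comparison", "film"), c("outside", "hospital"),
       c("reference", "scan"), c("telephone", "notification"),
       c("overnight", "read"), c("technologist", "worksheet"))
}

#' Generator configuration
#'
#' Bundles all knobs of the synthetic study design. Defaults emulate the
#' corpus the pipeline is built for: four imaging modalities with 100
#' reports each, three sections per report, a mean of 29 sentences per
#' report, noun phrases containing 2-4-word compound terms with a head
#' (stem) noun and 1-3 modifiers (word-length mass 0.74/0.18/0.05 on 2/3/4,
#' remainder on 5), modality-specific stem frequencies, and a dictionary
#' covering a configurable fraction of the planted gold pattern surfaces.
#'
#' @param seed Integer seed; the same seed and config give byte-identical
#'   output.
#' @param n_reports_per_modality Reports per modality (default 100).
#' @param sentences_per_report Mean sentences per report (default 29).
#' @param dictionary_coverage Fraction `c` in `[0, 1]` of distinct gold
#'   pattern surfaces present in the generated dictionaries (default 0.8).
#' @param pattern_length_dist Named probabilities over compound-term word
#'   counts; must sum to 1.
#' @param stems,modifiers Vocabulary word lists.
#' @param stem_boosts Named list per modality of stem weight multipliers.
#' @param top_classes Top-class labels of the primary (RadLex-style)
#'   ontology.
#' @param snomed_classes Top-class labels of the secondary (SNOMED-style)
#'   ontology.
#' @param attach_prob Probability that a vocabulary stem is attached as a
#'   leaf of an ontology.
#' @param p_term Probability that a sentence plants a compound term.
#' @param p_distractor Probability that a sentence plants a distractor
#'   phrase instead of filler.
#' @param n_distractors How many distractor phrases enter the dictionary
#'   (false-positive bait).
#' @param sections Section names, in report order.
#' @return A `radterm_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_reports_per_modality = 100,
                       sentences_per_report = 29,
                       dictionary_coverage = 0.8,
                       pattern_length_dist = c(`2` = 0.74, `3` = 0.18,
                                               `4` = 0.05, `5` = 0.03),
                       stems = default_stems(),
                       modifiers = default_modifiers(),
                       stem_boosts = default_stem_boosts(),
                       top_classes = radlex_top_classes(),
                       snomed_classes = snomed_top_classes(),
                       attach_prob = 0.8,
                       p_term = 0.7,
                       p_distractor = 0.12,
                       n_distractors = 4,
                       sections = c("findings", "interpretations",
                                    "impressions")) {
  if (dictionary_coverage < 0 || dictionary_coverage > 1) {
    abort("dictionary_coverage must be in [0, 1].")
  }
  if (abs(sum(pattern_length_dist) - 1) > 1e-8) {
    abort("pattern_length_dist must sum to 1.")
  }
  if (length(stems) == 0) abort("vocabulary must contain at least one stem.")
  if (length(top_classes) < 1) abort("need at least one top class.")
  structure(
    list(seed = as.integer(seed),
         n_reports_per_modality = n_reports_per_modality,
         sentences_per_report = sentences_per_report,
         dictionary_coverage = dictionary_coverage,
         pattern_length_dist = pattern_length_dist,
         stems = stems, modifiers = modifiers, stem_boosts = stem_boosts,
         top_classes = top_classes, snomed_classes = snomed_classes,
         attach_prob = attach_prob, p_term = p_term,
         p_distractor = p_distractor, n_distractors = n_distractors,
         sections = sections),
    class = "radterm_sim_config"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy ontology
#'
#' Builds a random tree: a root, the configured top classes as its direct
#' children, two levels of intermediate concepts under each top class, and
#' the vocabulary stems attached as leaves with probability `attach_prob`.
#' The `"radlex"` flavour uses `top_classes` (15 by default), the
#' `"snomed"` flavour `snomed_classes` (19); the two flavours draw
#' independent attachment sets, so their term coverage overlaps only
#' partially.
#'
#' @param config A `radterm_sim_config`.
#' @param flavor `"radlex"` or `"snomed"`.
#' @return A `radterm_ontology`.
#' @export
generate_ontology <- function(config = sim_config(),
                              flavor = c("radlex", "snomed")) {
  flavor <- match.arg(flavor)
  tops <- if (flavor == "radlex") config$top_classes else config$snomed_classes
  prefix <- if (flavor == "radlex") "RID" else "SCT"
  with_seed(config$seed + ifelse(flavor == "radlex", 101L, 202L), {
    rows <- list(tibble(concept_id = paste0(prefix, "0"),
                        preferred_term = paste0(flavor, " entity"),
                        parent_id = ""))
    top_ids <- sprintf("%sT%02d", prefix, seq_along(tops))
    rows[[2]] <- tibble(concept_id = top_ids, preferred_term = tops,
                        parent_id = paste0(prefix, "0"))
    mid1 <- sprintf("%sM%02d", prefix, seq_along(tops))
    rows[[3]] <- tibble(concept_id = mid1,
                        preferred_term = paste(tops, "group"),
                        parent_id = top_ids)
    mid2 <- sprintf("%sS%02d", prefix, seq_along(tops))
    rows[[4]] <- tibble(concept_id = mid2,
                        preferred_term = paste(tops, "subgroup"),
                        parent_id = mid1)
    attach <- stats::runif(length(config$stems)) < config$attach_prob
    if (any(attach)) {
      stems <- config$stems[attach]
      under <- sample(mid2, length(stems), replace = TRUE)
      rows[[5]] <- tibble(
        concept_id = sprintf("%sL%03d", prefix, which(attach)),
        preferred_term = stems,
        parent_id = under
      )
    }
    ontology(bind_rows(rows))
  })
}

# sentence frames: fixed filler tokens around a slot. "{NP}" takes a planted
# compound term (gold), "{D}" a distractor phrase (never gold).
.sim_term_frames <- list(
  c("there", "is", "{NP}", "."),
  c("no", "{NP}", "is", "seen", "."),
  c("the", "{NP}", "is", "unchanged", "."),
  c("{NP}", "is", "noted", "."),
  c("findings", "are", "related", "to", "{NP}", "."),
  c("there", "is", "no", "{NP}", "identified", ".")
)
.sim_distractor_frames <- list(
  c("comparison", "is", "made", "with", "the", "{D}", "."),
  c("the", "{D}", "is", "available", ".")
)
# filler vocabulary is disjoint from the stem/modifier lists so fillers can
# never collide with dictionary surfaces
.sim_filler_frames <- list(
  c("no", "significant", "abnormality", "."),
  c("the", "exam", "is", "unchanged", "."),
  c("findings", "are", "stable", ".")
)

#' Generate a synthetic annotated corpus with dictionaries
#'
#' Produces radiology-style reports over four modalities with three sections
#' each, planting compound terms (stem + 1-3 modifiers) into template
#' sentences. Every planted n-word term is recorded in the gold standard
#' under *all* its suffix patterns of length 2..n with exact character
#' offsets into the assembled report text, the stem word, and the stem's
#' ontology top class. Dictionaries (split over DEFAULT/RADLEX/GPD source
#' tags) contain a `dictionary_coverage` fraction of the distinct gold
#' pattern surfaces, plus distractor phrases planted in non-gold contexts to
#' create realistic false positives.
#'
#' @param config A `radterm_sim_config`.
#' @param graph Optional pre-built `radterm_ontology`; generated from
#'   `config` (radlex flavour) when `NULL`.
#' @param n_reports_per_modality Override of the config value (used for
#'   small validation corpora).
#' @param doc_prefix Prefix for document ids (keeps corpora disjoint).
#' @return List: `reports` (assembled, from [load_reports()]), `corpus`
#'   (long doc/modality/section/text tibble), `gold`, `lexicon` (merged),
#'   `lexicons` (list DEFAULT/RADLEX/GPD), `ontology`, `config`.
#' @export
generate_corpus <- function(config = sim_config(), graph = NULL,
                            n_reports_per_modality = NULL,
                            doc_prefix = "doc") {
  if (is.null(graph)) graph <- generate_ontology(config, "radlex")
  n_per <- n_reports_per_modality %||% config$n_reports_per_modality
  term_idx <- ontology_term_index(graph)
  stem_class <- vapply(config$stems, function(s) {
    ids <- term_idx[[s]]
    if (is.null(ids)) return("unclassified")
    labs <- trace_top_class(graph, ids[[1]])
    if (length(labs) == 1) labs else "unclassified"
  }, character(1))

  lens <- as.integer(names(config$pattern_length_dist))
  modalities <- c("CT", "MRI", "PET", "XRAY")

  with_seed(config$seed, {
    corpus_rows <- list()
    gold_rows <- list()
    for (m in modalities) {
      boosts <- config$stem_boosts[[m]]
      w <- rep(1, length(config$stems))
      names(w) <- config$stems
      if (!is.null(boosts)) w[names(boosts)] <- w[names(boosts)] * boosts
      for (r in seq_len(n_per)) {
        doc_id <- sprintf("%s_%s_%03d", doc_prefix, tolower(m), r)
        n_sent <- max(3L, rpois(1, config$sentences_per_report))
        # roughly half the sentences in the first section, the rest split
        # evenly over the others
        n_sec <- length(config$sections)
        k_first <- max(1L, ceiling(n_sent * 0.5))
        rest <- n_sent - k_first
        per_sec <- c(k_first, rep(rest %/% max(1L, n_sec - 1L), n_sec - 1L))
        per_sec[n_sec] <- per_sec[n_sec] + (n_sent - sum(per_sec))
        per_sec <- pmax(1L, per_sec)
        sec_texts <- setNames(vector("list", n_sec), config$sections)
        offset <- 0L
        for (si in seq_along(config$sections)) {
          sec <- config$sections[si]
          k <- per_sec[si]
          sent_parts <- character(0)
          for (s in seq_len(k)) {
            if (s > 1) offset <- offset + 1L  # space joining sentences
            u <- stats::runif(1)
            if (u < config$p_term) {
              frame <- .sim_term_frames[[sample.int(length(.sim_term_frames), 1)]]
              L <- sample(lens, 1, prob = config$pattern_length_dist)
              stem <- sample(config$stems, 1, prob = w)
              mods <- sample(config$modifiers, L - 1)
              term <- c(mods, stem)
              emitted <- emit_sentence(frame, "{NP}", term, offset)
              # gold: every suffix pattern of length >= 2
              tok_starts <- emitted$slot_starts
              tok_ends <- emitted$slot_ends
              idx <- seq_len(L - 1)
              gold_rows[[length(gold_rows) + 1]] <- tibble(
                doc_id = doc_id,
                start = tok_starts[idx],
                end = tok_ends[L],
                semantic_class = unname(stem_class[stem]),
                surface = vapply(idx, function(i)
                  paste(term[i:L], collapse = " "), character(1)),
                stem = stem
              )
            } else if (u < config$p_term + config$p_distractor) {
              frame <- .sim_distractor_frames[[sample.int(length(.sim_distractor_frames), 1)]]
              d <- default_distractors()[[sample.int(length(default_distractors()), 1)]]
              emitted <- emit_sentence(frame, "{D}", d, offset)
            } else {
              frame <- .sim_filler_frames[[sample.int(length(.sim_filler_frames), 1)]]
              emitted <- emit_sentence(frame, NULL, NULL, offset)
            }
            sent_parts <- c(sent_parts, emitted$text)
            offset <- emitted$offset
          }
          sec_text <- paste(sent_parts, collapse = " ")
          sec_texts[[sec]] <- sec_text
          # +1 for the newline that joins sections in raw_text
          offset <- offset + 1L
        }
        corpus_rows[[length(corpus_rows) + 1]] <- tibble(
          doc_id = doc_id, modality = m,
          section = config$sections,
          text = unlist(sec_texts[config$sections])
        )
      }
    }
    corpus <- bind_rows(corpus_rows)
    gold <- bind_rows(gold_rows)
    if (nrow(gold) > 0) {
      gold <- distinct(gold, .data$doc_id, .data$start, .data$end,
                       .keep_all = TRUE)
      gold <- arrange(gold, .data$doc_id, .data$start, .data$end)
    } else {
      gold <- tibble(doc_id = character(), start = integer(),
                     end = integer(), semantic_class = character(),
                     surface = character(), stem = character())
    }

    # dictionary: a coverage fraction of the distinct gold surfaces ...
    surfaces <- sort(unique(gold$surface), method = "radix")
    n_cov <- round(config$dictionary_coverage * length(surfaces))
    covered <- if (n_cov > 0) sort(sample(surfaces, n_cov)) else character()
    src <- if (length(covered) > 0)
      sample(c("DEFAULT", "RADLEX", "GPD"), length(covered), replace = TRUE,
             prob = c(0.45, 0.45, 0.10)) else character()
    cls <- vapply(covered, function(s) {
      unname(stem_class[identify_stem(s)])
    }, character(1), USE.NAMES = FALSE)
    dict <- tibble(
      concept_id = sprintf("SYN:%05d", match(covered, surfaces)),
      semantic_class = cls, surface = covered, source = src
    )
    # ... plus distractor bait that will fire as false positives
    dis <- default_distractors()[seq_len(min(config$n_distractors,
                                             length(default_distractors())))]
    dis_surf <- vapply(dis, paste, character(1), collapse = " ")
    dict <- bind_rows(dict, tibble(
      concept_id = sprintf("SYN:D%03d", seq_along(dis_surf)),
      semantic_class = "unclassified", surface = dis_surf, source = "GPD"
    ))
    lexicons <- lapply(c(DEFAULT = "DEFAULT", RADLEX = "RADLEX", GPD = "GPD"),
                       function(s) as_lexicon(dict[dict$source == s, ]))
    list(
      reports = load_reports(corpus),
      corpus = corpus,
      gold = gold,
      lexicon = as_lexicon(dict),
      lexicons = lexicons,
      ontology = graph,
      config = config
    )
  })
}

# lay out one sentence frame from `offset`, substituting `slot_tokens` for
# the slot marker; returns the sentence text, the end offset, and the
# per-token offsets of the planted words
emit_sentence <- function(frame, marker, slot_tokens, offset) {
  out <- character(0)
  slot_starts <- integer(0)
  slot_ends <- integer(0)
  cur <- offset
  first <- TRUE
  for (tok in frame) {
    words <- if (!is.null(marker) && tok == marker) slot_tokens else tok
    for (wi in seq_along(words)) {
      w <- words[wi]
      if (!first) cur <- cur + 1L  # joining space
      if (!is.null(marker) && tok == marker) {
        slot_starts <- c(slot_starts, cur)
        slot_ends <- c(slot_ends, cur + nchar(w))
      }
      out <- c(out, w)
      cur <- cur + nchar(w)
      first <- FALSE
    }
  }
  list(text = paste(out, collapse = " "), offset = cur,
       slot_starts = slot_starts, slot_ends = slot_ends)
}

#' Generate a prediction/gold pair with known error counts
#'
#' Starts from a generated corpus's gold standard and derives a prediction
#' set by construction: `n_missing` gold spans are dropped (exact false
#' negatives), `n_spurious` spans are invented at otherwise unused offsets
#' (exact false positives), and `n_shifted` spans have their end offset
#' moved (partial positives: same class, overlapping, unequal — they count
#' as one FN plus one FP each). The expected confusion counts are returned
#' alongside, so span matching can be checked in closed form.
#'
#' @param sim Output of [generate_corpus()] (or a config, which is
#'   generated first).
#' @param n_missing,n_spurious,n_shifted Perturbation counts.
#' @return List: `pred`, `gold`, `expected` (named tp/fp/fn),
#'   `n_partial_expected`.
#' @export
generate_eval_fixture <- function(sim = sim_config(n_reports_per_modality = 2),
                                  n_missing = 3, n_spurious = 2,
                                  n_shifted = 2) {
  if (inherits(sim, "radterm_sim_config")) sim <- generate_corpus(sim)
  gold <- sim$gold
  n <- nrow(gold)
  if (n_missing + n_shifted > n) abort("not enough gold spans to perturb.")
  with_seed(sim$config$seed + 7L, {
    pick <- sample.int(n, n_missing + n_shifted)
    drop_idx <- pick[seq_len(n_missing)]
    shift_idx <- setdiff(pick, drop_idx)
    pred <- gold[setdiff(seq_len(n), c(drop_idx, shift_idx)), , drop = FALSE]
    shifted <- gold[shift_idx, , drop = FALSE]
    if (nrow(shifted) > 0) {
      shifted$end <- shifted$end + 1L  # into the joining space: overlapping, unequal
      pred <- bind_rows(pred, shifted)
    }
    if (n_spurious > 0) {
      docs <- unique(gold$doc_id)
      pred <- bind_rows(pred, tibble(
        doc_id = sample(docs, n_spurious, replace = TRUE),
        start = 0L, end = seq_len(n_spurious) + 1L,
        semantic_class = "spurious",
        surface = paste("spurious span", seq_len(n_spurious)),
        stem = "span"
      ))
    }
    list(
      pred = arrange(pred, .data$doc_id, .data$start, .data$end),
      gold = gold,
      expected = c(tp = n - n_missing - n_shifted,
                   fp = n_spurious + n_shifted,
                   fn = n_missing + n_shifted),
      n_partial_expected = n_shifted
    )
  })
}

#' Write all artifacts of a generated study to disk
#'
#' Writes `corpus.tsv`, `gold.tsv`, `dict_default.bsv`, `dict_radlex.bsv`,
#' `dict_gpd.bsv`, `ontology_radlex.tsv` (and `ontology_snomed.tsv` when
#' given) under `out_dir`.
#'
#' @param sim Output of [generate_corpus()].
#' @param out_dir Output directory (created if needed).
#' @param snomed Optional second `radterm_ontology` to write.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir, snomed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    corpus = file.path(out_dir, "corpus.tsv"),
    gold = file.path(out_dir, "gold.tsv"),
    dict_default = file.path(out_dir, "dict_default.bsv"),
    dict_radlex = file.path(out_dir, "dict_radlex.bsv"),
    dict_gpd = file.path(out_dir, "dict_gpd.bsv"),
    ontology_radlex = file.path(out_dir, "ontology_radlex.tsv")
  )
  write_corpus_tsv(sim$corpus, paths[["corpus"]])
  write_annotations_tsv(sim$gold, paths[["gold"]])
  write_dictionary_bsv(sim$lexicons$DEFAULT, paths[["dict_default"]])
  write_dictionary_bsv(sim$lexicons$RADLEX, paths[["dict_radlex"]])
  write_dictionary_bsv(sim$lexicons$GPD, paths[["dict_gpd"]])
  write_ontology_table(sim$ontology, paths[["ontology_radlex"]])
  if (!is.null(snomed)) {
    paths[["ontology_snomed"]] <- file.path(out_dir, "ontology_snomed.tsv")
    write_ontology_table(snomed, paths[["ontology_snomed"]])
  }
  invisible(paths)
}
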