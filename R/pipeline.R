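#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full run. Two modes:
#' simulation (`simulate = TRUE`: a corpus, gold standard, dictionaries and
#' ontology are generated from `seed` and the `sim` options, and split into
#' development and validation reports) or file mode (paths to an existing
#' corpus TSV, gold TSV and dictionary BSVs). Referenced files are checked
#' at validation time, before any stage runs. Configs round-trip through
#' YAML.
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return Validated config list (class `radterm_pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    simulate = TRUE,
    sim = list(),                    # overrides for sim_config()
    val_reports_per_modality = 5L,   # simulation mode: held-out reports
    corpus = NULL, gold = NULL,      # file mode
    dictionaries = character(),      # file mode: BSV paths, ordered
    ontology = NULL,                 # optional ontology TSV (file mode)
    policy = "all",
    join_prepositions = FALSE,
    check_class = TRUE,
    stopwords = NULL,                # optional path to a stop-word file
    out_dir = "radterm_run"
  )
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$policy %in% c("all", "longest")) {
    abort("policy must be 'all' or 'longest'.")
  }
  if (!isTRUE(cfg$simulate)) {
    for (p in c(cfg$corpus, cfg$gold, cfg$dictionaries, cfg$ontology,
                cfg$stopwords)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(paste0("configured file does not exist: ", p))
      }
    }
    if (is.null(cfg$corpus) || is.null(cfg$gold) ||
        length(cfg$dictionaries) == 0) {
      abort("file mode needs `corpus`, `gold` and at least one dictionary.")
    }
  }
  class(cfg) <- "radterm_pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes the stages in order — obtain corpus and dictionaries (simulated
#' or loaded), annotate, evaluate, enhance (when a validation split is
#' available), stem analytics — writing every artifact plus a manifest under
#' `out_dir`. The manifest records the package version, seed, per-file MD5
#' hashes and the headline metrics, so a rerun with identical inputs can be
#' verified to reproduce the numbers exactly.
#'
#' @param config A `radterm_pipeline_config`, plain list, or YAML path.
#' @return The manifest list, invisibly. Artifacts are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "radterm_pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  stopwords <- if (!is.null(cfg$stopwords)) {
    tolower(trimws(readLines(cfg$stopwords, warn = FALSE)))
  } else radterm_stopwords()

  if (isTRUE(cfg$simulate)) {
    log_stage("simulate", paste0("seed ", cfg$seed))
    sc_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    sc <- do.call(sim_config, sc_args)
    dev <- generate_corpus(sc, doc_prefix = "dev")
    val <- generate_corpus(sim_config_derive(sc, cfg$seed + 1000L),
                           graph = dev$ontology,
                           n_reports_per_modality = cfg$val_reports_per_modality,
                           doc_prefix = "val")
    write_simulation(dev, file.path(cfg$out_dir, "fixtures"))
    reports <- dev$reports; gold <- dev$gold
    lex <- dev$lexicon; graph <- dev$ontology
    val_reports <- val$reports; val_gold <- val$gold
  } else {
    log_stage("load", cfg$corpus)
    reports <- load_reports(cfg$corpus)
    gold <- read_annotations_tsv(cfg$gold)
    lex <- merge_lexicons(lapply(cfg$dictionaries, read_dictionary_bsv))
    graph <- if (!is.null(cfg$ontology)) read_ontology_table(cfg$ontology)
             else NULL
    val_reports <- NULL; val_gold <- NULL
  }

  lex <- filter_single_terms(lex)
  log_stage("annotate", paste0(nrow(reports), " reports, ",
                               nrow(lex), " dictionary entries"))
  pred <- annotate_corpus(reports, lex, policy = cfg$policy,
                          join_prepositions = cfg$join_prepositions,
                          stopwords = stopwords)
  write_annotations_tsv(pred, file.path(cfg$out_dir, "annotations.tsv"))

  log_stage("evaluate", paste0(nrow(pred), " predictions vs ",
                               nrow(gold), " gold spans"))
  mres <- match_annotations(pred, gold, mode = "partial",
                            check_class = cfg$check_class)
  metrics <- per_modality_metrics(pred, gold, reports,
                                  check_class = cfg$check_class)

  enhance_glance <- NULL
  if (!is.null(val_reports)) {
    log_stage("enhance", paste0("validating on ", nrow(val_reports),
                                " held-out reports"))
    rep_enh <- enhance_and_validate(lex, reports, gold, val_reports,
                                    val_gold, policy = cfg$policy,
                                    check_class = cfg$check_class,
                                    join_prepositions = cfg$join_prepositions,
                                    stopwords = stopwords, graph = graph)
    write_dictionary_bsv(rep_enh$enhanced_lexicon,
                         file.path(cfg$out_dir, "cted.bsv"))
    write_cted_delta_tsv(rep_enh$delta, file.path(cfg$out_dir, "cted_delta.tsv"))
    enhance_glance <- glance(rep_enh)
  }

  log_stage("stemstats", "stem occurrence and matching ratios")
  stems <- bind_rows(
    extract_stems(mutate(mres$tp, category = "TP"), reports,
                  stopwords = stopwords),
    extract_stems(mutate(mres$fn, category = "FN"), reports,
                  stopwords = stopwords)
  )
  or_tab <- compute_or(stems)
  onts <- if (!is.null(graph)) list(RADLEX = graph) else list()
  mr_tab <- compute_mr(stems[stems$category == "FN", , drop = FALSE], onts)
  wl_tab <- word_length_profile(mres$fn)
  utils::write.table(or_tab, file.path(cfg$out_dir, "or.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mr_tab, file.path(cfg$out_dir, "mr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(wl_tab, file.path(cfg$out_dir, "wordlen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  metrics_out <- list(
    per_modality = metrics,
    enhancement = enhance_glance
  )
  jsonlite::write_json(metrics_out, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "radterm",
    version = as.character(utils::packageVersion("radterm")),
    seed = cfg$seed,
    policy = cfg$policy,
    n_reports = nrow(reports),
    n_gold = nrow(gold),
    metrics = metrics[metrics$modality == "All", ],
    enhancement = enhance_glance,
    files = lapply(setNames(files, sub(paste0("^", cfg$out_dir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_stage("done", cfg$out_dir)
  invisible(manifest)
}

# a config equal to `sc` but reseeded (used for the held-out split)
sim_config_derive <- function(sc, seed) {
  sc$seed <- as.integer(seed %% .Machine$integer.max)
  sc
}
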