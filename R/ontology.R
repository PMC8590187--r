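#' Construct an ontology graph from an edge table
#'
#' The hierarchy is exchanged as a tidy edge table: one row per parent link,
#' columns `concept_id`, `preferred_term`, `parent_id`, with the single root
#' carrying an empty `parent_id`. Multiple rows for one concept express
#' multiple parents (a DAG). On construction the graph is validated: exactly
#' one root, no cycles, and every concept reachable from the root by
#' following parent links upward. The *top classes* are the direct children
#' of the root — the coarse semantic classes (e.g. "anatomical entity",
#' "clinical finding") that ancestor tracing reports.
#'
#' @param edges Data frame with columns `concept_id`, `preferred_term`,
#'   `parent_id` (`NA` or `""` for the root row).
#' @return A `radterm_ontology` object.
#' @export
ontology <- function(edges) {
  need <- c("concept_id", "preferred_term", "parent_id")
  missing_cols <- setdiff(need, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("ontology table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  edges <- as_tibble(edges)
  edges$concept_id <- as.character(edges$concept_id)
  edges$preferred_term <- normalize_term(as.character(edges$preferred_term))
  edges$parent_id <- as.character(edges$parent_id)
  edges$parent_id[is.na(edges$parent_id)] <- ""

  concepts <- distinct(edges, .data$concept_id, .data$preferred_term)
  if (anyDuplicated(concepts$concept_id)) {
    dup <- concepts$concept_id[duplicated(concepts$concept_id)]
    abort(paste0("conflicting preferred terms for concept(s): ",
                 paste(unique(dup), collapse = ", ")))
  }

  root_rows <- edges$concept_id[edges$parent_id == ""]
  root_id <- unique(root_rows)
  if (length(root_id) != 1) {
    abort(paste0("ontology must have exactly one root (empty parent_id); found ",
                 length(root_id)))
  }
  parent_edges <- edges[edges$parent_id != "", , drop = FALSE]
  unknown <- setdiff(parent_edges$parent_id, concepts$concept_id)
  if (length(unknown) > 0) {
    abort(paste0("parent_id refers to unknown concept(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(parent_edges$parent_id == parent_edges$concept_id)) {
    abort("self-loop: a concept lists itself as parent.")
  }

  parents <- split(parent_edges$parent_id, parent_edges$concept_id)
  parents <- lapply(parents, unique)

  detect_cycle(parents, concepts$concept_id, root_id)

  reachable <- reachable_from_root(parents, concepts$concept_id, root_id)
  orphans <- setdiff(concepts$concept_id, reachable)
  if (length(orphans) > 0) {
    abort(paste0("concept(s) unreachable from root: ",
                 paste(orphans, collapse = ", ")))
  }

  top_ids <- unique(parent_edges$concept_id[parent_edges$parent_id == root_id])
  terms <- setNames(concepts$preferred_term, concepts$concept_id)

  structure(
    list(
      root_id = root_id,
      concepts = concepts,
      parents = parents,
      top_class_ids = top_ids,
      terms = terms
    ),
    class = "radterm_ontology"
  )
}

# DFS cycle check over the child -> parents map (colours: 0 new, 1 open, 2 done)
detect_cycle <- function(parents, ids, root_id) {
  colour <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- mget(id, envir = colour, ifnotfound = 0L)[[1]]
    if (st == 1L) abort(paste0("cycle detected through concept ", id))
    if (st == 2L) return(invisible())
    assign(id, 1L, envir = colour)
    for (p in parents[[id]]) visit(p)
    assign(id, 2L, envir = colour)
    invisible()
  }
  for (id in ids) visit(id)
}

# BFS downward: reachable = concepts with an all-parent-links path to root.
# Upward reachability along parents equals downward reachability from root
# over reversed edges when at least one parent chain reaches the root; we
# check the weaker (and intended) condition that *some* chain reaches root.
reachable_from_root <- function(parents, ids, root_id) {
  children <- new.env(parent = emptyenv())
  for (id in names(parents)) {
    for (p in parents[[id]]) {
      assign(p, c(mget(p, envir = children, ifnotfound = list(character()))[[1]], id),
             envir = children)
    }
  }
  seen <- character()
  queue <- root_id
  while (length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    kids <- mget(cur, envir = children, ifnotfound = list(character()))[[1]]
    queue <- c(queue, setdiff(kids, seen))
  }
  seen
}

#' Read an ontology hierarchy TSV
#'
#' @param path Tab-separated file with header
#'   `concept_id  preferred_term  parent_id`; one row per parent edge, root
#'   row with empty `parent_id`.
#' @return A `radterm_ontology`.
#' @export
read_ontology_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such ontology file: ", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = NULL, fileEncoding = "UTF-8")
  ontology(df)
}

#' Write an ontology to its TSV edge-table form
#'
#' @param graph A `radterm_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology_table <- function(graph, path) {
  stopifnot(inherits(graph, "radterm_ontology"))
  rows <- list(tibble(concept_id = graph$root_id,
                      preferred_term = unname(graph$terms[graph$root_id]),
                      parent_id = ""))
  for (id in names(graph$parents)) {
    rows[[length(rows) + 1]] <- tibble(
      concept_id = id,
      preferred_term = unname(graph$terms[id]),
      parent_id = graph$parents[[id]]
    )
  }
  df <- bind_rows(rows)
  df <- arrange(df, .data$concept_id, .data$parent_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Trace a concept to its top class(es)
#'
#' Follows parent links from a concept until reaching the classes directly
#' under the ontology root, the way a stem term like "effusion" is traced up
#' to "clinical finding". A concept with several parents can surface under
#' more than one top class; all are returned (downstream analytics bucket
#' such concepts as "Over two categories"). A top class traces to itself; the
#' root itself yields an empty set.
#'
#' @param graph A `radterm_ontology`.
#' @param concept_id Concept to trace.
#' @param labels If `TRUE` (default) return preferred-term labels; otherwise
#'   concept ids.
#' @return Character vector (a set) of top classes.
#' @export
trace_top_class <- function(graph, concept_id, labels = TRUE) {
  stopifnot(inherits(graph, "radterm_ontology"))
  if (!concept_id %in% graph$concepts$concept_id) {
    abort(paste0("unknown concept: ", concept_id))
  }
  tops <- character()
  stack <- concept_id
  seen <- character()
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    if (cur %in% graph$top_class_ids) {
      tops <- c(tops, cur)
      next
    }
    if (cur == graph$root_id) next
    stack <- c(stack, graph$parents[[cur]])
  }
  tops <- unique(tops)
  if (labels) unname(graph$terms[tops]) else tops
}

# preferred_term (normalized) -> concept ids; the exact-match term set used
# by the matching-ratio analysis.
ontology_term_index <- function(graph) {
  split(graph$concepts$concept_id, graph$concepts$preferred_term)
}

#' @export
print.radterm_ontology <- function(x, ...) {
  cat("<radterm ontology: ", nrow(x$concepts), " concepts, ",
      length(x$top_class_ids), " top classes under root '",
      unname(x$terms[x$root_id]), "'>\n", sep = "")
  invisible(x)
}
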