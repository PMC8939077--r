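# Quality control, release diffing, and the build orchestrator.

qc_row <- function(rule, ids, message, severity) {
  data.frame(rule = rule, ids = paste(ids, collapse = "|"),
             message = message, severity = severity, stringsAsFactors = FALSE)
}

#' Run quality-control checks on a build
#'
#' Rules: `duplicate_label` (case-insensitive label collision among
#' non-obsolete classes), `duplicate_logical_definition` (structurally
#' identical ground expressions with distinct ids, including mutual
#' entailments flagged by the classifier), `dangling_reference` (expression
#' atom or binding not found in the source ontologies, or `replaced_by`
#' outside the build), `missing_definition` (warning), and
#' `obsolete_with_logic`. QC reports and never throws.
#'
#' @param classes named list of `phenotype_class` objects.
#' @param edges optional data frame of derived is_a edges (unused by the
#'   current rules, accepted for interface stability).
#' @param sources list of source `ontology_graph`s used to resolve atoms.
#' @param equivalences optional data frame (`a`, `b`) of mutually entailing
#'   pairs from [classify()].
#' @return data frame with columns `rule`, `ids`, `message`, `severity`
#'   (severity `error` or `warning`), deterministically ordered.
#' @export
run_qc <- function(classes, edges = NULL, sources = list(),
                   equivalences = NULL) {
  if (is.null(names(classes)) && length(classes))
    names(classes) <- vapply(classes, `[[`, character(1), "id")
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- qc_row(...)
  live <- classes[vapply(classes, function(cl) !isTRUE(cl$obsolete),
                         logical(1))]

  # duplicate_label: case-insensitive, non-obsolete classes only
  labs <- tolower(vapply(live, `[[`, character(1), "label"))
  for (l in sort_c(unique(labs[duplicated(labs)]))) {
    ids <- sort_c(names(live)[labs == l])
    add("duplicate_label", ids,
        sprintf("label \"%s\" used by %d classes", l, length(ids)), "error")
  }

  # duplicate_logical_definition: canonical-form collisions + classifier
  # equivalences
  defs <- vapply(live, function(cl)
    if (is.null(cl$logical_definition)) NA_character_
    else expression_string(cl$logical_definition), character(1))
  dup_pairs <- character(0)
  for (d in sort_c(unique(defs[!is.na(defs) & duplicated(defs)]))) {
    ids <- sort_c(names(live)[!is.na(defs) & defs == d])
    dup_pairs <- c(dup_pairs, paste(ids, collapse = "|"))
    add("duplicate_logical_definition", ids,
        sprintf("logical definition shared by %d classes: %s",
                length(ids), d), "error")
  }
  if (!is.null(equivalences) && nrow(equivalences)) {
    for (k in seq_len(nrow(equivalences))) {
      ids <- sort_c(c(equivalences$a[k], equivalences$b[k]))
      key <- paste(ids, collapse = "|")
      if (key %in% dup_pairs) next
      dup_pairs <- c(dup_pairs, key)
      add("duplicate_logical_definition", ids,
          "classes are mutually entailing (logically equivalent)", "error")
    }
  }

  # dangling_reference
  known <- unique(unlist(lapply(sources, term_ids), use.names = FALSE))
  for (id in sort_c(names(classes))) {
    cl <- classes[[id]]
    refs <- character(0)
    if (!is.null(cl$logical_definition))
      refs <- expression_curies(cl$logical_definition)
    refs <- unique(c(refs, unlist(cl$provenance$bindings, use.names = FALSE)))
    miss <- sort_c(setdiff(refs, known))
    if (length(miss))
      add("dangling_reference", id,
          sprintf("unresolvable reference(s): %s",
                  paste(miss, collapse = ", ")), "error")
    if (!is.null(cl$replaced_by) && !cl$replaced_by %in% names(classes))
      add("dangling_reference", id,
          sprintf("replaced_by target %s not in build", cl$replaced_by),
          "error")
  }

  # missing_definition / obsolete_with_logic
  for (id in sort_c(names(classes))) {
    cl <- classes[[id]]
    if (!isTRUE(cl$obsolete) &&
        (is.null(cl$definition) || !nzchar(cl$definition)))
      add("missing_definition", id, "class has no text definition", "warning")
    if (isTRUE(cl$obsolete) && !is.null(cl$logical_definition))
      add("obsolete_with_logic", id,
          "obsolete class still carries a logical definition", "error")
  }

  if (!length(out))
    return(data.frame(rule = character(0), ids = character(0),
                      message = character(0), severity = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order_c(res$rule, res$ids), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Diff two releases
#'
#' `removed` means an id present in the old release and absent from the new
#' one — not merely obsoleted. A non-empty `removed` set marks the diff as
#' failing: terms must be obsoleted, never deleted.
#'
#' @param old,new `ontology_graph` releases.
#' @return an object of class `release_diff` with fields `added`, `removed`,
#'   `newly_obsoleted`, `label_changed`, `definition_changed`, `failing`.
#' @export
diff_releases <- function(old, new) {
  old_ids <- term_ids(old); new_ids <- term_ids(new)
  common <- intersect(old_ids, new_ids)
  obs <- function(g, ids) ids[vapply(g$terms[ids], function(t) t$obsolete,
                                     logical(1))]
  lab <- function(g, ids) vapply(g$terms[ids], function(t)
    t$label %||% NA_character_, character(1))
  def <- function(g, ids) vapply(g$terms[ids], function(t)
    t$definition %||% NA_character_, character(1))
  removed <- sort_c(setdiff(old_ids, new_ids))
  newly_obsoleted <- sort_c(setdiff(obs(new, common), obs(old, common)))
  lab_old <- lab(old, common); lab_new <- lab(new, common)
  def_old <- def(old, common); def_new <- def(new, common)
  neq <- function(a, b) xor(is.na(a), is.na(b)) | (!is.na(a) & !is.na(b) & a != b)
  structure(list(
    added = sort_c(setdiff(new_ids, old_ids)),
    removed = removed,
    newly_obsoleted = newly_obsoleted,
    label_changed = sort_c(common[neq(lab_old, lab_new)]),
    definition_changed = sort_c(common[neq(def_old, def_new)]),
    failing = length(removed) > 0),
    class = "release_diff")
}

#' @export
print.release_diff <- function(x, ...) {
  cat("<release_diff>", if (x$failing) "FAILING" else "ok", "\n")
  for (f in c("added", "removed", "newly_obsoleted", "label_changed",
              "definition_changed"))
    cat(sprintf("  %s: %d\n", f, length(x[[f]])))
  invisible(x)
}

#' Write a QC report as TSV
#' @param qc data frame from [run_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc[c("rule", "ids", "message")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a diff report as TSV
#' @param diff a `release_diff`.
#' @param path output path.
#' @export
write_diff_report <- function(diff, path) {
  rows <- list()
  for (f in c("added", "removed", "newly_obsoleted", "label_changed",
              "definition_changed"))
    if (length(diff[[f]]))
      rows[[f]] <- data.frame(change = f, id = diff[[f]], detail = "",
                              stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(change = character(0), id = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

as_graph_input <- function(x) {
  if (inherits(x, "ontology_graph")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_obo(x))
  stop("expected an ontology_graph or a file path", call. = FALSE)
}

release_graph <- function(classes, classification, config) {
  root <- config$root
  terms <- list(obo_term(root$id, label = root$label,
                         definition = root$definition %||% NULL))
  for (id in sort_c(names(classes))) {
    cl <- classes[[id]]
    terms[[length(terms) + 1L]] <-
      obo_term(cl$id, label = cl$label, definition = cl$definition,
               synonyms = cl$synonyms, obsolete = cl$obsolete,
               replaced_by = cl$replaced_by)
  }
  edges <- classification$edges
  rel <- data.frame(subject = edges$child, predicate = "is_a",
                    object = edges$parent, stringsAsFactors = FALSE)
  ontology_graph(terms, rel,
                 header = list(ontology = config$ontology_id %||% "phenotype",
                               root = root$id))
}

release_meta <- function(classes, patterns) {
  rel_map <- list()
  for (p in patterns) rel_map[names(p$relations)] <- p$relations
  meta <- list()
  for (id in names(classes)) {
    cl <- classes[[id]]
    if (is.null(cl$logical_definition)) next
    meta[[id]] <- list(
      logical_definition = expression_string(cl$logical_definition,
                                             relations = rel_map),
      pattern = cl$provenance$pattern,
      bindings = cl$provenance$bindings)
  }
  meta
}

#' Build a complete ontology release
#'
#' Runs the whole pipeline: parse sources, select entities and synchronize
#' the instance tables, mint missing ids, compile pattern instances, apply
#' obsoletions, classify, run QC, serialize to OBO and JSON, and diff
#' against the previous release when given. Each stage logs one line with
#' counts to standard error. Identical inputs give byte-identical OBO and
#' JSON artifacts.
#'
#' @param anatomy anatomy `ontology_graph` or path to an OBO file.
#' @param quality quality `ontology_graph` or OBO path.
#' @param patterns named list of `design_pattern` objects, or a directory of
#'   pattern YAML files.
#' @param config a `selection_config` (or YAML path) carrying the inclusion
#'   roots, exclusions, filters, auto patterns, root class and id scheme.
#' @param tables named list of instance tables, or a directory of
#'   `<pattern>.tsv` files; missing auto-pattern tables are created.
#' @param registry an `id_registry`, or a ledger path, or NULL for a fresh
#'   registry built from the config's prefix/width.
#' @param obsoletions data frame (or TSV path) with columns `id`,
#'   `replaced_by`, `reason`; optional.
#' @param previous previous release `ontology_graph` or OBO path; optional.
#' @param verbose log stage lines to standard error.
#' @return an object of class `ontology_release`: `obo` and `json` texts,
#'   `classes`, `classification`, `qc`, `diff` (or NULL), updated `tables`
#'   and `registry`, `sync_report`, and `status` (0 clean, 1 QC errors,
#'   2 failing diff).
#' @export
build_release <- function(anatomy, quality, patterns, config,
                          tables = list(), registry = NULL,
                          obsoletions = NULL, previous = NULL,
                          verbose = TRUE) {
  log_stage <- function(stage, n_in, n_out) {
    if (verbose)
      message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }
  if (is.character(config)) config <- read_selection_config(config)
  if (is.null(config$root))
    stop("config must provide the root phenotype class (root: {id, label})",
         call. = FALSE)
  anatomy <- as_graph_input(anatomy)
  quality <- as_graph_input(quality)
  if (is.character(patterns) && length(patterns) == 1 && dir.exists(patterns)) {
    files <- sort_c(list.files(patterns, pattern = "\\.ya?ml$",
                               full.names = TRUE))
    patterns <- lapply(files, parse_pattern)
  }
  names(patterns) <- vapply(patterns, `[[`, character(1), "pattern_id")
  log_stage("parse_sources", 2L, length(anatomy$terms) + length(quality$terms))

  if (is.character(tables) && length(tables) == 1 && dir.exists(tables)) {
    files <- sort_c(list.files(tables, pattern = "\\.tsv$", full.names = TRUE))
    tabs <- lapply(files, read_instance_table)
    names(tabs) <- sub("\\.tsv$", "", basename(files))
    tables <- tabs
  }
  sync <- sync_tables(anatomy, config, tables, patterns)
  tables <- sync$tables
  log_stage("select_sync", length(config$auto_patterns),
            sum(vapply(tables, nrow, integer(1))))

  if (is.null(registry))
    registry <- id_registry(config$prefix, config$width)
  else if (is.character(registry))
    registry <- read_id_registry(registry)
  minted <- mint_ids(tables, registry)
  tables <- minted$tables; registry <- minted$registry
  log_stage("mint", sum(vapply(tables, nrow, integer(1))),
            nrow(registry$issued))

  labels <- c(term_labels(anatomy), term_labels(quality))
  classes <- list()
  for (pid in sort_c(names(tables))) {
    if (!pid %in% names(patterns))
      stop("no pattern definition for table '", pid, "'", call. = FALSE)
    cls <- compile_table(patterns[[pid]], tables[[pid]], labels)
    for (cl in cls) classes[[cl$id]] <- cl
  }
  log_stage("compile", sum(vapply(tables, nrow, integer(1))), length(classes))

  if (!is.null(obsoletions)) {
    if (is.character(obsoletions)) obsoletions <- read_obsoletions(obsoletions)
    classes <- apply_obsoletions(classes, obsoletions)
    log_stage("obsolete", nrow(obsoletions), length(classes))
  }

  classification <- classify(classes, anatomy, quality, patterns,
                             root = config$root$id)
  log_stage("classify", length(classes), nrow(classification$edges))

  qc <- run_qc(classes, classification$edges,
               sources = list(anatomy, quality),
               equivalences = classification$equivalences)
  log_stage("qc", length(classes), nrow(qc))

  graph <- release_graph(classes, classification, config)
  obo <- write_obo(graph)
  json <- write_json_graph(graph, meta = release_meta(classes, patterns))
  log_stage("serialize", length(graph$terms), 2L)

  diff <- NULL
  if (!is.null(previous)) {
    diff <- diff_releases(as_graph_input(previous), graph)
    log_stage("diff", length(graph$terms),
              length(diff$added) + length(diff$removed))
  }

  status <- 0L
  if (!is.null(diff) && diff$failing) status <- 2L
  if (any(qc$severity == "error")) status <- 1L
  structure(list(obo = obo, json = json, graph = graph, classes = classes,
                 classification = classification, qc = qc, diff = diff,
                 tables = tables, registry = registry,
                 sync_report = sync$report, status = status),
            class = "ontology_release")
}

#' @export
print.ontology_release <- function(x, ...) {
  cat("<ontology_release> ", length(x$graph$terms), " terms, ",
      nrow(x$classification$edges), " is_a edges, status ", x$status, "\n",
      sep = "")
  n_err <- sum(x$qc$severity == "error")
  n_warn <- sum(x$qc$severity == "warning")
  cat("  qc: ", n_err, " error(s), ", n_warn, " warning(s)\n", sep = "")
  if (!is.null(x$diff))
    cat("  diff:", if (x$diff$failing) "FAILING" else "ok", "\n")
  invisible(x)
}
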