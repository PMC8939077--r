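# Which entity terms receive generated phenotype classes. Traversal from the
# inclusion roots follows only the configured relations — is_a and part_of by
# default, never develops_from: a phenotype of a developed structure must not
# propagate to its developmental precursor.

#' Read a selection configuration from YAML
#'
#' Fields: `traversal_relations` (default `is_a`, `part_of`),
#' `auto_patterns` (pattern ids applied to every newly included term),
#' `patterns: {<id>: {roots: [...]}}` (per-pattern inclusion roots),
#' `exclusions: {terms: [...], branches: [...]}` (branch exclusion removes
#' the term and its whole traversal closure), `filters:
#' [{pattern:, forbid_branch:}]` (per-pattern applicability filters),
#' `root: {id:, label:}` (the release's root phenotype class), `prefix` and
#' `width` (id minting scheme), `ontology_id` (release header).
#' `use_develops_from_inverse` is a stub for inverse develops_from
#' propagation and errors if enabled.
#'
#' @param x YAML text or file path.
#' @return an object of class `selection_config`.
#' @export
read_selection_config <- function(x) {
  doc <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    yaml::read_yaml(x) else yaml::yaml.load(x)
  selection_config(
    traversal_relations = doc$traversal_relations %||% c("is_a", "part_of"),
    auto_patterns = as.character(doc$auto_patterns %||% character(0)),
    patterns = doc$patterns %||% list(),
    excluded_terms = as.character(doc$exclusions$terms %||% character(0)),
    excluded_branches = as.character(doc$exclusions$branches %||% character(0)),
    filters = doc$filters %||% list(),
    root = doc$root,
    prefix = doc$prefix %||% "XPO",
    width = doc$width %||% 7L,
    ontology_id = doc$ontology_id,
    use_develops_from_inverse = isTRUE(doc$use_develops_from_inverse))
}

#' Construct a selection configuration
#'
#' @param traversal_relations relation names used when traversing from
#'   inclusion roots to lower-level terms.
#' @param auto_patterns pattern ids auto-applied to every new included term.
#' @param patterns named list, pattern id -> `list(roots = c(...))`.
#' @param excluded_terms CURIEs excluded individually.
#' @param excluded_branches CURIEs excluded together with their whole
#'   traversal closure.
#' @param filters list of `list(pattern =, forbid_branch =)` applicability
#'   filters.
#' @param root `list(id =, label =)` for the release root phenotype class.
#' @param prefix,width id-minting scheme (CURIE prefix and digit count).
#' @param ontology_id release ontology id for the OBO/JSON headers.
#' @param use_develops_from_inverse stub; must be FALSE (inverse
#'   develops_from propagation is not implemented).
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(traversal_relations = c("is_a", "part_of"),
                             auto_patterns = character(0),
                             patterns = list(),
                             excluded_terms = character(0),
                             excluded_branches = character(0),
                             filters = list(),
                             root = NULL,
                             prefix = "XPO", width = 7L,
                             ontology_id = NULL,
                             use_develops_from_inverse = FALSE) {
  if (isTRUE(use_develops_from_inverse))
    stop("inverse develops_from propagation is a declared extension point ",
         "and is not implemented", call. = FALSE)
  structure(list(traversal_relations = as.character(traversal_relations),
                 auto_patterns = auto_patterns,
                 patterns = patterns,
                 excluded_terms = excluded_terms,
                 excluded_branches = excluded_branches,
                 filters = filters,
                 root = root, prefix = prefix, width = as.integer(width),
                 ontology_id = ontology_id),
            class = "selection_config")
}

#' Relation-restricted descendants
#'
#' Reflexive-transitive closure of the inverse of the listed relations from
#' `root`: every term that reaches `root` through chains of those relations.
#' With the default relations this walks is_a and part_of but never
#' develops_from.
#'
#' @param graph an `ontology_graph`.
#' @param root CURIE present in the graph.
#' @param relations character vector of relation names to traverse.
#' @return CURIEs in deterministic (C-locale sorted) order, always including
#'   `root` itself.
#' @export
descendants <- function(graph, root, relations = c("is_a", "part_of")) {
  if (!root %in% term_ids(graph))
    stop("unknown root term: ", root, call. = FALSE)
  rel <- graph$relationships
  rel <- rel[rel$predicate %in% relations, , drop = FALSE]
  children <- split(rel$subject, rel$object)
  seen <- new.env(parent = emptyenv())
  assign(root, TRUE, envir = seen)
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in children[[v]] %||% character(0)) {
      if (is.null(get0(w, envir = seen))) {
        assign(w, TRUE, envir = seen)
        queue <- c(queue, w)
      }
    }
  }
  sort_c(ls(envir = seen))
}

#' Select the entity terms a pattern applies to
#'
#' Union of the relation-restricted descendants of the pattern's inclusion
#' roots, minus individually excluded terms, minus excluded branches (term
#' plus closure), minus any applicability-filter branch bound to this
#' pattern; obsolete terms are always excluded. Exclusion beats inclusion
#' when a term is reachable both ways.
#'
#' @param graph an `ontology_graph`.
#' @param config a `selection_config`.
#' @param pattern_id pattern whose inclusion roots and filters apply.
#' @return CURIEs in deterministic order.
#' @export
select_entities <- function(graph, config, pattern_id) {
  roots <- config$patterns[[pattern_id]]$roots
  if (is.null(roots))
    stop("no inclusion roots configured for pattern '", pattern_id, "'",
         call. = FALSE)
  cyc <- find_cycle(graph, config$traversal_relations)
  if (!is.null(cyc))
    stop("cycle over traversal relations {",
         paste(config$traversal_relations, collapse = ", "), "}: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  sel <- unique(unlist(lapply(roots, descendants, graph = graph,
                              relations = config$traversal_relations)))
  drop <- config$excluded_terms
  for (b in config$excluded_branches)
    if (b %in% term_ids(graph))
      drop <- c(drop, descendants(graph, b, config$traversal_relations))
  for (f in config$filters) {
    if (!identical(f$pattern, pattern_id)) next
    if (f$forbid_branch %in% term_ids(graph))
      drop <- c(drop, descendants(graph, f$forbid_branch,
                                  config$traversal_relations))
  }
  obs <- names(graph$terms)[vapply(graph$terms, function(t) t$obsolete,
                                   logical(1))]
  sort_c(setdiff(sel, c(drop, obs)))
}

#' Synchronize instance tables with the source ontology
#'
#' For each auto pattern, adds rows (ids left blank for minting) for newly
#' selected entities absent from its table, and flags rows whose entity is
#' no longer selected — removed, obsoleted, or newly excluded — for
#' obsoletion instead of deleting them. Idempotent: a second run on its own
#' output with unchanged inputs adds and flags nothing.
#'
#' @param graph an `ontology_graph`.
#' @param config a `selection_config` whose `auto_patterns` are all present
#'   in `patterns`.
#' @param tables named list, pattern id -> instance table data frame;
#'   missing tables are created.
#' @param patterns named list of `design_pattern` objects (needed for
#'   variable names and label templates). Auto patterns must have exactly
#'   one variable.
#' @return `list(tables =, report =)`; the report is a data frame with
#'   columns `pattern`, `action` (`add` or `flag`), `entity`.
#' @export
sync_tables <- function(graph, config, tables, patterns) {
  stopifnot(is.list(tables))
  unknown <- setdiff(config$auto_patterns, names(patterns))
  if (length(unknown))
    stop("auto_patterns not in pattern library: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  labels <- term_labels(graph)
  rep_pattern <- character(0); rep_action <- character(0)
  rep_entity <- character(0)
  for (pid in sort_c(config$auto_patterns)) {
    pat <- patterns[[pid]]
    if (length(pat$vars) != 1L)
      stop("auto pattern '", pid, "' must have exactly one variable",
           call. = FALSE)
    var <- names(pat$vars)
    tab <- tables[[pid]] %||% new_instance_table(pat)
    if (!var %in% names(tab))
      stop("table for '", pid, "' lacks column '", var, "'", call. = FALSE)
    sel <- select_entities(graph, config, pid)
    # flag rows whose entity left the selection (also entities gone from the
    # graph entirely); never delete
    gone <- !(tab[[var]] %in% sel)
    newly <- gone & tab$flag != "obsolete"
    if (any(newly)) {
      tab$flag[newly] <- "obsolete"
      rep_pattern <- c(rep_pattern, rep(pid, sum(newly)))
      rep_action <- c(rep_action, rep("flag", sum(newly)))
      rep_entity <- c(rep_entity, tab[[var]][newly])
    }
    add <- setdiff(sel, tab[[var]])
    if (length(add)) {
      new_rows <- data.frame(defined_class = "",
                             defined_class_label = vapply(add, function(e)
                               fill_template(pat$label_template,
                                             setNames(list(e), var), labels),
                               character(1)),
                             stringsAsFactors = FALSE)
      new_rows[[var]] <- add
      new_rows$flag <- ""
      tab <- rbind(tab[names(new_instance_table(pat))],
                   new_rows[names(new_instance_table(pat))])
      rep_pattern <- c(rep_pattern, rep(pid, length(add)))
      rep_action <- c(rep_action, rep("add", length(add)))
      rep_entity <- c(rep_entity, add)
    }
    tab <- tab[order_c(tab[[var]]), , drop = FALSE]
    rownames(tab) <- NULL
    tables[[pid]] <- tab
  }
  report <- data.frame(pattern = rep_pattern, action = rep_action,
                       entity = rep_entity, stringsAsFactors = FALSE)
  report <- report[order_c(report$pattern, report$action, report$entity), ,
                   drop = FALSE]
  rownames(report) <- NULL
  list(tables = tables, report = report)
}
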