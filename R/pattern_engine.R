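# DOSDP-style design patterns: YAML templates declaring variables, text
# templates for label/definition/synonyms, and an equivalent-class schema.
# Instantiating a pattern against term bindings yields a named, defined,
# logically-defined phenotype class.

count_slots <- function(text) {
  length(gregexpr("%s", text, fixed = TRUE)[[1]][
    gregexpr("%s", text, fixed = TRUE)[[1]] > 0])
}

validate_template <- function(tpl, declared, where) {
  if (is.null(tpl$text)) stop(where, ": template missing 'text'", call. = FALSE)
  vars <- as.character(tpl$vars %||% character(0))
  n <- count_slots(tpl$text)
  if (n != length(vars))
    stop(where, ": template has ", n, " %s slot(s) but ", length(vars),
         " variable reference(s)", call. = FALSE)
  undecl <- setdiff(vars, declared)
  if (length(undecl))
    stop(where, ": undeclared variable(s): ", paste(undecl, collapse = ", "),
         call. = FALSE)
  list(text = tpl$text, vars = vars)
}

#' Parse a design pattern from YAML
#'
#' Supported fields: `pattern_name`, `classes` (name -> CURIE), `relations`
#' (name -> CURIE), `vars` (name -> range CURIE), `name`/`def` templates
#' (`{text, vars}` with `%s` slots), `exact_synonym` (list of templates),
#' `equivalentTo` (`{text, vars}`, a parenthesized expression over declared
#' class/relation names), and `parent_patterns` (list of
#' `{pattern, vars}` entries declaring that every instance of this pattern is
#' subsumed by the mapped instance of the parent pattern).
#'
#' @param yaml_text YAML document as a string, or a path to a `.yaml` file.
#' @return an object of class `design_pattern`.
#' @export
parse_pattern <- function(yaml_text) {
  if (length(yaml_text) == 1 && !grepl("\n", yaml_text) &&
      file.exists(yaml_text))
    doc <- yaml::read_yaml(yaml_text)
  else
    doc <- yaml::yaml.load(yaml_text)
  if (is.null(doc$pattern_name)) stop("pattern missing 'pattern_name'",
                                      call. = FALSE)
  pid <- doc$pattern_name
  vars <- doc$vars %||% list()
  if (!length(vars)) stop("pattern '", pid, "' declares no variables",
                          call. = FALSE)
  declared <- names(vars)
  classes <- doc$classes %||% list()
  relations <- doc$relations %||% list()

  lab <- validate_template(doc$name, declared, paste0(pid, "/name"))
  def <- validate_template(doc$def, declared, paste0(pid, "/def"))
  syns <- lapply(seq_along(doc$exact_synonym %||% list()), function(i)
    validate_template(doc$exact_synonym[[i]], declared,
                      paste0(pid, "/exact_synonym[", i, "]")))

  if (is.null(doc$equivalentTo))
    stop("pattern '", pid, "' missing equivalentTo schema", call. = FALSE)
  eq_tpl <- doc$equivalentTo
  eq_vars <- as.character(eq_tpl$vars %||% character(0))
  undecl <- setdiff(eq_vars, declared)
  if (length(undecl))
    stop(pid, "/equivalentTo: undeclared variable(s): ",
         paste(undecl, collapse = ", "), call. = FALSE)
  schema <- parse_expression(eq_tpl$text, classes, relations, eq_vars)

  parents <- lapply(doc$parent_patterns %||% list(), function(p) {
    map <- lapply(p$vars %||% list(), as.character)
    bad <- setdiff(unlist(map, use.names = FALSE), declared)
    if (length(bad))
      stop(pid, "/parent_patterns: mapping uses undeclared variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    list(pattern = p$pattern, vars = map)
  })

  structure(list(pattern_id = pid,
                 classes = lapply(classes, as.character),
                 relations = lapply(relations, as.character),
                 vars = lapply(vars, as.character),
                 label_template = lab, definition_template = def,
                 synonym_templates = syns,
                 equivalence = schema,
                 parent_patterns = parents),
            class = "design_pattern")
}

#' @export
print.design_pattern <- function(x, ...) {
  cat("<design_pattern> ", x$pattern_id, "\n", sep = "")
  cat("  vars:", paste(sprintf("%s (%s)", names(x$vars),
                               unlist(x$vars)), collapse = ", "), "\n")
  cat("  label: ", x$label_template$text, "\n", sep = "")
  cat("  equivalentTo: ", expression_string(x$equivalence), "\n", sep = "")
  if (length(x$parent_patterns))
    cat("  parents:", paste(vapply(x$parent_patterns, `[[`, character(1),
                                   "pattern"), collapse = ", "), "\n")
  invisible(x)
}

fill_template <- function(tpl, bindings, labels) {
  out <- tpl$text
  for (v in tpl$vars) {
    curie <- bindings[[v]]
    lab <- labels[[curie]]
    out <- sub("%s", lab, out, fixed = TRUE)
  }
  out
}

#' Instantiate a design pattern
#'
#' Substitutes bound-term labels into the text templates and bound CURIEs
#' into the equivalence schema, producing a pre-composed phenotype class.
#' Pure: identical inputs always give an identical class.
#'
#' @param pattern a `design_pattern`.
#' @param bindings named list/character vector, variable name -> CURIE; must
#'   cover every pattern variable.
#' @param labels named list/character vector, CURIE -> label, covering every
#'   bound CURIE.
#' @param id CURIE for the generated class.
#' @return an object of class `phenotype_class` with fields `id`, `label`,
#'   `definition`, `synonyms`, `logical_definition`, `provenance`.
#' @export
instantiate <- function(pattern, bindings, labels, id) {
  stopifnot(inherits(pattern, "design_pattern"))
  bindings <- lapply(as.list(bindings), as.character)
  missing_b <- setdiff(names(pattern$vars), names(bindings))
  if (length(missing_b))
    stop("missing binding(s) for variable(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  labels <- as.list(labels)
  for (v in names(pattern$vars)) {
    curie <- bindings[[v]]
    if (is.null(labels[[curie]]) || is.na(labels[[curie]]))
      stop("no label for bound term ", curie, call. = FALSE)
  }
  lab <- fill_template(pattern$label_template, bindings, labels)
  def <- fill_template(pattern$definition_template, bindings, labels)
  syns <- lapply(pattern$synonym_templates, function(tpl)
    list(text = fill_template(tpl, bindings, labels), scope = "EXACT"))
  logical_def <- ground_expression(pattern$equivalence, bindings)
  structure(list(id = id, label = lab, definition = def, synonyms = syns,
                 logical_definition = logical_def,
                 obsolete = FALSE, replaced_by = NULL,
                 provenance = list(pattern = pattern$pattern_id,
                                   bindings = bindings[names(pattern$vars)])),
            class = "phenotype_class")
}

#' @export
print.phenotype_class <- function(x, ...) {
  cat("<phenotype_class> ", x$id, " \"", x$label, "\"",
      if (x$obsolete) " (obsolete)", "\n", sep = "")
  if (!is.null(x$logical_definition))
    cat("  = ", expression_string(x$logical_definition), "\n", sep = "")
  cat("  from pattern ", x$provenance$pattern, " [",
      paste(sprintf("%s=%s", names(x$provenance$bindings),
                    unlist(x$provenance$bindings)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

binding_key <- function(bindings) {
  v <- sort_c(names(bindings))
  paste(sprintf("%s=%s", v, unlist(bindings[v])), collapse = "|")
}

#' Create an empty instance table for a pattern
#'
#' Instance tables are TSVs with columns `defined_class`,
#' `defined_class_label`, one column per pattern variable (holding CURIEs),
#' and a `flag` bookkeeping column ("" or "obsolete").
#'
#' @param pattern a `design_pattern`.
#' @return a zero-row data frame with the right columns.
#' @export
new_instance_table <- function(pattern) {
  cols <- c("defined_class", "defined_class_label", names(pattern$vars), "flag")
  tab <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  tab
}

#' Read an instance table from TSV
#' @param path TSV file path.
#' @return data frame, all columns character, missing `flag` column added.
#' @export
read_instance_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL,
                           check.names = FALSE)
  if (is.null(tab$flag)) tab$flag <- rep("", nrow(tab))
  tab
}

#' Write an instance table to TSV
#' @param tab data frame.
#' @param path output path.
#' @export
write_instance_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

table_var_columns <- function(tab) {
  setdiff(names(tab), c("defined_class", "defined_class_label", "flag"))
}

#' Compile an instance table into phenotype classes
#'
#' One class per non-obsoleted row, in row order. Every row must already
#' carry a minted id (see [mint_ids()]); duplicate binding tuples and rows
#' referencing undeclared pattern variables are rejected.
#'
#' @param pattern a `design_pattern`.
#' @param table instance table data frame.
#' @param labels named map CURIE -> label for all bound terms.
#' @return list of `phenotype_class` objects.
#' @export
compile_table <- function(pattern, table, labels) {
  var_cols <- table_var_columns(table)
  unknown <- setdiff(var_cols, names(pattern$vars))
  if (length(unknown))
    stop("table for pattern '", pattern$pattern_id,
         "' has column(s) for unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_v <- setdiff(names(pattern$vars), var_cols)
  if (length(missing_v))
    stop("table for pattern '", pattern$pattern_id,
         "' is missing variable column(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  live <- table[table$flag != "obsolete", , drop = FALSE]
  if (!nrow(live)) return(list())
  keys <- vapply(seq_len(nrow(live)), function(i)
    binding_key(as.list(live[i, names(pattern$vars), drop = FALSE])),
    character(1))
  if (anyDuplicated(keys))
    stop("duplicate instance rows in pattern '", pattern$pattern_id, "': ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)
  blank <- !nzchar(live$defined_class)
  if (any(blank))
    stop("unminted row(s) in pattern '", pattern$pattern_id,
         "': run mint_ids() first", call. = FALSE)
  lapply(seq_len(nrow(live)), function(i) {
    bindings <- as.list(unlist(live[i, names(pattern$vars), drop = FALSE]))
    names(bindings) <- names(pattern$vars)
    instantiate(pattern, bindings, labels, live$defined_class[i])
  })
}
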