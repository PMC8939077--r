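# In-memory ontology graph and the OBO 1.4 dialect used for source
# ontologies and release artifacts.
#
# The dialect is deliberately closed: header tags format-version, ontology,
# data-version, and a `property_value: IAO:0000700 <CURIE>` line naming the
# ontology root; [Term] tags id, name, def, synonym, is_a, relationship,
# is_obsolete, replaced_by. Any other tag line is preserved opaquely and
# round-tripped verbatim.

SYNONYM_SCOPES <- c("EXACT", "RELATED", "BROAD", "NARROW")

#' Create an ontology term
#'
#' @param id CURIE of the form `PREFIX:digits`.
#' @param label term name (optional).
#' @param definition free-text definition (optional).
#' @param def_xrefs character vector of definition provenance cross-references.
#' @param synonyms list of `list(text =, scope =)` entries; scope is one of
#'   EXACT, RELATED, BROAD, NARROW.
#' @param obsolete logical; obsolete terms may carry `replaced_by`.
#' @param replaced_by CURIE of the replacement term (obsolete terms only).
#' @param extra character vector of raw OBO tag lines outside the supported
#'   dialect, carried through serialization unchanged.
#' @return an object of class `obo_term`.
#' @export
obo_term <- function(id, label = NULL, definition = NULL,
                     def_xrefs = character(0), synonyms = list(),
                     obsolete = FALSE, replaced_by = NULL,
                     extra = character(0)) {
  if (!is_curie(id)) stop("term id is not a CURIE: ", id, call. = FALSE)
  if (!is.null(replaced_by) && !isTRUE(obsolete))
    stop("replaced_by set on non-obsolete term ", id, call. = FALSE)
  for (s in synonyms) {
    if (!s$scope %in% SYNONYM_SCOPES)
      stop("bad synonym scope '", s$scope, "' on ", id, call. = FALSE)
  }
  structure(list(id = id, label = label, definition = definition,
                 def_xrefs = def_xrefs, synonyms = synonyms,
                 obsolete = isTRUE(obsolete), replaced_by = replaced_by,
                 extra = extra),
            class = "obo_term")
}

empty_relationships <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), stringsAsFactors = FALSE)
}

#' Create an ontology graph
#'
#' Holds terms plus typed directed relationships. Relationship subjects point
#' at objects child-to-parent: `eye part_of visual system` is the row
#' `(eye, part_of, visual system)`.
#'
#' @param terms list of [obo_term()] objects.
#' @param relationships data frame with columns `subject`, `predicate`,
#'   `object`; predicates are relation names (`is_a`, `part_of`,
#'   `develops_from`, ...).
#' @param header list with optional fields `format_version`, `ontology`,
#'   `data_version`, `root` (CURIE of the root term), `extra` (raw header
#'   lines).
#' @param validate run [validate_ontology_graph()] on the result.
#' @return an object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms = list(), relationships = empty_relationships(),
                           header = list(), validate = TRUE) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(terms) <- ids
  header$format_version <- header$format_version %||% "1.2"
  relationships <- as.data.frame(relationships, stringsAsFactors = FALSE)
  rownames(relationships) <- NULL
  g <- structure(list(header = header, terms = terms,
                      relationships = relationships,
                      extra_stanzas = header$extra_stanzas %||% character(0)),
                 class = "ontology_graph")
  g$header$extra_stanzas <- NULL
  if (validate) validate_ontology_graph(g)
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", x$header$ontology %||% "(unnamed)", "\n", sep = "")
  cat("  terms:", length(x$terms),
      " relationships:", nrow(x$relationships), "\n")
  preds <- table(x$relationships$predicate)
  if (length(preds))
    cat("  predicates:",
        paste(sprintf("%s=%d", names(preds), as.integer(preds)), collapse = " "),
        "\n")
  invisible(x)
}

term_ids <- function(graph) names(graph$terms)

term_labels <- function(graph) {
  vapply(graph$terms, function(t) t$label %||% NA_character_, character(1))
}

#' Validate ontology graph invariants
#'
#' Checks that every term id is a CURIE, relationship endpoints resolve,
#' no relationship is reflexive, the `is_a` sub-graph is acyclic, and
#' `replaced_by` only occurs on obsolete terms.
#'
#' @param graph an `ontology_graph`.
#' @return the graph, invisibly; errors on violation.
#' @export
validate_ontology_graph <- function(graph) {
  ids <- term_ids(graph)
  bad <- ids[!is_curie(ids)]
  if (length(bad)) stop("non-CURIE term ids: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rel <- graph$relationships
  if (nrow(rel)) {
    dangling <- setdiff(unique(c(rel$subject, rel$object)), ids)
    if (length(dangling))
      stop("dangling reference: relationship endpoint(s) not declared as terms: ",
           paste(sort_c(dangling), collapse = ", "), call. = FALSE)
    refl <- rel$subject == rel$object
    if (any(refl))
      stop("reflexive relationship on ", paste(unique(rel$subject[refl]),
                                               collapse = ", "), call. = FALSE)
  }
  for (t in graph$terms) {
    if (!is.null(t$replaced_by) && !t$obsolete)
      stop("replaced_by on non-obsolete term ", t$id, call. = FALSE)
  }
  cyc <- find_cycle(graph, "is_a")
  if (!is.null(cyc))
    stop("is_a cycle: ", paste(cyc, collapse = " -> "), call. = FALSE)
  invisible(graph)
}

# Return one cycle (vector of CURIEs, first == last) over the given
# predicates, or NULL if the restricted graph is acyclic.
find_cycle <- function(graph, relations) {
  rel <- graph$relationships
  rel <- rel[rel$predicate %in% relations, , drop = FALSE]
  adj <- split(rel$object, rel$subject)
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  found <- NULL
  visit <- function(v, path) {
    st <- get0(v, envir = state)
    if (identical(st, 2L)) return(NULL)
    if (identical(st, 1L)) {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    assign(v, 1L, envir = state)
    for (w in adj[[v]] %||% character(0)) {
      res <- visit(w, c(path, v))
      if (!is.null(res)) return(res)
    }
    assign(v, 2L, envir = state)
    NULL
  }
  for (v in unique(rel$subject)) {
    found <- visit(v, character(0))
    if (!is.null(found)) return(found)
  }
  NULL
}

# ---- OBO parsing ------------------------------------------------------------

obo_parse_error <- function(lineno, msg) {
  stop(sprintf("OBO parse error at line %d: %s", lineno, msg), call. = FALSE)
}

#' Parse an OBO document
#'
#' Parses the supported OBO 1.4 dialect into an [ontology_graph()]. `is_a:`
#' and `relationship:` lines become typed relationships; tags outside the
#' dialect are kept as opaque lines on the term and round-tripped. Trailing
#' `! comment` text on is_a/relationship lines is discarded.
#'
#' @param text a single string, or a character vector of lines, or a file
#'   path to an `.obo` file.
#' @return an `ontology_graph`.
#' @export
parse_obo <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readChar(text, file.info(text)$size, useBytes = TRUE)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)

  header <- list(extra = character(0))
  terms <- list()
  rel_s <- character(0); rel_p <- character(0); rel_o <- character(0)
  extra_stanzas <- character(0)

  i <- 1L; n <- length(lines)
  # header
  while (i <= n && !grepl("^\\[", lines[i])) {
    line <- lines[i]
    if (nzchar(trimws(line))) {
      m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
      if (length(m) == 0) obo_parse_error(i, paste0("malformed header line: ", line))
      tag <- m[2]; val <- trimws(m[3])
      if (tag == "format-version") header$format_version <- val
      else if (tag == "ontology") header$ontology <- val
      else if (tag == "data-version") header$data_version <- val
      else if (tag == "property_value" && grepl("^IAO:0000700\\s+", val))
        header$root <- trimws(sub("^IAO:0000700\\s+", "", val))
      else header$extra <- c(header$extra, line)
    }
    i <- i + 1L
  }

  strip_comment <- function(v) trimws(sub("\\s+!.*$", "", v))

  while (i <= n) {
    stanza_type <- lines[i]
    start <- i
    i <- i + 1L
    body_idx <- integer(0)
    while (i <= n && !grepl("^\\[", lines[i])) {
      if (nzchar(trimws(lines[i]))) body_idx <- c(body_idx, i)
      i <- i + 1L
    }
    if (stanza_type != "[Term]") {
      extra_stanzas <- c(extra_stanzas,
                         paste(lines[c(start, body_idx)], collapse = "\n"))
      next
    }
    id <- NULL; label <- NULL; definition <- NULL; def_xrefs <- character(0)
    synonyms <- list(); obsolete <- FALSE; replaced_by <- NULL
    extra <- character(0)
    st_p <- character(0); st_o <- character(0)
    for (j in body_idx) {
      line <- lines[j]
      m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
      if (length(m) == 0) obo_parse_error(j, paste0("malformed tag line: ", line))
      tag <- m[2]; val <- m[3]
      if (tag == "id") {
        id <- trimws(val)
        if (!is_curie(id)) obo_parse_error(j, paste0("id is not a CURIE: ", id))
      } else if (tag == "name") {
        label <- trimws(val)
      } else if (tag == "def") {
        dm <- regmatches(val, regexec('^"(.*)"\\s*(?:\\[([^]]*)\\])?\\s*$', val))[[1]]
        if (length(dm) == 0) obo_parse_error(j, "malformed def line")
        definition <- dm[2]
        if (nzchar(dm[3]))
          def_xrefs <- trimws(strsplit(dm[3], ",", fixed = TRUE)[[1]])
      } else if (tag == "synonym") {
        sm <- regmatches(val, regexec(
          '^"(.*)"\\s+(EXACT|RELATED|BROAD|NARROW)\\s*(?:\\[[^]]*\\])?\\s*$',
          val))[[1]]
        if (length(sm) == 0) obo_parse_error(j, "malformed synonym line")
        synonyms[[length(synonyms) + 1L]] <- list(text = sm[2], scope = sm[3])
      } else if (tag == "is_a") {
        obj <- strip_comment(val)
        if (!is_curie(obj)) obo_parse_error(j, paste0("is_a target is not a CURIE: ", obj))
        st_p <- c(st_p, "is_a"); st_o <- c(st_o, obj)
      } else if (tag == "relationship") {
        v <- strip_comment(val)
        rm_ <- regmatches(v, regexec("^([A-Za-z_]+)\\s+(\\S+)$", v))[[1]]
        if (length(rm_) == 0) obo_parse_error(j, "malformed relationship line")
        if (!is_curie(rm_[3]))
          obo_parse_error(j, paste0("relationship target is not a CURIE: ", rm_[3]))
        st_p <- c(st_p, rm_[2]); st_o <- c(st_o, rm_[3])
      } else if (tag == "is_obsolete") {
        obsolete <- identical(trimws(val), "true")
      } else if (tag == "replaced_by") {
        replaced_by <- strip_comment(val)
      } else {
        extra <- c(extra, line)
      }
    }
    if (is.null(id)) obo_parse_error(start, "[Term] stanza without id")
    rel_s <- c(rel_s, rep(id, length(st_p)))
    rel_p <- c(rel_p, st_p); rel_o <- c(rel_o, st_o)
    terms[[length(terms) + 1L]] <-
      obo_term(id, label = label, definition = definition,
               def_xrefs = def_xrefs, synonyms = synonyms,
               obsolete = obsolete, replaced_by = replaced_by, extra = extra)
  }

  rels <- data.frame(subject = as.character(rel_s), predicate = rel_p,
                     object = rel_o, stringsAsFactors = FALSE)
  header$extra_stanzas <- extra_stanzas
  ontology_graph(terms, rels, header)
}

# ---- OBO serialization ------------------------------------------------------

#' Serialize an ontology graph to OBO
#'
#' Deterministic: terms are emitted sorted by CURIE (C locale), tags in a
#' fixed order, is_a and relationship lines sorted by predicate then target.
#' `parse_obo(write_obo(g))` reproduces `g` up to this canonical ordering.
#' Refuses to serialize a graph violating its invariants.
#'
#' @param graph an `ontology_graph`.
#' @param path optional file path; when given the text is also written there
#'   (UTF-8, LF line endings).
#' @return the OBO document as a single string, invisibly when `path` given.
#' @export
write_obo <- function(graph, path = NULL) {
  validate_ontology_graph(graph)
  h <- graph$header
  out <- c(paste0("format-version: ", h$format_version %||% "1.2"))
  if (!is.null(h$ontology)) out <- c(out, paste0("ontology: ", h$ontology))
  if (!is.null(h$data_version)) out <- c(out, paste0("data-version: ", h$data_version))
  if (!is.null(h$root)) out <- c(out, paste0("property_value: IAO:0000700 ", h$root))
  out <- c(out, h$extra %||% character(0))

  rel <- graph$relationships
  for (id in sort_c(term_ids(graph))) {
    t <- graph$terms[[id]]
    out <- c(out, "", "[Term]", paste0("id: ", id))
    if (!is.null(t$label)) out <- c(out, paste0("name: ", t$label))
    if (!is.null(t$definition)) {
      xr <- paste(t$def_xrefs, collapse = ", ")
      out <- c(out, sprintf('def: "%s" [%s]', t$definition, xr))
    }
    for (s in t$synonyms)
      out <- c(out, sprintf('synonym: "%s" %s []', s$text, s$scope))
    mine <- rel[rel$subject == id, , drop = FALSE]
    if (nrow(mine)) {
      mine <- mine[order_c(mine$predicate != "is_a", mine$predicate, mine$object), ,
                   drop = FALSE]
      for (k in seq_len(nrow(mine))) {
        if (mine$predicate[k] == "is_a")
          out <- c(out, paste0("is_a: ", mine$object[k]))
        else
          out <- c(out, paste0("relationship: ", mine$predicate[k], " ",
                               mine$object[k]))
      }
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    if (!is.null(t$replaced_by)) out <- c(out, paste0("replaced_by: ", t$replaced_by))
    out <- c(out, t$extra)
  }
  for (st in graph$extra_stanzas) out <- c(out, "", st)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(txt)), con)
    return(invisible(txt))
  }
  txt
}

#' Serialize an ontology graph to graph JSON
#'
#' Emits the release JSON shape
#' `{"graphs":[{"nodes":[...],"edges":[...]}]}` with nodes carrying id (as an
#' OBO PURL IRI), label, definition, synonyms and obsolete flag, and edges
#' carrying subject/predicate/object. Ordering is deterministic (nodes by
#' CURIE, edges by subject, predicate, object). Node `meta` carries the
#' logical definition and pattern provenance when supplied.
#'
#' @param graph an `ontology_graph`.
#' @param meta optional named list (by CURIE) of extra per-node metadata,
#'   e.g. `list(logical_definition =, pattern =, bindings =)`.
#' @param path optional output file path.
#' @return JSON text (single string).
#' @export
write_json_graph <- function(graph, meta = NULL, path = NULL) {
  validate_ontology_graph(graph)
  ids <- sort_c(term_ids(graph))
  nodes <- lapply(ids, function(id) {
    t <- graph$terms[[id]]
    node <- list(id = curie_to_iri(id), curie = id)
    node$label <- t$label
    node$definition <- t$definition
    if (length(t$synonyms))
      node$synonyms <- lapply(t$synonyms, function(s)
        list(val = s$text, scope = s$scope))
    node$obsolete <- t$obsolete
    if (!is.null(t$replaced_by)) node$replaced_by <- curie_to_iri(t$replaced_by)
    if (!is.null(meta[[id]])) node$meta <- meta[[id]]
    node
  })
  rel <- graph$relationships
  if (nrow(rel)) {
    rel <- rel[order_c(rel$subject, rel$predicate, rel$object), , drop = FALSE]
    edges <- lapply(seq_len(nrow(rel)), function(k)
      list(subject = curie_to_iri(rel$subject[k]), predicate = rel$predicate[k],
           object = curie_to_iri(rel$object[k])))
  } else edges <- list()
  doc <- list(graphs = list(list(
    id = graph$header$ontology %||% "ontology",
    nodes = nodes, edges = edges)))
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                       null = "null", digits = NA))
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(txt)), con)
    return(invisible(txt))
  }
  txt
}

# canonical form used by tests and diffing: sorted terms and relationship rows
normalize_graph <- function(graph) {
  ids <- sort_c(term_ids(graph))
  rel <- graph$relationships
  rel <- rel[order_c(rel$subject, rel$predicate != "is_a", rel$predicate,
                     rel$object), , drop = FALSE]
  rownames(rel) <- NULL
  h <- graph$header
  h2 <- c(list(format_version = h$format_version %||% "1.2"),
          if (!is.null(h$ontology)) list(ontology = h$ontology),
          if (!is.null(h$data_version)) list(data_version = h$data_version),
          if (!is.null(h$root)) list(root = h$root),
          list(extra = h$extra %||% character(0),
               extra_stanzas = graph$extra_stanzas %||% character(0)))
  ontology_graph(graph$terms[ids], rel, h2, validate = FALSE)
}

#' Compare two ontology graphs for semantic equality
#'
#' Term-by-term and relationship-by-relationship comparison, ignoring
#' ordering.
#'
#' @param a,b `ontology_graph` objects.
#' @return TRUE or FALSE.
#' @export
graphs_equal <- function(a, b) {
  a <- normalize_graph(a); b <- normalize_graph(b)
  isTRUE(all.equal(a$terms, b$terms)) &&
    identical(a$relationships, b$relationships) &&
    isTRUE(all.equal(a$header, b$header))
}
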