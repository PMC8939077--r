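# Derives the complete is_a hierarchy of generated phenotype classes purely
# from their logical definitions, by structural subsumption over the EL-style
# fragment (class atoms, existential restrictions, intersections). Entity
# atoms are compared over the is_a + part_of closure of the anatomy ontology,
# quality atoms over the is_a closure of the quality ontology; develops_from
# never participates. Declared parent_patterns edges add subsumptions at the
# pattern level. This replaces a general EL reasoner for exactly this
# fragment; completeness relative to full EL is a documented limitation.

# reflexive-transitive ancestor sets per term, over the given relations
ancestor_closure <- function(graph, relations) {
  rel <- graph$relationships
  rel <- rel[rel$predicate %in% relations, , drop = FALSE]
  parents <- split(rel$object, rel$subject)
  memo <- new.env(parent = emptyenv())
  anc <- function(v) {
    got <- get0(v, envir = memo)
    if (!is.null(got)) return(got)
    assign(v, v, envir = memo)  # break cycles defensively
    out <- v
    for (p in parents[[v]] %||% character(0)) out <- c(out, anc(p))
    out <- unique(out)
    assign(v, out, envir = memo)
    out
  }
  setNames(lapply(term_ids(graph), anc), term_ids(graph))
}

# closure environment shared by entails() calls within one classification
make_entailment_context <- function(entity_graph, quality_graph, patterns = NULL) {
  ctx <- list(
    entity_anc = ancestor_closure(entity_graph, c("is_a", "part_of")),
    quality_anc = ancestor_closure(quality_graph, "is_a"),
    pattern_anc = if (!is.null(patterns)) pattern_ancestors(patterns))
  ctx
}

atom_ancestors <- function(ctx, x) {
  a <- ctx$entity_anc[[x]]
  if (!is.null(a)) return(a)
  a <- ctx$quality_anc[[x]]
  if (!is.null(a)) return(a)
  stop("unknown CURIE in expression: ", x, call. = FALSE)
}

atom_subsumed <- function(ctx, x, y) y %in% atom_ancestors(ctx, x)

entails_impl <- function(ctx, a, b) {
  if (b$kind == "and")
    return(all(vapply(b$args, function(bi) entails_impl(ctx, a, bi),
                      logical(1))))
  if (a$kind == "and")
    return(any(vapply(a$args, function(ai) entails_impl(ctx, ai, b),
                      logical(1))))
  if (a$kind == "atom" && b$kind == "atom")
    return(atom_subsumed(ctx, a$curie, b$curie))
  if (a$kind == "some" && b$kind == "some")
    return(identical(a$relation, b$relation) &&
             entails_impl(ctx, a$filler, b$filler))
  FALSE
}

# transitive closure of the declared parent_patterns lattice, with composed
# variable mappings (ancestor var -> descendant var)
pattern_ancestors <- function(patterns) {
  names(patterns) <- vapply(patterns, `[[`, character(1), "pattern_id")
  direct <- lapply(patterns, function(p) p$parent_patterns)
  out <- list()
  for (pid in names(direct)) {
    acc <- list()
    walk <- function(q, map, depth) {
      if (depth > length(direct) + 1L)
        stop("cycle in parent_patterns lattice at '", q, "'", call. = FALSE)
      for (pp in direct[[q]] %||% list()) {
        anc <- pp$pattern
        # pp$vars maps ancestor var -> q var; compose with map (q var -> pid var)
        comp <- lapply(pp$vars, function(qv) map[[qv]] %||% qv)
        acc[[length(acc) + 1L]] <<- list(pattern = anc, vars = comp)
        walk(anc, comp, depth + 1L)
      }
    }
    walk(pid, setNames(as.list(names(patterns[[pid]]$vars) %||% character(0)),
                       names(patterns[[pid]]$vars)), 1L)
    out[[pid]] <- acc
  }
  out
}

# pattern-level route: does (pattern_a, bindings_a) sit under
# (pattern_b, bindings_b) via a declared parent_patterns chain?
pattern_route_subsumed <- function(ctx, prov_a, prov_b) {
  if (is.null(ctx$pattern_anc) || is.null(prov_a) || is.null(prov_b))
    return(FALSE)
  for (anc in ctx$pattern_anc[[prov_a$pattern]] %||% list()) {
    if (!identical(anc$pattern, prov_b$pattern)) next
    vars_b <- names(prov_b$bindings)
    ok <- all(vapply(vars_b, function(v) {
      av <- anc$vars[[v]] %||% v
      ba <- prov_a$bindings[[av]]
      bb <- prov_b$bindings[[v]]
      !is.null(ba) && !is.null(bb) && atom_subsumed(ctx, ba, bb)
    }, logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

#' Structural entailment between ground class expressions
#'
#' Decides whether expression `a` is subsumed by expression `b` under the
#' structural rules of the supported fragment: class atoms compare through
#' the is_a closure (qualities) or the is_a + part_of closure (entities);
#' existential restrictions require the same relation and an entailed
#' filler; an intersection on the right requires every conjunct to be
#' entailed, on the left any conjunct may witness. When both expressions
#' come from pattern instances, declared `parent_patterns` edges provide an
#' additional route under their variable mapping.
#'
#' @param a,b ground expression trees (no unbound slots).
#' @param entity_graph anatomy `ontology_graph` (atoms close over is_a +
#'   part_of).
#' @param quality_graph quality `ontology_graph` (atoms close over is_a).
#' @param patterns optional named list of `design_pattern` objects supplying
#'   the parent_patterns lattice.
#' @param prov_a,prov_b optional provenance (`list(pattern =, bindings =)`)
#'   of the two expressions, enabling the pattern-level route.
#' @return TRUE or FALSE.
#' @export
entails <- function(a, b, entity_graph, quality_graph, patterns = NULL,
                    prov_a = NULL, prov_b = NULL) {
  if (!expression_is_ground(a) || !expression_is_ground(b))
    stop("entails() requires ground expressions", call. = FALSE)
  ctx <- make_entailment_context(entity_graph, quality_graph, patterns)
  entails_impl(ctx, a, b) || pattern_route_subsumed(ctx, prov_a, prov_b)
}

#' Classify phenotype classes into an is_a hierarchy
#'
#' Computes all pairwise entailments between the logical definitions of the
#' non-obsolete classes (structural rules plus the pattern lattice), takes
#' the transitive reduction of the induced strict partial order, and
#' attaches classes with no derived parent directly to the root phenotype
#' class. Mutually entailing distinct classes (logical equivalents) are both
#' kept, reported for QC, and tie-broken to no is_a edge between them.
#' The output contains only is_a edges, is acyclic, and every non-obsolete
#' class reaches the root.
#'
#' @param classes list of `phenotype_class` objects.
#' @param entity_graph,quality_graph source `ontology_graph`s.
#' @param patterns named list of `design_pattern` objects.
#' @param root CURIE of the root phenotype class (supplied by the editors'
#'   configuration, not generated).
#' @return an object of class `subsumption_result`: `edges` (data frame
#'   `child`, `parent` of direct is_a assertions), `root`, and
#'   `equivalences` (data frame `a`, `b` of mutually entailing pairs).
#' @export
classify <- function(classes, entity_graph, quality_graph, patterns, root) {
  if (is.null(names(classes)) && length(classes))
    names(classes) <- vapply(classes, `[[`, character(1), "id")
  if (anyDuplicated(names(classes)))
    stop("duplicate class ids", call. = FALSE)
  ctx <- make_entailment_context(entity_graph, quality_graph, patterns)
  live <- classes[vapply(classes, function(cl)
    !isTRUE(cl$obsolete) && !is.null(cl$logical_definition), logical(1))]
  ids <- sort_c(names(live))
  n <- length(ids)
  sub <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ci <- live[[ids[i]]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- live[[ids[j]]]
      sub[i, j] <- entails_impl(ctx, ci$logical_definition,
                                cj$logical_definition) ||
        pattern_route_subsumed(ctx, ci$provenance, cj$provenance)
    }
  }
  mutual <- sub & t(sub)
  eq_idx <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  equivalences <- data.frame(a = ids[eq_idx[, 1L]], b = ids[eq_idx[, 2L]],
                             stringsAsFactors = FALSE)
  strict <- sub & !t(sub)
  # transitive reduction: drop edges implied by a 2-chain
  implied <- (strict %*% strict) > 0
  direct <- strict & !implied
  edge_idx <- which(direct, arr.ind = TRUE)
  edges <- data.frame(child = ids[edge_idx[, 1L]],
                      parent = ids[edge_idx[, 2L]], stringsAsFactors = FALSE)
  # root attachment for classes with no derived parent
  no_parent <- ids[!(ids %in% edges$child)]
  if (length(no_parent))
    edges <- rbind(edges, data.frame(child = no_parent, parent = root,
                                     stringsAsFactors = FALSE))
  edges <- edges[order_c(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, root = root, equivalences = equivalences),
            class = "subsumption_result")
}

#' @export
print.subsumption_result <- function(x, ...) {
  cat("<subsumption_result> root ", x$root, ", ", nrow(x$edges),
      " is_a edges", sep = "")
  if (nrow(x$equivalences))
    cat(", ", nrow(x$equivalences), " equivalent pair(s) flagged", sep = "")
  cat("\n")
  invisible(x)
}
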