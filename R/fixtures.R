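# Deterministic synthetic source ontologies and a shipped 14-pattern suite,
# so the whole pipeline runs and is testable without downloading any real
# ontology. Fixture CURIE prefixes are TOYA (anatomy), TOYQ (quality),
# TOYR (relations), TOYP (generated phenotype classes) so tests can never
# collide with real XAO/PATO/XPO ids.

toy_curie <- function(prefix, n) sprintf("%s:%07d", prefix, n)

#' Generate a toy anatomy ontology
#'
#' A rooted DAG shaped like a miniature anatomy ontology: a fixed core
#' (anatomical entity root; anatomical structure and, optionally, anatomical
#' space branches; a visual system with an eye that is part_of it; an optic
#' vesicle linked to the eye only by develops_from; a heart inside a
#' cardiovascular system; a brain with a brain ventricle that is both an
#' anatomical space and part_of the brain) plus randomly attached generic
#' structures. Every term reaches the root through is_a/part_of; at least
#' one develops_from edge is always present. Deterministic for a fixed seed.
#'
#' @param n_entities total number of terms (>= 10 to hold the core).
#' @param seed integer seed for the generator.
#' @param prop named proportions for `is_a`, `part_of`, `develops_from`
#'   edges; must sum to 1 and leave is_a + part_of positive.
#' @param include_space include the anatomical-space branch.
#' @param n_extra_edges additional random part_of cross-edges (DAG
#'   thickening) beyond the spanning structure.
#' @return an `ontology_graph` with header root set.
#' @export
make_toy_anatomy <- function(n_entities = 30, seed = 1,
                             prop = c(is_a = 0.6, part_of = 0.3,
                                      develops_from = 0.1),
                             include_space = TRUE, n_extra_edges = 2) {
  if (n_entities < 10) stop("n_entities must be >= 10", call. = FALSE)
  if (abs(sum(prop) - 1) > 1e-8)
    stop("relation proportions must sum to 1", call. = FALSE)
  if (prop[["is_a"]] + prop[["part_of"]] <= 0)
    stop("infeasible relation mix: a rooted DAG needs is_a/part_of edges",
         call. = FALSE)
  with_seed(seed, {
    labels <- c("anatomical entity", "anatomical structure",
                if (include_space) "anatomical space",
                "visual system", "eye", "optic vesicle",
                "cardiovascular system", "heart", "brain",
                if (include_space) "brain ventricle")
    id_of <- function(lab) toy_curie("TOYA", match(lab, labels))
    edge <- function(s, p, o) data.frame(subject = id_of(s), predicate = p,
                                         object = id_of(o),
                                         stringsAsFactors = FALSE)
    rels <- rbind(
      edge("anatomical structure", "is_a", "anatomical entity"),
      if (include_space) edge("anatomical space", "is_a", "anatomical entity"),
      edge("visual system", "is_a", "anatomical structure"),
      edge("eye", "part_of", "visual system"),
      edge("optic vesicle", "is_a", "anatomical structure"),
      edge("cardiovascular system", "is_a", "anatomical structure"),
      edge("heart", "part_of", "cardiovascular system"),
      edge("brain", "is_a", "anatomical structure"),
      if (include_space) edge("brain ventricle", "is_a", "anatomical space"),
      if (include_space) edge("brain ventricle", "part_of", "brain"),
      # the developmental precursor link: the eye develops from the optic
      # vesicle, and nothing else connects the two
      edge("eye", "develops_from", "optic vesicle"))

    n_core <- length(labels)
    p_isa <- prop[["is_a"]] / (prop[["is_a"]] + prop[["part_of"]])
    structure_ids <- setdiff(id_of(labels), c(
      id_of("anatomical entity"),
      if (include_space) id_of(c("anatomical space", "brain ventricle"))))
    if (n_entities > n_core) {
      for (i in seq(n_core + 1L, n_entities)) {
        lab <- sprintf("structure %03d", i - n_core)
        labels <- c(labels, lab)
        parent <- sample(structure_ids, 1L)
        pred <- if (stats::runif(1) < p_isa) "is_a" else "part_of"
        rels <- rbind(rels, data.frame(subject = toy_curie("TOYA", i),
                                       predicate = pred, object = parent,
                                       stringsAsFactors = FALSE))
        structure_ids <- c(structure_ids, toy_curie("TOYA", i))
      }
    }
    # extra develops_from edges per the relation mix (the core already has 1)
    n_df <- max(0L, round(prop[["develops_from"]] * n_entities) - 1L)
    all_ids <- toy_curie("TOYA", seq_len(n_entities))
    k <- 0L; attempts <- 0L
    while (k < n_df + n_extra_edges && attempts < 1000L) {
      attempts <- attempts + 1L
      pair <- sample(all_ids, 2L)
      pred <- if (k < n_df) "develops_from" else "part_of"
      dup <- any(rels$subject == pair[1] & rels$object == pair[2])
      rev_isa <- any(rels$subject == pair[2] & rels$object == pair[1])
      if (dup || rev_isa) next
      cand <- rbind(rels, data.frame(subject = pair[1], predicate = pred,
                                     object = pair[2],
                                     stringsAsFactors = FALSE))
      g_try <- ontology_graph(
        lapply(seq_len(n_entities), function(j)
          obo_term(all_ids[j], label = labels[j])),
        cand, header = list(), validate = FALSE)
      if (!is.null(find_cycle(g_try, c("is_a", "part_of")))) next
      rels <- cand
      k <- k + 1L
    }
    terms <- lapply(seq_len(n_entities), function(j)
      obo_term(toy_curie("TOYA", j), label = labels[j],
               definition = paste0("Toy anatomy term: ", labels[j], ".")))
    ontology_graph(terms, rels,
                   header = list(ontology = "toy-anatomy",
                                 root = id_of("anatomical entity")))
  })
}

#' Generate the toy quality ontology
#'
#' A fixed is_a tree (every node has exactly one parent) holding the
#' qualities the shipped pattern suite needs: a size branch with the
#' increased/decreased pair, an amount branch with absent, position with
#' mislocalised, viability with necrotic, a process-quality branch with the
#' apoptosis/proliferation rates and development, and an `abnormal` modifier
#' under qualifier.
#'
#' @param n_extra additional generic quality leaves under morphology.
#' @param seed seed (only the generic leaves' labels depend on it; the core
#'   tree is fixed).
#' @return an `ontology_graph`.
#' @export
make_quality_ontology <- function(n_extra = 0, seed = 1) {
  core <- list(
    c("quality", NA),
    c("morphology", "quality"),
    c("size", "morphology"),
    c("increased size", "size"),
    c("decreased size", "size"),
    c("amount", "quality"),
    c("increased amount", "amount"),
    c("decreased amount", "amount"),
    c("absent", "amount"),
    c("position", "quality"),
    c("mislocalised", "position"),
    c("viability", "quality"),
    c("necrotic", "viability"),
    c("qualifier", "quality"),
    c("abnormal", "qualifier"),
    c("process quality", "quality"),
    c("increased apoptosis", "process quality"),
    c("decreased apoptosis", "process quality"),
    c("increased cell population proliferation", "process quality"),
    c("decreased cell population proliferation", "process quality"),
    c("development", "process quality"))
  labels <- vapply(core, `[[`, character(1), 1L)
  parents <- vapply(core, `[[`, character(1), 2L)
  if (n_extra > 0) {
    labels <- c(labels, sprintf("quality %03d", seq_len(n_extra)))
    parents <- c(parents, rep("morphology", n_extra))
  }
  ids <- toy_curie("TOYQ", seq_along(labels))
  terms <- lapply(seq_along(labels), function(j)
    obo_term(ids[j], label = labels[j],
             definition = paste0("Toy quality term: ", labels[j], ".")))
  has_parent <- !is.na(parents)
  rels <- data.frame(subject = ids[has_parent], predicate = "is_a",
                     object = ids[match(parents[has_parent], labels)],
                     stringsAsFactors = FALSE)
  ontology_graph(terms, rels,
                 header = list(ontology = "toy-quality", root = ids[1]))
}

toy_quality_id <- function(label) {
  g <- make_quality_ontology()
  ids <- term_ids(g)
  ids[match(label, term_labels(g))]
}

suite_spec <- function() {
  list(
    list(id = "abnormal_anatomical_entity",
         label = "abnormal %s", quality = "quality", parents = character(0)),
    list(id = "absent_anatomical_entity",
         label = "absent %s", quality = "absent",
         parents = "abnormal_anatomical_entity", synonyms = "missing %s"),
    list(id = "abnormal_morphology_of_anatomical_entity",
         label = "abnormal morphology of the %s", quality = "morphology",
         parents = "abnormal_anatomical_entity"),
    list(id = "abnormal_development_of_anatomical_entity",
         label = "abnormal development of the %s", quality = "development",
         parents = "abnormal_anatomical_entity"),
    list(id = "mislocalized_anatomical_entity",
         label = "mislocalized %s", quality = "mislocalised",
         parents = "abnormal_anatomical_entity"),
    list(id = "necrotic_anatomical_entity",
         label = "necrotic %s", quality = "necrotic",
         parents = "abnormal_anatomical_entity"),
    list(id = "abnormally_increased_size_of_anatomical_entity",
         label = "increased size of the %s", quality = "increased size",
         parents = c("abnormal_anatomical_entity",
                     "abnormal_morphology_of_anatomical_entity"),
         synonyms = "enlarged %s"),
    list(id = "abnormally_decreased_size_of_anatomical_entity",
         label = "decreased size of the %s", quality = "decreased size",
         parents = c("abnormal_anatomical_entity",
                     "abnormal_morphology_of_anatomical_entity"),
         synonyms = "hypoplastic %s"),
    list(id = "abnormally_increased_number_of_anatomical_entity",
         label = "increased number of the %s", quality = "increased amount",
         parents = "abnormal_anatomical_entity"),
    list(id = "abnormally_decreased_number_of_anatomical_entity",
         label = "decreased number of the %s", quality = "decreased amount",
         parents = "abnormal_anatomical_entity"),
    list(id = "increased_apoptosis_in_anatomical_entity",
         label = "increased apoptosis in the %s",
         quality = "increased apoptosis",
         parents = "abnormal_anatomical_entity"),
    list(id = "decreased_apoptosis_in_anatomical_entity",
         label = "decreased apoptosis in the %s",
         quality = "decreased apoptosis",
         parents = "abnormal_anatomical_entity"),
    list(id = "increased_cell_population_proliferation_in_anatomical_entity",
         label = "increased cell population proliferation in the %s",
         quality = "increased cell population proliferation",
         parents = "abnormal_anatomical_entity"),
    list(id = "decreased_cell_population_proliferation_in_anatomical_entity",
         label = "decreased cell population proliferation in the %s",
         quality = "decreased cell population proliferation",
         parents = "abnormal_anatomical_entity"))
}

pattern_yaml <- function(sp, quality_ids, entity_range = "TOYA:0000001") {
  capfirst <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))
  classes <- setNames(list(quality_ids[["quality"]], quality_ids[["abnormal"]]),
                      c("quality", "abnormal"))
  if (!sp$quality %in% names(classes))
    classes[[sp$quality]] <- quality_ids[[sp$quality]]
  doc <- list(
    pattern_name = sp$id,
    classes = classes,
    relations = list(`has part` = "TOYR:0000001",
                     `inheres in` = "TOYR:0000002",
                     `has modifier` = "TOYR:0000003"),
    vars = list(anatomical_entity = entity_range),
    name = list(text = sp$label, vars = list("anatomical_entity")),
    def = list(text = paste0(capfirst(sp$label), "."),
               vars = list("anatomical_entity")),
    equivalentTo = list(
      text = sprintf(paste0("'has part' some ('%s' and ('inheres in' some ",
                            "%%s) and ('has modifier' some abnormal))"),
                     sp$quality),
      vars = list("anatomical_entity")))
  if (!is.null(sp$synonyms))
    doc$exact_synonym <- lapply(sp$synonyms, function(s)
      list(text = s, vars = list("anatomical_entity")))
  if (length(sp$parents))
    doc$parent_patterns <- lapply(sp$parents, function(p)
      list(pattern = p, vars = list(anatomical_entity = "anatomical_entity")))
  yaml::as.yaml(doc)
}

#' Generate the shipped 14-pattern suite
#'
#' The fourteen single-entity design patterns auto-applied to every new
#' anatomy term: abnormal X; absent X; abnormal morphology of X; abnormal
#' development of X; mislocalized X; necrotic X; abnormally
#' increased/decreased size of X; abnormally increased/decreased number of
#' X; increased/decreased apoptosis in X; increased/decreased cell
#' population proliferation in X. All share the uPheno-convention schema
#' `has part some (Q and (inheres in some E) and (has modifier some
#' abnormal))`; quality-specific patterns declare `abnormal X` (and, for the
#' size patterns, `abnormal morphology of X`) as parent patterns. Each
#' pattern is produced as YAML and parsed through [parse_pattern()].
#'
#' @param dir optional directory; when given, one `<pattern_id>.yaml` file
#'   per pattern is written there.
#' @return named list of 14 `design_pattern` objects, each carrying its
#'   YAML source as attribute `"yaml"`.
#' @export
make_pattern_suite <- function(dir = NULL) {
  qg <- make_quality_ontology()
  quality_ids <- setNames(as.list(term_ids(qg)), term_labels(qg))
  specs <- suite_spec()
  pats <- lapply(specs, function(sp) {
    y <- pattern_yaml(sp, quality_ids)
    p <- parse_pattern(y)
    attr(p, "yaml") <- y
    p
  })
  names(pats) <- vapply(pats, `[[`, character(1), "pattern_id")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in pats)
      writeLines(attr(p, "yaml"), file.path(dir, paste0(p$pattern_id, ".yaml")))
  }
  pats
}

#' Default selection configuration for the shipped suite
#'
#' All 14 patterns are auto patterns rooted at the anatomy root; traversal
#' uses is_a and part_of only. With `process_filters = TRUE` (the default,
#' mirroring the biology: cellular processes do not occur in acellular
#' spaces) the four apoptosis/proliferation patterns carry an applicability
#' filter forbidding the anatomical-space branch.
#'
#' @param anatomy the anatomy `ontology_graph` (for the root and the
#'   anatomical-space branch CURIEs).
#' @param patterns pattern list from [make_pattern_suite()].
#' @param process_filters attach the anatomical-space filters.
#' @param excluded_terms,excluded_branches extra exclusions.
#' @return a `selection_config`.
#' @export
make_suite_config <- function(anatomy, patterns = make_pattern_suite(),
                              process_filters = TRUE,
                              excluded_terms = character(0),
                              excluded_branches = character(0)) {
  root <- anatomy$header$root %||% stop("anatomy graph has no header root")
  labs <- term_labels(anatomy)
  space <- term_ids(anatomy)[match("anatomical space", labs)]
  filters <- list()
  if (process_filters && !is.na(space)) {
    proc <- grep("apoptosis|proliferation", names(patterns), value = TRUE)
    filters <- lapply(proc, function(p)
      list(pattern = p, forbid_branch = space))
  }
  selection_config(
    traversal_relations = c("is_a", "part_of"),
    auto_patterns = names(patterns),
    patterns = setNames(lapply(names(patterns), function(p)
      list(roots = root)), names(patterns)),
    excluded_terms = excluded_terms,
    excluded_branches = excluded_branches,
    filters = filters,
    root = list(id = "TOYP:9000000", label = "abnormal phenotype",
                definition = "Root of the toy phenotype ontology."),
    prefix = "TOYP", width = 7L,
    ontology_id = "toy-phenotype")
}
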