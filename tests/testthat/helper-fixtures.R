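# Shared fixtures, built in code.

# hand-built three-stanza document: eye is_a organ, eye part_of visual system
three_stanza_obo <- function() {
  paste(
    "format-version: 1.2",
    "ontology: tiny-anatomy",
    "",
    "[Term]",
    "id: TOYA:0000001",
    "name: organ",
    'def: "A compound anatomical structure." [TST:curator]',
    "",
    "[Term]",
    "id: TOYA:0000002",
    "name: visual system",
    "",
    "[Term]",
    "id: TOYA:0000003",
    "name: eye",
    'synonym: "ocular organ" EXACT []',
    "is_a: TOYA:0000001",
    "relationship: part_of TOYA:0000002",
    sep = "\n")
}

# precursor fixture: optic vesicle linked to the eye only by develops_from
precursor_graph <- function() {
  ontology_graph(
    list(obo_term("TOYA:0000001", label = "anatomical structure"),
         obo_term("TOYA:0000002", label = "visual system"),
         obo_term("TOYA:0000003", label = "eye"),
         obo_term("TOYA:0000004", label = "optic vesicle")),
    data.frame(
      subject = c("TOYA:0000002", "TOYA:0000003", "TOYA:0000004",
                  "TOYA:0000004"),
      predicate = c("is_a", "part_of", "is_a", "develops_from"),
      object = c("TOYA:0000001", "TOYA:0000002", "TOYA:0000001",
                 "TOYA:0000003"),
      stringsAsFactors = FALSE),
    header = list(ontology = "tiny-anatomy", root = "TOYA:0000001"))
}

suite_fixture <- function(n_entities = 10, seed = 1, process_filters = FALSE,
                          include_space = TRUE) {
  anatomy <- make_toy_anatomy(n_entities, seed = seed,
                              include_space = include_space)
  patterns <- make_pattern_suite()
  list(anatomy = anatomy,
       quality = make_quality_ontology(),
       patterns = patterns,
       config = make_suite_config(anatomy, patterns,
                                  process_filters = process_filters))
}

quiet_build <- function(fx, ...) {
  suppressMessages(build_release(fx$anatomy, fx$quality, fx$patterns,
                                 fx$config, verbose = FALSE, ...))
}

# boolean transitive closure of an edge list over the given ids
edge_closure <- function(edges, ids) {
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  keep <- edges$child %in% ids & edges$parent %in% ids
  m[cbind(match(edges$child[keep], ids), match(edges$parent[keep], ids))] <- TRUE
  repeat {
    m2 <- m | ((m %*% m) > 0)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# brute-force all-pairs entailment oracle over a class list
oracle_strict_matrix <- function(classes, anatomy, quality, patterns) {
  ids <- sort(vapply(classes, `[[`, character(1), "id"), method = "radix")
  names(classes) <- vapply(classes, `[[`, character(1), "id")
  n <- length(ids)
  sub <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- classes[[ids[i]]]; b <- classes[[ids[j]]]
    sub[i, j] <- entails(a$logical_definition, b$logical_definition,
                         anatomy, quality, patterns,
                         prov_a = a$provenance, prov_b = b$provenance)
  }
  sub & !t(sub)
}

# random class set: a sample of (pattern, entity) instances
random_class_set <- function(seed, max_classes = 50) {
  fx <- suite_fixture(n_entities = 12, seed = seed)
  entities <- select_entities(fx$anatomy, fx$config,
                              "abnormal_anatomical_entity")
  combos <- expand.grid(pattern = names(fx$patterns), entity = entities,
                        stringsAsFactors = FALSE)
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(s); force(code)
  }
  pick <- with_seed(seed + 1000L,
                    combos[sample(nrow(combos), min(max_classes, nrow(combos))), ])
  labels <- c(stats::setNames(
    vapply(fx$anatomy$terms, function(t) t$label, character(1)),
    names(fx$anatomy$terms)),
    stats::setNames(vapply(fx$quality$terms, function(t) t$label, character(1)),
                    names(fx$quality$terms)))
  classes <- lapply(seq_len(nrow(pick)), function(k) {
    instantiate(fx$patterns[[pick$pattern[k]]],
                stats::setNames(list(pick$entity[k]), "anatomical_entity"),
                labels, sprintf("TOYP:%07d", k))
  })
  list(classes = classes, fx = fx)
}
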