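fixture_classes <- function(g, pats, entities, pattern_ids, prefix_n = 1) {
  labels <- stats::setNames(vapply(g$terms, `[[`, character(1), "label"),
                            names(g$terms))
  qg <- make_quality_ontology()
  labels <- c(labels, stats::setNames(
    vapply(qg$terms, `[[`, character(1), "label"), names(qg$terms)))
  k <- prefix_n - 1
  out <- list()
  for (pid in pattern_ids) for (e in entities) {
    k <- k + 1
    out[[length(out) + 1L]] <-
      instantiate(pats[[pid]], list(anatomical_entity = e), labels,
                  sprintf("TOYP:%07d", k))
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

test_that("part_of propagates subsumption but develops_from never does", {
  g <- precursor_graph()  # eye part_of visual system; eye develops_from optic vesicle
  q <- make_quality_ontology()
  pats <- make_pattern_suite()
  cls <- fixture_classes(g, pats,
                         c("TOYA:0000002", "TOYA:0000003", "TOYA:0000004"),
                         "abnormal_anatomical_entity")
  ids <- names(cls)
  vis <- ids[1]; eye <- ids[2]; vesicle <- ids[3]
  # abnormal(eye) is subsumed by abnormal(visual system)
  expect_true(entails(cls[[eye]]$logical_definition,
                      cls[[vis]]$logical_definition, g, q))
  # but not by abnormal(optic vesicle): only develops_from links them
  expect_false(entails(cls[[eye]]$logical_definition,
                       cls[[vesicle]]$logical_definition, g, q))
  expect_false(entails(cls[[vesicle]]$logical_definition,
                       cls[[eye]]$logical_definition, g, q))
  # reflexivity
  for (id in ids)
    expect_true(entails(cls[[id]]$logical_definition,
                        cls[[id]]$logical_definition, g, q))

  res <- classify(cls, g, q, pats, root = "TOYP:9000000")
  expect_true(any(res$edges$child == eye & res$edges$parent == vis))
  closure <- edge_closure(res$edges, ids)
  expect_false(closure[eye, vesicle])
  expect_false(closure[vesicle, eye])
})

test_that("quality-specific patterns classify under their abnormal counterparts", {
  g <- precursor_graph()
  q <- make_quality_ontology()
  pats <- make_pattern_suite()
  cls <- fixture_classes(g, pats, "TOYA:0000003",
                         c("abnormal_anatomical_entity",
                           "abnormal_morphology_of_anatomical_entity",
                           "abnormally_decreased_size_of_anatomical_entity"))
  ids <- names(cls)
  # decreased-size(eye) entails abnormal(eye): derivable both structurally
  # (decreased size is_a ... is_a quality) and via the declared pattern lattice
  expect_true(entails(cls[[3]]$logical_definition, cls[[1]]$logical_definition,
                      g, q, pats,
                      prov_a = cls[[3]]$provenance,
                      prov_b = cls[[1]]$provenance))
  res <- classify(cls, g, q, pats, root = "TOYP:9000000")
  closure <- edge_closure(res$edges, ids)
  expect_true(closure[ids[3], ids[2]])  # decreased size under abnormal morphology
  expect_true(closure[ids[3], ids[1]])  # and transitively under abnormal
  expect_true(closure[ids[2], ids[1]])
  # direct edges form a transitive reduction: no shortcut edge
  expect_false(any(res$edges$child == ids[3] & res$edges$parent == ids[1]))
})

test_that("the declared pattern lattice adds entailments the structure alone misses", {
  # a deliberately non-structural parent: child quality (absent) is NOT under
  # the parent's quality atom (morphology), only the declared edge links them
  y_parent <- paste(
    "pattern_name: morph_parent",
    "classes: {morphology: 'TOYQ:0000002', abnormal: 'TOYQ:0000015'}",
    "relations: {'has part': 'TOYR:0000001', 'inheres in': 'TOYR:0000002', 'has modifier': 'TOYR:0000003'}",
    "vars: {anatomical_entity: 'TOYA:0000001'}",
    "name: {text: 'abnormal morphology of %s', vars: [anatomical_entity]}",
    "def: {text: 'Abnormal morphology of %s.', vars: [anatomical_entity]}",
    "equivalentTo:",
    "  text: \"'has part' some (morphology and ('inheres in' some %s) and ('has modifier' some abnormal))\"",
    "  vars: [anatomical_entity]",
    sep = "\n")
  y_child <- paste(
    "pattern_name: absent_child",
    "classes: {absent: 'TOYQ:0000009', abnormal: 'TOYQ:0000015'}",
    "relations: {'has part': 'TOYR:0000001', 'inheres in': 'TOYR:0000002', 'has modifier': 'TOYR:0000003'}",
    "vars: {anatomical_entity: 'TOYA:0000001'}",
    "name: {text: 'absent %s', vars: [anatomical_entity]}",
    "def: {text: 'Absent %s.', vars: [anatomical_entity]}",
    "equivalentTo:",
    "  text: \"'has part' some (absent and ('inheres in' some %s) and ('has modifier' some abnormal))\"",
    "  vars: [anatomical_entity]",
    "parent_patterns:",
    "  - pattern: morph_parent",
    "    vars: {anatomical_entity: anatomical_entity}",
    sep = "\n")
  pats <- list(parse_pattern(y_parent), parse_pattern(y_child))
  names(pats) <- c("morph_parent", "absent_child")
  g <- precursor_graph(); q <- make_quality_ontology()
  labels <- c(stats::setNames(vapply(g$terms, `[[`, character(1), "label"),
                              names(g$terms)))
  a <- instantiate(pats$absent_child, list(anatomical_entity = "TOYA:0000003"),
                   labels, "TOYP:0000001")
  b <- instantiate(pats$morph_parent, list(anatomical_entity = "TOYA:0000003"),
                   labels, "TOYP:0000002")
  # structurally false (absent is not under morphology in the quality tree)
  expect_false(entails(a$logical_definition, b$logical_definition, g, q))
  # true through the declared pattern edge
  expect_true(entails(a$logical_definition, b$logical_definition, g, q, pats,
                      prov_a = a$provenance, prov_b = b$provenance))
  res <- classify(list(a, b), g, q, pats, root = "TOYP:9000000")
  expect_true(any(res$edges$child == a$id & res$edges$parent == b$id))
})

test_that("classification equals the brute-force all-pairs entailment oracle", {
  for (seed in 1:20) {
    rc <- random_class_set(seed, max_classes = 50)
    cls <- rc$classes; fx <- rc$fx
    res <- classify(cls, fx$anatomy, fx$quality, fx$patterns,
                    root = "TOYP:9000000")
    ids <- sort(vapply(cls, `[[`, character(1), "id"), method = "radix")
    got <- edge_closure(res$edges, ids)
    want <- oracle_strict_matrix(cls, fx$anatomy, fx$quality, fx$patterns)
    # closure over the reduction must reproduce the strict entailment order
    expect_identical(got[ids, ids], want[ids, ids], label = paste("seed", seed))
  }
})

test_that("output is pure is_a, acyclic, and rooted", {
  for (seed in c(4, 9)) {
    fx <- suite_fixture(10, seed = seed)
    rel <- quiet_build(fx)
    # only is_a edges even though inputs used part_of/develops_from
    expect_true(all(rel$graph$relationships$predicate == "is_a"))
    ids <- names(rel$classes)
    closure <- edge_closure(rel$classification$edges,
                            c(ids, rel$classification$root))
    # acyclic: nothing reaches itself
    expect_false(any(diag(closure)))
    # every class reaches the root
    expect_true(all(closure[ids, rel$classification$root]))
  }
})

test_that("deleting develops_from edges leaves classification unchanged", {
  fx <- suite_fixture(10, seed = 5)
  rel1 <- quiet_build(fx)
  fx2 <- fx
  fx2$anatomy$relationships <- fx2$anatomy$relationships[
    fx2$anatomy$relationships$predicate != "develops_from", , drop = FALSE]
  rel2 <- quiet_build(fx2)
  expect_identical(rel1$classification$edges, rel2$classification$edges)
  expect_identical(rel1$obo, rel2$obo)
})

test_that("swapping a quality atom in a schema re-derives the hierarchy", {
  g <- precursor_graph(); q <- make_quality_ontology()
  mk_yaml <- function(name, qlabel, qid) paste(
    sprintf("pattern_name: %s", name),
    sprintf("classes: {'%s': '%s', abnormal: 'TOYQ:0000015'}", qlabel, qid),
    "relations: {'has part': 'TOYR:0000001', 'inheres in': 'TOYR:0000002', 'has modifier': 'TOYR:0000003'}",
    "vars: {anatomical_entity: 'TOYA:0000001'}",
    sprintf("name: {text: '%s of %%s', vars: [anatomical_entity]}", qlabel),
    sprintf("def: {text: 'Abnormal %s of %%s.', vars: [anatomical_entity]}", qlabel),
    "equivalentTo:",
    sprintf("  text: \"'has part' some ('%s' and ('inheres in' some %%s) and ('has modifier' some abnormal))\"", qlabel),
    "  vars: [anatomical_entity]",
    sep = "\n")
  pats3 <- list(
    size_parent = parse_pattern(mk_yaml("size_parent", "size", "TOYQ:0000003")),
    amount_parent = parse_pattern(mk_yaml("amount_parent", "amount",
                                          "TOYQ:0000006")),
    child = parse_pattern(mk_yaml("child", "decreased size", "TOYQ:0000005")))
  labels <- c("TOYA:0000003" = "eye")
  inst <- function(p, id) instantiate(p, list(anatomical_entity = "TOYA:0000003"),
                                      labels, id)
  cls <- list(inst(pats3$size_parent, "TOYP:0000001"),
              inst(pats3$amount_parent, "TOYP:0000002"),
              inst(pats3$child, "TOYP:0000003"))
  res1 <- classify(cls, g, q, pats3, root = "TOYP:9000000")
  ids <- sprintf("TOYP:%07d", 1:3)
  closure1 <- edge_closure(res1$edges, ids)
  # decreased size sits under the size parent, not the amount parent
  expect_true(closure1[ids[3], ids[1]])
  expect_false(closure1[ids[3], ids[2]])

  # pattern maintenance swaps the quality: decreased size -> decreased amount
  swapped <- parse_pattern(gsub("TOYQ:0000005", "TOYQ:0000008", fixed = TRUE,
                                mk_yaml("child", "decreased size",
                                        "TOYQ:0000005")))
  pats3$child <- swapped
  cls[[3]] <- inst(swapped, "TOYP:0000003")
  res2 <- classify(cls, g, q, pats3, root = "TOYP:9000000")
  closure2 <- edge_closure(res2$edges, ids)
  # with no manual edits the class now classifies under the amount parent
  expect_true(closure2[ids[3], ids[2]])
  expect_false(closure2[ids[3], ids[1]])
})

test_that("mutually entailing classes are reported and tie-broken to no edge", {
  g <- precursor_graph(); q <- make_quality_ontology()
  pats <- make_pattern_suite()
  labels <- c("TOYA:0000003" = "eye")
  a <- instantiate(pats[["abnormal_anatomical_entity"]],
                   list(anatomical_entity = "TOYA:0000003"), labels,
                   "TOYP:0000001")
  b <- instantiate(pats[["abnormal_anatomical_entity"]],
                   list(anatomical_entity = "TOYA:0000003"), labels,
                   "TOYP:0000002")
  b$label <- "duplicate abnormal eye"
  res <- classify(list(a, b), g, q, pats, root = "TOYP:9000000")
  expect_equal(nrow(res$equivalences), 1)
  expect_setequal(c(res$equivalences$a, res$equivalences$b),
                  c("TOYP:0000001", "TOYP:0000002"))
  expect_false(any(res$edges$child == "TOYP:0000001" &
                     res$edges$parent == "TOYP:0000002"))
  expect_false(any(res$edges$child == "TOYP:0000002" &
                     res$edges$parent == "TOYP:0000001"))
  # both still emitted and rooted
  expect_setequal(res$edges$child, c("TOYP:0000001", "TOYP:0000002"))
})

test_that("expressions with unknown CURIEs are rejected", {
  g <- precursor_graph(); q <- make_quality_ontology()
  bad <- precompose:::ex_atom("ZZZ:0000001")
  ok <- precompose:::ex_atom("TOYA:0000003")
  expect_error(entails(bad, ok, g, q), "unknown CURIE")
})
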