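---
title: "Compiling pre-composed phenotype ontologies from design patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling pre-composed phenotype ontologies from design patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precompose)
```

## The problem

Model-organism knowledgebases annotate experimental phenotypes either
post-composed — a curator pairs an anatomy term (the *entity*, E) with a
quality term (Q) at annotation time — or pre-composed, against a phenotype
ontology in which `decreased size of the heart` already exists as a single
named class. Pre-composition trades curator variability for ontology size:
nearly every anatomy term spawns a family of phenotype classes, so the
phenotype ontology is several times larger than the anatomy ontology it
derives from, and maintaining it by hand is infeasible.

`precompose` treats this as a compilation problem. The phenotype ontology
is never edited directly: it is a deterministic function of (i) the source
anatomy and quality ontologies, (ii) a library of design patterns, (iii)
TSV instantiation tables, and (iv) a selection/exclusion configuration.
Curation happens only in the flat files; every build re-derives everything
else, including the complete is_a hierarchy.

## The model

### Design patterns and logical definitions

A design pattern is a YAML document declaring variables (each with a range
class), text templates for the label, definition and synonyms (`%s` slots
paired with an ordered variable-reference list, substituted verbatim — any
article such as "the" is written into the template text), and an
equivalent-class schema. All fourteen shipped patterns use the uPheno-style
EQ shape

```
has_part some (Q and (inheres_in some E) and (has_modifier some abnormal))
```

where `Q` is the pattern's fixed quality class and `E` the bound anatomical
entity. Upstream pattern libraries do not publish a single canonical token
sequence for these schemas, so this package adopts that shape as its
convention and documents it here rather than claiming token-for-token
equality with any particular released ontology. Relation names
(`has_part`, `inheres_in`, `has_modifier`) stay symbolic in the parsed
model and are mapped to CURIEs only at serialization, since configurations
refer to relations by name.

Patterns may declare `parent_patterns`: an assertion that every instance of
the pattern is subsumed by the mapped instance of a parent pattern. For the
shipped suite the quality-specific patterns declare `abnormal X` as parent
(and the size patterns additionally `abnormal morphology of X`). With the
uniform schema above these edges are usually re-derivable structurally from
the quality hierarchy; they exist because a pattern author may use a schema
whose subsumption is *not* structurally visible, and the declared lattice
must still hold then (the test suite exercises exactly that case).

### Term selection

Which entities receive generated classes is decided by
relation-restricted traversal: from each pattern's inclusion roots, the
reflexive-transitive closure of the *inverse* of the configured relations —
`is_a` and `part_of` by default, and deliberately never `develops_from`. A
phenotype observed in a developed structure must not propagate to its
developmental precursor: every abnormal eye is part of an abnormal visual
system, but an abnormal eye does not imply an abnormal optic vesicle.
Using `develops_from` in the *inverse* direction (does abnormal development
of a precursor imply abnormal development of the derivative?) is a genuinely
open modelling question; the configuration exposes a
`use_develops_from_inverse` stub that errors if enabled, so the decision is
visible but cannot be toggled silently.

Selections are pruned by individually excluded terms, excluded branches
(term plus its whole traversal closure), and per-pattern applicability
filters. The shipped configuration filters the four apoptosis/proliferation
patterns away from the anatomical-space branch, because cellular processes
do not occur in acellular spaces. Exclusion always beats inclusion when a
multi-parent DAG makes a term reachable both ways — this is the
conservative choice: a missing phenotype class is a term request away,
whereas a biologically nonsensical one pollutes downstream annotation.
Obsolete anatomy terms are always excluded. Mixed `is_a`/`part_of` cycles
are rejected at selection time so the closure is well defined.

### Synchronization and identifier minting

`sync_tables()` makes the tables track the anatomy: new selected entities
gain one blank-id row per auto pattern; rows whose entity left the
selection are flagged `obsolete`, never deleted — deletion is reserved for
the explicit obsoletion workflow, and the release diff enforces that.
Sync is idempotent on its own output.

`mint_ids()` fills blank ids with consecutive zero-padded CURIEs in
deterministic row order (pattern id, then entity CURIE). The registry is a
flat TSV ledger; an issued (pattern, bindings) pair keeps its id forever —
if a row is removed and later re-added, it gets its original id back — and
numeric ids are never reused. The default width is 7 digits, matching the
convention of existing pre-composed phenotype ontologies; both prefix and
width are configuration. The `issued_on` provenance column is empty by
default precisely so that rebuilds from identical inputs are byte-identical;
callers who want timestamps pass them explicitly and accept the diff noise.

### Classification

The is_a hierarchy is computed purely from logical definitions by
structural subsumption over the fragment the schemas live in:

* **atoms**: `X ⊑ Y` iff `Y` is in the reflexive-transitive ancestor
  closure of `X` — over `is_a` for qualities, over `is_a` + `part_of` for
  entities. Folding `part_of` into the entity closure is what makes
  `abnormal eye ⊑ abnormal visual system` derivable; it is applied
  uniformly to all patterns (a per-pattern override would be configuration,
  but no shipped pattern needs one);
* **existential restrictions**: same relation, entailed filler;
* **intersections**: everything on the right must be entailed; anything on
  the left may witness;
* **pattern lattice**: declared `parent_patterns` edges, transitively
  composed through their variable mappings, with each mapped binding
  compared in the entity closure.

`classify()` evaluates all pairs, removes mutual entailments (logically
equivalent distinct classes are both kept, reported to QC as duplicate
logical definitions, and tie-broken to no edge between them), takes the
transitive reduction of the remaining strict order, and attaches classes
with no derived parent directly to the root phenotype class, which is
supplied by the configuration rather than generated. The output therefore
contains only is_a edges, is acyclic, and every non-obsolete class reaches
the root. This is a structural decision procedure for exactly this
fragment, not a general EL reasoner: property chains other than the fixed
part_of closure, nested role hierarchies and equivalence-axiom inference
are out of scope, and a schema outside the fragment would need the general
reasoner this replaces. Within the fragment, correctness is checked in the
test suite by comparing the transitive closure of `classify()` output
against a brute-force all-pairs `entails()` oracle on twenty seeded random
class sets of up to 50 classes.

Because classification is re-derived on every build, maintenance edits
propagate automatically: swapping the quality atom in a pattern schema
re-homes every instance of that pattern in the hierarchy with no manual
subclass edits (tested explicitly).

### QC, serialization, diffing

Five QC rules cover the checks a release pipeline needs: duplicate labels
(case-insensitive, non-obsolete classes), duplicate logical definitions
(canonical-form equality plus classifier-detected mutual entailment),
dangling references, obsolete classes still carrying logic (all errors),
and missing text definitions (warning). QC reports and never throws; the
build status carries the severity.

Serialization is deterministic by construction — terms sorted by CURIE in
the C locale, fixed tag order, UTF-8, LF — so two builds from identical
inputs are byte-identical and releases can be diffed textually. The OBO
dialect is deliberately closed (header `format-version`/`ontology`/
`data-version` plus a `property_value: IAO:0000700` root line; term tags
`id`, `name`, `def`, `synonym`, `is_a`, `relationship`, `is_obsolete`,
`replaced_by`); tags outside it round-trip opaquely. Logical definitions
are not emitted as OBO `intersection_of` lines; they live in the JSON
release (canonical expression strings plus pattern/bindings provenance),
which keeps the OBO surface within the round-trip-tested dialect. OWL
emission is out of scope.

`diff_releases()` distinguishes additions, obsoletions and label/definition
changes from true removals; any removed id marks the diff — and the build —
as failing, because ids must be retired by obsoletion, with `replaced_by`
targets required to be live classes (no chains, no transitive resolution).

## The synthetic fixtures

Real anatomy ontologies are large and versioned; the package instead ships
a generator whose defaults emulate the features the pipeline must handle:

* `make_toy_anatomy()` — a rooted DAG (default 30 terms, ~60/30/10%
  is_a/part_of/develops_from mix) with a fixed core: separate
  anatomical-structure and anatomical-space branches, an eye `part_of` a
  visual system, an eye–optic-vesicle pair linked *only* by
  `develops_from`, a multi-parent brain ventricle (space child and
  `part_of` brain), plus randomly attached generic structures and random
  DAG-thickening edges. Randomness runs under an explicit seed with global
  RNG state restored, so fixtures are reproducible everywhere.
* `make_quality_ontology()` — a fixed single-parent is_a tree with the
  branches the suite needs (size with the increased/decreased pair, amount
  with absent, position, viability, process qualities, and the `abnormal`
  modifier).
* `make_pattern_suite()` — the fourteen auto-applied patterns, generated as
  YAML and parsed through the public parser. The apoptosis/proliferation
  patterns are modelled with process-rate quality classes so one uniform
  schema serves all fourteen; a production deployment would bind real
  process ontology terms through a two-variable "process in location"
  pattern, which the engine also supports and the tests exercise.

Fixture CURIE prefixes (TOYA/TOYQ/TOYR/TOYP) can never collide with real
ontology ids. What passing tests on these fixtures shows is that the
*pipeline machinery* — selection, minting, compilation, classification, QC,
diffing — is correct on graphs with the right structural features; the
fixtures make no claim of statistical realism about anatomy topology, term
counts, or label style of any real ontology.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run builds of 10–12 anatomy
terms (140–168 classes), classify random sets of up to 50 classes against
the quadratic brute-force oracle over twenty seeds, and grow fixtures over
three build cycles; these sizes exercise every code path while keeping a
full run in the low minutes on one core. Classification is O(n²)
entailment checks plus an O(n³)-style boolean reduction, which is
comfortable at release scales of a few thousand classes; all-pairs work,
not parser throughput, dominates.

Ordering is the only tie-break anywhere: terms, rows, edges and reports are
sorted by CURIE (C locale) so builds are reproducible across platforms and
locales. Degenerate inputs are handled explicitly: empty documents and
empty tables are valid, a header-only ontology round-trips, obsolete terms
may not carry logic or (unless obsolete) `replaced_by`, and reflexive
relationships, dangling references, is_a cycles and mixed traversal cycles
are hard errors at parse or selection time.

## Known limitations

* The classifier is complete only for the supported expression fragment;
  it is a replacement for a general EL reasoner exactly there and nowhere
  else.
* The OBO dialect is closed; exotic tags survive round-trips opaquely but
  are not interpreted. OWL/RDF serialization is not provided.
* Obsoletion handles replacement only (`replaced_by`); merge semantics are
  expressed as obsoletion-with-replacement.
* Inverse develops_from propagation is surfaced as a configuration stub
  that refuses to enable, pending a principled answer to the modelling
  question it raises.
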