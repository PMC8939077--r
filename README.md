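# precompose

`precompose` is an R toolkit for building **pre-composed phenotype
ontologies** the way modern model-organism phenotype ontologies are built:
not by hand-curating thousands of classes, but by *compiling* them from an
anatomy ontology, a library of DOSDP-style design patterns, and flat TSV
instantiation tables.

It is aimed at ontology engineers and biocurators who maintain a phenotype
ontology for a model organism and want the entire release — term labels,
text definitions, synonyms, logical definitions, the complete is_a
hierarchy, stable identifiers, QC reports and release diffs — to be a
deterministic function of versioned flat files.

## What it does

A phenotype such as *decreased size of the heart* is, logically, an
entity–quality (EQ) pair: the anatomical entity `heart` bearing the quality
`decreased size`, abnormally. A design pattern captures one such quality
template once:

```
label:        "decreased size of the %s"
equivalentTo: has_part some ('decreased size'
                 and (inheres_in some %s)
                 and (has_modifier some abnormal))
```

and the compiler instantiates it for every appropriate anatomical entity.
The pipeline stages are:

1. **Parse** the anatomy and quality ontologies (a closed OBO 1.4 dialect,
   round-tripped exactly).
2. **Select** the entity terms each pattern applies to, by
   relation-restricted traversal from configured inclusion roots: `is_a`
   and `part_of` are followed, `develops_from` never is — an abnormal eye
   is part of an abnormal visual system, but need not imply an abnormal
   optic vesicle. Exclusion lists, excluded branches and per-pattern
   applicability filters (e.g. no proliferation phenotypes inside acellular
   anatomical spaces) prune the selection.
3. **Sync** the instance tables: new anatomy terms gain one row per
   auto-applied pattern; rows whose entity vanished or became excluded are
   flagged for obsoletion, never deleted.
4. **Mint** stable zero-padded identifiers for new rows; an issued
   (pattern, bindings) pair keeps its id forever, and ids are never reused.
5. **Compile** each row through its pattern into a named, defined,
   logically-defined phenotype class.
6. **Obsolete** classes listed in the obsoletion TSV (label prefixed
   `obsolete`, logical definition dropped, `replaced_by` recorded; the term
   stays in the release).
7. **Classify**: the complete is_a hierarchy is derived *purely from the
   logical definitions* by structural subsumption over the EL-style
   fragment the pattern schemas live in (class atoms, existential
   restrictions, intersections), with entity atoms compared over the
   is_a + part_of closure and quality atoms over is_a; declared
   parent-pattern edges add lattice-level subsumptions. No manual subclass
   assertions exist anywhere.
8. **QC**: duplicate labels, duplicate logical definitions, dangling
   references, obsolete-with-logic (errors) and missing definitions
   (warnings).
9. **Serialize** to deterministic OBO and graph JSON, and **diff** against
   the previous release — a term that disappears without obsoletion fails
   the build.

A synthetic-fixture module (`make_toy_anatomy()`, `make_quality_ontology()`,
`make_pattern_suite()`) generates a deterministic toy anatomy DAG, a quality
tree, and the standard suite of 14 auto-applied patterns (abnormal X, absent
X, abnormal morphology/development of X, mislocalized X, necrotic X,
increased/decreased size and number of X, increased/decreased apoptosis and
cell-population proliferation in X), so everything runs without downloading
any real ontology.

## Worked example

```r
library(precompose)

anatomy  <- make_toy_anatomy(12, seed = 1)      # 12-term toy anatomy DAG
quality  <- make_quality_ontology()             # fixed quality tree
patterns <- make_pattern_suite()                # the 14 auto patterns
config   <- make_suite_config(anatomy, patterns)

rel <- build_release(anatomy, quality, patterns, config)
#> [parse_sources] in=2 out=33
#> [select_sync] in=14 out=152
#> [mint] in=152 out=152
#> [compile] in=152 out=152
#> [classify] in=152 out=309
#> [qc] in=152 out=0
#> [serialize] in=153 out=2

rel
#> <ontology_release> 153 terms, 309 is_a edges, status 0
#>   qc: 0 error(s), 0 warning(s)
```

The 12 anatomy terms yield 152 phenotype classes rather than
14 × 12 = 168 because the default configuration filters the
apoptosis/proliferation patterns away from the anatomical-space branch
(4 patterns × 4 space-reachable terms in this fixture). The release holds
those 152 classes plus the root, connected by 309 derived is_a edges, e.g.:

```r
rel$classes[["TOYP:0000005"]]
#> <phenotype_class> TOYP:0000005 "abnormal eye"
#>   = has part some (TOYQ:0000001 and has modifier some TOYQ:0000015
#>       and inheres in some TOYA:0000005)
#>   from pattern abnormal_anatomical_entity [anatomical_entity=TOYA:0000005]
```

and `abnormal eye` classifies under `abnormal visual system` because the
eye is `part_of` the visual system — while no edge links it to
`abnormal optic vesicle`, which is connected to the eye only by
`develops_from`.

A thin command-line wrapper (`inst/scripts/precompose`) exposes
`build`, `sync`, `qc` and `diff` subcommands over the same functions, with
exit codes 0 (clean), 1 (QC errors), 2 (failing diff), 3 (input error).

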