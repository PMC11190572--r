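---
title: "Computable species descriptions: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computable species descriptions: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscribe)
```

## The model: individual-based semantic phenotypes

Traditional species descriptions are natural-language prose; computers
cannot query them. phenoscribe implements the individual-based (ABox)
alternative: a description is a knowledge graph whose nodes are *ontology
individuals* — one instance per anatomical structure, spatial region,
quality, or measurement datum mentioned — and whose edges are object
properties from standard relation vocabularies (`part_of`/`has_part`,
`has_characteristic`/`characteristic_of`, magnitude comparisons,
positional relations, measurement relations). Every node is typed by a
class from an anatomy or quality ontology, so the description inherits
the ontology's hierarchy: a `red brown` individual *is a* colour, a
`protibia` individual is *part of* an insect leg.

Descriptions are authored in a small statement language. A statement is a
chain that begins and ends with a node, alternates nodes and edges, and
closes with `;`:

```
uberon-male_organism > aism-metafemur > bspo-dorsal_margin > aism-cuticular_carina;
```

Each term carries its source-ontology prefix. Edges are alias glyphs
(`>` has_part, `<` part_of, `>>` has_characteristic, `<<`
characteristic_of, `|>|`/`|<|` increased/decreased in magnitude) or
dotted property names (`.iao-is_quality_measured_as`). The eight statement
families — presence, absence (`!>`), count/list, quality, absolute and
relative measurement, within-species comparison, between-species
comparison (`[exclude = True]` operands owned by the foreign species), and
positional statements — cover the constructs used in the dung-beetle
descriptions this package grew from.

### Identity rules

Identity is the crux of compiling chains into a graph:

* an **untagged** term occurrence is a fresh individual scoped to its
  statement and chain position (skolem id `<otu>/s<stmt>/p<pos>`);
* a **tagged** occurrence (`aism-pronotum:id-1549f8`) merges with every
  other occurrence of that tag within the OTU (`<otu>/<tag>`) — tags exist
  precisely to assert cross-line identity, e.g. the two lines of a
  measurement;
* a **negated** edge (`!>`) denies existence: its object stays a class,
  no individual is minted, and the OWL rendering is a class assertion of
  `ObjectComplementOf(ObjectSomeValuesFrom(has_part, C))` on the subject
  (individual-level absence has no direct OWL construct);
* an **exclude** operand belongs to the foreign OTU named in the same
  statement and never counts toward the focal description.

These rules make the individual count a deterministic function of the
source text, which the tests exploit as an oracle.

## The pipeline

`run_pipeline()` chains six steps with fail-fast gates: (1) compile to a
Turtle ABox; (2) shape validation — the run halts here if the graph does
not conform; (3) TBox assembly; (4) reasoning — the run halts if the graph
is inconsistent; (5) annotated NL generation; (6) semantic count queries.
Artifacts are deterministic: serializers sort prefixes, subjects,
predicates and objects, timestamps come from the project configuration's
`created` field, so re-running an unchanged configuration is byte-for-byte
a no-op.

### Validation shapes

The default shapes reconstruct the two published gate criteria — all
phenotypes linked to species names, and required metadata present — as
four checks: species linkage (every individual connected, undirected,
to its OTU's organism), OTU taxon id, organism catalog number, and datum
cardinality (exactly one measurement value, at least one unit). Shapes
serialize to SHACL-vocabulary Turtle; the connectivity check has no plain
SHACL-core equivalent, so its serialization approximates it as a
minCount-1 constraint on the OTU-membership annotation while the internal
validator performs true reachability. `load_shapes()` restores the exact
semantics via a kind annotation.

### Reasoning fragment

The reasoner is a rule-based EL-style materializer, not a tableau DL
reasoner: it computes (a) the subclass type closure; (b) the transitive
parthood closure over asserted `part_of` edges plus inverted `has_part`
edges; (c) skolemization — an individual typed by a class carrying
existential "with N parts" definitions acquires one named part per axiom
(deterministic ids `<ind>/skolem/<class>`), *unless* an asserted part of
the filler class already witnesses the axiom, which avoids double-counting
against query tallies; (d) extensions of defined region classes
`X or (part_of some X)`, combining individual-level parthood with
class-level `part_of` axioms lifted through the subclass hierarchy (an
antenna counts as head even when no individual-level chain reaches a head
individual); and (e) clash detection: a denied part that is asserted or
inferred, or one individual typed by two disjoint classes. This fragment
covers every inference the toolchain needs while staying dependency-light;
inconsistency is reported as a result, never thrown.

Logical definitions are encoded in the TBox as `subClassOf` existential
restrictions rather than `equivalentClass`/`intersectionOf` expressions —
for materialization in this fragment the two encodings behave identically,
and the former keeps the Turtle flat.

### NL generation

Generation walks the statements in authoring order and renders telegraphic
lines: `locators...: quality;`, `...: present;`/`...: absent;`,
`Q = value, unit: U;`, `Q smaller/larger than Q of B of ...;`, and
positional `A <rel> B of ...;`. Locator chains come from parent pointers
assigned when a node is first introduced; tagged back-references that
re-anchor a chain onto an earlier node never reassign pointers (keeping
them acyclic) and are elided from measurement unit phrases, matching the
published rendering where a relative unit reads "diameter of ocellate
setigerous cuticular puncture" without repeating the anchoring pronotum.
Consecutive lines sharing locator prefixes can be nested with the prefix
elided (`nl_text(doc, nested = TRUE)`); the flat form repeats full chains.
The published conversions truncated between-species comparisons to
"hind wing: length;" with an asterisk; phenoscribe renders the full
sentence naming both operands and the foreign species, and keeps the
truncated historical form behind `legacy_asterisk = TRUE` for regression
comparison. Exact nesting rules of the original converter are not
documented anywhere; ours are reverse-engineered from the four printed
treatments and may differ on unseen patterns.

### Queries

Two presets mirror the published analysis: individuals per
characteristic class (colour, shape, size, texture — a count of OTU-owned
base individuals whose inferred types include the class or a subclass) and
individuals per body region (the four defined classes; membership in two
regions counts in both). Skolem parts are excluded from counts by default
(`include_skolems = TRUE` exposes the other tally, since it is unknown
whether the original pipeline counted them). `export_sparql_bundle()`
writes the materialized graph plus one SPARQL query per preset class so an
external engine reproduces the counts; one test cross-checks against the
Python rdflib engine.

## The fixture ontology and what it does (not) show

The bundled TBox (`inst/extdata/fixture_tbox.ttl`) is a curated
mini-ontology standing in for the twelve OBO ontologies a real project
would merge: ~190 classes with a quality spine (colour / shape / size /
texture parents), a head / thorax / abdomen / leg parthood skeleton,
spatial-region vocabulary for postcomposition, logical definitions for the
palpus, labial palpus and tarsi "with N parts" classes, and the four
defined region classes (`inst/extdata/defined_classes.yaml`). IRIs are
minted under the project namespace except the handful of terms whose OBO
ids are established (BFO part_of; the PATO quality parents; the AISM
body-region classes). Every curated edge is in that single file so tests
can cite it. Which of the project's new anatomy terms carry logical
definitions is not enumerated anywhere; the fixture defines only those the
worked statements rely on (notably the four-palpomere maxillary palpus).
Legs are deliberately not made class-level parts of the thorax, keeping
the leg and thorax query rows independent.

The synthetic generator (`generate_description()`) emits seeded random
statements from all eight families over this vocabulary and returns
constructively computed ground truth (individuals, per-class and
per-region counts, measurement values) that the tests compare against the
compiled and reasoned graph. It emulates structural variety, not
biological realism: no trait correlations, no intraspecific variation, and
quality assignments are uniform draws. Passing tests therefore demonstrate
correctness of the machinery on in-vocabulary descriptions, not robustness
to arbitrary real-world ontologies.

## Reproduction scale and known deltas

The four golden description files re-encode the published *Grebennikovius*
treatments from their printed natural-language descriptions (the
supplementary description sources and pinned ontology versions are not
bundled and are not fetched). Under this re-encoding the four descriptions
compile to 742 base individuals against 756 reported for the originals
(−1.9%); the characteristic-query grid matches the published counts
exactly for colour (all four species) and texture, is within a few
individuals for size, and diverges for shape and the region rows — the
published region counts appear to include individuals beyond the strict
"X or (part_of some X)" extension stated in the text. The acceptance test
that compares these totals against the published values is expected to
fail until the original supplementary sources are used; it is kept exact
rather than loosened, and the golden encodings were fixed once from the
printed text, not adjusted toward the published numbers.

## Numerical and procedural choices

* Problem sizes in the test suite: randomized closure/extension checks use
  200 graphs of 5–50 nodes; generator-oracle checks use 50 seeds of
  ~11-statement descriptions — sizes at which brute-force oracles are
  exact and instantaneous.
* Merge conflicts when loading TBox files resolve first-loaded-wins for
  labels (with a warning) and union for axioms, mirroring desk-scale
  ROBOT-style merges.
* Both OTU-binding spellings (`::otu` and `:otu`) are accepted when the
  suffix names a declared OTU, since the published statements use both;
  `:name` otherwise lexes as an identity tag. Intervals ("1–2 diameters")
  have no syntax; the average is stored as the measurement value.
* Measurement literals are decimals; units are always modeled as an edge
  to a unit individual (absolute) or a quality-of-entity individual
  (relative).
* The habitat nanopublications use a project-namespace `inhabits` property
  and `habitat/forest` term recorded in the configuration; no external
  environment-ontology id is asserted because none is fixed by the source
  data. Emission is file-only TriG (four named graphs per nanopub:
  head, assertion, provenance, publication info); no trusty-URI hashing,
  signing or network publication.

## Limitations

Beyond the fragment boundaries above: no OWL-DL tableau reasoning or
justification trees (clash reports list the minimal responsible facts);
no general SPARQL engine (counts are native, the bundle is for external
engines); no error recovery beyond first-error-per-statement in the
parser; no modeling of intraspecific variation. The Turtle/TriG
reader-writer covers the constructs this toolchain emits, not the full
grammars.
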