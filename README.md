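# phenoscribe

Computable species descriptions from semantic phenotype scripts.

Taxonomic species descriptions are written as natural-language prose, which
makes the phenotypic data they carry all but invisible to computational
analysis. phenoscribe implements the individual-based (ABox) alternative
for R: a description is authored in a small statement language built on
entity–quality annotation with ontology terms, compiled into an OWL
knowledge graph of typed individuals, validated against shape constraints,
enriched by a materializing reasoner, rendered back into annotated
natural language for publication, and queried for trait counts. Per-species
assertions can additionally be packaged as nanopublications (TriG named
graphs). The intended users are taxonomists and biodiversity informaticians
producing machine-readable (FAIR) descriptions — the worked fixtures
describe four *Grebennikovius* dung-beetle species.

## The model in brief

A statement is a node–edge chain closed by `;`, where nodes are
prefix-qualified ontology terms and edges are relation aliases:

```
uberon-male_organism > aism-metafemur > bspo-dorsal_margin > aism-cuticular_carina;
```

reads "the dorsal margin of the metafemur bears a cuticular carina".
Aliases map to object properties: `>` has_part, `<` part_of (BFO:0000050,
transitive), `>>` has_characteristic, `<<` characteristic_of, `|>|` / `|<|`
increased/decreased_in_magnitude_relative_to; `!>` denies a part
(rendered in OWL as `not (has_part some C)`), and dotted names
(`.iao-is_quality_measured_as`) reference any registered property.
Compilation mints one individual per untagged term occurrence; identity
tags (`:md-c4c164`) merge occurrences across statements; `[exclude = True]`
operands belong to another species' description. Reasoning materializes
subclass types, transitive parthood, skolem parts for "with N parts"
logical definitions, and membership in defined body-region classes
`X or (part_of some X)`.

## Worked example

```r
library(phenoscribe)
tb  <- build_fixture_ontology()
doc <- parse_document(c(
  "OTU grebennikovius_armiger ;",
  "uberon-male_organism > aism-metafemur > bspo-dorsal_margin > aism-cuticular_carina;",
  "uberon-male_organism > aism-protibia !> aism-dorsal_protibial_cuticular_tooth_4;",
  "uberon-male_organism > aism-maxillary_palpus_with_4_palpomeres;",
  "uberon-male_organism >> pato-length .iao-is_quality_measured_as iao-measurement_datum:md-c4c164 .aism-has_unit unit-millimeter;",
  "iao-measurement_datum:md-c4c164 .iao-has_measurement_value 4.5;"
), fixture_config_path())

g <- compile_abox(doc, tb)
#> <phs_abox: 12 individuals, 10 assertions, 4 OTUs>
validate_graph(g, default_shapes(), tb)
#> <validation: conforms = TRUE, 0 violations>
inf <- materialize(g, tb)
#> <phs_inferred: 16 individuals (4 skolem), consistent: TRUE, 0 clashes>
```

The 12 base individuals are the four organism records plus one individual
per term occurrence; reasoning adds 4 skolem palpomeres because the
fixture ontology logically defines the four-palpomere maxillary palpus as
having each palpomere as a part. The regenerated description:

```r
cat(nl_text(generate_nl(inf, "grebennikovius_armiger")), sep = "\n")
#> male organism, metafemur, dorsal margin, cuticular carina: present;
#> male organism, protibia, dorsal protibial cuticular tooth 4: absent;
#> male organism, maxillary palpus with 4 palpomeres: present;
#> male organism, length = 4.5, unit: millimeter;
```

and a region query (`head_or_part` counts the palpus via the class-level
parthood chain maxillary palpus → maxilla → head; `leg_or_part` counts the
protibia, carina chain and metafemur):

```r
query_table(run_preset_query(inf, "regions"))[, 1:2]
#>             class grebennikovius_armiger
#> 1    head_or_part                      1
#> 2  thorax_or_part                      0
#> 3 abdomen_or_part                      0
#> 4     leg_or_part                      4
```

`run_pipeline()` chains compile → validate → TBox → reason → NL → queries
with fail-fast gates after validation and reasoning;
`inst/scripts/phenoc.R` exposes the same steps as a `phenoc` command line
(`parse`, `compile`, `validate`, `reason`, `nl`, `query`, `nanopub`,
`run`, `fixtures`, `makefile`). Four golden description files under
`inst/extdata/goldens/` re-encode the published *Grebennikovius*
treatments; `generate_description()` produces seeded synthetic
descriptions with ground-truth tallies for testing.

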