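# Project configuration for the bundled Grebennikovius description fixtures.
title: "Grebennikovius semantic species descriptions (fixture study)"
authors:
  - "Fixture Curator"
created: "2024-06-13"
prefixes:
  aism: "https://w3id.org/phenoscribe/aism/"
  colao: "https://w3id.org/phenoscribe/colao/"
  pato: "https://w3id.org/phenoscribe/pato/"
  bspo: "https://w3id.org/phenoscribe/bspo/"
  uberon: "https://w3id.org/phenoscribe/uberon/"
  iao: "https://w3id.org/phenoscribe/iao/"
  ro: "https://w3id.org/phenoscribe/ro/"
  unit: "https://w3id.org/phenoscribe/unit/"
otus:
  - id: grebennikovius_armiger
    label: "Grebennikovius armiger"
    taxon_id: "http://zoobank.org/883D3610-BE9D-4818-AE90-7D729A205190"
    parent_name_usage_id: "https://www.gbif.org/species/10360397"
    catalog_number: "http://id.luomus.fi/GAC.37252"
    habitat: forest
  - id: grebennikovius_basilewskyi
    label: "Grebennikovius basilewskyi"
    taxon_id: "https://www.gbif.org/species/10023107"
    parent_name_usage_id: "https://www.gbif.org/species/10360397"
    catalog_number: "http://id.luomus.fi/GAC.37261"
    habitat: forest
  - id: grebennikovius_lupanganus
    label: "Grebennikovius lupanganus"
    taxon_id: "http://zoobank.org/1D32A7F2-0376-436B-976F-54C2EEEC430C"
    parent_name_usage_id: "https://www.gbif.org/species/10360397"
    catalog_number: "http://id.luomus.fi/GAC.37250"
    habitat: forest
  - id: grebennikovius_pafelo
    label: "Grebennikovius pafelo"
    taxon_id: "http://zoobank.org/6AA504F4-91BB-4EF9-AF8F-31EDA06AD5F9"
    parent_name_usage_id: "https://www.gbif.org/species/10360397"
    catalog_number: "http://id.luomus.fi/GAC.37245"
    habitat: forest
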