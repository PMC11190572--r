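test_that("a fully linked compiled graph conforms to the default shapes", {
  g <- compile_pattern_document()
  rep <- validate_graph(g, default_shapes(), fixture_tbox())
  expect_true(rep$conforms)
  expect_equal(nrow(rep$violations), 0L)
})

test_that("an individual unreachable from any organism violates species linkage", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-gena;",
                          "aism-cuticular_seta:id-orphan >> pato-smooth;"),
                        fixture_config())
  g <- compile_abox(doc, tb)
  rep <- validate_graph(g, default_shapes(), tb)
  expect_false(rep$conforms)
  expect_true(all(rep$violations$shape == "species_linkage"))
  expect_true(any(grepl("id-orphan", rep$violations$focus)))
})

test_that("missing OTU metadata triggers the taxon-id and catalog-number shapes", {
  tb <- fixture_tbox()
  cfg <- read_project_config(fixture_config())
  cfg$otus[[1]]$taxon_id <- NULL
  cfg$otus[[2]]$catalog_number <- NULL
  doc <- parse_document("OTU grebennikovius_armiger ;", cfg)
  g <- compile_abox(doc, tb)
  rep <- validate_graph(g, default_shapes(), tb)
  expect_false(rep$conforms)
  expect_setequal(rep$violations$shape,
                  c("otu_taxon_id", "organism_catalog_number"))
})

test_that("datum cardinality violations match a direct triple scan", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  # datum lacking its measurement value
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          paste0("uberon-male_organism >> pato-length ",
                                 ".iao-is_quality_measured_as iao-measurement_datum:md-1 ",
                                 ".aism-has_unit unit-millimeter;")), cfg)
  g <- compile_abox(doc, tb)
  rep <- validate_graph(g, default_shapes(), tb)
  expect_false(rep$conforms)
  expect_true(any(rep$violations$shape == "datum_value" &
                  rep$violations$constraint == "minCount"))
  # oracle: scan the assertion table directly
  datum <- g$individuals$id[g$individuals$cls == "iao-measurement_datum"]
  expect_equal(sum(g$assertions$subject == datum &
                   g$assertions$predicate == "iao-has_measurement_value"), 0L)

  # datum with two values
  doc2 <- parse_document(c("OTU grebennikovius_armiger ;",
                           paste0("uberon-male_organism >> pato-length ",
                                  ".iao-is_quality_measured_as iao-measurement_datum:md-1 ",
                                  ".aism-has_unit unit-millimeter;"),
                           "iao-measurement_datum:md-1 .iao-has_measurement_value 4.5;",
                           "iao-measurement_datum:md-1 .iao-has_measurement_value 4.6;"),
                         cfg)
  g2 <- compile_abox(doc2, tb)
  rep2 <- validate_graph(g2, default_shapes(), tb)
  expect_true(any(rep2$violations$shape == "datum_value" &
                  rep2$violations$constraint == "maxCount"))
})

test_that("validation is monotone: adding a violating node keeps existing violations", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "aism-cuticular_seta:id-orphan >> pato-smooth;"),
                        fixture_config())
  g <- compile_abox(doc, tb)
  v1 <- validate_graph(g, default_shapes(), tb)$violations
  doc2 <- parse_document(c("OTU grebennikovius_armiger ;",
                           "aism-cuticular_seta:id-orphan >> pato-smooth;",
                           "aism-cuticular_groove:id-orphan2 >> pato-smooth;"),
                         fixture_config())
  g2 <- compile_abox(doc2, tb)
  v2 <- validate_graph(g2, default_shapes(), tb)$violations
  expect_true(all(do.call(paste, v1) %in% do.call(paste, v2)))
  expect_gt(nrow(v2), nrow(v1))
})

test_that("shapes serialize to SHACL Turtle and reload with identical behaviour", {
  tb <- fixture_tbox()
  shapes <- default_shapes()
  txt <- serialize_shapes(shapes, tb)
  expect_match(txt, "sh:NodeShape")
  expect_match(txt, "sh:minCount")
  shapes2 <- load_shapes(txt, tb)
  expect_length(shapes2, length(shapes))
  g <- compile_pattern_document()
  r1 <- validate_graph(g, shapes, tb)
  r2 <- validate_graph(g, shapes2, tb)
  expect_identical(r1$violations, r2$violations)
})

test_that("a shape referencing an unknown property is a definition error", {
  tb <- fixture_tbox()
  bad <- list(shape("bad", target_class = "iao-measurement_datum",
                    path = "iao-no_such_property", min = 1L))
  g <- compile_pattern_document()
  expect_error(validate_graph(g, bad, tb), "unknown property")
})
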