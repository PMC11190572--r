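test_that("'head is red' yields a single individual under the colour class", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-head_capsule >> pato-red;"),
                        fixture_config())
  inf <- materialize(compile_abox(doc, tb), tb)
  res <- count_by_class(inf, "pato-colour")
  tab <- query_table(res)
  expect_equal(tab$grebennikovius_armiger[tab$class == "pato-colour"], 1L)
  expect_equal(tab$grebennikovius_basilewskyi[tab$class == "pato-colour"], 0L)
})

test_that("an empty graph counts zero everywhere and unknown classes error", {
  tb <- fixture_tbox()
  doc <- parse_document("OTU grebennikovius_armiger ;", fixture_config())
  inf <- materialize(compile_abox(doc, tb), tb)
  res <- run_preset_query(inf, "characteristics")
  expect_true(all(res$rows$count == 0L))
  res2 <- run_preset_query(inf, "regions")
  expect_true(all(res2$rows$count == 0L))
  expect_error(count_by_class(inf, "pato-no_such"), "unknown classes")
  expect_error(count_by_region(inf, "no_such_region"), "unknown defined classes")
})

test_that("class counts equal an exhaustive type-scan oracle", {
  tb <- fixture_tbox()
  inf <- materialize(compile_pattern_document(), tb)
  anc <- subclass_ancestors(tb)
  ind <- inf$base$individuals
  for (cls in c("pato-colour", "pato-shape", "pato-size", "pato-texture")) {
    res <- count_by_class(inf, cls)
    for (o in unique(res$rows$otu)) {
      oracle <- sum(vapply(which(ind$otu == o & !ind$skolem), function(i) {
        cls %in% c(ind$cls[i], anc[[ind$cls[i]]])
      }, logical(1)))
      expect_equal(res$rows$count[res$rows$otu == o], oracle,
                   info = paste(cls, o))
    }
  }
})

test_that("region counts use defined-class extensions; antenna parts count as head", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-antenna >> pato-elongated;"),
                        fixture_config())
  inf <- materialize(compile_abox(doc, tb), tb)
  tab <- query_table(run_preset_query(inf, "regions"))
  expect_equal(tab$grebennikovius_armiger[tab$class == "head_or_part"], 1L)
  expect_equal(tab$grebennikovius_armiger[tab$class == "abdomen_or_part"], 0L)
})

test_that("counts are invariant under statement reordering", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  stmts <- c("uberon-male_organism > aism-gena >> pato-red;",
             "uberon-male_organism > aism-pronotum >> pato-convex;",
             "uberon-male_organism > aism-protibia >> pato-curved;")
  doc1 <- parse_document(c("OTU grebennikovius_armiger ;", stmts), cfg)
  doc2 <- parse_document(c("OTU grebennikovius_armiger ;", rev(stmts)), cfg)
  inf1 <- materialize(compile_abox(doc1, tb), tb)
  inf2 <- materialize(compile_abox(doc2, tb), tb)
  for (preset in c("characteristics", "regions")) {
    t1 <- query_table(run_preset_query(inf1, preset))
    t2 <- query_table(run_preset_query(inf2, preset))
    expect_identical(t1, t2)
  }
})

test_that("query results export as TSV and JSON tables keyed class x OTU", {
  tb <- fixture_tbox()
  inf <- materialize(compile_pattern_document(), tb)
  res <- run_preset_query(inf, "characteristics")
  tsv <- tempfile(fileext = ".tsv")
  write_query_result(res, tsv, "tsv")
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_identical(back$class,
                   c("pato-colour", "pato-shape", "pato-size", "pato-texture"))
  expect_true("grebennikovius_armiger" %in% names(back))
  js <- tempfile(fileext = ".json")
  write_query_result(res, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$class, back$class)
})

test_that("the exported SPARQL bundle reproduces internal counts in an external engine", {
  tb <- fixture_tbox()
  inf <- materialize(compile_pattern_document(), tb)
  dir <- tempfile("bundle")
  files <- export_sparql_bundle(inf, dir)
  expect_true(file.exists(file.path(dir, "inferred.ttl")))
  rq <- grep("\\.rq$", files, value = TRUE)
  expect_equal(sum(grepl("count_(colour|shape|size|texture)", rq)), 4L)

  # cross-engine oracle: run one preset query with the Python rdflib engine
  py <- sprintf(
    "import rdflib, json\ng = rdflib.Graph()\ng.parse('%s', format='turtle')\nq = open('%s').read()\nprint(json.dumps({str(r[0]): int(r[1]) for r in g.query(q)}))",
    file.path(dir, "inferred.ttl"), file.path(dir, "count_shape.rq"))
  out <- suppressWarnings(system2("python", "-", input = py, stdout = TRUE,
                                  stderr = FALSE))
  external <- jsonlite::fromJSON(paste(out, collapse = ""))
  internal <- count_by_class(inf, "pato-shape")$rows
  for (o in names(external)) {
    expect_equal(external[[o]], internal$count[internal$otu == o],
                 info = o)
  }
  # OTUs with zero matches are simply absent from the external result
  zero <- setdiff(internal$otu, names(external))
  expect_true(all(internal$count[internal$otu %in% zero] == 0L))
})
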