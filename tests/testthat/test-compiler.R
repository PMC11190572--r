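test_that("node lists distribute the incoming edge over every item", {
  g <- compile_pattern_document()
  prot <- g$individuals[g$individuals$cls == "aism-protibia", ]
  # the count-phenotype statement mints three tooth individuals on one protibia
  teeth <- g$assertions[g$assertions$predicate == "ro-has_part" &
                        g$assertions$subject %in% prot$id &
                        !is.na(g$assertions$object), ]
  tooth_cls <- g$individuals$cls[match(teeth$object, g$individuals$id)]
  expect_equal(sum(grepl("dorsal_protibial_cuticular_tooth", tooth_cls)), 3L)
  expect_setequal(grep("tooth", tooth_cls, value = TRUE),
                  paste0("aism-dorsal_protibial_cuticular_tooth_", 1:3))
})

test_that("identity tags merge individuals across statements", {
  g <- compile_pattern_document()
  datums <- g$individuals[g$individuals$cls == "iao-measurement_datum", ]
  # two datum tags in the document, each spanning two statements
  expect_equal(nrow(datums), 2L)
  lit <- g$assertions[!is.na(g$assertions$literal), ]
  expect_setequal(lit$literal, c(4.5, 1.5))
  expect_identical(lit$predicate, rep("iao-has_measurement_value", 2L))
})

test_that("alias glyph mapping is a bijection onto the six object properties", {
  tb <- fixture_tbox()
  glyphs <- c(">", "<", ">>", "<<", "|>|", "|<|")
  curies <- vapply(glyphs, function(g) tbox_property(tb, g)$curie, character(1))
  expect_setequal(curies, c("ro-has_part", "ro-part_of",
                            "ro-has_characteristic", "ro-characteristic_of",
                            "ro-increased_in_magnitude_relative_to",
                            "ro-decreased_in_magnitude_relative_to"))
  expect_equal(anyDuplicated(curies), 0L)
})

test_that("negated assertions deny at the class level without minting individuals", {
  g <- compile_pattern_document()
  neg <- g$assertions[g$assertions$polarity == "neg", ]
  expect_equal(nrow(neg), 2L)
  expect_true(all(!is.na(neg$object_class)))
  expect_true(all(is.na(neg$object)))
  expect_false("aism-dorsal_protibial_cuticular_tooth_4" %in% g$individuals$cls)
})

test_that("exclude nodes are owned by the foreign OTU and excluded from the focal tally", {
  g <- compile_pattern_document()
  foreign <- g$individuals[g$individuals$otu == "grebennikovius_basilewskyi", ]
  expect_setequal(setdiff(foreign$cls, "uberon-male_organism"),
                  c("pato-length", "aism-hind_wing"))
  # oracle: recount ownership by hand from the individual table
  focal_n <- sum(g$individuals$otu == "grebennikovius_armiger" &
                 !g$individuals$skolem)
  expect_equal(unname(count_individuals(g)["grebennikovius_armiger"]), focal_n)
  # the between-species comparison edge spans the two OTUs
  cmp <- g$assertions[g$assertions$predicate ==
                      "ro-decreased_in_magnitude_relative_to", ]
  cmp <- cmp[g$individuals$otu[match(cmp$object, g$individuals$id)] ==
             "grebennikovius_basilewskyi", ]
  expect_equal(nrow(cmp), 1L)
  expect_equal(g$individuals$otu[match(cmp$subject, g$individuals$id)],
               "grebennikovius_armiger")
})

test_that("resolve_cross_otu returns the foreign individual and rejects focal exclusion", {
  g <- compile_pattern_document()
  node <- structure(list(kind = "term", term = "aism-hind_wing",
                         tag = "id-6b490e", otu = NA_character_,
                         exclude = TRUE, value = NA_real_, items = NULL,
                         line = 1L), class = "ps_node")
  hit <- resolve_cross_otu(g, node, focal_otu = "grebennikovius_armiger")
  expect_identical(hit$otu, "grebennikovius_basilewskyi")
  plain <- node; plain$exclude <- FALSE; plain$tag <- NA_character_
  hit2 <- resolve_cross_otu(g, plain, focal_otu = "grebennikovius_armiger")
  expect_identical(hit2$otu, "grebennikovius_armiger")
})

test_that("compile errors: unresolved terms, tag conflicts, unknown OTUs", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-no_such_part > pato-no_such_quality;"),
                        cfg)
  expect_error(compile_abox(doc, tb),
               "aism-no_such_part.*pato-no_such_quality")
  doc2 <- parse_document(c("OTU grebennikovius_armiger ;",
                           "uberon-male_organism > aism-protibia:id-x;",
                           "uberon-male_organism > aism-mesotibia:id-x;"), cfg)
  expect_error(compile_abox(doc2, tb), "tag conflict")
  doc3 <- parse_document(c("OTU grebennikovius_armiger ;",
                           "uberon-male_organism > aism-hind_wing:id-w[exclude = True];"),
                         cfg)
  expect_error(compile_abox(doc3, tb), "no foreign OTU")
})

test_that("an empty document compiles to OTU records only", {
  doc <- parse_document("OTU grebennikovius_armiger ;", fixture_config())
  g <- compile_abox(doc, fixture_tbox())
  expect_equal(nrow(g$otus), 4L)
  expect_true(all(g$individuals$cls == "uberon-male_organism"))
  expect_equal(nrow(g$assertions), 0L)
})

test_that("the serialized ABox is deterministic and round-trips", {
  tb <- fixture_tbox()
  g <- compile_pattern_document()
  t1 <- serialize_abox(g, tb)
  t2 <- serialize_abox(g, tb)
  expect_identical(t1, t2)
  g2 <- load_abox(t1, tb)
  expect_true(abox_equal(g, g2))
  # the absence statement emits the complement-of-restriction pattern
  expect_match(t1, "owl:complementOf")
  expect_match(t1, "owl:someValuesFrom")
})

test_that("individual count is a deterministic function of the AST", {
  g <- compile_pattern_document()
  doc <- parse_document(pattern_document(), fixture_config())
  # oracle: term occurrences minus negated-edge objects (class-level
  # denials, no individual) minus (tag occurrences - distinct tags) minus
  # excluded foreign nodes, plus the focal organism
  occ <- 0L; tags <- character(0); tag_occ <- 0L
  walk <- function(el) {
    if (el$kind == "list") return(invisible(lapply(el$items, walk)))
    if (el$kind != "term") return(invisible())
    if (isTRUE(el$exclude)) return(invisible())
    if (el$term == "uberon-male_organism") return(invisible())
    occ <<- occ + 1L
    if (!is.na(el$tag)) { tag_occ <<- tag_occ + 1L; tags <<- c(tags, el$tag) }
  }
  for (s in doc$statements) {
    neg_prev <- FALSE
    for (el in s$elements) {
      if (inherits(el, "ps_edge")) {
        neg_prev <- isTRUE(el$negated)
      } else {
        if (!neg_prev) walk(el)
        neg_prev <- FALSE
      }
    }
  }
  expected <- occ - (tag_occ - length(unique(tags))) + 1L  # + organism
  got <- unname(count_individuals(g)["grebennikovius_armiger"])
  expect_equal(got, expected)
})
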