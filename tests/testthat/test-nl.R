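pattern_nl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      inf <- materialize(compile_pattern_document(), fixture_tbox())
      cache <<- generate_nl(inf, "grebennikovius_armiger")
    }
    cache
  }
})

test_that("measurement, absence, presence and quality templates match the printed forms", {
  tx <- nl_text(pattern_nl())
  expect_true("male organism, length = 4.5, unit: millimeter;" %in% tx)
  expect_true("male organism, posterior longitudinal hypomeral carina: absent;" %in% tx)
  expect_true("male organism, protibia, dorsal protibial cuticular tooth 4: absent;" %in% tx)
  expect_true("male organism, metafemur, dorsal margin, cuticular carina: present;" %in% tx)
  expect_true("male organism: ovate;" %in% tx)
  expect_true("male organism, vertex, posterior region, medial region: smooth;" %in% tx)
  expect_true(paste0("male organism, pronotum, interpunctural distance = 1.5, ",
                     "unit: diameter of ocellate setigerous cuticular puncture;") %in% tx)
})

test_that("within-species comparison and positional lines follow the printed chains", {
  tx <- nl_text(pattern_nl())
  expect_true(paste0("male organism, clypeus, anterior region, setigerous cuticular ",
                     "puncture: diameter smaller than diameter of setigerous ",
                     "cuticular puncture of frons;") %in% tx)
  expect_true(paste0("male organism, elytron with 9 striae, elytral interstria 8, ",
                     "cuticular carina medial_to lateral region of elytron ",
                     "with 9 striae;") %in% tx)
  expect_true(paste0("male organism, abdominal tergite VIII, anatomical margin ",
                     "coincident with cuticular groove of abdominal tergite VIII;") %in% tx)
  expect_true(paste0("male organism, left ventral conjunctiva of paramere: ",
                     "thickness similar in magnitude relative to thickness of ",
                     "right ventral conjunctiva of paramere of male organism;") %in% tx)
})

test_that("between-species comparisons emit the full sentence, or the legacy stub on request", {
  inf <- materialize(compile_pattern_document(), fixture_tbox())
  tx <- nl_text(generate_nl(inf, "grebennikovius_armiger"))
  full <- grep("^the length of the hind wing", tx, value = TRUE)
  expect_length(full, 1L)
  expect_match(full, "smaller than")
  expect_match(full, "hind wing of the male organism of Grebennikovius basilewskyi;")
  legacy <- nl_text(generate_nl(inf, "grebennikovius_armiger",
                                legacy_asterisk = TRUE))
  expect_true("hind wing: length;*" %in% legacy)
})

test_that("a comparison with a missing foreign operand is a dangling reference", {
  inf <- materialize(compile_pattern_document(), fixture_tbox())
  cmp <- inf$base$assertions[inf$base$assertions$predicate ==
                             "ro-decreased_in_magnitude_relative_to", ]
  cmp <- cmp[inf$base$individuals$otu[match(cmp$object,
                                            inf$base$individuals$id)] ==
             "grebennikovius_basilewskyi", ][1, ]
  broken <- inf
  keep <- !(broken$base$assertions$subject == cmp$object &
            broken$base$assertions$predicate == "ro-characteristic_of")
  broken$base$assertions <- broken$base$assertions[keep, ]
  expect_error(render_between_species(broken, cmp), "missing foreign operand")
})

test_that("every base individual of the OTU appears in at least one line", {
  inf <- materialize(compile_pattern_document(), fixture_tbox())
  doc <- generate_nl(inf, "grebennikovius_armiger")
  covered <- unique(unlist(lapply(doc$lines, function(l) l$inds)))
  ind <- inf$base$individuals
  focal <- ind$id[ind$otu == "grebennikovius_armiger" & !ind$skolem]
  expect_true(all(focal %in% c(covered, "grebennikovius_armiger/organism")))
})

test_that("NL generation is deterministic and nesting elides shared locators reversibly", {
  inf <- materialize(compile_pattern_document(), fixture_tbox())
  d1 <- generate_nl(inf, "grebennikovius_armiger")
  d2 <- generate_nl(inf, "grebennikovius_armiger")
  expect_identical(nl_text(d1), nl_text(d2))
  nested <- nl_text(d1, nested = TRUE)
  expect_length(nested, length(nl_text(d1)))
  expect_true(any(grepl("^  ", nested)))
})

test_that("hyperlink annotation wraps every distinct term label exactly once per line", {
  doc <- pattern_nl()
  md <- annotate_links(doc, "markdown")
  body <- md[-seq_along(doc$header)]
  for (k in seq_along(doc$lines)) {
    n_links <- lengths(regmatches(body[k], gregexpr("\\]\\(", body[k])))
    expect_equal(n_links, length(doc$lines[[k]]$links), info = body[k])
  }
  # html and plain renderings
  html <- annotate_links(doc, "html")
  expect_true(any(grepl("<a href=", html)))
  plain <- annotate_links(doc, "text")
  expect_false(any(grepl("\\]\\(|<a href", plain)))
  # a known term links to its ontology IRI
  expect_true(any(grepl("\\[pronotum\\]\\(https://w3id.org/phenoscribe/aism/pronotum\\)",
                        md)))
})
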