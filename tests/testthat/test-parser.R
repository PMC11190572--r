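test_that("the lexer tokenizes terms, tags, OTU bindings and options", {
  toks <- ps_lex("pato-length:id-d38816[exclude = True]")
  expect_identical(toks$type, c("TERM", "COLON", "TERM", "PUNCT", "IDENT",
                                "PUNCT", "IDENT", "PUNCT"))
  toks2 <- ps_lex("uberon-male_organism::grebennikovius_armiger")
  expect_identical(toks2$type[1:3], c("TERM", "DCOLON", "IDENT"))
  expect_equal(nrow(ps_lex("")), 0L)
  expect_error(ps_lex("aism-x @ aism-y"), "illegal character")
})

test_that("chains, negation and node lists parse into alternating ASTs", {
  s <- parse_statement(
    "uberon-male_organism > aism-metafemur > bspo-dorsal_margin > aism-cuticular_carina;")
  expect_length(s$elements, 7L)
  kinds <- vapply(s$elements, function(e) class(e)[1], character(1))
  expect_identical(kinds, rep(c("ps_node", "ps_edge"), length.out = 7L))

  s2 <- parse_statement(
    "uberon-male_organism !> colao-posterior_longitudinal_hypomeral_carina;")
  expect_true(s2$elements[[2]]$negated)

  s3 <- parse_statement("uberon-male_organism >> (pato-ovate, pato-flattened);")
  expect_identical(s3$elements[[3]]$kind, "list")
  expect_length(s3$elements[[3]]$items, 2L)
})

test_that("dotted properties, tags and terminal literals parse", {
  s <- parse_statement(paste0(
    "uberon-male_organism >> pato-length ",
    ".iao-is_quality_measured_as iao-measurement_datum:md-c4c164 ",
    ".aism-has_unit unit-millimeter;"))
  expect_identical(s$elements[[4]]$property, "iao-is_quality_measured_as")
  expect_identical(s$elements[[5]]$tag, "md-c4c164")

  s2 <- parse_statement(
    "iao-measurement_datum:md-c4c164 .iao-has_measurement_value 4.5;")
  last <- s2$elements[[length(s2$elements)]]
  expect_identical(last$kind, "literal")
  expect_equal(last$value, 4.5)
})

test_that("both OTU-binding spellings are accepted when the OTU is declared", {
  otus <- c("grebennikovius_armiger", "grebennikovius_basilewskyi")
  s <- parse_statement("uberon-male_organism::grebennikovius_armiger > aism-hind_wing;",
                       declared_otus = otus)
  expect_identical(s$elements[[1]]$otu, "grebennikovius_armiger")
  s2 <- parse_statement("uberon-male_organism:grebennikovius_basilewskyi > aism-hind_wing;",
                        declared_otus = otus)
  expect_identical(s2$elements[[1]]$otu, "grebennikovius_basilewskyi")
  # same suffix with no declaration is an identity tag
  s3 <- parse_statement("uberon-male_organism:grebennikovius_basilewskyi > aism-hind_wing;")
  expect_identical(s3$elements[[1]]$tag, "grebennikovius_basilewskyi")
})

test_that("structural errors are reported with positions", {
  expect_error(parse_statement("aism-a > aism-b > ;"), "end with a node")
  expect_error(parse_statement("> aism-b;"), "begin with a node")
  expect_error(parse_statement("aism-a > aism-b"), "unterminated")
  expect_error(parse_document(c("OTU grebennikovius_armiger ;",
                                "zzz-term > aism-protibia;"),
                              fixture_config()), "unresolved prefix")
  expect_error(parse_document("aism-a > aism-b;", fixture_config()),
               "before any OTU")
  expect_warning(parse_statement("aism-a[foo = bar] > aism-b;"),
                 "unknown node option")
})

test_that("every printed pattern statement parses and round-trips idempotently", {
  otus <- c("grebennikovius_armiger", "grebennikovius_basilewskyi")
  for (src in pattern_statements()) {
    s <- parse_statement(src, declared_otus = otus)
    canon <- unparse_statement(s)
    s2 <- parse_statement(canon, declared_otus = otus)
    expect_identical(unparse_statement(s2), canon, info = src)
  }
})

test_that("documents preserve statement order and OTU ownership", {
  doc <- parse_document(pattern_document(), fixture_config())
  expect_s3_class(doc, "ps_document")
  expect_identical(doc$otus, "grebennikovius_armiger")
  expect_length(doc$statements, length(pattern_statements()))
  owners <- vapply(doc$statements, function(s) s$otu, character(1))
  expect_true(all(owners == "grebennikovius_armiger"))
  # canonical unparse re-parses to the same canonical text
  canon <- unparse_document(doc)
  doc2 <- parse_document(canon, fixture_config())
  expect_identical(unparse_document(doc2), canon)
})
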