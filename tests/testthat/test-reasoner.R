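test_that("type closure follows subclass axioms", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-gena >> pato-red;"),
                        fixture_config())
  inf <- materialize(compile_abox(doc, tb), tb)
  red <- inf$base$individuals$id[inf$base$individuals$cls == "pato-red"]
  expect_true("pato-colour" %in% inf$types[[red]])
  expect_true("pato-quality" %in% inf$types[[red]])
})

test_that("part-of closure combines asserted edges, inversion and class axioms", {
  tb <- fixture_tbox()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-antenna_with_9_antennomeres > aism-antennal_club > aism-flagellomere_5;"),
                        fixture_config())
  inf <- materialize(compile_abox(doc, tb), tb)
  ind <- inf$base$individuals
  flag <- ind$id[ind$cls == "aism-flagellomere_5"]
  club <- ind$id[ind$cls == "aism-antennal_club"]
  antenna <- ind$id[ind$cls == "aism-antenna_with_9_antennomeres"]
  # transitive closure through the two has_part edges (inverted)
  expect_true(all(c(club, antenna) %in% inf$part_closure[[flag]]))
  # the flagellomere classifies into the head region through the class spine
  expect_true(flag %in% classify_into(inf, "head_or_part"))
})

test_that("skolemization mints one palpomere per axiom and suppresses witnessed parts", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-maxillary_palpus_with_4_palpomeres;"),
                        cfg)
  inf <- materialize(compile_abox(doc, tb), tb)
  sk <- inf$base$individuals[inf$base$individuals$skolem, ]
  expect_equal(sum(grepl("maxillary_palpomere", sk$cls)), 4L)

  # an asserted palpomere part suppresses its skolem
  doc2 <- parse_document(c("OTU grebennikovius_armiger ;",
                           "uberon-male_organism > aism-maxillary_palpus_with_4_palpomeres > aism-maxillary_palpomere_I;"),
                         cfg)
  inf2 <- materialize(compile_abox(doc2, tb), tb)
  sk2 <- inf2$base$individuals[inf2$base$individuals$skolem, ]
  expect_equal(sum(grepl("maxillary_palpomere", sk2$cls)), 3L)
  expect_false("aism-maxillary_palpomere_I" %in% sk2$cls)
})

test_that("materialization is idempotent and skolem ids are deterministic", {
  tb <- fixture_tbox()
  g <- compile_pattern_document()
  inf1 <- materialize(g, tb)
  inf2 <- materialize(inf1, tb)
  expect_equal(nrow(inf2$base$individuals), nrow(inf1$base$individuals))
  expect_equal(nrow(inf2$base$assertions), nrow(inf1$base$assertions))
  inf3 <- materialize(g, tb)
  expect_identical(sort(inf3$base$individuals$id),
                   sort(inf1$base$individuals$id))
})

test_that("denied parts clash only when the denied class is asserted or inferred", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  doc <- parse_document(c("OTU grebennikovius_armiger ;",
                          "uberon-male_organism > aism-protibia:id-pt !> aism-dorsal_protibial_cuticular_tooth_4;"),
                        cfg)
  inf <- materialize(compile_abox(doc, tb), tb)
  expect_true(inf$consistent)

  doc2 <- parse_document(c("OTU grebennikovius_armiger ;",
                           "uberon-male_organism > aism-protibia:id-pt !> aism-dorsal_protibial_cuticular_tooth_4;",
                           "uberon-male_organism > aism-protibia:id-pt > aism-dorsal_protibial_cuticular_tooth_4;"),
                         cfg)
  inf2 <- materialize(compile_abox(doc2, tb), tb)
  expect_false(inf2$consistent)
  expect_equal(inf2$clashes[[1]]$kind, "denied_part")
  expect_identical(inf2$clashes[[1]]$denied_class,
                   "aism-dorsal_protibial_cuticular_tooth_4")
})

test_that("disjoint classes co-asserted through subtyping are inconsistent", {
  # oracle: direct check of the disjointness pair against the type closure
  tmp <- tempfile(fileext = ".ttl")
  writeLines(c(
    '@prefix pato: <https://w3id.org/phenoscribe/pato/> .',
    '@prefix aism: <https://w3id.org/phenoscribe/aism/> .',
    '@prefix uberon: <https://w3id.org/phenoscribe/uberon/> .',
    '@prefix ro: <https://w3id.org/phenoscribe/ro/> .',
    '@prefix phs: <https://w3id.org/phenoscribe/> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    'ro:has_characteristic a owl:ObjectProperty ; phs:alias ">>" .',
    'ro:has_part a owl:ObjectProperty ; phs:alias ">" .',
    'uberon:male_organism a owl:Class .',
    'pato:red a owl:Class ; owl:disjointWith pato:yellow .',
    'pato:yellow a owl:Class .',
    'pato:reddish_yellow a owl:Class ; rdfs:subClassOf pato:red , pato:yellow .'),
    tmp)
  tb <- load_tbox(tmp)
  cfg <- list(prefixes = tb$prefixes,
              otus = list(list(id = "otu_a", taxon_id = "urn:a",
                               catalog_number = "urn:c")))
  doc <- parse_document(c("OTU otu_a ;",
                          "uberon-male_organism >> pato-reddish_yellow;"), cfg)
  inf <- materialize(compile_abox(doc, tb), tb)
  expect_false(inf$consistent)
  expect_equal(inf$clashes[[1]]$kind, "disjoint")
  bad <- inf$clashes[[1]]$subject
  expect_true(all(c("pato-red", "pato-yellow") %in% inf$types[[bad]]))
})

test_that("defined-class extensions match a naive fixpoint oracle on random graphs", {
  tb <- fixture_tbox()
  cfg <- fixture_config()
  ents <- phenoscribe:::synthetic_entity_pool()
  anc <- subclass_ancestors(tb)
  set.seed(42)
  for (trial in 1:20) {
    # random organism-rooted chains over the entity pool
    n_chain <- sample(2:6, 1)
    lines <- "OTU grebennikovius_armiger ;"
    for (k in seq_len(n_chain)) {
      depth <- sample(1:3, 1)
      picks <- ents$curie[sample.int(nrow(ents), depth)]
      lines <- c(lines, paste0("uberon-male_organism > ",
                               paste(picks, collapse = " > "), ";"))
    }
    doc <- parse_document(lines, cfg)
    g <- compile_abox(doc, tb)
    inf <- materialize(g, tb)
    # oracle: naive reachability over assertion edges + class axioms
    ind <- inf$base$individuals
    asrt <- inf$base$assertions
    part_edges <- rbind(
      data.frame(from = asrt$subject[asrt$predicate == "ro-part_of" &
                                     !is.na(asrt$object)],
                 to = asrt$object[asrt$predicate == "ro-part_of" &
                                  !is.na(asrt$object)]),
      data.frame(from = asrt$object[asrt$predicate == "ro-has_part" &
                                    !is.na(asrt$object)],
                 to = asrt$subject[asrt$predicate == "ro-has_part" &
                                   !is.na(asrt$object)]))
    wholes_of <- function(id) {
      seen <- character(0); frontier <- id
      while (length(frontier)) {
        nxt <- setdiff(part_edges$to[part_edges$from %in% frontier], seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      seen
    }
    class_up <- function(cls) c(cls, anc[[cls]])
    class_wholes <- function(cls) {
      seen <- character(0); frontier <- class_up(cls)
      repeat {
        direct <- unique(tb$part_axioms$whole[tb$part_axioms$cls %in% frontier])
        direct <- unique(unlist(lapply(direct, class_up)))
        new <- setdiff(direct, seen)
        if (!length(new)) break
        seen <- c(seen, new); frontier <- new
      }
      seen
    }
    for (region in c("head_or_part", "thorax_or_part", "abdomen_or_part",
                     "leg_or_part")) {
      base_cls <- tb$defined$base[tb$defined$name == region]
      oracle <- ind$id[vapply(seq_len(nrow(ind)), function(i) {
        classes <- unique(unlist(lapply(
          c(ind$id[i], wholes_of(ind$id[i])),
          function(j) class_up(ind$cls[match(j, ind$id)]))))
        base_cls %in% classes ||
          any(vapply(classes, function(cc) base_cls %in% class_wholes(cc),
                     logical(1)))
      }, logical(1))]
      expect_setequal(classify_into(inf, region), oracle)
    }
  }
})
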