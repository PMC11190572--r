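# ABox compiler: turns a parsed description document into a knowledge graph
# of ontology individuals. Identity rules: untagged term occurrences are
# statement-scoped individuals; tagged occurrences merge across statements
# within an OTU; "exclude"-marked nodes are owned by the foreign OTU named
# in the same statement and never count toward the focal description.

IND_NS <- paste0(PHS_NS, "ind/")

abox_empty <- function(prefixes = character()) {
  structure(list(
    individuals = data.frame(id = character(), cls = character(),
                             otu = character(), tag = character(),
                             stmt = integer(), pos = integer(),
                             skolem = logical(), stringsAsFactors = FALSE),
    assertions = data.frame(ord = integer(), stmt = integer(),
                            subject = character(), predicate = character(),
                            object = character(), literal = numeric(),
                            object_class = character(), polarity = character(),
                            stringsAsFactors = FALSE),
    otus = data.frame(otu_id = character(), label = character(),
                      taxon_id = character(), parent_id = character(),
                      catalog_number = character(), habitat = character(),
                      organism_class = character(), organism_id = character(),
                      stringsAsFactors = FALSE),
    prefixes = prefixes
  ), class = "phs_abox")
}

#' @export
print.phs_abox <- function(x, ...) {
  cat(sprintf("<phs_abox: %d individuals, %d assertions, %d OTUs>\n",
              nrow(x$individuals), nrow(x$assertions), nrow(x$otus)))
  invisible(x)
}

#' Compile a parsed document into the ABox knowledge graph
#'
#' One individual is minted per untagged term occurrence (scoped to its
#' statement and chain position, skolem id `<otu>/s<stmt>/p<pos>`); tagged
#' occurrences merge across statements (`<otu>/<tag>`). Alias glyphs map to
#' their object properties; node lists distribute the incoming edge over
#' every item; `!>` records a negated has-part assertion whose object stays
#' at the class level (an existence denial, not an individual).
#'
#' @param doc a `ps_document` from [parse_document()].
#' @param tbox a `phs_tbox`; every term and property must resolve in it.
#' @return A `phs_abox` knowledge graph.
#' @export
compile_abox <- function(doc, tbox) {
  graph <- abox_empty(prefixes = tbox$prefixes)

  # OTU records (all declared OTUs, so foreign references resolve)
  for (o in doc$config$otus) {
    org_id <- paste0(o$id, "/organism")
    graph$otus <- rbind(graph$otus, data.frame(
      otu_id = o$id,
      label = if (is.null(o$label)) gsub("_", " ", o$id) else o$label,
      taxon_id = if (is.null(o$taxon_id)) NA_character_ else o$taxon_id,
      parent_id = if (is.null(o$parent_name_usage_id)) NA_character_
                  else o$parent_name_usage_id,
      catalog_number = if (is.null(o$catalog_number)) NA_character_
                       else o$catalog_number,
      habitat = if (is.null(o$habitat)) NA_character_ else o$habitat,
      organism_class = o$organism_class,
      organism_id = org_id,
      stringsAsFactors = FALSE))
  }

  # strict vocabulary check: collect every missing term before failing
  missing <- character(0)
  walk_nodes <- function(stmt, f) {
    for (el in stmt$elements) {
      if (inherits(el, "ps_node")) {
        if (el$kind == "term") f(el)
        if (el$kind == "list") for (it in el$items) f(it)
      }
    }
  }
  for (stmt in doc$statements) {
    walk_nodes(stmt, function(el) {
      if (!tbox_has_class(tbox, el$term)) missing <<- c(missing, el$term)
    })
    for (el in stmt$elements) {
      if (inherits(el, "ps_edge")) {
        key <- if (el$negated) ">" else if (!is.na(el$glyph)) el$glyph
               else el$property
        if (is.null(tbox_property(tbox, key))) missing <- c(missing, key)
      }
    }
  }
  if (length(missing)) {
    stop(sprintf("compile error: unresolved terms: %s",
                 paste(sort(unique(missing)), collapse = ", ")),
         call. = FALSE)
  }

  env <- new.env(parent = emptyenv())
  env$ind <- list()   # id -> row list
  env$asrt <- list()
  env$ord <- 0L

  get_ind <- function(id) env$ind[[id]]
  put_ind <- function(id, cls, otu, tag = NA_character_, stmt = NA_integer_,
                      pos = NA_integer_) {
    ex <- env$ind[[id]]
    if (!is.null(ex)) {
      if (!identical(ex$cls, cls)) {
        stop(sprintf(
          "tag conflict: individual '%s' declared as %s and as %s",
          id, ex$cls, cls), call. = FALSE)
      }
      return(id)
    }
    env$ind[[id]] <- list(id = id, cls = cls, otu = otu, tag = tag,
                          stmt = stmt, pos = pos, skolem = FALSE)
    id
  }
  assert <- function(stmt_i, s, p, o = NA_character_, lit = NA_real_,
                     ocls = NA_character_, polarity = "pos") {
    env$ord <- env$ord + 1L
    env$asrt[[env$ord]] <- list(ord = env$ord, stmt = stmt_i, subject = s,
                                predicate = p, object = o, literal = lit,
                                object_class = ocls, polarity = polarity)
  }

  otu_row <- function(otu_id) graph$otus[graph$otus$otu_id == otu_id, ]

  # organism individuals
  for (k in seq_len(nrow(graph$otus))) {
    put_ind(graph$otus$organism_id[k], graph$otus$organism_class[k],
            graph$otus$otu_id[k])
  }

  for (i in seq_along(doc$statements)) {
    stmt <- doc$statements[[i]]
    focal <- stmt$otu
    # foreign OTU referenced by exclude-marked nodes in this statement
    foreign <- NA_character_
    walk_nodes(stmt, function(el) {
      if (isTRUE(el$exclude) && !is.na(el$otu)) foreign <<- el$otu
    })
    if (!is.na(foreign)) {
      if (identical(foreign, focal)) {
        stop(sprintf(
          "statement %d: 'exclude' names the focal OTU '%s'", i, focal),
          call. = FALSE)
      }
      if (!foreign %in% graph$otus$otu_id) {
        stop(sprintf("statement %d: unknown OTU '%s'", i, foreign),
             call. = FALSE)
      }
    }

    resolve <- function(el, pos) {
      owner <- if (isTRUE(el$exclude)) {
        if (is.na(foreign)) {
          stop(sprintf(
            "statement %d: 'exclude' node has no foreign OTU in reach", i),
            call. = FALSE)
        }
        foreign
      } else if (!is.na(el$otu)) el$otu else focal
      if (!owner %in% graph$otus$otu_id) {
        stop(sprintf("statement %d: unknown OTU '%s'", i, owner),
             call. = FALSE)
      }
      orow <- otu_row(owner)
      if (identical(el$term, orow$organism_class) && is.na(el$tag)) {
        return(orow$organism_id)
      }
      if (!is.na(el$tag)) {
        return(put_ind(paste0(owner, "/", el$tag), el$term, owner,
                       tag = el$tag, stmt = i, pos = pos))
      }
      put_ind(sprintf("%s/s%d/p%d", owner, i, pos), el$term, owner,
              stmt = i, pos = pos)
    }

    els <- stmt$elements
    first <- els[[1]]
    if (first$kind == "list") {
      stop(sprintf("statement %d: cannot begin with a node list", i),
           call. = FALSE)
    }
    current <- resolve(first, 1L)
    pos <- 1L
    k <- 2L
    while (k <= length(els)) {
      edge <- els[[k]]
      node <- els[[k + 1L]]
      key <- if (edge$negated) ">" else if (!is.na(edge$glyph)) edge$glyph
             else edge$property
      prop <- tbox_property(tbox, key)
      if (edge$negated) {
        if (node$kind != "term") {
          stop(sprintf("statement %d: '!>' requires a class object", i),
               call. = FALSE)
        }
        assert(i, current, prop$curie, ocls = node$term, polarity = "neg")
        # negated object is a class-level denial; chain cannot continue
        if (k + 1L < length(els)) {
          stop(sprintf("statement %d: chain continues after a negated edge",
                       i), call. = FALSE)
        }
        break
      }
      if (node$kind == "literal") {
        assert(i, current, prop$curie, lit = node$value)
        if (k + 1L < length(els)) {
          stop(sprintf("statement %d: chain continues after a literal", i),
               call. = FALSE)
        }
        break
      }
      if (node$kind == "list") {
        for (it in node$items) {
          pos <- pos + 1L
          ind <- resolve(it, pos)
          assert(i, current, prop$curie, o = ind)
        }
        if (k + 1L < length(els)) {
          stop(sprintf("statement %d: chain continues after a node list", i),
               call. = FALSE)
        }
        break
      }
      pos <- pos + 1L
      ind <- resolve(node, pos)
      assert(i, current, prop$curie, o = ind)
      current <- ind
      k <- k + 2L
    }
  }

  graph$individuals <- do.call(rbind, lapply(env$ind, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  rownames(graph$individuals) <- NULL
  if (length(env$asrt)) {
    graph$assertions <- do.call(rbind, lapply(env$asrt, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  }
  graph
}

#' Resolve an exclude-marked node to its foreign-owned individual
#'
#' Comparison statements may reference entities of another OTU; those
#' operands are owned by the foreign OTU and excluded from the focal
#' description's individual tally. Given a compiled graph and the node,
#' this returns the matching individual row.
#'
#' @param graph a compiled `phs_abox`.
#' @param node a `ps_node` with `exclude = TRUE` (tag or OTU binding set),
#'   or an ordinary node, which resolves against the focal OTU.
#' @param focal_otu the focal OTU id (used for non-exclude nodes).
#' @return One row of `graph$individuals`.
#' @export
resolve_cross_otu <- function(graph, node, focal_otu = NULL) {
  ind <- graph$individuals
  if (isTRUE(node$exclude)) {
    if (!is.na(node$tag)) {
      hit <- ind[!is.na(ind$tag) & ind$tag == node$tag, , drop = FALSE]
    } else if (!is.na(node$otu)) {
      hit <- ind[ind$otu == node$otu & ind$cls == node$term, , drop = FALSE]
    } else {
      hit <- ind[ind$cls == node$term &
                 (is.null(focal_otu) | ind$otu != focal_otu), , drop = FALSE]
    }
    if (nrow(hit) == 0L) {
      stop(sprintf("no foreign individual matches node '%s'", node$term),
           call. = FALSE)
    }
    if (!is.null(focal_otu) && any(hit$otu == focal_otu)) {
      stop("'exclude' node resolves to the focal OTU", call. = FALSE)
    }
    return(hit[1, ])
  }
  hit <- ind[ind$cls == node$term &
             (if (is.null(focal_otu)) TRUE else ind$otu == focal_otu), ,
             drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("no individual matches node '%s'", node$term), call. = FALSE)
  }
  hit[1, ]
}

ind_iri <- function(id) paste0(IND_NS, id)

abox_serial_prefixes <- function(graph) {
  pfx <- c(graph$prefixes,
           rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS,
           phs = PHS_NS, obo = OBO_NS)
  pfx[!duplicated(names(pfx))]
}

#' Serialize a knowledge graph to canonical Turtle
#'
#' Emits typed individuals with their OTU-membership, tag and provenance
#' annotations, positive assertions as plain triples, negated has-part
#' assertions as a class assertion of the complement of an existential
#' restriction, and one reified provenance resource per assertion so the
#' graph reloads losslessly. Output is deterministic: two runs on the same
#' graph are byte-identical.
#'
#' @param graph a `phs_abox` (compiled, optionally materialized).
#' @param tbox the `phs_tbox` used to resolve term IRIs.
#' @param path optional output file.
#' @return Turtle text.
#' @export
serialize_abox <- function(graph, tbox, path = NULL) {
  rows <- list()
  add <- function(s, p, o, o_type = "iri", o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- rdf_triple_row(s, p, o, o_type, o_dt)
  }
  rdf_type <- paste0(RDF_NS, "type")
  xsd_int <- paste0(XSD_NS, "integer")
  xsd_dec <- paste0(XSD_NS, "decimal")
  xsd_bool <- paste0(XSD_NS, "boolean")

  for (k in seq_len(nrow(graph$otus))) {
    o <- graph$otus[k, ]
    s <- paste0(PHS_NS, "otu/", o$otu_id)
    add(s, rdf_type, paste0(PHS_NS, "OTU"))
    add(s, paste0(RDFS_NS, "label"), o$label, "literal")
    add(s, paste0(PHS_NS, "otuId"), o$otu_id, "literal")
    if (!is.na(o$taxon_id)) add(s, paste0(PHS_NS, "taxonID"), o$taxon_id)
    if (!is.na(o$parent_id)) {
      add(s, paste0(PHS_NS, "parentNameUsageID"), o$parent_id)
    }
    if (!is.na(o$catalog_number)) {
      add(s, paste0(PHS_NS, "catalogNumber"), o$catalog_number)
    }
    if (!is.na(o$habitat)) add(s, paste0(PHS_NS, "habitat"), o$habitat,
                               "literal")
    add(s, paste0(PHS_NS, "organismClass"), o$organism_class, "literal")
    add(s, paste0(PHS_NS, "organism"), ind_iri(o$organism_id))
  }

  for (k in seq_len(nrow(graph$individuals))) {
    r <- graph$individuals[k, ]
    s <- ind_iri(r$id)
    add(s, rdf_type, paste0(OWL_NS, "NamedIndividual"))
    add(s, rdf_type, term_iri(tbox, r$cls))
    add(s, paste0(PHS_NS, "indId"), r$id, "literal")
    add(s, paste0(PHS_NS, "otu"), r$otu, "literal")
    if (!is.na(r$tag)) add(s, paste0(PHS_NS, "tag"), r$tag, "literal")
    if (!is.na(r$stmt)) add(s, paste0(PHS_NS, "stmtIndex"),
                            as.character(r$stmt), "literal", xsd_int)
    if (!is.na(r$pos)) add(s, paste0(PHS_NS, "chainPos"),
                           as.character(r$pos), "literal", xsd_int)
    if (isTRUE(r$skolem)) add(s, paste0(PHS_NS, "skolem"), "true", "literal",
                              xsd_bool)
  }

  bn <- 0L
  for (k in seq_len(nrow(graph$assertions))) {
    a <- graph$assertions[k, ]
    s <- ind_iri(a$subject)
    p_iri <- term_iri(tbox, a$predicate)
    ann <- paste0(PHS_NS, "assertion/", a$ord)
    add(ann, rdf_type, paste0(PHS_NS, "Assertion"))
    add(ann, paste0(PHS_NS, "ord"), as.character(a$ord), "literal", xsd_int)
    if (!is.na(a$stmt)) add(ann, paste0(PHS_NS, "stmtIndex"),
                            as.character(a$stmt), "literal", xsd_int)
    add(ann, paste0(PHS_NS, "subj"), s)
    add(ann, paste0(PHS_NS, "pred"), p_iri)
    add(ann, paste0(PHS_NS, "polarity"), a$polarity, "literal")
    if (a$polarity == "neg") {
      cls_iri <- term_iri(tbox, a$object_class)
      add(ann, paste0(PHS_NS, "objClass"), cls_iri)
      # s rdf:type [ owl:complementOf [ Restriction has_part some C ] ]
      bn <- bn + 1L; comp <- sprintf("_:c%d", bn)
      bn <- bn + 1L; restr <- sprintf("_:c%d", bn)
      add(s, rdf_type, comp, "blank")
      add(comp, rdf_type, paste0(OWL_NS, "Class"))
      add(comp, paste0(OWL_NS, "complementOf"), restr, "blank")
      add(restr, rdf_type, paste0(OWL_NS, "Restriction"))
      add(restr, paste0(OWL_NS, "onProperty"), p_iri)
      add(restr, paste0(OWL_NS, "someValuesFrom"), cls_iri)
    } else if (!is.na(a$literal)) {
      lit <- format(a$literal, trim = TRUE, scientific = FALSE)
      add(ann, paste0(PHS_NS, "objLit"), lit, "literal", xsd_dec)
      add(s, p_iri, lit, "literal", xsd_dec)
    } else {
      add(ann, paste0(PHS_NS, "objInd"), ind_iri(a$object))
      add(s, p_iri, ind_iri(a$object))
    }
  }

  g <- rdf_graph(do.call(rbind, rows), abox_serial_prefixes(graph))
  serialize_turtle(g, path)
}

#' Load a knowledge graph serialized by [serialize_abox()]
#'
#' @param x Turtle text or a file path.
#' @param tbox the `phs_tbox` used to map IRIs back to curies.
#' @return A `phs_abox` equal to the serialized graph.
#' @export
load_abox <- function(x, tbox) {
  g <- parse_turtle(x)
  tr <- g$triples
  rdf_type <- paste0(RDF_NS, "type")
  graph <- abox_empty(prefixes = tbox$prefixes)
  one <- function(s, p) {
    v <- tr$o[tr$s == s & tr$p == p]
    if (length(v)) v[1] else NA_character_
  }
  curie_of <- function(iri) {
    hit <- match(iri, tbox$classes$iri)
    if (!is.na(hit)) return(tbox$classes$curie[hit])
    hit <- match(iri, tbox$properties$iri)
    if (!is.na(hit)) return(tbox$properties$curie[hit])
    iri_to_curie(iri, tbox$prefixes)
  }

  otu_subjects <- sort(unique(tr$s[tr$p == rdf_type &
                                   tr$o == paste0(PHS_NS, "OTU")]))
  for (s in otu_subjects) {
    org_iri <- one(s, paste0(PHS_NS, "organism"))
    graph$otus <- rbind(graph$otus, data.frame(
      otu_id = one(s, paste0(PHS_NS, "otuId")),
      label = one(s, paste0(RDFS_NS, "label")),
      taxon_id = one(s, paste0(PHS_NS, "taxonID")),
      parent_id = one(s, paste0(PHS_NS, "parentNameUsageID")),
      catalog_number = one(s, paste0(PHS_NS, "catalogNumber")),
      habitat = one(s, paste0(PHS_NS, "habitat")),
      organism_class = one(s, paste0(PHS_NS, "organismClass")),
      organism_id = substring(org_iri, nchar(IND_NS) + 1L),
      stringsAsFactors = FALSE))
  }

  ind_subjects <- sort(unique(tr$s[tr$p == paste0(PHS_NS, "indId")]))
  ind_rows <- lapply(ind_subjects, function(s) {
    types <- tr$o[tr$s == s & tr$p == rdf_type & tr$o_type == "iri"]
    types <- setdiff(types, paste0(OWL_NS, "NamedIndividual"))
    cls <- curie_of(types[1])
    data.frame(id = one(s, paste0(PHS_NS, "indId")), cls = cls,
               otu = one(s, paste0(PHS_NS, "otu")),
               tag = one(s, paste0(PHS_NS, "tag")),
               stmt = as.integer(one(s, paste0(PHS_NS, "stmtIndex"))),
               pos = as.integer(one(s, paste0(PHS_NS, "chainPos"))),
               skolem = identical(one(s, paste0(PHS_NS, "skolem")), "true"),
               stringsAsFactors = FALSE)
  })
  if (length(ind_rows)) graph$individuals <- do.call(rbind, ind_rows)

  ann_subjects <- tr$s[tr$p == rdf_type & tr$o == paste0(PHS_NS, "Assertion")]
  ords <- as.integer(vapply(ann_subjects, function(s)
    one(s, paste0(PHS_NS, "ord")), character(1)))
  ann_subjects <- ann_subjects[order(ords)]
  asrt_rows <- lapply(ann_subjects, function(s) {
    obj_ind <- one(s, paste0(PHS_NS, "objInd"))
    obj_cls <- one(s, paste0(PHS_NS, "objClass"))
    obj_lit <- one(s, paste0(PHS_NS, "objLit"))
    data.frame(
      ord = as.integer(one(s, paste0(PHS_NS, "ord"))),
      stmt = as.integer(one(s, paste0(PHS_NS, "stmtIndex"))),
      subject = substring(one(s, paste0(PHS_NS, "subj")),
                          nchar(IND_NS) + 1L),
      predicate = curie_of(one(s, paste0(PHS_NS, "pred"))),
      object = if (is.na(obj_ind)) NA_character_
               else substring(obj_ind, nchar(IND_NS) + 1L),
      literal = if (is.na(obj_lit)) NA_real_ else as.numeric(obj_lit),
      object_class = if (is.na(obj_cls)) NA_character_ else curie_of(obj_cls),
      polarity = one(s, paste0(PHS_NS, "polarity")),
      stringsAsFactors = FALSE)
  })
  if (length(asrt_rows)) graph$assertions <- do.call(rbind, asrt_rows)
  graph
}

#' Equality of two knowledge graphs
#' @param a,b `phs_abox` objects.
#' @return `TRUE` when individuals, assertions and OTU records coincide.
#' @export
abox_equal <- function(a, b) {
  norm <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  isTRUE(all.equal(norm(a$individuals), norm(b$individuals))) &&
    isTRUE(all.equal(norm(a$assertions), norm(b$assertions))) &&
    isTRUE(all.equal(norm(a$otus), norm(b$otus)))
}

#' Count base (non-skolem) individuals per OTU
#' @param graph a `phs_abox`.
#' @param otu optional OTU id filter.
#' @param include_skolems count reasoner-materialized parts too?
#' @return Named integer vector of counts per OTU.
#' @export
count_individuals <- function(graph, otu = NULL, include_skolems = FALSE) {
  ind <- graph$individuals
  if (!include_skolems) ind <- ind[!ind$skolem, , drop = FALSE]
  if (!is.null(otu)) ind <- ind[ind$otu %in% otu, , drop = FALSE]
  tab <- table(factor(ind$otu, levels = sort(unique(graph$otus$otu_id))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
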