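# TBox store: classes, properties, subclass axioms, class-level parthood,
# logical ("with_N_parts") definitions and defined region classes, loaded
# from Turtle files. Terms are addressed by dash-curies as written in
# description scripts ("aism-protibia"); IRIs are kept alongside.

#' @noRd
tbox_empty <- function() {
  structure(list(
    prefixes = character(),
    classes = data.frame(curie = character(), iri = character(),
                         label = character(), stringsAsFactors = FALSE),
    subclass = data.frame(child = character(), parent = character(),
                          stringsAsFactors = FALSE),
    properties = data.frame(curie = character(), iri = character(),
                            label = character(), alias = character(),
                            transitive = logical(), inverse = character(),
                            category = character(), datatype = logical(),
                            stringsAsFactors = FALSE),
    part_axioms = data.frame(cls = character(), whole = character(),
                             stringsAsFactors = FALSE),
    logical_defs = data.frame(cls = character(), property = character(),
                              filler = character(), stringsAsFactors = FALSE),
    disjoint = data.frame(a = character(), b = character(),
                          stringsAsFactors = FALSE),
    defined = data.frame(name = character(), base = character(),
                         stringsAsFactors = FALSE)
  ), class = "phs_tbox")
}

#' @export
print.phs_tbox <- function(x, ...) {
  cat(sprintf(paste0("<phs_tbox: %d classes, %d properties, %d subclass ",
                     "axioms, %d part axioms, %d logical defs, %d defined ",
                     "classes>\n"),
              nrow(x$classes), nrow(x$properties), nrow(x$subclass),
              nrow(x$part_axioms), nrow(x$logical_defs), nrow(x$defined)))
  invisible(x)
}

# derive the dash-curie for an IRI given the description-language prefix map;
# longest base wins so nested namespaces resolve correctly
iri_to_curie <- function(iri, prefixes) {
  prefixes <- prefixes[order(-nchar(unname(prefixes)))]
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    if (startsWith(iri, base)) {
      return(paste0(pfx, "-", substring(iri, nchar(base) + 1L)))
    }
  }
  NA_character_
}

# split "aism-antero-distal_margin" at the first dash
split_curie <- function(curie) {
  m <- regmatches(curie, regexec("^([A-Za-z][A-Za-z0-9_]*)-(.+)$", curie))[[1]]
  if (length(m) == 0L) return(NULL)
  list(prefix = m[2], local = m[3])
}

humanize_label <- function(local) gsub("_", " ", local)

# non-term namespaces never used as description-language term prefixes
tbox_reserved_prefixes <- function() c("rdf", "rdfs", "owl", "xsd", "phs",
                                       "obo", "sh")

#' Load and merge TBox ontology files
#'
#' Reads one or more Turtle files declaring OWL classes, object/datatype
#' properties, `rdfs:subClassOf` axioms (named parents, class-level
#' `part_of` existential restrictions, and `has_part` existential
#' restrictions interpreted as logical "with N parts" definitions),
#' transitivity and inverse declarations, disjointness, and defined region
#' classes. Files are merged with axiom union; when the same IRI carries
#' conflicting labels, the first-loaded label wins with a warning.
#'
#' @param paths character vector of Turtle file paths.
#' @return A `phs_tbox` store.
#' @export
load_tbox <- function(paths) {
  store <- tbox_empty()
  for (path in paths) {
    if (!file.exists(path)) {
      stop(sprintf("TBox file not found: %s", path), call. = FALSE)
    }
    g <- parse_turtle(path)
    store <- tbox_absorb(store, g, path)
  }
  tbox_check(store)
  store
}

tbox_absorb <- function(store, g, path) {
  tr <- g$triples
  rdf_type <- paste0(RDF_NS, "type")
  term_prefixes <- g$prefixes[!names(g$prefixes) %in% tbox_reserved_prefixes()]
  for (pfx in names(term_prefixes)) {
    if (pfx %in% names(store$prefixes) &&
        store$prefixes[[pfx]] != term_prefixes[[pfx]]) {
      stop(sprintf("%s: prefix '%s' redeclared with a different base",
                   path, pfx), call. = FALSE)
    }
    store$prefixes[[pfx]] <- term_prefixes[[pfx]]
  }

  subj_of_type <- function(ty) unique(tr$s[tr$p == rdf_type &
                                           tr$o == paste0(OWL_NS, ty)])
  ann <- function(s, p_iri) {
    v <- tr$o[tr$s == s & tr$p == p_iri]
    if (length(v)) v[1] else NA_character_
  }
  curie_of <- function(iri) {
    explicit <- ann(iri, paste0(PHS_NS, "curie"))
    if (!is.na(explicit)) return(explicit)
    iri_to_curie(iri, store$prefixes)
  }
  label_of <- function(iri, curie) {
    lb <- ann(iri, paste0(RDFS_NS, "label"))
    if (!is.na(lb)) return(lb)
    parts <- split_curie(curie)
    if (is.null(parts)) curie else humanize_label(parts$local)
  }

  # ---- properties
  prop_iris <- union(subj_of_type("ObjectProperty"),
                     subj_of_type("DatatypeProperty"))
  trans_iris <- subj_of_type("TransitiveProperty")
  for (iri in sort(prop_iris)) {
    curie <- curie_of(iri)
    if (is.na(curie)) {
      stop(sprintf("%s: cannot derive a curie for property <%s>", path, iri),
           call. = FALSE)
    }
    inv_iri <- ann(iri, paste0(OWL_NS, "inverseOf"))
    row <- data.frame(
      curie = curie, iri = iri, label = label_of(iri, curie),
      alias = ann(iri, paste0(PHS_NS, "alias")),
      transitive = iri %in% trans_iris,
      inverse = NA_character_,
      category = {
        cat_ <- ann(iri, paste0(PHS_NS, "category"))
        if (is.na(cat_)) "core" else cat_
      },
      datatype = iri %in% subj_of_type("DatatypeProperty"),
      stringsAsFactors = FALSE)
    attr(row, "inverse_iri") <- inv_iri
    existing <- match(curie, store$properties$curie)
    if (is.na(existing)) {
      store$properties <- rbind(store$properties, row)
      if (!is.na(inv_iri)) {
        attr(store$properties, "pending_inverse") <-
          rbind(attr(store$properties, "pending_inverse"),
                data.frame(curie = curie, inv_iri = inv_iri,
                           stringsAsFactors = FALSE))
      }
    } else {
      store$properties$transitive[existing] <-
        store$properties$transitive[existing] || row$transitive
    }
  }
  # resolve inverse IRIs to curies once all properties are known
  pend <- attr(store$properties, "pending_inverse")
  if (!is.null(pend)) {
    for (k in seq_len(nrow(pend))) {
      i <- match(pend$curie[k], store$properties$curie)
      j <- match(pend$inv_iri[k], store$properties$iri)
      if (!is.na(i) && !is.na(j)) {
        store$properties$inverse[i] <- store$properties$curie[j]
        if (is.na(store$properties$inverse[j])) {
          store$properties$inverse[j] <- store$properties$curie[i]
        }
      }
    }
  }

  # ---- classes
  class_iris <- setdiff(subj_of_type("Class"), prop_iris)
  class_iris <- class_iris[!startsWith(class_iris, "_:")]
  for (iri in sort(class_iris)) {
    curie <- curie_of(iri)
    if (is.na(curie)) {
      stop(sprintf("%s: cannot derive a curie for class <%s>", path, iri),
           call. = FALSE)
    }
    lb <- label_of(iri, curie)
    existing <- match(curie, store$classes$curie)
    if (is.na(existing)) {
      store$classes <- rbind(store$classes,
                             data.frame(curie = curie, iri = iri, label = lb,
                                        stringsAsFactors = FALSE))
    } else if (!identical(store$classes$label[existing], lb) &&
               !is.na(ann(iri, paste0(RDFS_NS, "label")))) {
      warning(sprintf(
        "%s: label conflict for %s ('%s' vs '%s'); keeping first-loaded",
        path, curie, store$classes$label[existing], lb), call. = FALSE)
    }
  }

  # ---- subclass axioms, part axioms, logical defs
  part_of_iri <- function() {
    i <- match("ro-part_of", store$properties$curie)
    if (is.na(i)) NA_character_ else store$properties$iri[i]
  }
  has_part_iri <- function() {
    i <- match("ro-has_part", store$properties$curie)
    if (is.na(i)) NA_character_ else store$properties$iri[i]
  }
  sub_rows <- tr[tr$p == paste0(RDFS_NS, "subClassOf"), , drop = FALSE]
  for (k in seq_len(nrow(sub_rows))) {
    s_curie <- curie_of(sub_rows$s[k])
    o <- sub_rows$o[k]
    if (sub_rows$o_type[k] == "blank") {
      on_prop <- ann(o, paste0(OWL_NS, "onProperty"))
      filler <- ann(o, paste0(OWL_NS, "someValuesFrom"))
      if (is.na(on_prop) || is.na(filler)) next
      f_curie <- curie_of(filler)
      if (identical(on_prop, part_of_iri())) {
        store$part_axioms <- unique(rbind(
          store$part_axioms,
          data.frame(cls = s_curie, whole = f_curie, stringsAsFactors = FALSE)))
      } else if (identical(on_prop, has_part_iri())) {
        store$logical_defs <- unique(rbind(
          store$logical_defs,
          data.frame(cls = s_curie, property = "ro-has_part",
                     filler = f_curie, stringsAsFactors = FALSE)))
      }
    } else {
      o_curie <- curie_of(o)
      store$subclass <- unique(rbind(
        store$subclass,
        data.frame(child = s_curie, parent = o_curie,
                   stringsAsFactors = FALSE)))
    }
  }

  # ---- disjointness
  dj <- tr[tr$p == paste0(OWL_NS, "disjointWith"), , drop = FALSE]
  for (k in seq_len(nrow(dj))) {
    a <- curie_of(dj$s[k]); b <- curie_of(dj$o[k])
    pair <- sort(c(a, b))
    store$disjoint <- unique(rbind(
      store$disjoint,
      data.frame(a = pair[1], b = pair[2], stringsAsFactors = FALSE)))
  }

  # ---- defined region classes
  def_iris <- unique(tr$s[tr$p == rdf_type &
                          tr$o == paste0(PHS_NS, "DefinedClass")])
  for (iri in sort(def_iris)) {
    nm <- ann(iri, paste0(RDFS_NS, "label"))
    base_iri <- ann(iri, paste0(PHS_NS, "definedBase"))
    base <- curie_of(base_iri)
    store$defined <- unique(rbind(
      store$defined,
      data.frame(name = nm, base = base, stringsAsFactors = FALSE)))
  }
  attr(store$properties, "pending_inverse") <- NULL
  store
}

tbox_check <- function(store) {
  # subclass graph must be acyclic
  edges <- store$subclass
  if (nrow(edges)) {
    anc <- transitive_closure_pairs(edges$child, edges$parent)
    loops <- anc$from[anc$from == anc$to]
    if (length(loops)) {
      stop(sprintf("subclass cycle involving %s", loops[1]), call. = FALSE)
    }
  }
  # every axiom references declared classes
  declared <- store$classes$curie
  refs <- unique(c(store$subclass$child, store$subclass$parent,
                   store$part_axioms$cls, store$part_axioms$whole,
                   store$logical_defs$cls, store$logical_defs$filler,
                   store$defined$base))
  missing <- setdiff(refs, declared)
  if (length(missing)) {
    stop(sprintf("axioms reference undeclared classes: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(store)
}

# transitive closure of an edge relation given as parallel vectors;
# returns data.frame(from, to) of all reachable pairs (no reflexive pairs)
transitive_closure_pairs <- function(from, to) {
  pairs <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  repeat {
    joined <- merge(pairs, pairs, by.x = "to", by.y = "from")
    new_pairs <- unique(data.frame(from = joined$from, to = joined$to.y,
                                   stringsAsFactors = FALSE))
    merged <- unique(rbind(pairs, new_pairs))
    if (nrow(merged) == nrow(pairs)) return(merged)
    pairs <- merged
  }
}

#' Resolve a term curie to its IRI
#'
#' @param store a `phs_tbox`.
#' @param curie dash-curie such as `"aism-protibia"`.
#' @return The absolute IRI (declared, or minted from the prefix map).
#' @export
term_iri <- function(store, curie) {
  i <- match(curie, store$classes$curie)
  if (!is.na(i)) return(store$classes$iri[i])
  j <- match(curie, store$properties$curie)
  if (!is.na(j)) return(store$properties$iri[j])
  parts <- split_curie(curie)
  if (!is.null(parts) && parts$prefix %in% names(store$prefixes)) {
    return(paste0(store$prefixes[[parts$prefix]], parts$local))
  }
  stop(sprintf("unresolved term: %s", curie), call. = FALSE)
}

#' Human-readable label for a term curie
#' @inheritParams term_iri
#' @return The declared `rdfs:label`, or the underscore-to-space humanized
#'   local name when the term carries no label.
#' @export
term_label <- function(store, curie) {
  i <- match(curie, store$classes$curie)
  if (!is.na(i)) return(store$classes$label[i])
  j <- match(curie, store$properties$curie)
  if (!is.na(j)) return(store$properties$label[j])
  parts <- split_curie(curie)
  if (is.null(parts)) curie else humanize_label(parts$local)
}

tbox_has_class <- function(store, curie) curie %in% store$classes$curie

# property lookup by alias glyph or curie; NULL if unknown
tbox_property <- function(store, key) {
  p <- store$properties
  i <- match(key, p$curie)
  if (is.na(i)) i <- match(key, p$alias)
  if (is.na(i)) return(NULL)
  as.list(p[i, ])
}

#' Ancestor classes (subclass closure) for every class
#'
#' @param store a `phs_tbox`.
#' @return Named list mapping each class curie to the character vector of
#'   its ancestors (excluding itself).
#' @export
subclass_ancestors <- function(store) {
  out <- stats::setNames(vector("list", nrow(store$classes)),
                         store$classes$curie)
  out[] <- list(character(0))
  if (nrow(store$subclass)) {
    cl <- transitive_closure_pairs(store$subclass$child, store$subclass$parent)
    for (child in unique(cl$from)) {
      out[[child]] <- sort(unique(cl$to[cl$from == child]))
    }
  }
  out
}

#' Register a defined class "X or (part_of some X)"
#'
#' Registers a class whose extension, computed by the reasoner, contains
#' every individual that is an instance of `base` (or a subclass) or whose
#' transitive parthood closure reaches such an instance -- the query
#' pattern used for body-region membership.
#'
#' @param store a `phs_tbox`.
#' @param name label for the defined class (e.g. `"head_or_part"`).
#' @param base curie of the base class (e.g. `"aism-insect_head"`).
#' @return The updated store.
#' @export
add_defined_class <- function(store, name, base) {
  if (!tbox_has_class(store, base)) {
    stop(sprintf("unresolved base class for defined class '%s': %s",
                 name, base), call. = FALSE)
  }
  i <- match(name, store$defined$name)
  if (!is.na(i)) {
    warning(sprintf("defined class '%s' replaced", name), call. = FALSE)
    store$defined$base[i] <- base
  } else {
    store$defined <- rbind(store$defined,
                           data.frame(name = name, base = base,
                                      stringsAsFactors = FALSE))
  }
  store
}

#' Register defined classes from a small YAML spec
#'
#' The YAML maps names to base-class curies, e.g.
#' `head_or_part: aism-insect_head`.
#'
#' @param store a `phs_tbox`.
#' @param path YAML file path.
#' @return The updated store.
#' @export
load_defined_classes <- function(store, path) {
  spec <- yaml::read_yaml(path)
  for (nm in names(spec)) {
    store <- add_defined_class(store, nm, spec[[nm]])
  }
  store
}

#' Serialize a TBox store back to Turtle
#'
#' Reloading the result with [load_tbox()] yields an identical store.
#'
#' @param store a `phs_tbox`.
#' @param path optional output path.
#' @return Turtle text.
#' @export
serialize_tbox <- function(store, path = NULL) {
  rows <- list()
  add <- function(s, p, o, o_type = "iri", o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- rdf_triple_row(s, p, o, o_type, o_dt)
  }
  rdf_type <- paste0(RDF_NS, "type")
  label_p <- paste0(RDFS_NS, "label")
  subp <- paste0(RDFS_NS, "subClassOf")
  bn <- 0L

  for (k in seq_len(nrow(store$properties))) {
    p <- store$properties[k, ]
    add(p$iri, rdf_type,
        paste0(OWL_NS, if (p$datatype) "DatatypeProperty"
                       else "ObjectProperty"))
    if (p$transitive) add(p$iri, rdf_type, paste0(OWL_NS, "TransitiveProperty"))
    add(p$iri, label_p, p$label, "literal")
    if (is.na(iri_to_curie(p$iri, store$prefixes)) ||
        !identical(iri_to_curie(p$iri, store$prefixes), p$curie)) {
      add(p$iri, paste0(PHS_NS, "curie"), p$curie, "literal")
    }
    if (!is.na(p$alias)) add(p$iri, paste0(PHS_NS, "alias"), p$alias, "literal")
    add(p$iri, paste0(PHS_NS, "category"), p$category, "literal")
    if (!is.na(p$inverse)) {
      add(p$iri, paste0(OWL_NS, "inverseOf"), term_iri(store, p$inverse))
    }
  }
  for (k in seq_len(nrow(store$classes))) {
    cl <- store$classes[k, ]
    add(cl$iri, rdf_type, paste0(OWL_NS, "Class"))
    add(cl$iri, label_p, cl$label, "literal")
    if (is.na(iri_to_curie(cl$iri, store$prefixes)) ||
        !identical(iri_to_curie(cl$iri, store$prefixes), cl$curie)) {
      add(cl$iri, paste0(PHS_NS, "curie"), cl$curie, "literal")
    }
  }
  for (k in seq_len(nrow(store$subclass))) {
    add(term_iri(store, store$subclass$child[k]), subp,
        term_iri(store, store$subclass$parent[k]))
  }
  restr <- function(s_curie, prop_curie, filler_curie) {
    bn <<- bn + 1L
    b <- sprintf("_:r%d", bn)
    add(term_iri(store, s_curie), subp, b, "blank")
    add(b, rdf_type, paste0(OWL_NS, "Restriction"))
    add(b, paste0(OWL_NS, "onProperty"), term_iri(store, prop_curie))
    add(b, paste0(OWL_NS, "someValuesFrom"), term_iri(store, filler_curie))
  }
  for (k in seq_len(nrow(store$part_axioms))) {
    restr(store$part_axioms$cls[k], "ro-part_of", store$part_axioms$whole[k])
  }
  for (k in seq_len(nrow(store$logical_defs))) {
    restr(store$logical_defs$cls[k], store$logical_defs$property[k],
          store$logical_defs$filler[k])
  }
  for (k in seq_len(nrow(store$disjoint))) {
    add(term_iri(store, store$disjoint$a[k]), paste0(OWL_NS, "disjointWith"),
        term_iri(store, store$disjoint$b[k]))
  }
  for (k in seq_len(nrow(store$defined))) {
    d_iri <- paste0(PHS_NS, "def/", store$defined$name[k])
    add(d_iri, rdf_type, paste0(PHS_NS, "DefinedClass"))
    add(d_iri, label_p, store$defined$name[k], "literal")
    add(d_iri, paste0(PHS_NS, "definedBase"),
        term_iri(store, store$defined$base[k]))
  }

  pfx <- c(store$prefixes,
           rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS,
           phs = PHS_NS, obo = OBO_NS)
  pfx <- pfx[!duplicated(names(pfx))]
  g <- rdf_graph(do.call(rbind, rows), pfx)
  serialize_turtle(g, path)
}

#' Load the bundled fixture mini-ontology
#'
#' A deterministic, self-contained TBox standing in for the OBO anatomy and
#' quality ontologies used by dung-beetle descriptions: a quality spine
#' (colour / shape / size / texture parents), a head / thorax / abdomen /
#' leg parthood hierarchy with transitive `part_of`, logical
#' "with N parts" definitions, and the four defined body-region classes.
#' Every curated edge lives in the single data file
#' `inst/extdata/fixture_tbox.ttl`.
#'
#' @return A `phs_tbox` store.
#' @export
build_fixture_ontology <- function() {
  path <- system.file("extdata", "fixture_tbox.ttl", package = "phenoscribe")
  if (path == "") {
    # during in-source development
    path <- file.path("inst", "extdata", "fixture_tbox.ttl")
  }
  store <- load_tbox(path)
  defs <- system.file("extdata", "defined_classes.yaml",
                      package = "phenoscribe")
  if (defs == "") defs <- file.path("inst", "extdata", "defined_classes.yaml")
  if (file.exists(defs)) store <- load_defined_classes(store, defs)
  store
}
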