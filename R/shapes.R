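# Shape-constraint validation of the compiled knowledge graph, run before
# reasoning. Shapes are a SHACL subset (targetClass + path with
# minCount/maxCount/class/datatype) plus two structural kinds with no plain
# SHACL-core equivalent: species linkage (every individual connected to its
# OTU's organism) and OTU metadata fields.

#' Construct a shape
#'
#' @param id shape identifier.
#' @param kind `"property"` (SHACL-style path constraint on a target
#'   class), `"connectivity"` (species linkage) or `"otu_field"` (required
#'   OTU metadata field).
#' @param target_class target class curie (property shapes).
#' @param path property curie (property shapes).
#' @param min,max cardinality bounds (`NA` = unbounded).
#' @param node_class required class of object individuals (`NA` = any).
#' @param field OTU record field (otu_field shapes).
#' @return A `phs_shape` object.
#' @export
shape <- function(id, kind = "property", target_class = NA_character_,
                  path = NA_character_, min = NA_integer_, max = NA_integer_,
                  node_class = NA_character_, field = NA_character_) {
  stopifnot(kind %in% c("property", "connectivity", "otu_field"))
  if (!is.na(min) && min < 0 || !is.na(max) && max < 0) {
    stop("shape counts must be non-negative", call. = FALSE)
  }
  structure(list(id = id, kind = kind, target_class = target_class,
                 path = path, min = min, max = max, node_class = node_class,
                 field = field), class = "phs_shape")
}

#' The default shape set
#'
#' Reconstructs the validation criteria the pipeline gates on: (a) every
#' non-organism individual is connected to an organism (phenotypes are
#' linked to species names); (b) every OTU has a taxon identifier; (c)
#' every organism's OTU has a catalog number; (d) every measurement datum
#' carries exactly one measurement value and at least one unit.
#'
#' @return List of `phs_shape` objects.
#' @export
default_shapes <- function() {
  list(
    shape("species_linkage", kind = "connectivity"),
    shape("otu_taxon_id", kind = "otu_field", field = "taxon_id"),
    shape("organism_catalog_number", kind = "otu_field",
          field = "catalog_number"),
    shape("datum_value", target_class = "iao-measurement_datum",
          path = "iao-has_measurement_value", min = 1L, max = 1L),
    shape("datum_unit", target_class = "iao-measurement_datum",
          path = "aism-has_unit", min = 1L)
  )
}

#' Validate a knowledge graph against shapes
#'
#' @param graph a `phs_abox`.
#' @param shapes list of `phs_shape` (default [default_shapes()]).
#' @param tbox a `phs_tbox` (subclass closure widens shape targets).
#' @return A `phs_validation_report`: list with `conforms` and a
#'   `violations` data.frame (shape, focus, constraint, message), ordered
#'   deterministically.
#' @export
validate_graph <- function(graph, shapes = default_shapes(), tbox) {
  anc <- subclass_ancestors(tbox)
  viol <- list()
  bad <- function(shape_id, focus, constraint, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      shape = shape_id, focus = focus, constraint = constraint,
      message = message, stringsAsFactors = FALSE)
  }
  ind <- graph$individuals
  asrt <- graph$assertions

  for (sh in shapes) {
    if (sh$kind == "connectivity") {
      # undirected reachability from each OTU organism over assertion edges
      edges <- asrt[!is.na(asrt$object), c("subject", "object")]
      reach_from <- function(start) {
        seen <- start
        frontier <- start
        while (length(frontier)) {
          nb <- unique(c(edges$object[edges$subject %in% frontier],
                         edges$subject[edges$object %in% frontier]))
          frontier <- setdiff(nb, seen)
          seen <- c(seen, frontier)
        }
        seen
      }
      linked <- unique(unlist(lapply(graph$otus$organism_id, reach_from)))
      orphans <- setdiff(ind$id, linked)
      for (o in sort(orphans)) {
        bad(sh$id, o, "connectivity",
            sprintf("individual '%s' is not connected to any OTU organism", o))
      }
    } else if (sh$kind == "otu_field") {
      for (k in seq_len(nrow(graph$otus))) {
        v <- graph$otus[[sh$field]][k]
        if (is.na(v) || !nzchar(v)) {
          bad(sh$id, graph$otus$otu_id[k], sh$field,
              sprintf("OTU '%s' lacks %s", graph$otus$otu_id[k], sh$field))
        }
      }
    } else {
      if (is.null(tbox_property(tbox, sh$path))) {
        stop(sprintf("shape '%s' references unknown property '%s'",
                     sh$id, sh$path), call. = FALSE)
      }
      targets <- ind$id[vapply(ind$cls, function(cc) {
        sh$target_class %in% c(cc, anc[[cc]])
      }, logical(1))]
      for (f in sort(targets)) {
        hits <- asrt[asrt$subject == f & asrt$predicate == sh$path &
                     asrt$polarity == "pos", , drop = FALSE]
        n <- nrow(hits)
        if (!is.na(sh$min) && n < sh$min) {
          bad(sh$id, f, "minCount",
              sprintf("'%s' has %d < %d values for %s", f, n, sh$min, sh$path))
        }
        if (!is.na(sh$max) && n > sh$max) {
          bad(sh$id, f, "maxCount",
              sprintf("'%s' has %d > %d values for %s", f, n, sh$max, sh$path))
        }
        if (!is.na(sh$node_class) && n > 0L) {
          for (obj in hits$object[!is.na(hits$object)]) {
            ocls <- ind$cls[ind$id == obj]
            if (!sh$node_class %in% c(ocls, anc[[ocls]])) {
              bad(sh$id, f, "class",
                  sprintf("object '%s' of %s is not a %s", obj, sh$path,
                          sh$node_class))
            }
          }
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(shape = character(), focus = character(),
               constraint = character(), message = character(),
               stringsAsFactors = FALSE)
  violations <- violations[order(violations$shape, violations$focus,
                                 violations$constraint), , drop = FALSE]
  rownames(violations) <- NULL
  structure(list(conforms = nrow(violations) == 0L, violations = violations),
            class = "phs_validation_report")
}

#' @export
print.phs_validation_report <- function(x, ...) {
  cat(sprintf("<validation: conforms = %s, %d violations>\n",
              x$conforms, nrow(x$violations)))
  if (nrow(x$violations)) print(utils::head(x$violations, 10))
  invisible(x)
}

#' Serialize shapes to SHACL-compatible Turtle
#'
#' Property shapes map to standard `sh:NodeShape`/`sh:property`
#' constraints. The connectivity and OTU-field shapes are emitted as
#' minCount constraints on the corresponding annotation properties (the
#' closest plain-SHACL rendering of the structural check) and tagged with
#' a `phs:kind` annotation so [load_shapes()] restores the exact semantics.
#'
#' @param shapes list of `phs_shape`.
#' @param tbox a `phs_tbox` for IRI resolution.
#' @param path optional output file.
#' @return Turtle text.
#' @export
serialize_shapes <- function(shapes, tbox, path = NULL) {
  rows <- list()
  add <- function(s, p, o, o_type = "iri", o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- rdf_triple_row(s, p, o, o_type, o_dt)
  }
  rdf_type <- paste0(RDF_NS, "type")
  xsd_int <- paste0(XSD_NS, "integer")
  bn <- 0L
  for (sh in shapes) {
    s <- paste0(PHS_NS, "shape/", sh$id)
    add(s, rdf_type, paste0(SH_NS, "NodeShape"))
    add(s, paste0(PHS_NS, "kind"), sh$kind, "literal")
    if (sh$kind == "property") {
      add(s, paste0(SH_NS, "targetClass"), term_iri(tbox, sh$target_class))
      bn <- bn + 1L; b <- sprintf("_:p%d", bn)
      add(s, paste0(SH_NS, "property"), b, "blank")
      add(b, paste0(SH_NS, "path"), term_iri(tbox, sh$path))
      if (!is.na(sh$min)) add(b, paste0(SH_NS, "minCount"),
                              as.character(sh$min), "literal", xsd_int)
      if (!is.na(sh$max)) add(b, paste0(SH_NS, "maxCount"),
                              as.character(sh$max), "literal", xsd_int)
      if (!is.na(sh$node_class)) {
        add(b, paste0(SH_NS, "class"), term_iri(tbox, sh$node_class))
      }
    } else if (sh$kind == "otu_field") {
      add(s, paste0(SH_NS, "targetClass"), paste0(PHS_NS, "OTU"))
      bn <- bn + 1L; b <- sprintf("_:p%d", bn)
      add(s, paste0(SH_NS, "property"), b, "blank")
      fld <- if (sh$field == "taxon_id") "taxonID" else "catalogNumber"
      add(s, paste0(PHS_NS, "field"), sh$field, "literal")
      add(b, paste0(SH_NS, "path"), paste0(PHS_NS, fld))
      add(b, paste0(SH_NS, "minCount"), "1", "literal", xsd_int)
    } else {
      add(s, paste0(SH_NS, "targetClass"), paste0(OWL_NS, "NamedIndividual"))
      bn <- bn + 1L; b <- sprintf("_:p%d", bn)
      add(s, paste0(SH_NS, "property"), b, "blank")
      add(b, paste0(SH_NS, "path"), paste0(PHS_NS, "otu"))
      add(b, paste0(SH_NS, "minCount"), "1", "literal", xsd_int)
    }
  }
  pfx <- c(tbox$prefixes, sh = SH_NS, phs = PHS_NS, obo = OBO_NS,
           owl = OWL_NS, rdf = RDF_NS, xsd = XSD_NS)
  pfx <- pfx[!duplicated(names(pfx))]
  serialize_turtle(rdf_graph(do.call(rbind, rows), pfx), path)
}

#' Load shapes written by [serialize_shapes()]
#'
#' @param x Turtle text or file path.
#' @param tbox a `phs_tbox`.
#' @return List of `phs_shape` objects.
#' @export
load_shapes <- function(x, tbox) {
  g <- parse_turtle(x)
  tr <- g$triples
  rdf_type <- paste0(RDF_NS, "type")
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
  subs <- sort(unique(tr$s[tr$p == rdf_type &
                           tr$o == paste0(SH_NS, "NodeShape")]))
  lapply(subs, function(s) {
    id <- sub(paste0(PHS_NS, "shape/"), "", s, fixed = TRUE)
    kind <- one(s, paste0(PHS_NS, "kind"))
    if (kind == "connectivity") return(shape(id, kind = "connectivity"))
    if (kind == "otu_field") {
      return(shape(id, kind = "otu_field",
                   field = one(s, paste0(PHS_NS, "field"))))
    }
    b <- one(s, paste0(SH_NS, "property"))
    mn <- one(b, paste0(SH_NS, "minCount"))
    mx <- one(b, paste0(SH_NS, "maxCount"))
    ncls <- one(b, paste0(SH_NS, "class"))
    shape(id,
          target_class = curie_of(one(s, paste0(SH_NS, "targetClass"))),
          path = curie_of(one(b, paste0(SH_NS, "path"))),
          min = if (is.na(mn)) NA_integer_ else as.integer(mn),
          max = if (is.na(mx)) NA_integer_ else as.integer(mx),
          node_class = if (is.na(ncls)) NA_character_ else curie_of(ncls))
  })
}
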