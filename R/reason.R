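# Rule-based materializing reasoner (EL-style fragment): subclass type
# closure, transitive part-of with has-part inversion, skolemization of
# existential "with N parts" definitions, membership in defined classes
# "X or (part_of some X)", and clash detection for denied parts and
# disjoint classes. Inconsistency is a result, never an exception.

#' Materialize inferred knowledge over an ABox
#'
#' Computes (1) the type closure of every individual along subclass axioms;
#' (2) the transitive parthood closure over asserted `part_of` edges and
#' inverted `has_part` edges; (3) skolem part individuals for every
#' logical-definition axiom not already witnessed by an asserted part of
#' the filler class (so a "maxillary palpus with 4 palpomeres" individual
#' acquires one palpomere part per axiom); and (4) the extension of every
#' defined region class. Re-running on its own output adds nothing.
#'
#' @param graph a `phs_abox` (or a `phs_inferred`, whose base is reused).
#' @param tbox a `phs_tbox`.
#' @return A `phs_inferred` object: list with `base` (graph including
#'   skolems), `types`, `part_closure`, `defined_members`, `consistent`,
#'   `clashes`.
#' @export
materialize <- function(graph, tbox) {
  if (inherits(graph, "phs_inferred")) graph <- graph$base
  anc <- subclass_ancestors(tbox)
  with_anc <- function(cls) {
    extra <- anc[[cls]]
    if (is.null(extra)) cls else c(cls, extra)
  }

  ind <- graph$individuals
  asrt <- graph$assertions

  # ---- skolemization to fixpoint
  defs <- tbox$logical_defs
  next_ord <- if (nrow(asrt)) max(asrt$ord) else 0L
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(ind))) {
      types_k <- with_anc(ind$cls[k])
      hit <- defs[defs$cls %in% types_k, , drop = FALSE]
      if (nrow(hit) == 0L) next
      id_k <- ind$id[k]
      # asserted/materialized parts of this individual
      part_ids <- c(asrt$object[asrt$subject == id_k &
                                asrt$predicate == "ro-has_part" &
                                asrt$polarity == "pos" & !is.na(asrt$object)],
                    asrt$subject[!is.na(asrt$object) &
                                 asrt$object == id_k &
                                 asrt$predicate == "ro-part_of" &
                                 asrt$polarity == "pos"])
      part_cls <- unlist(lapply(ind$cls[ind$id %in% part_ids], with_anc))
      for (d in seq_len(nrow(hit))) {
        filler <- hit$filler[d]
        if (filler %in% part_cls) next
        sk_id <- paste0(id_k, "/skolem/", filler)
        if (sk_id %in% ind$id) next
        ind <- rbind(ind, data.frame(
          id = sk_id, cls = filler, otu = ind$otu[k], tag = NA_character_,
          stmt = NA_integer_, pos = NA_integer_, skolem = TRUE,
          stringsAsFactors = FALSE))
        next_ord <- next_ord + 1L
        asrt <- rbind(asrt, data.frame(
          ord = next_ord, stmt = NA_integer_, subject = id_k,
          predicate = "ro-has_part", object = sk_id, literal = NA_real_,
          object_class = NA_character_, polarity = "pos",
          stringsAsFactors = FALSE))
        added <- TRUE
      }
    }
    if (!added) break
  }
  graph$individuals <- ind
  graph$assertions <- asrt

  # ---- type closure
  types <- stats::setNames(lapply(ind$cls, with_anc), ind$id)

  # ---- parthood closure (individual level)
  pos <- asrt[asrt$polarity == "pos" & !is.na(asrt$object), , drop = FALSE]
  part_from <- c(pos$subject[pos$predicate == "ro-part_of"],
                 pos$object[pos$predicate == "ro-has_part"])
  part_to <- c(pos$object[pos$predicate == "ro-part_of"],
               pos$subject[pos$predicate == "ro-has_part"])
  part_closure <- stats::setNames(vector("list", nrow(ind)), ind$id)
  part_closure[] <- list(character(0))
  if (length(part_from)) {
    cl <- transitive_closure_pairs(part_from, part_to)
    for (p in unique(cl$from)) {
      part_closure[[p]] <- sort(unique(cl$to[cl$from == p]))
    }
  }

  # ---- class-level parthood reachability (via subclass lifting)
  class_reach <- reach_by_class(tbox, anc)

  # ---- defined-class extensions
  defined_members <- stats::setNames(
    vector("list", nrow(tbox$defined)), tbox$defined$name)
  for (k in seq_len(nrow(tbox$defined))) {
    base_cls <- tbox$defined$base[k]
    member <- vapply(ind$id, function(i) {
      tset <- unique(c(types[[i]],
                       unlist(types[part_closure[[i]]], use.names = FALSE)))
      if (base_cls %in% tset) return(TRUE)
      any(vapply(tset, function(cc) {
        base_cls %in% class_reach[[cc]]
      }, logical(1)))
    }, logical(1))
    defined_members[[k]] <- sort(ind$id[member])
  }

  inferred <- structure(list(base = graph, types = types,
                             part_closure = part_closure,
                             defined_members = defined_members,
                             tbox = tbox,
                             consistent = NA, clashes = list()),
                        class = "phs_inferred")
  cons <- check_consistency(inferred)
  inferred$consistent <- cons$consistent
  inferred$clashes <- cons$clashes
  inferred
}

# For each class: set of classes reachable as wholes through class-level
# part_of axioms, lifted through the subclass hierarchy, transitively, with
# ancestors of every reached whole included.
reach_by_class <- function(tbox, anc = subclass_ancestors(tbox)) {
  classes <- tbox$classes$curie
  with_anc <- function(cls) c(cls, anc[[cls]])
  direct <- stats::setNames(lapply(classes, function(cc) {
    ups <- with_anc(cc)
    unique(tbox$part_axioms$whole[tbox$part_axioms$cls %in% ups])
  }), classes)
  reach <- stats::setNames(lapply(classes, function(cc) {
    unique(unlist(lapply(direct[[cc]], with_anc), use.names = FALSE))
  }), classes)
  repeat {
    changed <- FALSE
    for (cc in classes) {
      ext <- unique(unlist(reach[intersect(reach[[cc]], classes)],
                           use.names = FALSE))
      merged <- unique(c(reach[[cc]], ext))
      if (length(merged) > length(reach[[cc]])) {
        reach[[cc]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reach
}

#' @export
print.phs_inferred <- function(x, ...) {
  cat(sprintf(
    "<phs_inferred: %d individuals (%d skolem), consistent: %s, %d clashes>\n",
    nrow(x$base$individuals), sum(x$base$individuals$skolem),
    x$consistent, length(x$clashes)))
  invisible(x)
}

#' Check an inferred graph for logical clashes
#'
#' A clash arises when an individual carrying a negated has-part assertion
#' (an absence) has an asserted or inferred part of the denied class, or
#' when two classes declared disjoint both type one individual. Each clash
#' reports the minimal set of facts responsible.
#'
#' @param inferred a `phs_inferred`.
#' @return list with `consistent` flag and `clashes` (list of records).
#' @export
check_consistency <- function(inferred) {
  graph <- inferred$base
  types <- inferred$types
  clashes <- list()

  # denied parts: subject s denies has_part some C
  neg <- graph$assertions[graph$assertions$polarity == "neg", , drop = FALSE]
  for (k in seq_len(nrow(neg))) {
    s <- neg$subject[k]; denied <- neg$object_class[k]
    parts <- names(inferred$part_closure)[vapply(
      inferred$part_closure, function(w) s %in% w, logical(1))]
    bad <- parts[vapply(parts, function(p) denied %in% types[[p]],
                        logical(1))]
    for (p in bad) {
      clashes[[length(clashes) + 1L]] <- list(
        kind = "denied_part", subject = s, denied_class = denied, part = p,
        facts = c(sprintf("%s !has_part %s", s, denied),
                  sprintf("%s part_of+ %s with type %s", p, s, denied)))
    }
  }

  # disjoint classes co-asserted
  dj <- inferred$tbox$disjoint
  for (k in seq_len(nrow(dj))) {
    both <- names(types)[vapply(types, function(tt) {
      dj$a[k] %in% tt && dj$b[k] %in% tt
    }, logical(1))]
    for (i in both) {
      clashes[[length(clashes) + 1L]] <- list(
        kind = "disjoint", subject = i, classes = c(dj$a[k], dj$b[k]),
        facts = sprintf("%s typed by disjoint classes %s / %s",
                        i, dj$a[k], dj$b[k]))
    }
  }
  list(consistent = length(clashes) == 0L, clashes = clashes)
}

#' Extension of a defined region class
#'
#' @param inferred a `phs_inferred`.
#' @param defined_class name of a registered defined class.
#' @return Character vector of member individual ids.
#' @export
classify_into <- function(inferred, defined_class) {
  if (!defined_class %in% names(inferred$defined_members)) {
    stop(sprintf("unknown defined class '%s'", defined_class), call. = FALSE)
  }
  inferred$defined_members[[defined_class]]
}

#' Serialize an inferred graph to Turtle
#'
#' The base graph is serialized as by [serialize_abox()]; inferred types
#' and defined-class memberships are added as plain `rdf:type` triples
#' (flagged inferred via an annotation property on the type class pair
#' being absent from assertions), so an external SPARQL engine can query
#' them directly.
#'
#' @param inferred a `phs_inferred`.
#' @param path optional output file.
#' @return Turtle text.
#' @export
serialize_inferred <- function(inferred, path = NULL) {
  graph <- inferred$base
  tbox <- inferred$tbox
  base_txt <- serialize_abox(graph, tbox)
  g <- parse_turtle(base_txt)
  rows <- list(g$triples)
  rdf_type <- paste0(RDF_NS, "type")
  for (id in names(inferred$types)) {
    asserted <- graph$individuals$cls[graph$individuals$id == id]
    for (cls in setdiff(inferred$types[[id]], asserted)) {
      rows[[length(rows) + 1L]] <-
        rdf_triple_row(ind_iri(id), rdf_type, term_iri(tbox, cls))
    }
  }
  for (nm in names(inferred$defined_members)) {
    d_iri <- paste0(PHS_NS, "def/", nm)
    for (id in inferred$defined_members[[nm]]) {
      rows[[length(rows) + 1L]] <-
        rdf_triple_row(ind_iri(id), rdf_type, d_iri)
    }
  }
  out <- rdf_graph(unique(do.call(rbind, rows)), g$prefixes)
  serialize_turtle(out, path)
}
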