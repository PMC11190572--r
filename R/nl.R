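# Natural-language generation: traverses the knowledge graph per source
# statement (statement order, depth-first along the compiled chain) and
# renders telegraphic trait lines. Templates follow the conventions of the
# published treatments: presence "X: present;", absence "X: absent;",
# quality "locators...: quality;", measurement "Q = value, unit: U;",
# within-species comparison "Q <rel> Q of B of ...;", positional
# "A <rel> B of ...;". Between-species comparisons render the full
# sentence naming the foreign OTU (the historical truncated form is
# available behind `legacy_asterisk`).

nl_line <- function(text, locators, inds, links, kind) {
  list(text = text, locators = locators, inds = inds, links = links,
       kind = kind)
}

#' Generate the annotated NL description for one OTU
#'
#' @param inferred a `phs_inferred` (a consistent graph is expected).
#' @param otu OTU id to describe.
#' @param legacy_asterisk reproduce the truncated "hind wing: length;*"
#'   rendering of between-species comparisons instead of the full sentence.
#' @return A `phs_nldoc`: list with `otu`, `header`, `lines`, `links`.
#' @export
generate_nl <- function(inferred, otu, legacy_asterisk = FALSE) {
  graph <- inferred$base
  tbox <- inferred$tbox
  ind <- graph$individuals
  asrt <- graph$assertions
  orow <- graph$otus[graph$otus$otu_id == otu, ]
  if (nrow(orow) == 0L) stop(sprintf("unknown OTU '%s'", otu), call. = FALSE)

  cls_of <- function(id) ind$cls[match(id, ind$id)]
  lab <- function(id) term_label(tbox, cls_of(id))
  iri_of <- function(id) term_iri(tbox, cls_of(id))
  otu_of <- function(id) ind$otu[match(id, ind$id)]

  # statements owned by this OTU: owner = OTU of the first chain subject
  stmt_ids <- sort(unique(asrt$stmt[!is.na(asrt$stmt)]))
  owner_of <- vapply(stmt_ids, function(i) {
    rows <- asrt[!is.na(asrt$stmt) & asrt$stmt == i, , drop = FALSE]
    otu_of(rows$subject[which.min(rows$ord)])
  }, character(1))
  stmt_ids <- stmt_ids[owner_of == otu]

  # literal-only statements (measurement value lines) are folded into the
  # measurement statement that introduced their datum
  is_value_stmt <- vapply(stmt_ids, function(i) {
    rows <- asrt[asrt$stmt == i & !is.na(asrt$stmt), , drop = FALSE]
    all(!is.na(rows$literal))
  }, logical(1))

  datum_value <- function(id) {
    v <- asrt$literal[asrt$subject == id &
                      asrt$predicate == "iao-has_measurement_value" &
                      !is.na(asrt$literal)]
    if (length(v)) v[1] else NA_real_
  }

  lines <- list()
  push <- function(l) lines[[length(lines) + 1L]] <<- l

  for (i in stmt_ids[!is_value_stmt]) {
    rows <- asrt[!is.na(asrt$stmt) & asrt$stmt == i, , drop = FALSE]
    rows <- rows[order(rows$ord), , drop = FALSE]
    cats <- vapply(rows$predicate, function(p) {
      pr <- tbox_property(tbox, p)
      if (is.null(pr)) "core" else pr$category
    }, character(1))

    # parent pointers: a node's parent is the subject of the row that first
    # introduced it; later occurrences (tagged back-references closing a
    # chain onto an earlier node) never reassign, so pointers stay acyclic
    parent <- list()
    seen <- rows$subject[1]
    for (k in seq_len(nrow(rows))) {
      o <- rows$object[k]
      if (!is.na(o) && !o %in% seen) {
        parent[[o]] <- rows$subject[k]
        seen <- c(seen, o)
      }
      seen <- unique(c(seen, rows$subject[k]))
    }
    root <- rows$subject[1]
    path_to <- function(id) {
      out <- id
      guard <- 0L
      while (id %in% names(parent) && guard < 1000L) {
        id <- parent[[id]]
        out <- c(id, out)
        guard <- guard + 1L
      }
      out
    }
    links_for <- function(ids) {
      stats::setNames(vapply(ids, iri_of, character(1)),
                      vapply(ids, lab, character(1)))
    }
    stmt_nodes <- unique(c(rows$subject, rows$object[!is.na(rows$object)]))

    # trailing chain from a node onward, following row order
    # with stop_at_seen, tagged back-references to nodes already introduced
    # earlier in the chain are elided (they re-anchor identity, and the
    # printed unit phrases stop before them) -- except the first step, so a
    # unit's immediate bearer always prints
    trail_after <- function(start_k, start_node, stop_at_seen = FALSE) {
      seen_before <- unique(c(rows$subject[seq_len(start_k)],
                              rows$object[seq_len(start_k)]))
      cur <- start_node
      out <- character(0)
      k <- start_k + 1L
      while (k <= nrow(rows)) {
        if (identical(rows$subject[k], cur) && !is.na(rows$object[k])) {
          nxt <- rows$object[k]
          if (stop_at_seen && length(out) > 0L &&
              (nxt %in% seen_before || identical(nxt, orow$organism_id))) {
            break
          }
          out <- c(out, nxt)
          cur <- nxt
        }
        k <- k + 1L
      }
      out
    }

    if (any(rows$polarity == "neg")) {
      k <- which(rows$polarity == "neg")[1]
      locs <- path_to(rows$subject[k])
      denied <- rows$object_class[k]
      txt <- paste0(paste(vapply(locs, lab, character(1)), collapse = ", "),
                    ", ", term_label(tbox, denied), ": absent;")
      lk <- links_for(locs)
      lk[term_label(tbox, denied)] <- term_iri(tbox, denied)
      push(nl_line(txt, vapply(locs, lab, character(1)), locs, lk, "absence"))
    } else if (any(cats == "comparison")) {
      k <- which(cats == "comparison")[1]
      q1 <- rows$subject[k]; q2 <- rows$object[k]
      rel <- term_label(tbox, rows$predicate[k])
      if (!identical(otu_of(q2), otu)) {
        push(render_between_species(inferred, rows[k, ],
                                    legacy_asterisk = legacy_asterisk))
      } else {
        locs <- utils::head(path_to(q1), -1L)
        rhs <- c(q2, trail_after(k, q2))
        txt <- paste0(
          paste(vapply(locs, lab, character(1)), collapse = ", "),
          ": ", lab(q1), " ", rel, " ",
          paste(vapply(rhs, lab, character(1)), collapse = " of "), ";")
        push(nl_line(txt, vapply(locs, lab, character(1)),
                     unique(c(locs, q1, rhs)),
                     links_for(unique(c(locs, q1, rhs))), "comparison"))
      }
    } else if (any(cats == "measurement")) {
      k <- which(rows$predicate == "iao-is_quality_measured_as")[1]
      q <- rows$subject[k]; datum <- rows$object[k]
      locs <- utils::head(path_to(q), -1L)
      ku <- which(rows$predicate == "aism-has_unit")
      unit_txt <- ""
      unit_ids <- character(0)
      if (length(ku)) {
        u <- rows$object[ku[1]]
        unit_ids <- c(u, trail_after(ku[1], u, stop_at_seen = TRUE))
        unit_txt <- paste(vapply(unit_ids, lab, character(1)),
                          collapse = " of ")
      }
      val <- datum_value(datum)
      txt <- paste0(
        paste(vapply(locs, lab, character(1)), collapse = ", "),
        ", ", lab(q), " = ",
        format(val, trim = TRUE, scientific = FALSE),
        ", unit: ", unit_txt, ";")
      covered <- unique(c(locs, q, datum, unit_ids, stmt_nodes))
      push(nl_line(txt, vapply(locs, lab, character(1)), covered,
                   links_for(setdiff(covered, datum)), "measurement"))
    } else if (any(cats == "positional")) {
      k <- which(cats == "positional")[1]
      a <- rows$subject[k]; b <- rows$object[k]
      locs <- path_to(a)
      rhs <- c(b, trail_after(k, b))
      txt <- paste0(
        paste(vapply(locs, lab, character(1)), collapse = ", "),
        " ", term_label(tbox, rows$predicate[k]), " ",
        paste(vapply(rhs, lab, character(1)), collapse = " of "), ";")
      push(nl_line(txt, vapply(locs, lab, character(1)),
                   unique(c(locs, rhs)), links_for(unique(c(locs, rhs))),
                   "position"))
    } else if (any(rows$predicate == "ro-has_characteristic")) {
      qrows <- which(rows$predicate == "ro-has_characteristic")
      for (k in qrows) {
        bearer <- rows$subject[k]; q <- rows$object[k]
        locs <- path_to(bearer)
        txt <- paste0(
          paste(vapply(locs, lab, character(1)), collapse = ", "),
          ": ", lab(q), ";")
        push(nl_line(txt, vapply(locs, lab, character(1)),
                     unique(c(locs, q)), links_for(unique(c(locs, q))),
                     "quality"))
      }
    } else {
      # pure parthood chain(s): one presence line per terminal part
      objs <- rows$object[!is.na(rows$object)]
      terminals <- setdiff(objs, rows$subject)
      if (length(terminals) == 0L) terminals <- utils::tail(objs, 1L)
      for (t in terminals) {
        locs <- path_to(t)
        txt <- paste0(
          paste(vapply(locs, lab, character(1)), collapse = ", "),
          ": present;")
        push(nl_line(txt, vapply(locs, lab, character(1)), locs,
                     links_for(locs), "presence"))
      }
    }
  }

  # completeness: every base individual of the OTU appears in >= 1 line
  covered <- unique(unlist(lapply(lines, function(l) l$inds)))
  focal <- ind$id[ind$otu == otu & !ind$skolem]
  orphans <- setdiff(setdiff(focal, covered), orow$organism_id)
  if (length(orphans) && length(stmt_ids)) {
    stop(sprintf("NL generation: individuals unreachable from the organism: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }

  org_lab <- term_label(tbox, orow$organism_class)
  header <- c(
    org_lab,
    paste("Catalog Number", orow$catalog_number),
    paste(org_lab, "has role in modeling TU denotes species"),
    paste("species Taxon ID", orow$taxon_id),
    paste("species Parent Name Usage ID", orow$parent_id))

  links <- list()
  for (l in lines) for (nm in names(l$links)) links[[nm]] <- l$links[[nm]]

  structure(list(otu = otu, label = orow$label, header = header,
                 lines = lines, links = unlist(links)),
            class = "phs_nldoc")
}

#' Render a between-species comparison line
#'
#' @param inferred a `phs_inferred`.
#' @param assertion one row of the assertion table whose predicate is a
#'   magnitude comparison spanning two OTUs.
#' @param legacy_asterisk emit the truncated historical form.
#' @return An NL line record.
#' @export
render_between_species <- function(inferred, assertion,
                                   legacy_asterisk = FALSE) {
  graph <- inferred$base
  tbox <- inferred$tbox
  ind <- graph$individuals
  asrt <- graph$assertions
  cls_of <- function(id) ind$cls[match(id, ind$id)]
  lab <- function(id) term_label(tbox, cls_of(id))
  iri_of <- function(id) term_iri(tbox, cls_of(id))

  q1 <- assertion$subject; q2 <- assertion$object
  b1_rows <- asrt$subject[!is.na(asrt$object) & asrt$object == q1 &
                          asrt$predicate == "ro-has_characteristic"]
  b1 <- if (length(b1_rows)) b1_rows[1] else NA_character_
  # the foreign quality's bearer follows it in the chain via characteristic_of
  b2_rows <- asrt$object[asrt$subject == q2 &
                         asrt$predicate == "ro-characteristic_of" &
                         !is.na(asrt$object)]
  if (length(b2_rows) == 0L) {
    stop("between-species comparison: missing foreign operand", call. = FALSE)
  }
  b2 <- b2_rows[1]
  f_otu <- ind$otu[match(q2, ind$id)]
  f_row <- graph$otus[graph$otus$otu_id == f_otu, ]
  if (nrow(f_row) == 0L) {
    stop(sprintf("dangling reference: OTU '%s' not declared", f_otu),
         call. = FALSE)
  }
  ids <- c(b1, q1, q2, b2)
  links <- stats::setNames(vapply(ids, iri_of, character(1)),
                           vapply(ids, lab, character(1)))
  if (legacy_asterisk) {
    txt <- paste0(lab(b1), ": ", lab(q1), ";*")
  } else {
    org_lab <- term_label(tbox, f_row$organism_class)
    txt <- sprintf("the %s of the %s is %s the %s of the %s of the %s of %s;",
                   lab(q1), lab(b1), term_label(tbox, assertion$predicate),
                   lab(q2), lab(b2), org_lab, f_row$label)
  }
  nl_line(txt, lab(b1), ids, links, "between_species")
}

#' Plain-text lines of an NL document
#'
#' @param doc a `phs_nldoc`.
#' @param nested nest consecutive lines sharing locator prefixes (the
#'   shared prefix is elided and the line indented); the flat form repeats
#'   full locator chains.
#' @return Character vector of lines.
#' @export
nl_text <- function(doc, nested = FALSE) {
  if (!nested) {
    return(vapply(doc$lines, function(l) l$text, character(1)))
  }
  out <- character(0)
  prev <- character(0)
  for (l in doc$lines) {
    locs <- l$locators
    shared <- 0L
    while (shared < length(locs) && shared < length(prev) &&
           identical(locs[shared + 1L], prev[shared + 1L])) {
      shared <- shared + 1L
    }
    txt <- l$text
    if (shared > 0L) {
      prefix <- paste0(paste(locs[seq_len(shared)], collapse = ", "), ", ")
      if (startsWith(txt, prefix)) {
        txt <- paste0(strrep("  ", shared), substring(txt, nchar(prefix) + 1L))
      }
    }
    out <- c(out, txt)
    prev <- locs
  }
  out
}

#' @export
print.phs_nldoc <- function(x, ...) {
  cat(x$label, "\n")
  cat(paste(x$header, collapse = "\n"), "\n\n")
  cat(paste(nl_text(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Annotate an NL document with term hyperlinks
#'
#' Every phenotypic term label is wrapped in a link to its ontology IRI.
#'
#' @param doc a `phs_nldoc`.
#' @param format `"markdown"`, `"html"` or `"text"` (links stripped).
#' @return Character vector: header then one entry per line.
#' @export
annotate_links <- function(doc, format = c("markdown", "html", "text")) {
  format <- match.arg(format)
  render_line <- function(l) {
    txt <- l$text
    if (format == "text") return(txt)
    labels <- names(l$links)
    labels <- labels[order(-nchar(labels))]
    # two passes with placeholders so a short label never matches inside an
    # already-inserted link for a longer label
    for (j in seq_along(labels)) {
      hit <- regexpr(labels[j], txt, fixed = TRUE)
      if (hit > 0L) {
        pre <- substr(txt, 1L, hit - 1L)
        post <- substr(txt, hit + nchar(labels[j]), nchar(txt))
        txt <- paste0(pre, sprintf("\x01%d\x02", j), post)
      }
    }
    for (j in seq_along(labels)) {
      iri <- l$links[[labels[j]]]
      repl <- if (format == "markdown") {
        sprintf("[%s](%s)", labels[j], iri)
      } else {
        sprintf("<a href=\"%s\">%s</a>", iri, labels[j])
      }
      txt <- sub(sprintf("\x01%d\x02", j), repl, txt, fixed = TRUE)
    }
    txt
  }
  c(doc$header, vapply(doc$lines, render_line, character(1)))
}
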