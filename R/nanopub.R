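# Nanopublication packaging: per-species habitat assertions as four named
# RDF graphs (head, assertion, provenance, publication info), emitted as
# one TriG document. File-only emission; no signing or network publication.

NP_NS <- "http://www.nanopub.org/nschema#"
PROV_NS <- "http://www.w3.org/ns/prov#"
DCT_NS <- "http://purl.org/dc/terms/"

#' Build a habitat nanopublication for one species record
#'
#' The assertion graph states that the taxon inhabits the habitat term;
#' provenance derives the assertion from the species' description graph and
#' attributes it to the project authors; publication info carries creator
#' and creation date. URIs are deterministic functions of the OTU id and
#' habitat, so identical inputs give identical nanopublications.
#'
#' @param record one OTU record: a row of `graph$otus` or a list with at
#'   least `otu_id` and `taxon_id` (plus optional `habitat`).
#' @param habitat habitat term name (default from the record).
#' @param authors character vector of authors for attribution.
#' @param created ISO date string recorded as creation time.
#' @return A `phs_nanopub`: list with `uri` and `graphs` (quad table).
#' @export
build_habitat_nanopub <- function(record, habitat = NULL,
                                  authors = "unknown",
                                  created = "2024-06-13") {
  record <- as.list(record)
  if (is.null(record$taxon_id) || is.na(record$taxon_id)) {
    stop(sprintf("OTU '%s' has no taxon id; cannot build a nanopublication",
                 record$otu_id), call. = FALSE)
  }
  if (is.null(habitat)) habitat <- record$habitat
  if (is.null(habitat) || is.na(habitat)) {
    stop("no habitat term given", call. = FALSE)
  }
  np <- paste0(PHS_NS, "np/", record$otu_id, "-", habitat)
  g_head <- paste0(np, "/head")
  g_assert <- paste0(np, "/assertion")
  g_prov <- paste0(np, "/provenance")
  g_pubinfo <- paste0(np, "/pubinfo")
  habitat_iri <- paste0(PHS_NS, "habitat/", habitat)

  rows <- list()
  add <- function(g, s, p, o, o_type = "iri", o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- rdf_triple_row(s, p, o, o_type, o_dt, g)
  }
  rdf_type <- paste0(RDF_NS, "type")

  add(g_head, np, rdf_type, paste0(NP_NS, "Nanopublication"))
  add(g_head, np, paste0(NP_NS, "hasAssertion"), g_assert)
  add(g_head, np, paste0(NP_NS, "hasProvenance"), g_prov)
  add(g_head, np, paste0(NP_NS, "hasPublicationInfo"), g_pubinfo)

  add(g_assert, record$taxon_id, paste0(PHS_NS, "inhabits"), habitat_iri)
  add(g_assert, habitat_iri, paste0(RDFS_NS, "label"), habitat, "literal")

  add(g_prov, g_assert, paste0(PROV_NS, "wasDerivedFrom"),
      paste0(PHS_NS, "otu/", record$otu_id))
  for (a in authors) {
    add(g_prov, g_assert, paste0(PROV_NS, "wasAttributedTo"), a, "literal")
  }

  add(g_pubinfo, np, paste0(DCT_NS, "created"), created, "literal",
      paste0(XSD_NS, "date"))
  for (a in authors) {
    add(g_pubinfo, np, paste0(DCT_NS, "creator"), a, "literal")
  }
  add(g_pubinfo, np, paste0(DCT_NS, "license"),
      "https://creativecommons.org/licenses/by/4.0/")

  structure(list(uri = np, graphs = do.call(rbind, rows)),
            class = "phs_nanopub")
}

#' @export
print.phs_nanopub <- function(x, ...) {
  cat(sprintf("<nanopub %s: %d quads in %d graphs>\n", x$uri,
              nrow(x$graphs), length(unique(x$graphs$graph))))
  invisible(x)
}

#' Build habitat nanopublications for every OTU of a graph
#'
#' @param graph a `phs_abox`.
#' @param habitat habitat term (default: each record's own).
#' @param authors,created see [build_habitat_nanopub()].
#' @return List of `phs_nanopub`.
#' @export
build_nanopubs <- function(graph, habitat = NULL, authors = "unknown",
                           created = "2024-06-13") {
  lapply(seq_len(nrow(graph$otus)), function(k) {
    build_habitat_nanopub(graph$otus[k, ], habitat = habitat,
                          authors = authors, created = created)
  })
}

#' Serialize nanopublications to one TriG document
#'
#' @param pubs list of `phs_nanopub`.
#' @param path optional output file.
#' @return TriG text.
#' @export
serialize_nanopubs <- function(pubs, path = NULL) {
  quads <- do.call(rbind, lapply(pubs, function(p) p$graphs))
  pfx <- c(np = NP_NS, phs = PHS_NS, prov = PROV_NS, dct = DCT_NS,
           rdf = RDF_NS, rdfs = RDFS_NS, xsd = XSD_NS)
  serialize_trig(rdf_graph(quads, pfx), path)
}

#' Structural validity of a nanopublication
#'
#' Checks the nanopub rule: exactly one assertion, provenance and pubinfo
#' graph, all referenced from the head graph, and a non-empty assertion.
#'
#' @param pub a `phs_nanopub` (or an [rdf_graph()] holding one nanopub's
#'   quads).
#' @return `TRUE` or a character vector of problems.
#' @export
check_nanopub <- function(pub) {
  quads <- if (inherits(pub, "phs_nanopub")) pub$graphs else pub$triples
  problems <- character(0)
  heads <- quads[quads$p == paste0(NP_NS, "hasAssertion"), , drop = FALSE]
  if (nrow(heads) != 1L) problems <- c(problems, "head must reference exactly one assertion graph")
  for (part in c("hasAssertion", "hasProvenance", "hasPublicationInfo")) {
    refs <- quads$o[quads$p == paste0(NP_NS, part)]
    if (length(refs) != 1L) {
      problems <- c(problems, sprintf("expected one %s reference", part))
    } else if (!refs %in% quads$graph) {
      problems <- c(problems, sprintf("%s graph %s is empty", part, refs))
    }
  }
  a_ref <- quads$o[quads$p == paste0(NP_NS, "hasAssertion")]
  if (length(a_ref) == 1L && sum(quads$graph == a_ref) < 1L) {
    problems <- c(problems, "assertion graph is empty")
  }
  if (length(problems)) problems else TRUE
}
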