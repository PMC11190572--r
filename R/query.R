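# Semantic count queries over the materialized knowledge graph: individuals
# per phenotypic-characteristic class (colour / shape / size / texture) and
# per body region (the four defined "X or part_of some X" classes), plus an
# export bundle so an external SPARQL engine reproduces the counts.

#' Count individuals per ontology class and OTU
#'
#' For each (class, OTU) pair, counts the OTU-owned base individuals whose
#' inferred types include the class or any subclass. Skolem parts
#' materialized by the reasoner are excluded unless requested.
#'
#' @param inferred a `phs_inferred`.
#' @param classes character vector of class curies.
#' @param otus OTU ids (default: all in the graph).
#' @param include_skolems count materialized skolem parts too?
#' @return A `phs_query_result`: list with `rows` (class, otu, count) and
#'   `metadata`.
#' @export
count_by_class <- function(inferred, classes, otus = NULL,
                           include_skolems = FALSE) {
  graph <- inferred$base
  unknown <- classes[!classes %in% inferred$tbox$classes$curie]
  if (length(unknown)) {
    stop(sprintf("unknown classes: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(otus)) otus <- sort(graph$otus$otu_id)
  ind <- graph$individuals
  if (!include_skolems) ind <- ind[!ind$skolem, , drop = FALSE]
  rows <- do.call(rbind, lapply(classes, function(cls) {
    do.call(rbind, lapply(otus, function(o) {
      ids <- ind$id[ind$otu == o]
      n <- sum(vapply(ids, function(i) cls %in% inferred$types[[i]],
                      logical(1)))
      data.frame(class = cls, otu = o, count = as.integer(n),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(rows = rows,
                 metadata = list(query = "count_by_class",
                                 classes = classes, otus = otus,
                                 include_skolems = include_skolems)),
            class = "phs_query_result")
}

#' Count individuals per body region and OTU
#'
#' Counts membership in the defined region classes
#' ("X or (part_of some X)" for head, thorax, abdomen, leg). An individual
#' belonging to two regions counts in both.
#'
#' @param inferred a `phs_inferred`.
#' @param regions defined-class names (default: all registered).
#' @param otus OTU ids (default: all).
#' @param include_skolems count materialized skolem parts too?
#' @return A `phs_query_result`.
#' @export
count_by_region <- function(inferred, regions = NULL, otus = NULL,
                            include_skolems = FALSE) {
  graph <- inferred$base
  if (is.null(regions)) regions <- names(inferred$defined_members)
  unknown <- regions[!regions %in% names(inferred$defined_members)]
  if (length(unknown)) {
    stop(sprintf("unknown defined classes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(otus)) otus <- sort(graph$otus$otu_id)
  ind <- graph$individuals
  if (!include_skolems) ind <- ind[!ind$skolem, , drop = FALSE]
  rows <- do.call(rbind, lapply(regions, function(rg) {
    members <- classify_into(inferred, rg)
    do.call(rbind, lapply(otus, function(o) {
      n <- sum(ind$id %in% members & ind$otu == o)
      data.frame(class = rg, otu = o, count = as.integer(n),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(rows = rows,
                 metadata = list(query = "count_by_region",
                                 regions = regions, otus = otus,
                                 include_skolems = include_skolems)),
            class = "phs_query_result")
}

#' @export
print.phs_query_result <- function(x, ...) {
  print(query_table(x))
  invisible(x)
}

#' Pivot a query result to a classes-by-OTUs table
#' @param result a `phs_query_result`.
#' @return data.frame with one row per class and one column per OTU.
#' @export
query_table <- function(result) {
  rows <- result$rows
  classes <- unique(rows$class)
  otus <- unique(rows$otu)
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (o in otus) {
    out[[o]] <- vapply(classes, function(cl) {
      rows$count[rows$class == cl & rows$otu == o]
    }, integer(1))
  }
  out
}

#' Write a query result as TSV or JSON
#' @param result a `phs_query_result`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_query_result <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- query_table(result)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

preset_characteristic_classes <- function() {
  c("pato-colour", "pato-shape", "pato-size", "pato-texture")
}

#' Run a preset query
#'
#' `"characteristics"` counts individuals under the four quality parents
#' (colour, shape, size, texture); `"regions"` counts the four body-region
#' defined classes.
#'
#' @param inferred a `phs_inferred`.
#' @param preset preset name.
#' @param ... passed to the underlying count operation.
#' @return A `phs_query_result`.
#' @export
run_preset_query <- function(inferred, preset = c("characteristics",
                                                  "regions"), ...) {
  preset <- match.arg(preset)
  if (preset == "characteristics") {
    count_by_class(inferred, preset_characteristic_classes(), ...)
  } else {
    count_by_region(inferred, ...)
  }
}

sparql_count_query <- function(class_iri) {
  paste0(
    "PREFIX phs: <", PHS_NS, ">\n",
    "SELECT ?otu (COUNT(DISTINCT ?i) AS ?n) WHERE {\n",
    "  ?i a <", class_iri, "> ;\n",
    "     phs:otu ?otu .\n",
    "  FILTER NOT EXISTS { ?i phs:skolem true }\n",
    "} GROUP BY ?otu ORDER BY ?otu\n")
}

#' Export a SPARQL bundle reproducing the preset counts
#'
#' Writes the materialized graph as Turtle (inferred types and defined-class
#' memberships asserted as plain `rdf:type` triples) together with one
#' SPARQL query file per preset class, so an external SPARQL engine returns
#' exactly the counts of [run_preset_query()].
#'
#' @param inferred a `phs_inferred`.
#' @param dir output directory (created if needed).
#' @param presets which presets to include.
#' @return Character vector of written file paths.
#' @export
export_sparql_bundle <- function(inferred, dir,
                                 presets = c("characteristics", "regions")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graph_path <- file.path(dir, "inferred.ttl")
  serialize_inferred(inferred, graph_path)
  written <- graph_path
  tbox <- inferred$tbox
  if ("characteristics" %in% presets) {
    for (cls in preset_characteristic_classes()) {
      p <- file.path(dir, paste0("count_", sub("^pato-", "", cls), ".rq"))
      writeLines(sparql_count_query(term_iri(tbox, cls)), p)
      written <- c(written, p)
    }
  }
  if ("regions" %in% presets) {
    for (nm in names(inferred$defined_members)) {
      p <- file.path(dir, paste0("count_", nm, ".rq"))
      writeLines(sparql_count_query(paste0(PHS_NS, "def/", nm)), p)
      written <- c(written, p)
    }
  }
  written
}
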