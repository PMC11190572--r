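# End-to-end pipeline: parse -> compile (1) -> shape validation (2) ->
# TBox assembly (3) -> reasoning (4) -> NL generation (5) -> semantic
# queries (6), with fail-fast gates after steps 2 and 4 and deterministic
# artifacts (re-running an unchanged configuration is a byte-for-byte
# no-op).

#' Run the description-processing pipeline
#'
#' @param config project configuration ([read_project_config()] input).
#' @param description description source text or `.phs` path.
#' @param out_dir output directory for artifacts.
#' @param tbox a `phs_tbox`; default is the bundled fixture ontology.
#' @param shapes shape list; default [default_shapes()].
#' @param legacy_asterisk passed to [generate_nl()].
#' @return A `phs_pipeline_report`: list with `ok`, `failed_step`, `steps`
#'   (status table with artifact hashes) and the key in-memory results.
#' @export
run_pipeline <- function(config, description, out_dir,
                         tbox = build_fixture_ontology(),
                         shapes = default_shapes(),
                         legacy_asterisk = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- read_project_config(config)
  steps <- list()
  note <- function(step, name, status, artifacts = character(0)) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, name = name, status = status,
      artifacts = paste(basename(artifacts), collapse = ";"),
      md5 = paste(unname(tools::md5sum(artifacts[file.exists(artifacts)])),
                  collapse = ";"),
      stringsAsFactors = FALSE)
  }
  finish <- function(ok, failed_step = NA_integer_, ...) {
    structure(list(ok = ok, failed_step = failed_step,
                   steps = do.call(rbind, steps), ...),
              class = "phs_pipeline_report")
  }

  # step 1: compile to OWL ABox
  doc <- parse_document(description, config)
  graph <- compile_abox(doc, tbox)
  abox_path <- file.path(out_dir, "abox.ttl")
  serialize_abox(graph, tbox, abox_path)
  note(1L, "compile", "ok", abox_path)

  # step 2: shape validation (gate)
  report <- validate_graph(graph, shapes, tbox)
  report_path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(list(conforms = report$conforms,
                            violations = report$violations),
                       report_path, auto_unbox = TRUE, digits = NA)
  shapes_path <- file.path(out_dir, "shapes.ttl")
  serialize_shapes(shapes, tbox, shapes_path)
  if (!report$conforms) {
    note(2L, "validate", "failed", c(report_path, shapes_path))
    return(finish(FALSE, 2L, graph = graph, validation = report))
  }
  note(2L, "validate", "ok", c(report_path, shapes_path))

  # step 3: merged TBox artifact
  tbox_path <- file.path(out_dir, "tbox.ttl")
  serialize_tbox(tbox, tbox_path)
  note(3L, "tbox", "ok", tbox_path)

  # step 4: reasoning (gate)
  inferred <- materialize(graph, tbox)
  inferred_path <- file.path(out_dir, "inferred.ttl")
  serialize_inferred(inferred, inferred_path)
  consistency_path <- file.path(out_dir, "consistency.json")
  jsonlite::write_json(
    list(consistent = inferred$consistent,
         clashes = lapply(inferred$clashes, function(cl)
           lapply(cl, function(v) unname(v)))),
    consistency_path, auto_unbox = TRUE, digits = NA)
  if (!inferred$consistent) {
    note(4L, "reason", "failed", c(inferred_path, consistency_path))
    return(finish(FALSE, 4L, graph = graph, inferred = inferred))
  }
  note(4L, "reason", "ok", c(inferred_path, consistency_path))

  # step 5: NL generation
  nl_paths <- character(0)
  nl_docs <- list()
  for (o in unique(vapply(doc$statements, function(s) s$otu, character(1)))) {
    nld <- generate_nl(inferred, o, legacy_asterisk = legacy_asterisk)
    nl_docs[[o]] <- nld
    md <- file.path(out_dir, paste0("description_", o, ".md"))
    writeLines(annotate_links(nld, "markdown"), md)
    txt <- file.path(out_dir, paste0("description_", o, ".txt"))
    writeLines(c(nld$header, nl_text(nld)), txt)
    nl_paths <- c(nl_paths, md, txt)
  }
  note(5L, "nl", "ok", nl_paths)

  # step 6: semantic queries
  chars <- run_preset_query(inferred, "characteristics")
  regions <- run_preset_query(inferred, "regions")
  q_paths <- c(file.path(out_dir, "characteristics.tsv"),
               file.path(out_dir, "regions.tsv"))
  write_query_result(chars, q_paths[1], "tsv")
  write_query_result(regions, q_paths[2], "tsv")
  bundle <- export_sparql_bundle(inferred, file.path(out_dir, "sparql"))
  note(6L, "query", "ok", c(q_paths, bundle))

  finish(TRUE, graph = graph, inferred = inferred, nl = nl_docs,
         characteristics = chars, regions = regions)
}

#' @export
print.phs_pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline: %s%s>\n",
              if (x$ok) "ok" else "FAILED",
              if (!x$ok) sprintf(" at step %d", x$failed_step) else ""))
  print(x$steps)
  invisible(x)
}

#' Reproducibility manifest for a pipeline configuration
#'
#' @param config project configuration.
#' @param tbox_paths TBox files whose digests to record (default: the
#'   bundled fixture file).
#' @return Character vector of manifest lines (tool version, config hash,
#'   TBox digests).
#' @export
print_version_manifest <- function(config,
                                   tbox_paths = NULL) {
  if (is.null(tbox_paths)) {
    tbox_paths <- system.file("extdata", "fixture_tbox.ttl",
                              package = "phenoscribe")
    if (tbox_paths == "") {
      tbox_paths <- file.path("inst", "extdata", "fixture_tbox.ttl")
    }
  }
  version <- tryCatch(as.character(utils::packageVersion("phenoscribe")),
                      error = function(e) "dev")
  config <- read_project_config(config)
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(config, cfg_file)
  lines <- c(sprintf("phenoscribe %s", version),
             sprintf("config %s", unname(tools::md5sum(cfg_file))))
  for (p in tbox_paths) {
    lines <- c(lines, sprintf("tbox %s %s", basename(p),
                              unname(tools::md5sum(p))))
  }
  lines
}

#' Write a Makefile wrapper for the pipeline CLI
#'
#' Generates a Makefile whose targets call the bundled `phenoc` command
#' line script step by step, mirroring the make-driven workflow.
#'
#' @param path output Makefile path.
#' @param description description source path.
#' @param config configuration path.
#' @param out_dir artifact directory.
#' @return `path`, invisibly.
#' @export
write_makefile <- function(path, description = "description.phs",
                           config = "project.yaml", out_dir = "out") {
  script <- system.file("scripts", "phenoc.R", package = "phenoscribe")
  if (script == "") script <- file.path("inst", "scripts", "phenoc.R")
  lines <- c(
    sprintf("PHENOC = Rscript %s", script),
    sprintf("DESC = %s", description),
    sprintf("CONFIG = %s", config),
    sprintf("OUT = %s", out_dir),
    "",
    "all: $(OUT)/regions.tsv",
    "",
    "$(OUT)/abox.ttl: $(DESC) $(CONFIG)",
    "\t$(PHENOC) compile $(DESC) -c $(CONFIG) -o $(OUT)",
    "",
    "$(OUT)/validation.json: $(OUT)/abox.ttl",
    "\t$(PHENOC) validate $(DESC) -c $(CONFIG) -o $(OUT)",
    "",
    "$(OUT)/inferred.ttl: $(OUT)/validation.json",
    "\t$(PHENOC) reason $(DESC) -c $(CONFIG) -o $(OUT)",
    "",
    "$(OUT)/regions.tsv: $(OUT)/inferred.ttl",
    "\t$(PHENOC) run $(DESC) -c $(CONFIG) -o $(OUT)",
    "",
    ".PHONY: all")
  writeLines(lines, path)
  invisible(path)
}
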