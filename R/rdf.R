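# Minimal RDF triple store with a Turtle/TriG reader and a deterministic
# writer. Covers the constructs this toolchain emits: prefixed names, full
# IRIs, blank node property lists, collections, plain/typed literals and
# (for TriG) named graphs. Not a general-purpose RDF library.

#' Construct an RDF graph object
#'
#' A lightweight container for a set of triples (optionally quads, when a
#' `graph` column names a TriG graph) plus a prefix map used for
#' serialization.
#'
#' @param triples data.frame with columns `s`, `p`, `o`, `o_type`
#'   (`"iri"`, `"blank"` or `"literal"`), `o_dt` (datatype IRI or `NA`) and
#'   optionally `graph` (named-graph IRI or `NA` for the default graph).
#' @param prefixes named character vector mapping prefix labels to IRI bases.
#' @return An object of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = NULL, prefixes = character()) {
  if (is.null(triples)) {
    triples <- data.frame(s = character(), p = character(), o = character(),
                          o_type = character(), o_dt = character(),
                          graph = character(), stringsAsFactors = FALSE)
  }
  if (is.null(triples$graph)) triples$graph <- rep(NA_character_, nrow(triples))
  if (is.null(triples$o_dt)) triples$o_dt <- rep(NA_character_, nrow(triples))
  structure(list(triples = triples, prefixes = prefixes), class = "rdf_graph")
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d prefixes>\n",
              nrow(x$triples), length(x$prefixes)))
  invisible(x)
}

rdf_triple_row <- function(s, p, o, o_type = "iri", o_dt = NA_character_,
                           graph = NA_character_) {
  data.frame(s = s, p = p, o = o, o_type = o_type, o_dt = o_dt, graph = graph,
             stringsAsFactors = FALSE)
}

## ---- tokenizer -------------------------------------------------------------

rdf_token_patterns <- list(
  WS      = "^[ \t\r\n]+",
  COMMENT = "^#[^\n]*",
  PREFIX  = "^@prefix",
  BASE    = "^@base",
  IRIREF  = "^<[^<>\"{}|^`\\\\ ]*>",
  STRING  = "^\"([^\"\\\\]|\\\\.)*\"",
  BLANK   = "^_:[A-Za-z0-9_]+",
  DTSEP   = "^\\^\\^",
  NUMBER  = "^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
  PNAME   = "^([A-Za-z][A-Za-z0-9_\\-]*)?:([A-Za-z0-9_][A-Za-z0-9_\\-]*)?",
  IDENT   = "^[A-Za-z][A-Za-z0-9_\\-]*",
  PUNCT   = "^[.;,\\[\\](){}]"
)

rdf_tokenize <- function(text) {
  pos <- 1L
  n <- nchar(text)
  types <- character(0); vals <- character(0); lines <- integer(0)
  line <- 1L
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(rdf_token_patterns)) {
      m <- regexpr(rdf_token_patterns[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        tok <- substr(rest, 1L, len)
        if (!(ty %in% c("WS", "COMMENT"))) {
          types <- c(types, ty); vals <- c(vals, tok); lines <- c(lines, line)
        }
        line <- line + lengths(regmatches(tok, gregexpr("\n", tok, fixed = TRUE)))
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("turtle: illegal character %s at line %d",
                   dQuote(substr(rest, 1, 1)), line), call. = FALSE)
    }
  }
  data.frame(type = types, val = vals, line = lines, stringsAsFactors = FALSE)
}

## ---- parser ----------------------------------------------------------------

# Shared by parse_turtle() and parse_trig(). Returns an rdf_graph.
rdf_parse <- function(text, trig = FALSE, file = NULL) {
  toks <- tryCatch(rdf_tokenize(text), error = function(e) {
    stop(sprintf("%s: %s", if (is.null(file)) "input" else file,
                 conditionMessage(e)), call. = FALSE)
  })
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$toks <- toks
  st$prefixes <- character()
  st$bcount <- 0L
  st$rows <- list()
  st$graph <- NA_character_
  st$file <- if (is.null(file)) "input" else file

  peek <- function() if (st$i <= nrow(st$toks)) st$toks[st$i, ] else NULL
  advance <- function() { t <- st$toks[st$i, ]; st$i <- st$i + 1L; t }
  fail <- function(msg, tk = peek()) {
    ln <- if (!is.null(tk)) tk$line else NA
    stop(sprintf("%s: %s (line %s)", st$file, msg, ln), call. = FALSE)
  }
  expect <- function(val) {
    tk <- peek()
    if (is.null(tk) || tk$val != val) fail(sprintf("expected '%s'", val), tk)
    advance()
  }
  emit <- function(s, p, o, o_type, o_dt = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <-
      rdf_triple_row(s, p, o, o_type, o_dt, st$graph)
  }
  new_bnode <- function() {
    st$bcount <- st$bcount + 1L
    sprintf("_:g%d", st$bcount)
  }
  resolve_pname <- function(val, tk) {
    m <- regmatches(val, regexec("^([^:]*):(.*)$", val))[[1]]
    pfx <- m[2]; local <- m[3]
    if (!pfx %in% names(st$prefixes))
      fail(sprintf("undeclared prefix '%s'", pfx), tk)
    paste0(st$prefixes[[pfx]], local)
  }

  # returns list(val=, type=, dt=)
  parse_term <- function(as_subject = FALSE) {
    tk <- peek()
    if (is.null(tk)) fail("unexpected end of input", tk)
    if (tk$type == "IRIREF") {
      advance()
      return(list(val = substr(tk$val, 2, nchar(tk$val) - 1L), type = "iri",
                  dt = NA_character_))
    }
    if (tk$type == "PNAME") {
      advance()
      return(list(val = resolve_pname(tk$val, tk), type = "iri",
                  dt = NA_character_))
    }
    if (tk$type == "BLANK") {
      advance()
      return(list(val = tk$val, type = "blank", dt = NA_character_))
    }
    if (tk$type == "STRING") {
      advance()
      raw <- substr(tk$val, 2, nchar(tk$val) - 1L)
      raw <- gsub("\\\\([\"\\\\])", "\\1", raw)
      raw <- gsub("\\\\n", "\n", raw)
      dt <- NA_character_
      if (!is.null(peek()) && peek()$type == "DTSEP") {
        advance()
        dt <- parse_term()$val
      }
      return(list(val = raw, type = "literal", dt = dt))
    }
    if (tk$type == "NUMBER") {
      advance()
      dt <- if (grepl("[.eE]", tk$val)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      return(list(val = tk$val, type = "literal", dt = dt))
    }
    if (tk$type == "IDENT" && tk$val %in% c("true", "false")) {
      advance()
      return(list(val = tk$val, type = "literal",
                  dt = paste0(XSD_NS, "boolean")))
    }
    if (tk$val == "[") {
      advance()
      id <- new_bnode()
      if (!is.null(peek()) && peek()$val != "]") {
        parse_pred_obj_list(id)
      }
      expect("]")
      return(list(val = id, type = "blank", dt = NA_character_))
    }
    if (tk$val == "(") {
      advance()
      items <- list()
      while (!is.null(peek()) && peek()$val != ")") {
        items[[length(items) + 1L]] <- parse_term()
      }
      expect(")")
      if (length(items) == 0L)
        return(list(val = paste0(RDF_NS, "nil"), type = "iri",
                    dt = NA_character_))
      head_id <- new_bnode()
      cur <- head_id
      for (k in seq_along(items)) {
        it <- items[[k]]
        emit(cur, paste0(RDF_NS, "first"), it$val, it$type, it$dt)
        nxt <- if (k < length(items)) new_bnode() else paste0(RDF_NS, "nil")
        emit(cur, paste0(RDF_NS, "rest"), nxt,
             if (k < length(items)) "blank" else "iri")
        cur <- nxt
      }
      return(list(val = head_id, type = "blank", dt = NA_character_))
    }
    fail(sprintf("unexpected token '%s'", tk$val), tk)
  }

  parse_pred_obj_list <- function(subj) {
    repeat {
      tk <- peek()
      if (is.null(tk)) fail("unexpected end of predicate-object list", tk)
      p <- if (tk$type == "IDENT" && tk$val == "a") {
        advance(); paste0(RDF_NS, "type")
      } else parse_term()$val
      repeat {
        o <- parse_term()
        emit(subj, p, o$val, o$type, o$dt)
        if (!is.null(peek()) && peek()$val == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$val == ";") {
        advance()
        # permit trailing ';' before '.' or ']'
        if (!is.null(peek()) && peek()$val %in% c(".", "]", "}")) break
      } else break
    }
  }

  parse_triples_block <- function() {
    s <- parse_term(as_subject = TRUE)
    parse_pred_obj_list(s$val)
  }

  while (!is.null(peek())) {
    tk <- peek()
    if (tk$type == "PREFIX") {
      advance()
      ptk <- peek()
      if (is.null(ptk) || ptk$type != "PNAME") fail("expected prefix name", ptk)
      advance()
      pfx <- sub(":.*$", "", ptk$val)
      iritk <- peek()
      if (is.null(iritk) || iritk$type != "IRIREF") fail("expected IRI", iritk)
      advance()
      st$prefixes[[pfx]] <- substr(iritk$val, 2, nchar(iritk$val) - 1L)
      expect(".")
    } else if (tk$type == "BASE") {
      advance(); parse_term(); expect(".")
    } else if (trig && (tk$type %in% c("IRIREF", "PNAME")) &&
               st$i < nrow(st$toks) && st$toks[st$i + 1L, "val"] == "{") {
      g <- parse_term()
      expect("{")
      st$graph <- g$val
      while (!is.null(peek()) && peek()$val != "}") {
        parse_triples_block()
        if (!is.null(peek()) && peek()$val == ".") advance()
      }
      expect("}")
      st$graph <- NA_character_
    } else {
      parse_triples_block()
      expect(".")
    }
  }

  triples <- if (length(st$rows)) do.call(rbind, st$rows) else NULL
  rdf_graph(triples, st$prefixes)
}

#' Parse Turtle text or a Turtle file
#'
#' @param x Turtle text (single string) or a path to a `.ttl` file.
#' @return An [rdf_graph()] object.
#' @export
parse_turtle <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    rdf_parse(paste(readLines(x, warn = FALSE), collapse = "\n"), file = x)
  } else {
    rdf_parse(paste(x, collapse = "\n"))
  }
}

#' Parse TriG text or a TriG file (named graphs)
#'
#' @param x TriG text (single string) or a path to a `.trig` file.
#' @return An [rdf_graph()] object; the `graph` column holds graph IRIs.
#' @export
parse_trig <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    rdf_parse(paste(readLines(x, warn = FALSE), collapse = "\n"),
              trig = TRUE, file = x)
  } else {
    rdf_parse(paste(x, collapse = "\n"), trig = TRUE)
  }
}

## ---- serializer ------------------------------------------------------------

rdf_shorten <- function(iri, prefixes) {
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    if (startsWith(iri, base)) {
      local <- substring(iri, nchar(base) + 1L)
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_\\-]*$", local)) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

rdf_render_object <- function(o, o_type, o_dt, prefixes) {
  if (o_type == "literal") {
    if (!is.na(o_dt) && o_dt %in% paste0(XSD_NS, c("decimal", "integer",
                                                   "boolean", "double"))) {
      return(o)
    }
    esc <- gsub("\\", "\\\\", o, fixed = TRUE)
    esc <- gsub("\"", "\\\"", esc, fixed = TRUE)
    esc <- gsub("\n", "\\n", esc, fixed = TRUE)
    lit <- paste0("\"", esc, "\"")
    if (!is.na(o_dt) && o_dt != paste0(XSD_NS, "string")) {
      lit <- paste0(lit, "^^", rdf_shorten(o_dt, prefixes))
    }
    return(lit)
  }
  if (o_type == "blank" || startsWith(o, "_:")) return(o)
  rdf_shorten(o, prefixes)
}

rdf_serialize_block <- function(tr, prefixes, indent = "") {
  out <- character(0)
  subj_order <- unique(tr$s)
  subj_order <- subj_order[order(startsWith(subj_order, "_:"), subj_order)]
  type_iri <- paste0(RDF_NS, "type")
  for (s in subj_order) {
    rows <- tr[tr$s == s, , drop = FALSE]
    preds <- unique(rows$p)
    preds <- preds[order(preds != type_iri, preds)]
    s_txt <- if (startsWith(s, "_:")) s else rdf_shorten(s, prefixes)
    plines <- character(0)
    for (p in preds) {
      prow <- rows[rows$p == p, , drop = FALSE]
      objs <- vapply(seq_len(nrow(prow)), function(k) {
        rdf_render_object(prow$o[k], prow$o_type[k], prow$o_dt[k], prefixes)
      }, character(1))
      objs <- sort(unique(objs))
      p_txt <- if (p == type_iri) "a" else rdf_shorten(p, prefixes)
      plines <- c(plines, paste0(p_txt, " ", paste(objs, collapse = " , ")))
    }
    out <- c(out, paste0(indent, s_txt, " ",
                         paste(plines,
                               collapse = paste0(" ;\n", indent, "    ")),
                         " ."))
  }
  out
}

#' Serialize an RDF graph to Turtle
#'
#' Output is canonical: prefixes, subjects, predicates and objects are
#' emitted in a deterministic sorted order, so two equal graphs serialize
#' byte-identically.
#'
#' @param graph an [rdf_graph()].
#' @param path optional file path; when given the text is also written there.
#' @return The Turtle text, invisibly when `path` is given.
#' @export
serialize_turtle <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "rdf_graph"))
  pfx <- if (length(graph$prefixes)) {
    graph$prefixes[order(names(graph$prefixes))]
  } else {
    character(0)
  }
  header <- sprintf("@prefix %s: <%s> .", names(pfx), unname(pfx))
  body <- rdf_serialize_block(graph$triples, pfx)
  txt <- paste(c(header, "", body, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Serialize an RDF graph with named graphs to TriG
#'
#' @inheritParams serialize_turtle
#' @return The TriG text, invisibly when `path` is given.
#' @export
serialize_trig <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "rdf_graph"))
  pfx <- if (length(graph$prefixes)) {
    graph$prefixes[order(names(graph$prefixes))]
  } else {
    character(0)
  }
  header <- sprintf("@prefix %s: <%s> .", names(pfx), unname(pfx))
  tr <- graph$triples
  out <- header
  default <- tr[is.na(tr$graph), , drop = FALSE]
  if (nrow(default)) out <- c(out, "", rdf_serialize_block(default, pfx))
  for (g in sort(unique(tr$graph[!is.na(tr$graph)]))) {
    block <- tr[!is.na(tr$graph) & tr$graph == g, , drop = FALSE]
    out <- c(out, "", paste0(rdf_shorten(g, pfx), " {"),
             rdf_serialize_block(block, pfx, indent = "    "), "}")
  }
  txt <- paste(c(out, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Test two RDF graphs for triple-set equality
#'
#' Compares the triple multisets (as sets) ignoring row order. Blank node
#' labels are compared literally, which suffices for graphs produced by this
#' package's deterministic serializer.
#'
#' @param a,b [rdf_graph()] objects.
#' @return `TRUE` if the triple sets are identical.
#' @export
rdf_equal <- function(a, b) {
  key <- function(g) {
    tr <- g$triples
    dt <- ifelse(is.na(tr$o_dt), "", tr$o_dt)
    gr <- ifelse(is.na(tr$graph), "", tr$graph)
    sort(paste(gr, tr$s, tr$p, tr$o, tr$o_type, dt, sep = "\r"))
  }
  identical(key(a), key(b))
}

# subset helper: all objects o with subject s and predicate p
rdf_objects <- function(graph, s, p) {
  tr <- graph$triples
  tr$o[tr$s == s & tr$p == p]
}

# walk an rdf:first/rdf:rest collection starting at `node`
rdf_collection <- function(graph, node) {
  out <- character(0)
  nil <- paste0(RDF_NS, "nil")
  while (!identical(node, nil)) {
    f <- rdf_objects(graph, node, paste0(RDF_NS, "first"))
    if (length(f) == 0L) break
    out <- c(out, f[1])
    nxt <- rdf_objects(graph, node, paste0(RDF_NS, "rest"))
    if (length(nxt) == 0L) break
    node <- nxt[1]
  }
  out
}
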