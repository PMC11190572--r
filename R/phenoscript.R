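# Parser for the semantic-phenotype description language. A statement is an
# alternating chain of nodes (ontology terms, numeric literals, or
# parenthesised node lists) and edges (alias glyphs or dotted properties),
# terminated by ";". Terms are dash-curies ("aism-protibia"); a node may
# carry an identity tag (":md-c4c164"), an OTU binding ("::otu_id", and
# ":otu_id" when the suffix names a declared OTU) and a bracketed option
# ("[exclude = True]").

ps_glyphs <- c("!>", "|>|", "|<|", ">>", "<<", ">", "<")

ps_token_patterns <- list(
  WS      = "^[ \t\r\n]+",
  COMMENT = "^#[^\n]*",
  GLYPH   = "^(!>|\\|>\\||\\|<\\||>>|<<|>|<)",
  DOTPROP = "^\\.[A-Za-z][A-Za-z0-9_]*-[A-Za-z0-9_\\-]+",
  NUMBER  = "^[0-9]+(\\.[0-9]+)?",
  TERM    = "^[A-Za-z][A-Za-z0-9_]*-[A-Za-z0-9_\\-]*[A-Za-z0-9_]",
  DCOLON  = "^::",
  COLON   = "^:",
  IDENT   = "^[A-Za-z_][A-Za-z0-9_\\-]*",
  PUNCT   = "^[();,\\[\\]=]"
)

#' Tokenize description-language source text
#'
#' @param text source text.
#' @return data.frame with columns `type`, `val`, `line`, `col`.
#' @export
ps_lex <- function(text) {
  pos <- 1L; n <- nchar(text); line <- 1L; col <- 1L
  types <- character(0); vals <- character(0)
  lines <- integer(0); cols <- integer(0)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(ps_token_patterns)) {
      m <- regexpr(ps_token_patterns[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        tok <- substr(rest, 1L, len)
        if (!(ty %in% c("WS", "COMMENT"))) {
          types <- c(types, ty); vals <- c(vals, tok)
          lines <- c(lines, line); cols <- c(cols, col)
        }
        nl <- lengths(regmatches(tok, gregexpr("\n", tok, fixed = TRUE)))
        if (nl > 0L) {
          line <- line + nl
          col <- nchar(sub(".*\n", "", tok)) + 1L
        } else {
          col <- col + len
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("lex error: illegal character %s at line %d, col %d",
                   dQuote(substr(rest, 1, 1)), line, col), call. = FALSE)
    }
  }
  data.frame(type = types, val = vals, line = lines, col = cols,
             stringsAsFactors = FALSE)
}

ps_node <- function(kind, term = NA_character_, tag = NA_character_,
                    otu = NA_character_, exclude = FALSE, value = NA_real_,
                    items = NULL, line = NA_integer_) {
  structure(list(kind = kind, term = term, tag = tag, otu = otu,
                 exclude = exclude, value = value, items = items,
                 line = line), class = "ps_node")
}

ps_edge <- function(glyph = NA_character_, property = NA_character_,
                    negated = FALSE, line = NA_integer_) {
  structure(list(kind = "edge", glyph = glyph, property = property,
                 negated = negated, line = line), class = "ps_edge")
}

# parser state over a token data.frame
ps_state <- function(toks, declared_otus = character(),
                     prefixes = NULL) {
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L
  st$otus <- declared_otus
  st$prefixes <- prefixes
  st
}
ps_peek <- function(st) if (st$i <= nrow(st$toks)) st$toks[st$i, ] else NULL
ps_advance <- function(st) { t <- st$toks[st$i, ]; st$i <- st$i + 1L; t }
ps_fail <- function(st, msg, tk = ps_peek(st)) {
  ln <- if (!is.null(tk)) tk$line else NA
  stop(sprintf("syntax error: %s (line %s)", msg, ln), call. = FALSE)
}

ps_check_prefix <- function(st, curie, tk) {
  if (is.null(st$prefixes)) return(invisible())
  parts <- split_curie(curie)
  if (is.null(parts) || !parts$prefix %in% names(st$prefixes)) {
    ps_fail(st, sprintf("unresolved prefix in term '%s'", curie), tk)
  }
}

ps_parse_option <- function(st, node) {
  ps_advance(st)  # "["
  key_tk <- ps_peek(st)
  if (is.null(key_tk) || key_tk$type != "IDENT") ps_fail(st, "expected option key")
  ps_advance(st)
  eq <- ps_peek(st)
  if (is.null(eq) || eq$val != "=") ps_fail(st, "expected '=' in option")
  ps_advance(st)
  val_tk <- ps_peek(st)
  if (is.null(val_tk)) ps_fail(st, "expected option value")
  ps_advance(st)
  close <- ps_peek(st)
  if (is.null(close) || close$val != "]") ps_fail(st, "expected ']'")
  ps_advance(st)
  if (key_tk$val == "exclude") {
    node$exclude <- identical(val_tk$val, "True") || identical(val_tk$val, "true")
  } else {
    warning(sprintf("unknown node option '%s' ignored (line %d)",
                    key_tk$val, key_tk$line), call. = FALSE)
  }
  node
}

ps_parse_term_node <- function(st) {
  tk <- ps_peek(st)
  if (is.null(tk) || tk$type != "TERM") ps_fail(st, "expected a term")
  ps_advance(st)
  ps_check_prefix(st, tk$val, tk)
  node <- ps_node("term", term = tk$val, line = tk$line)
  nxt <- ps_peek(st)
  if (!is.null(nxt) && nxt$type %in% c("COLON", "DCOLON")) {
    sep <- ps_advance(st)
    name_tk <- ps_peek(st)
    if (is.null(name_tk) || !name_tk$type %in% c("IDENT", "TERM")) {
      ps_fail(st, "expected a tag or OTU id after ':'")
    }
    ps_advance(st)
    if (sep$type == "DCOLON" || name_tk$val %in% st$otus) {
      node$otu <- name_tk$val
    } else {
      node$tag <- name_tk$val
    }
  }
  nxt <- ps_peek(st)
  if (!is.null(nxt) && nxt$val == "[") node <- ps_parse_option(st, node)
  node
}

ps_parse_node <- function(st) {
  tk <- ps_peek(st)
  if (is.null(tk)) ps_fail(st, "unexpected end of statement")
  if (tk$type == "NUMBER") {
    ps_advance(st)
    return(ps_node("literal", value = as.numeric(tk$val), line = tk$line))
  }
  if (tk$val == "(") {
    ps_advance(st)
    items <- list(ps_parse_term_node(st))
    while (!is.null(ps_peek(st)) && ps_peek(st)$val == ",") {
      ps_advance(st)
      items[[length(items) + 1L]] <- ps_parse_term_node(st)
    }
    close <- ps_peek(st)
    if (is.null(close) || close$val != ")") ps_fail(st, "expected ')'")
    ps_advance(st)
    return(ps_node("list", items = items, line = tk$line))
  }
  ps_parse_term_node(st)
}

ps_parse_one_statement <- function(st) {
  first <- ps_peek(st)
  if (!is.null(first) && (first$type %in% c("GLYPH", "DOTPROP"))) {
    ps_fail(st, "statement must begin with a node, not an edge")
  }
  elements <- list(ps_parse_node(st))
  repeat {
    tk <- ps_peek(st)
    if (is.null(tk)) {
      ps_fail(st, "unterminated statement (missing ';')",
              st$toks[nrow(st$toks), ])
    }
    if (tk$val == ";") {
      ps_advance(st)
      break
    }
    if (tk$type == "GLYPH") {
      ps_advance(st)
      elements[[length(elements) + 1L]] <-
        ps_edge(glyph = tk$val, negated = tk$val == "!>", line = tk$line)
    } else if (tk$type == "DOTPROP") {
      ps_advance(st)
      curie <- substring(tk$val, 2L)
      ps_check_prefix(st, curie, tk)
      elements[[length(elements) + 1L]] <- ps_edge(property = curie,
                                                   line = tk$line)
    } else {
      ps_fail(st, sprintf("expected an edge or ';', found '%s'", tk$val), tk)
    }
    nxt <- ps_peek(st)
    if (is.null(nxt) || nxt$val == ";") {
      ps_fail(st, "statement must end with a node, not an edge", tk)
    }
    elements[[length(elements) + 1L]] <- ps_parse_node(st)
  }
  structure(list(elements = elements, line = elements[[1]]$line),
            class = "ps_statement")
}

#' Parse a single description statement
#'
#' @param text one `";"`-terminated statement.
#' @param declared_otus character vector of OTU ids; a `":name"` suffix is
#'   read as an OTU binding when `name` is declared, as an identity tag
#'   otherwise.
#' @return A `ps_statement`: a list of alternating node/edge elements.
#' @export
parse_statement <- function(text, declared_otus = character()) {
  st <- ps_state(ps_lex(text), declared_otus)
  stmt <- ps_parse_one_statement(st)
  if (!is.null(ps_peek(st))) ps_fail(st, "trailing input after statement")
  stmt
}

#' Read a project configuration
#'
#' @param config a YAML file path, YAML text, or an already-parsed list.
#'   Must declare `prefixes` (prefix to IRI base) and `otus` (records with
#'   `id`, `label`, `taxon_id`, `parent_name_usage_id`, `catalog_number`,
#'   `habitat`, optional `organism_class`).
#' @return The configuration list.
#' @export
read_project_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$prefixes)) {
    stop("config must declare a 'prefixes' map", call. = FALSE)
  }
  if (is.null(config$otus)) config$otus <- list()
  for (k in seq_along(config$otus)) {
    if (is.null(config$otus[[k]]$organism_class)) {
      config$otus[[k]]$organism_class <- "uberon-male_organism"
    }
  }
  config
}

#' Parse a description document
#'
#' A document interleaves OTU headers (`OTU <id> ;`) with statements; each
#' statement is owned by the most recent OTU. Every term prefix must be
#' declared in the configuration.
#'
#' @param text description source text (or a path to a `.phs` file).
#' @param config project configuration ([read_project_config()] input).
#' @return A `ps_document`: list with `config`, `otus` and `statements`
#'   (each statement carries its owning `otu`).
#' @export
parse_document <- function(text, config) {
  config <- read_project_config(config)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  } else {
    text <- paste(text, collapse = "\n")
  }
  otu_ids <- vapply(config$otus, function(o) o$id, character(1))
  st <- ps_state(ps_lex(text), otu_ids, prefixes = config$prefixes)
  statements <- list()
  seen_otus <- character(0)
  current <- NA_character_
  while (!is.null(ps_peek(st))) {
    tk <- ps_peek(st)
    if (tk$type == "IDENT" && tk$val == "OTU") {
      ps_advance(st)
      name_tk <- ps_peek(st)
      if (is.null(name_tk) || name_tk$type != "IDENT") {
        ps_fail(st, "expected an OTU id after 'OTU'")
      }
      ps_advance(st)
      if (!name_tk$val %in% otu_ids) {
        ps_fail(st, sprintf("OTU '%s' not declared in config", name_tk$val),
                name_tk)
      }
      semi <- ps_peek(st)
      if (is.null(semi) || semi$val != ";") ps_fail(st, "expected ';'")
      ps_advance(st)
      current <- name_tk$val
      seen_otus <- union(seen_otus, current)
    } else {
      if (is.na(current)) {
        ps_fail(st, "statement before any OTU header")
      }
      stmt <- ps_parse_one_statement(st)
      stmt$otu <- current
      statements[[length(statements) + 1L]] <- stmt
    }
  }
  structure(list(config = config, otus = seen_otus, statements = statements),
            class = "ps_document")
}

#' @export
print.ps_document <- function(x, ...) {
  cat(sprintf("<ps_document: %d OTUs, %d statements>\n",
              length(x$otus), length(x$statements)))
  invisible(x)
}

ps_unparse_node <- function(node) {
  if (node$kind == "literal") {
    return(format(node$value, trim = TRUE, scientific = FALSE))
  }
  if (node$kind == "list") {
    return(paste0("(", paste(vapply(node$items, ps_unparse_node, character(1)),
                             collapse = ", "), ")"))
  }
  out <- node$term
  if (!is.na(node$otu)) out <- paste0(out, "::", node$otu)
  if (!is.na(node$tag)) out <- paste0(out, ":", node$tag)
  if (isTRUE(node$exclude)) out <- paste0(out, "[exclude = True]")
  out
}

#' Render a statement back to canonical source text
#'
#' The canonical form re-parses to an identical AST (round-trip
#' idempotence); OTU bindings normalize to the `"::"` spelling.
#'
#' @param stmt a `ps_statement`.
#' @return A single source line ending in `";"`.
#' @export
unparse_statement <- function(stmt) {
  parts <- vapply(stmt$elements, function(el) {
    if (inherits(el, "ps_edge")) {
      if (!is.na(el$glyph)) el$glyph else paste0(".", el$property)
    } else {
      ps_unparse_node(el)
    }
  }, character(1))
  paste0(paste(parts, collapse = " "), ";")
}

#' Render a whole document to canonical source text
#' @param doc a `ps_document`.
#' @return Character vector of source lines.
#' @export
unparse_document <- function(doc) {
  out <- character(0)
  current <- NA_character_
  for (stmt in doc$statements) {
    if (!identical(stmt$otu, current)) {
      current <- stmt$otu
      out <- c(out, sprintf("OTU %s ;", current))
    }
    out <- c(out, unparse_statement(stmt))
  }
  out
}
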