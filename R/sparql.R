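# Minimal SPARQL SELECT parser for the supported fragment:
#   PREFIX declarations, SELECT [DISTINCT] ?vars|*, WHERE { basic graph
#   pattern + simple FILTER comparisons }.
# Everything outside the fragment (OPTIONAL, UNION, GRAPH, property paths,
# aggregates, ...) is rejected with an "unsupported fragment" error. The
# fragment suffices for the package's federated query templates, which are
# pure BGPs with an owl:sameAs mediator pattern.

#' SparqlQuery: a parsed SELECT query over a basic graph pattern
#'
#' @slot select projected variable names (without "?"), or "*".
#' @slot distinct logical, SELECT DISTINCT.
#' @slot patterns list of triple patterns from [tp()].
#' @slot filters list of comparison filters: list(var, op, value).
#' @export
setClass("SparqlQuery",
         representation(select = "character", distinct = "logical",
                        patterns = "list", filters = "list"))

setValidity("SparqlQuery", function(object) {
  if (!length(object@patterns)) return("query has no triple patterns")
  TRUE
})

#' Construct a triple pattern
#'
#' Each position is a variable (`"?x"`) or a ground canonical term (IRI
#' term or literal term).
#'
#' @param s,p,o subject, predicate, object terms.
#' @return a triple pattern (named list with class "TriplePattern").
#' @export
tp <- function(s, p, o) {
  chk <- function(t, pos) {
    if (isVariable(t) || validGroundTerm(t)) return(t)
    stop("invalid term in triple pattern (", pos, "): ", t)
  }
  structure(list(s = chk(s, "subject"), p = chk(p, "predicate"),
                 o = chk(o, "object")),
            class = "TriplePattern")
}

patternVars <- function(p) {
  t <- unlist(p[c("s", "p", "o")], use.names = FALSE)
  unique(vapply(t[isVariable(t)], varName, character(1)))
}

#' @rdname SparqlQuery-class
#' @param patterns list of triple patterns.
#' @param select projected variables (names, no "?") or "*".
#' @param distinct SELECT DISTINCT semantics.
#' @param filters list of `list(var, op, value)` comparisons.
#' @return a `SparqlQuery`.
#' @export
bgpQuery <- function(patterns, select = "*", distinct = FALSE,
                     filters = list()) {
  methods::new("SparqlQuery", select = select, distinct = distinct,
               patterns = patterns, filters = filters)
}

setMethod("show", "SparqlQuery", function(object) {
  cat(sprintf("SparqlQuery: SELECT %s%s over %d triple pattern(s), %d filter(s)\n",
              if (object@distinct) "DISTINCT " else "",
              paste(object@select, collapse = " "),
              length(object@patterns), length(object@filters)))
})

UNSUPPORTED <- c("OPTIONAL", "UNION", "GRAPH", "SERVICE", "MINUS", "VALUES",
                 "BIND", "EXISTS", "ORDER", "GROUP", "HAVING", "LIMIT",
                 "OFFSET", "ASK", "CONSTRUCT", "DESCRIBE")

sparqlTokens <- function(body) {
  pat <- paste0(
    '<[^>]*>',                                   # IRI
    '|"(?:\\\\.|[^"\\\\])*"(?:\\^\\^<[^>]*>|@[A-Za-z][A-Za-z0-9-]*)?', # literal
    '|\\?[A-Za-z_][A-Za-z0-9_]*',                # variable
    '|FILTER\\s*\\([^)]*\\)',                    # filter
    '|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%#-]*',# prefixed name
    '|-?[0-9]+\\.[0-9]+|-?[0-9]+',               # numbers
    '|\\ba\\b',                                  # rdf:type shorthand
    '|\\.')
  m <- gregexpr(pat, body, perl = TRUE)
  regmatches(body, m)[[1]]
}

expandTerm <- function(tok, prefixes) {
  if (startsWith(tok, "<") || startsWith(tok, "\"") || startsWith(tok, "?"))
    return(tok)
  if (tok == "a") return(iriTerm(RDF_TYPE))
  if (grepl("^-?[0-9]+$", tok)) return(intLiteral(as.integer(tok)))
  if (grepl("^-?[0-9]+\\.[0-9]+$", tok))
    return(paste0("\"", tok, "\"^^<", XSD_DOUBLE, ">"))
  m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", tok))[[1]]
  if (length(m) && m[2] %in% names(prefixes))
    return(iriTerm(paste0(prefixes[[m[2]]], m[3])))
  stop("unsupported fragment: unresolvable token '", tok, "'")
}

parseFilter <- function(tok) {
  m <- regmatches(tok, regexec(
    "^FILTER\\s*\\(\\s*\\?([A-Za-z_][A-Za-z0-9_]*)\\s*(>=|<=|!=|>|<|=)\\s*(.+?)\\s*\\)$",
    tok))[[1]]
  if (!length(m)) stop("unsupported fragment: FILTER must be a simple comparison")
  rhsTok <- m[4]
  rhs <- if (grepl('^"', rhsTok)) unescapeLiteral(gsub('^"|"$', "", rhsTok))
         else suppressWarnings(as.numeric(rhsTok))
  if (is.null(rhs) || (is.numeric(rhs) && is.na(rhs)))
    stop("unsupported fragment: FILTER operand '", rhsTok, "'")
  list(var = m[2], op = m[3], value = rhs)
}

#' Parse a SPARQL SELECT query
#'
#' @param text query text (or a length-1 path readable via [parseSparqlFile()]).
#' @return a `SparqlQuery`.
#' @export
parseSparql <- function(text) {
  text <- paste(text, collapse = "\n")
  noStr <- gsub('"(?:\\\\.|[^"\\\\])*"', '""', text, perl = TRUE)
  hit <- UNSUPPORTED[vapply(UNSUPPORTED, function(k)
    grepl(paste0("\\b", k, "\\b"), noStr, ignore.case = TRUE), logical(1))]
  if (length(hit))
    stop("unsupported fragment: ", paste(hit, collapse = ", "),
         " (only SELECT over basic graph patterns with simple FILTERs)")
  prefixes <- character(0)
  pm <- gregexpr("PREFIX\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>", text,
                 perl = TRUE, ignore.case = TRUE)
  for (tokm in regmatches(text, pm)[[1]]) {
    g <- regmatches(tokm, regexec(
      "PREFIX\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>", tokm,
      ignore.case = TRUE))[[1]]
    prefixes[g[2]] <- g[3]
  }
  sm <- regmatches(text, regexec(
    "SELECT\\s+(DISTINCT\\s+)?(.*?)\\s*WHERE\\s*\\{(.*)\\}", text,
    ignore.case = TRUE))[[1]]
  if (!length(sm)) stop("unsupported fragment: expected SELECT ... WHERE { ... }")
  distinct <- nzchar(trimws(sm[2]))
  selTok <- trimws(sm[3])
  select <- if (selTok == "*") "*" else {
    v <- regmatches(selTok, gregexpr("\\?[A-Za-z_][A-Za-z0-9_]*", selTok))[[1]]
    if (!length(v)) stop("unsupported fragment: empty SELECT clause")
    vapply(v, varName, character(1), USE.NAMES = FALSE)
  }
  toks <- sparqlTokens(sm[4])
  patterns <- list()
  filters <- list()
  buf <- character(0)
  for (tok in toks) {
    if (startsWith(tok, "FILTER")) { filters[[length(filters) + 1L]] <- parseFilter(tok); next }
    if (tok == ".") {
      if (length(buf) %% 3L != 0L)
        stop("unsupported fragment: triple pattern with ", length(buf), " terms")
      next
    }
    buf <- c(buf, tok)
    if (length(buf) == 3L) {
      terms <- vapply(buf, expandTerm, character(1), prefixes = prefixes,
                      USE.NAMES = FALSE)
      patterns[[length(patterns) + 1L]] <- tp(terms[1], terms[2], terms[3])
      buf <- character(0)
    }
  }
  if (length(buf))
    stop("unsupported fragment: dangling terms in graph pattern")
  bgpQuery(patterns, select = select, distinct = distinct, filters = filters)
}

#' @rdname parseSparql
#' @param path path to a .rq file.
#' @export
parseSparqlFile <- function(path) parseSparql(readLines(path, warn = FALSE))

applyFilters <- function(bindings, filters) {
  for (f in filters) {
    if (!f$var %in% names(bindings))
      stop("FILTER references unbound variable ?", f$var)
    lhs <- if (is.numeric(f$value)) termNumber(bindings[[f$var]])
           else vapply(termValue(bindings[[f$var]]), as.character, character(1))
    keep <- switch(f$op,
                   ">" = lhs > f$value, "<" = lhs < f$value,
                   ">=" = lhs >= f$value, "<=" = lhs <= f$value,
                   "=" = lhs == f$value, "!=" = lhs != f$value)
    keep[is.na(keep)] <- FALSE
    bindings <- bindings[keep, , drop = FALSE]
  }
  bindings
}

projectBindings <- function(bindings, query) {
  vars <- if (identical(query@select, "*")) names(bindings) else query@select
  miss <- setdiff(vars, names(bindings))
  for (v in miss) bindings[[v]] <- rep(NA_character_, nrow(bindings))
  out <- bindings[vars]
  rownames(out) <- NULL
  if (query@distinct) out <- unique(out)
  out
}
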