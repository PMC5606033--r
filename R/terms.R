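# RDF term model. Terms are carried everywhere as canonical N-Triples-style
# tokens so that equality, joins and N-Quads serialization are all plain
# string operations:
#   IRI            <http://example.org/x>
#   plain literal  "text"
#   typed literal  "23904678"^^<http://www.w3.org/2001/XMLSchema#integer>
#   variable       ?name            (query layer only; never stored)

XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
XSD_DOUBLE  <- "http://www.w3.org/2001/XMLSchema#double"
RDF_TYPE    <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
OWL_SAMEAS  <- "http://www.w3.org/2002/07/owl#sameAs"

#' Construct an IRI term
#'
#' Wraps an absolute IRI string into the canonical `<...>` token used
#' throughout the package.
#'
#' @param x character vector of absolute IRIs (must contain a scheme colon).
#' @return character vector of IRI terms.
#' @export
iriTerm <- function(x) {
  if (any(!nzchar(x) | !grepl(":", x, fixed = TRUE)))
    stop("IRIs must be non-empty and absolute (contain a scheme colon)")
  paste0("<", x, ">")
}

#' @rdname iriTerm
#' @param term character vector of terms.
#' @export
isIRITerm <- function(term) startsWith(term, "<") & endsWith(term, ">")

#' @rdname iriTerm
#' @export
isLiteralTerm <- function(term) startsWith(term, "\"")

#' @rdname iriTerm
#' @export
isVariable <- function(term) startsWith(term, "?")

varName <- function(term) substring(term, 2L)

#' @rdname iriTerm
#' @export
iriText <- function(term) {
  stopifnot(all(isIRITerm(term)))
  substr(term, 2L, nchar(term) - 1L)
}

escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescapeLiteral <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Literal term constructors
#'
#' Build plain, integer-typed or double-typed literal terms. Numeric
#' lexical forms are fixed (no scientific notation for integers) so that
#' identical values always yield identical terms.
#'
#' @param x values to encode.
#' @return character vector of literal terms.
#' @export
plainLiteral <- function(x) paste0("\"", escapeLiteral(as.character(x)), "\"")

#' @rdname plainLiteral
#' @export
intLiteral <- function(x) {
  paste0("\"", format(as.integer(x), scientific = FALSE, trim = TRUE),
         "\"^^<", XSD_INTEGER, ">")
}

#' @rdname plainLiteral
#' @export
dblLiteral <- function(x) {
  paste0("\"", vapply(as.numeric(x), function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (grepl(".", s, fixed = TRUE)) s <- sub("\\.?0+$", "", s)
    s
  }, character(1)), "\"^^<", XSD_DOUBLE, ">")
}

#' Extract the value carried by a term
#'
#' Literals typed as xsd:integer/xsd:double are returned as numerics, other
#' literals as their (unescaped) lexical form, IRIs as the IRI string.
#'
#' @param term character vector of terms.
#' @return list of values (numeric or character).
#' @export
termValue <- function(term) {
  lapply(term, function(t) {
    if (isIRITerm(t)) return(iriText(t))
    if (!isLiteralTerm(t)) stop("not a ground term: ", t)
    m <- regmatches(t, regexec('^"(.*)"(?:\\^\\^<([^>]*)>)?$', t))[[1]]
    lex <- unescapeLiteral(m[2])
    dt <- m[3]
    if (nzchar(dt) && dt %in% c(XSD_INTEGER, XSD_DOUBLE)) as.numeric(lex) else lex
  })
}

#' @rdname termValue
#' @export
termNumber <- function(term) {
  v <- termValue(term)
  vapply(v, function(x) if (is.numeric(x)) x else suppressWarnings(as.numeric(x)),
         numeric(1))
}

# percent-encoding for key text embedded in minted IRIs
encodeKeyText <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

#' Mint a deterministic IRI from a natural key
#'
#' Same inputs always yield the same IRI; key text is percent-encoded so the
#' result parses as an absolute IRI. The key is recoverable from the last
#' path segment (see [keyTextFromIRI()]).
#'
#' @param baseIri namespace prefix ending in "/" (plain IRI string).
#' @param kind resource kind (e.g. "gene", "sample"), becomes a path segment.
#' @param ... one or more non-empty key fields.
#' @return a single IRI term.
#' @export
mintIRI <- function(baseIri, kind, ...) {
  keys <- as.character(unlist(list(...)))
  if (length(keys) == 0L || any(is.na(keys)) || any(!nzchar(keys)))
    stop("mintIRI: empty natural key for kind '", kind, "'")
  iriTerm(paste0(baseIri, kind, "/", paste(encodeKeyText(keys), collapse = "/")))
}

#' @rdname mintIRI
#' @param term IRI term(s) minted by `mintIRI`.
#' @export
keyTextFromIRI <- function(term) {
  vapply(term, function(t) {
    p <- iriText(t)
    utils::URLdecode(sub(".*/", "", p))
  }, character(1), USE.NAMES = FALSE)
}

validGroundTerm <- function(term) {
  isIRITerm(term) |
    grepl('^"(\\\\.|[^"\\\\])*"(\\^\\^<[^>]+>|@[A-Za-z][A-Za-z0-9-]*)?$', term)
}
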