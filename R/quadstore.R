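#' QuadStore: an in-memory multiset of RDF quads
#'
#' Holds subject/predicate/object/graph quads, each component a canonical
#' term token (see [iriTerm()]). Subjects, predicates and graphs are IRIs;
#' objects are IRIs or literals. The store is a multiset: duplicates are
#' kept as inserted; [datasetStats()] counts distinct quads.
#'
#' @slot quads data.frame with character columns subject, predicate,
#'   object, graph.
#' @export
setClass("QuadStore", representation(quads = "data.frame"))

setValidity("QuadStore", function(object) {
  q <- object@quads
  need <- c("subject", "predicate", "object", "graph")
  if (!all(need %in% names(q)))
    return("quads must have columns subject, predicate, object, graph")
  if (nrow(q) == 0L) return(TRUE)
  for (col in c("subject", "predicate", "graph")) {
    bad <- !isIRITerm(q[[col]])
    if (any(bad))
      return(sprintf("%s contains a non-IRI term: %s", col, q[[col]][bad][1]))
  }
  badO <- !validGroundTerm(q$object)
  if (any(badO))
    return(sprintf("malformed object term: %s", q$object[badO][1]))
  TRUE
})

quadDF <- function(subject = character(), predicate = character(),
                   object = character(), graph = character()) {
  data.frame(subject = subject, predicate = predicate, object = object,
             graph = graph, stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname QuadStore-class
#' @param subject,predicate,object,graph equal-length character vectors of
#'   canonical terms, or `subject` may be a 4-column data.frame.
#' @return a `QuadStore`.
#' @export
QuadStore <- function(subject = character(), predicate = character(),
                      object = character(), graph = character()) {
  df <- if (is.data.frame(subject)) {
    stopifnot(all(c("subject", "predicate", "object", "graph") %in% names(subject)))
    d <- subject[c("subject", "predicate", "object", "graph")]
    rownames(d) <- NULL
    d
  } else quadDF(subject, predicate, object, graph)
  methods::new("QuadStore", quads = df)
}

#' @rdname QuadStore-class
#' @param x a `QuadStore`.
#' @export
quads <- function(x) x@quads

#' @rdname QuadStore-class
#' @export
nquads <- function(x) nrow(x@quads)

#' @rdname QuadStore-class
#' @export
graphIRIs <- function(x) sort(unique(x@quads$graph))

#' @rdname QuadStore-class
#' @param ... `QuadStore`s to concatenate.
#' @export
bindStores <- function(...) {
  parts <- lapply(list(...), quads)
  QuadStore(do.call(rbind, c(list(quadDF()), parts)))
}

#' @rdname QuadStore-class
#' @param graph graph IRI term(s) to keep.
#' @export
subsetGraph <- function(x, graph) {
  QuadStore(x@quads[x@quads$graph %in% graph, , drop = FALSE])
}

#' @rdname QuadStore-class
#' @export
dedupQuads <- function(x) QuadStore(unique(x@quads))

setMethod("show", "QuadStore", function(object) {
  g <- graphIRIs(object)
  cat(sprintf("QuadStore with %d quads in %d named graph(s)\n",
              nquads(object), length(g)))
  for (gi in utils::head(g, 5))
    cat("  ", gi, ": ", sum(object@quads$graph == gi), " quads\n", sep = "")
  if (length(g) > 5) cat("  ...\n")
})

quadKeys <- function(x) {
  q <- quads(x)
  paste(q$subject, q$predicate, q$object, q$graph)
}

#' Multiset equality of two quad stores
#'
#' @param a,b `QuadStore`s.
#' @return TRUE iff the two stores hold the same quads with the same
#'   multiplicities, in any order.
#' @export
sameQuadMultiset <- function(a, b) {
  identical(sort(quadKeys(a)), sort(quadKeys(b)))
}

#' Dataset statistics
#'
#' Distinct counts over the quad multiset of a store, as reported for RDF
#' datasets: distinct quads, subjects, predicates and objects.
#'
#' @slot nTriples,nSubjects,nPredicates,nObjects distinct counts.
#' @slot sizeBytes serialized N-Quads size (NA when not computed).
#' @export
setClass("DatasetStats",
         representation(nTriples = "integer", nSubjects = "integer",
                        nPredicates = "integer", nObjects = "integer",
                        sizeBytes = "numeric"))

setValidity("DatasetStats", function(object) {
  if (object@nSubjects > object@nTriples) return("nSubjects > nTriples")
  if (object@nPredicates > object@nTriples) return("nPredicates > nTriples")
  TRUE
})

#' @rdname DatasetStats-class
#' @param x a `QuadStore`.
#' @param sizeBytes also compute the serialized size.
#' @return a `DatasetStats`.
#' @export
datasetStats <- function(x, sizeBytes = FALSE) {
  q <- unique(quads(x))
  sz <- if (sizeBytes && nrow(q))
    sum(nchar(paste(q$subject, q$predicate, q$object, q$graph, ".\n"),
              type = "bytes")) else NA_real_
  methods::new("DatasetStats",
               nTriples = nrow(q),
               nSubjects = length(unique(q$subject)),
               nPredicates = length(unique(q$predicate)),
               nObjects = length(unique(q$object)),
               sizeBytes = sz)
}

setMethod("show", "DatasetStats", function(object) {
  cat(sprintf("DatasetStats: %d triples, %d subjects, %d predicates, %d objects\n",
              object@nTriples, object@nSubjects, object@nPredicates,
              object@nObjects))
})

#' @rdname DatasetStats-class
#' @export
nTriples <- function(x) x@nTriples
#' @rdname DatasetStats-class
#' @export
nSubjects <- function(x) x@nSubjects
#' @rdname DatasetStats-class
#' @export
nPredicates <- function(x) x@nPredicates
#' @rdname DatasetStats-class
#' @export
nObjects <- function(x) x@nObjects

## ---- N-Quads serialization ------------------------------------------------

#' Read and write N-Quads
#'
#' `writeNQuads` serializes a store one quad per line; `readNQuads` parses
#' the file back. Round-tripping preserves the quad multiset exactly,
#' including literal datatypes.
#'
#' @param x a `QuadStore`.
#' @param path file path.
#' @return `readNQuads` returns a `QuadStore`; `writeNQuads` returns `path`
#'   invisibly.
#' @export
writeNQuads <- function(x, path) {
  q <- quads(x)
  bad <- !(isIRITerm(q$subject) & isIRITerm(q$predicate) & isIRITerm(q$graph) &
             validGroundTerm(q$object))
  if (any(bad))
    stop("cannot serialize malformed quad: ",
         paste(q[which(bad)[1], ], collapse = " "))
  lines <- if (nrow(q)) paste(q$subject, q$predicate, q$object, q$graph, ".")
           else character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# scan one term starting at position i of line; returns list(term, next_i)
scanTerm <- function(line, i, lineno) {
  n <- nchar(line)
  while (i <= n && substr(line, i, i) %in% c(" ", "\t")) i <- i + 1L
  if (i > n) stop("N-Quads parse error (line ", lineno, "): unexpected end")
  ch <- substr(line, i, i)
  if (ch == "<") {
    j <- regexpr(">", substring(line, i), fixed = TRUE)
    if (j < 0) stop("N-Quads parse error (line ", lineno, "): unterminated IRI")
    return(list(term = substr(line, i, i + j - 1L), i = i + j))
  }
  if (ch == "\"") {
    j <- i + 1L
    while (j <= n) {
      cj <- substr(line, j, j)
      if (cj == "\\") { j <- j + 2L; next }
      if (cj == "\"") break
      j <- j + 1L
    }
    if (j > n) stop("N-Quads parse error (line ", lineno, "): unterminated literal")
    end <- j
    rest <- substring(line, j + 1L)
    m <- regmatches(rest, regexpr("^(\\^\\^<[^>]*>|@[A-Za-z][A-Za-z0-9-]*)", rest))
    if (length(m) && nzchar(m)) end <- j + nchar(m)
    return(list(term = substr(line, i, end), i = end + 1L))
  }
  if (ch == ".") return(list(term = ".", i = i + 1L))
  stop("N-Quads parse error (line ", lineno, "): unexpected character '", ch, "'")
}

#' @rdname writeNQuads
#' @export
readNQuads <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  linenos <- which(keep)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    i <- 1L
    terms <- character(4)
    for (t in 1:4) {
      sc <- scanTerm(lines[k], i, linenos[k])
      terms[t] <- sc$term
      i <- sc$i
    }
    dot <- scanTerm(lines[k], i, linenos[k])
    if (dot$term != ".")
      stop("N-Quads parse error (line ", linenos[k], "): expected terminating '.'")
    out[[k]] <- terms
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(character(), ncol = 4)
  QuadStore(quadDF(m[, 1], m[, 2], m[, 3], m[, 4]))
}
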