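# owl:sameAs link discovery between named graphs.
#
# Exact-key rules equate key resources (the minted gene/sample/cg/ensembl
# IRIs emitted by the RDFizer) whose decoded key text agrees after a
# normalization policy. Positional rules equate CNV segment resources on
# the same normalized chromosome with identical (start, end) — the default,
# exact mode — or with intervals overlapping after symmetric extension by a
# tolerance (overlap mode). Discovered links are materialized into a
# dedicated links graph rather than merged into the sources, so the
# federator can treat owl:sameAs as an explicit mediator join relation.

LINKS_GRAPH <- function(base = FED_BASE) iriTerm(paste0(base, "graph/links"))

#' Key-normalization policies
#'
#' `verbatim` is the identity; `case_fold` uppercases; the
#' `tcga_patient_barcode` policy truncates a TCGA barcode to its first
#' three dash-separated fields (the patient), so "TCGA-13-0920-01A"
#' normalizes to "TCGA-13-0920". All policies are idempotent.
#'
#' @param x character vector of raw keys.
#' @param policy one of "verbatim", "case_fold", "tcga_patient_barcode".
#' @return normalized keys (empty in, empty out).
#' @export
normalizeKey <- function(x, policy = c("verbatim", "case_fold",
                                       "tcga_patient_barcode")) {
  policy <- match.arg(policy)
  x <- as.character(x)
  switch(policy,
    verbatim = x,
    case_fold = toupper(x),
    tcga_patient_barcode = vapply(strsplit(x, "-", fixed = TRUE), function(p)
      paste(utils::head(p, 3), collapse = "-"), character(1)))
}

#' LinkRule: one owl:sameAs discovery rule
#'
#' @slot ruleKind "exact_key" or "positional".
#' @slot id short rule identifier carried into link provenance.
#' @slot leftGraph,rightGraph graph IRI terms the rule compares.
#' @slot leftPredicates,rightPredicates named character vectors of
#'   predicate IRI terms: a single `key` entry for exact rules; `chrom`,
#'   `start`, `end` entries for positional rules.
#' @slot normalizer key-normalization policy (exact rules).
#' @slot mode "exact" or "overlap" (positional rules).
#' @slot toleranceBp symmetric extension in bp (overlap mode only; must be
#'   0 in exact mode).
#' @export
setClass("LinkRule",
         representation(ruleKind = "character", id = "character",
                        leftGraph = "character", rightGraph = "character",
                        leftPredicates = "character",
                        rightPredicates = "character",
                        normalizer = "character", mode = "character",
                        toleranceBp = "integer"))

setValidity("LinkRule", function(object) {
  if (!object@ruleKind %in% c("exact_key", "positional"))
    return("ruleKind must be exact_key or positional")
  if (object@ruleKind == "positional") {
    if (!all(c("chrom", "start", "end") %in% names(object@leftPredicates)))
      return("positional rule needs chrom/start/end predicates")
    if (object@mode == "exact" && object@toleranceBp != 0L)
      return("toleranceBp must be 0 in exact mode")
  }
  if (identical(object@leftGraph, object@rightGraph))
    return("self-linking within one graph is not enabled")
  TRUE
})

#' @rdname LinkRule-class
#' @param leftGraph,rightGraph graph IRI terms.
#' @param leftPredicate,rightPredicate key predicate IRI terms.
#' @param normalizer normalization policy name.
#' @param id rule identifier.
#' @return a `LinkRule`.
#' @export
exactKeyRule <- function(leftGraph, leftPredicate, rightGraph, rightPredicate,
                         normalizer = "verbatim", id = "exact") {
  methods::new("LinkRule", ruleKind = "exact_key", id = id,
               leftGraph = leftGraph, rightGraph = rightGraph,
               leftPredicates = c(key = leftPredicate),
               rightPredicates = c(key = rightPredicate),
               normalizer = normalizer, mode = "exact", toleranceBp = 0L)
}

#' @rdname LinkRule-class
#' @param leftPredicates,rightPredicates named (chrom, start, end)
#'   predicate IRI terms.
#' @param mode "exact" (identical start/end) or "overlap".
#' @param toleranceBp symmetric extension for overlap mode.
#' @export
positionalRule <- function(leftGraph, leftPredicates, rightGraph,
                           rightPredicates, mode = c("exact", "overlap"),
                           toleranceBp = 0L, id = "positional") {
  mode <- match.arg(mode)
  methods::new("LinkRule", ruleKind = "positional", id = id,
               leftGraph = leftGraph, rightGraph = rightGraph,
               leftPredicates = leftPredicates,
               rightPredicates = rightPredicates,
               normalizer = "verbatim", mode = mode,
               toleranceBp = as.integer(toleranceBp))
}

emptyLinks <- function() {
  data.frame(subject = character(), object = character(), rule = character(),
             stringsAsFactors = FALSE)
}

# distinct key resources carried by a predicate within a graph
graphKeys <- function(store, graph, predicate, policy) {
  q <- quads(store)
  sel <- q$graph == graph & q$predicate == predicate
  obj <- unique(q$object[sel])
  if (!length(obj)) return(data.frame(node = character(), key = character()))
  raw <- ifelse(isIRITerm(obj), keyTextFromIRI(obj),
                vapply(termValue(obj), as.character, character(1)))
  key <- normalizeKey(raw, policy)
  keep <- nzchar(key)
  data.frame(node = obj[keep], key = key[keep], stringsAsFactors = FALSE)
}

#' Discover owl:sameAs links by exact key equality
#'
#' A link (a, b) is asserted iff the normalized key of resource a in the
#' left graph equals the normalized key of resource b in the right graph
#' and both are non-empty; equivalent to the exhaustive pairwise
#' comparison. Links are stored once in rule direction (left -> right).
#'
#' @param storeA,storeB `QuadStore`s holding the rule's graphs.
#' @param rule an exact-key `LinkRule`.
#' @return data.frame of links (subject, object, rule), deduplicated.
#' @export
discoverExactLinks <- function(storeA, storeB, rule) {
  stopifnot(rule@ruleKind == "exact_key")
  ka <- graphKeys(storeA, rule@leftGraph, rule@leftPredicates[["key"]],
                  rule@normalizer)
  kb <- graphKeys(storeB, rule@rightGraph, rule@rightPredicates[["key"]],
                  rule@normalizer)
  if (!nrow(ka) || !nrow(kb)) {
    warning("key predicate matched no resources in one graph; rule '",
            rule@id, "' yields no links")
    return(emptyLinks())
  }
  m <- merge(ka, kb, by = "key", suffixes = c(".a", ".b"))
  unique(data.frame(subject = m$node.a, object = m$node.b,
                    rule = rep(rule@id, nrow(m)), stringsAsFactors = FALSE))
}

# subjects with a complete locus in a graph
graphLoci <- function(store, graph, preds) {
  q <- quads(store)
  q <- q[q$graph == graph, , drop = FALSE]
  pick <- function(p) {
    s <- q[q$predicate == preds[[p]], c("subject", "object")]
    s[!duplicated(s$subject), , drop = FALSE]
  }
  ch <- pick("chrom"); st <- pick("start"); en <- pick("end")
  m <- merge(merge(ch, st, by = "subject", suffixes = c(".c", ".s")),
             en, by = "subject")
  if (!nrow(m))
    return(data.frame(subject = character(), chrom = character(),
                      start = integer(), end = integer()))
  data.frame(subject = m$subject,
             chrom = normalizeChrom(vapply(termValue(m$object.c),
                                           as.character, character(1))),
             start = as.integer(termNumber(m$object.s)),
             end = as.integer(termNumber(m$object)),
             stringsAsFactors = FALSE)
}

lociToGRanges <- function(df, extend = 0L) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start - extend, end = df$end + extend))
}

#' Discover owl:sameAs links by genomic position
#'
#' Exact mode links two segment resources iff they sit on the same
#' normalized chromosome with identical (start, end). Overlap mode links
#' them iff, after extending both intervals by `toleranceBp` on each side,
#' they share at least 1 bp on the same chromosome. Equals the brute-force
#' pairwise scan.
#'
#' @param storeA,storeB `QuadStore`s holding the rule's graphs.
#' @param rule a positional `LinkRule`.
#' @return data.frame of links (subject, object, rule), deduplicated.
#' @export
discoverPositionalLinks <- function(storeA, storeB, rule) {
  stopifnot(rule@ruleKind == "positional")
  la <- graphLoci(storeA, rule@leftGraph, rule@leftPredicates)
  lb <- graphLoci(storeB, rule@rightGraph, rule@rightPredicates)
  if (!nrow(la) || !nrow(lb)) return(emptyLinks())
  if (rule@mode == "exact") {
    m <- merge(la, lb, by = c("chrom", "start", "end"),
               suffixes = c(".a", ".b"))
    out <- data.frame(subject = m$subject.a, object = m$subject.b,
                      rule = rep(rule@id, nrow(m)), stringsAsFactors = FALSE)
  } else {
    hits <- GenomicRanges::findOverlaps(
      lociToGRanges(la, rule@toleranceBp), lociToGRanges(lb, rule@toleranceBp))
    out <- data.frame(subject = la$subject[S4Vectors::queryHits(hits)],
                      object = lb$subject[S4Vectors::subjectHits(hits)],
                      rule = rep(rule@id, length(hits)),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

#' Map a genomic region to overlapping genes
#'
#' Returns every gene whose annotated interval shares at least 1 bp with
#' the query locus on the same chromosome (overlap semantics, not
#' containment, so boundary-spanning genes are retained).
#'
#' @param chrom,start,end the query locus (1-based inclusive).
#' @param annotation data.frame with columns gene_symbol, chrom, start, end.
#' @return sorted character vector of unique gene symbols.
#' @export
mapRegionToGenes <- function(chrom, start, end, annotation) {
  stopifnot(all(annotation$start >= 1), all(annotation$end >= annotation$start))
  qr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                               IRanges::IRanges(start, end))
  gr <- GenomicRanges::GRanges(normalizeChrom(annotation$chrom),
                               IRanges::IRanges(annotation$start,
                                                annotation$end))
  hits <- GenomicRanges::findOverlaps(gr, qr)
  sort(unique(annotation$gene_symbol[S4Vectors::queryHits(hits)]))
}

#' Per-pair link statistics
#'
#' Counts deduplicated owl:sameAs pairs per source pair: links found by
#' several rules for the same pair are counted once.
#'
#' @param linkSets list of link data.frames (from `discover*Links`).
#' @param pairs character vector, one source-pair label per link set.
#' @return data.frame with columns pair, links (deduplicated count).
#' @export
linkStats <- function(linkSets, pairs) {
  stopifnot(length(linkSets) == length(pairs))
  out <- lapply(unique(pairs), function(p) {
    dfs <- linkSets[pairs == p]
    all <- unique(do.call(rbind, lapply(dfs, function(d)
      d[c("subject", "object")])))
    data.frame(pair = p, links = if (is.null(all)) 0L else nrow(all),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Materialize links as owl:sameAs quads
#'
#' @param links data.frame of links (subject, object, ...).
#' @param graph links-graph IRI term.
#' @return a `QuadStore` with one owl:sameAs quad per link.
#' @export
linksAsQuads <- function(links, graph = LINKS_GRAPH()) {
  n <- nrow(links)
  QuadStore(links$subject, rep(iriTerm(OWL_SAMEAS), n), links$object,
            rep(graph, n))
}
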