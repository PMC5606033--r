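# Federated BGP query answering over multiple quad-store sources.
#
# Two-level source selection: level 1 picks relevant endpoints per triple
# pattern, level 2 the relevant named graphs within them, driven by an
# exact predicate-level capability index (no false positives or negatives,
# hence recall-preserving). Patterns answerable by a single (endpoint,
# graph) are grouped into maximal exclusive groups executed as one
# sub-query; owl:sameAs patterns resolve against the dedicated links store
# and act as mediator joins. Results are merged by hash joins on shared
# variables, smallest relation first, and equal the evaluation of the whole
# BGP over the union of all graphs plus the links graph.

MEDIATOR_ID <- ".links"

#' Federation: a set of named sources plus a links store
#'
#' @slot endpoints named list of endpoint id -> `QuadStore`; graph IRIs
#'   must be unique across the federation.
#' @slot links `QuadStore` of owl:sameAs quads (the mediator join relation).
#' @export
setClass("Federation",
         representation(endpoints = "list", links = "QuadStore"))

setValidity("Federation", function(object) {
  if (is.null(names(object@endpoints)) ||
      any(!nzchar(names(object@endpoints))))
    return("endpoints must be a named list")
  if (MEDIATOR_ID %in% names(object@endpoints))
    return(sprintf("endpoint id '%s' is reserved", MEDIATOR_ID))
  gs <- unlist(lapply(object@endpoints, graphIRIs))
  if (anyDuplicated(gs))
    return(paste("graph IRI hosted by more than one endpoint:",
                 gs[duplicated(gs)][1]))
  TRUE
})

#' @rdname Federation-class
#' @param endpoints named list of endpoint id -> `QuadStore`.
#' @param links `QuadStore` of owl:sameAs links.
#' @return a `Federation`.
#' @export
Federation <- function(endpoints, links = QuadStore()) {
  methods::new("Federation", endpoints = endpoints, links = links)
}

#' @rdname Federation-class
#' @param x a `Federation`.
#' @export
endpointIds <- function(x) names(x@endpoints)

#' @rdname Federation-class
#' @param id endpoint id.
#' @export
endpointStore <- function(x, id) {
  if (id == MEDIATOR_ID) return(x@links)
  if (!id %in% names(x@endpoints)) stop("indexing error: unknown endpoint '", id, "'")
  x@endpoints[[id]]
}

#' @rdname Federation-class
#' @export
linksStore <- function(x) x@links

#' @rdname Federation-class
#' @param includeLinks also merge the links graph.
#' @export
unionStore <- function(x, includeLinks = TRUE) {
  parts <- unname(x@endpoints)
  if (includeLinks) parts <- c(parts, list(x@links))
  do.call(bindStores, parts)
}

setMethod("show", "Federation", function(object) {
  cat(sprintf("Federation with %d endpoint(s), %d sameAs link(s)\n",
              length(object@endpoints), nquads(object@links)))
  for (id in endpointIds(object)) {
    st <- object@endpoints[[id]]
    cat(sprintf("  %s: %d quads in %d graph(s)\n", id, nquads(st),
                length(graphIRIs(st))))
  }
})

#' CapabilityIndex: exact per-predicate source membership
#'
#' One row per (predicate, endpoint, graph) with at least one matching
#' triple, plus per-cell counts (triples, distinct subjects/objects) used
#' for smallest-first join ordering.
#'
#' @slot index data.frame(predicate, endpoint, graph, n, nSubj, nObj).
#' @export
setClass("CapabilityIndex", representation(index = "data.frame"))

#' @rdname CapabilityIndex-class
#' @param fed a `Federation`.
#' @return a `CapabilityIndex` covering all endpoints and the links store.
#' @export
buildCapabilityIndex <- function(fed) {
  one <- function(id, store) {
    q <- quads(store)
    if (!nrow(q)) return(NULL)
    agg <- stats::aggregate(
      cbind(n = rep(1L, nrow(q))) ~ predicate + graph, data = q, FUN = sum)
    ns <- stats::aggregate(subject ~ predicate + graph, data = q,
                           FUN = function(v) length(unique(v)))
    no <- stats::aggregate(object ~ predicate + graph, data = q,
                           FUN = function(v) length(unique(v)))
    m <- merge(merge(agg, ns, by = c("predicate", "graph")), no,
               by = c("predicate", "graph"))
    data.frame(predicate = m$predicate, endpoint = id, graph = m$graph,
               n = m$n, nSubj = m$subject, nObj = m$object,
               stringsAsFactors = FALSE)
  }
  parts <- c(lapply(endpointIds(fed), function(id)
    one(id, endpointStore(fed, id))),
    list(one(MEDIATOR_ID, linksStore(fed))))
  idx <- do.call(rbind, parts)
  if (is.null(idx))
    idx <- data.frame(predicate = character(), endpoint = character(),
                      graph = character(), n = integer(), nSubj = integer(),
                      nObj = integer(), stringsAsFactors = FALSE)
  idx <- idx[order(idx$endpoint, idx$graph, idx$predicate), , drop = FALSE]
  rownames(idx) <- NULL
  methods::new("CapabilityIndex", index = idx)
}

#' @rdname CapabilityIndex-class
#' @param x a `CapabilityIndex`.
#' @export
capabilityIndex <- function(x) x@index

setMethod("show", "CapabilityIndex", function(object) {
  cat(sprintf("CapabilityIndex: %d predicates over %d (endpoint, graph) pairs\n",
              length(unique(object@index$predicate)),
              nrow(unique(object@index[c("endpoint", "graph")]))))
})

allSourcePairs <- function(index) {
  u <- unique(index@index[c("endpoint", "graph")])
  rownames(u) <- NULL
  u
}

#' Triple-pattern-wise source selection
#'
#' For each triple pattern of a query, the set of (endpoint, graph) pairs
#' that can contribute matches: bound-predicate patterns select via the
#' capability index (exact, hence recall-preserving — every contributing
#' source is kept); variable-predicate patterns select every pair, since no
#' pruning is possible without risking recall.
#'
#' @param query a `SparqlQuery` (or list of triple patterns).
#' @param index a `CapabilityIndex` built over the target federation.
#' @return list, one data.frame(endpoint, graph) per pattern.
#' @export
selectSources <- function(query, index) {
  patterns <- if (is(query, "SparqlQuery")) query@patterns else query
  idx <- index@index
  lapply(patterns, function(p) {
    if (isVariable(p$p)) return(allSourcePairs(index))
    sel <- idx[idx$predicate == p$p, c("endpoint", "graph"), drop = FALSE]
    rownames(sel) <- NULL
    sel
  })
}

#' QueryPlan: exclusive groups plus mediator joins
#'
#' Nodes are maximal groups of triple patterns answerable by a single
#' (endpoint, graph) — executed as one sub-query — plus one node per
#' multi-source pattern (executed against each selected source and
#' unioned). owl:sameAs nodes resolved from the links store are the
#' mediator joins. A pattern with empty selection yields an empty-result
#' marker: the query answer is empty, not an error.
#'
#' @slot nodes list of list(patterns, sources, sameAs, empty).
#' @slot query the planned `SparqlQuery`.
#' @export
setClass("QueryPlan", representation(nodes = "list", query = "SparqlQuery"))

#' @rdname QueryPlan-class
#' @param query a `SparqlQuery`.
#' @param selection per-pattern selection from [selectSources()].
#' @return a `QueryPlan`.
#' @export
planQuery <- function(query, selection) {
  patterns <- query@patterns
  stopifnot(length(selection) == length(patterns))
  keyOf <- vapply(seq_along(patterns), function(i) {
    sel <- selection[[i]]
    if (nrow(sel) == 0L) "EMPTY"
    else if (nrow(sel) == 1L) paste(sel$endpoint, sel$graph, sep = "\r")
    else paste0("MULTI", i)
  }, character(1))
  nodes <- lapply(split(seq_along(patterns), keyOf), function(ix) {
    sel <- unique(do.call(rbind, selection[ix]))
    if (!is.null(sel)) rownames(sel) <- NULL
    ps <- patterns[ix]
    list(patterns = ps,
         sources = if (is.null(sel))
           data.frame(endpoint = character(), graph = character()) else sel,
         sameAs = all(vapply(ps, function(p)
           identical(p$p, iriTerm(OWL_SAMEAS)), logical(1))),
         empty = any(keyOf[ix] == "EMPTY"))
  })
  names(nodes) <- NULL
  methods::new("QueryPlan", nodes = nodes, query = query)
}

#' @rdname QueryPlan-class
#' @param plan a `QueryPlan`.
#' @export
planNodes <- function(plan) plan@nodes

#' Number of sub-queries a plan issues
#'
#' An exclusive group counts one sub-query per selected source (one, by
#' construction); a multi-source node counts one per source. The naive
#' comparison point is #patterns x #(endpoint, graph) pairs.
#'
#' @param plan a `QueryPlan`.
#' @return integer count.
#' @export
planSubqueryCount <- function(plan) {
  sum(vapply(plan@nodes, function(nd)
    if (nd$empty) 0L else nrow(nd$sources), integer(1)))
}

#' @rdname planSubqueryCount
#' @param query the query.
#' @param index the `CapabilityIndex` of the federation.
#' @export
naiveSubqueryCount <- function(query, index) {
  length(query@patterns) * nrow(allSourcePairs(index))
}

setMethod("show", "QueryPlan", function(object) {
  cat(sprintf("QueryPlan: %d node(s), %d sub-queries\n",
              length(object@nodes), planSubqueryCount(object)))
  for (nd in object@nodes) {
    tag <- if (nd$empty) "empty-result marker"
           else if (nd$sameAs) "mediator sameAs join"
           else if (nrow(nd$sources) == 1L)
             sprintf("exclusive group @ %s %s", nd$sources$endpoint,
                     nd$sources$graph)
           else sprintf("union over %d sources", nrow(nd$sources))
    cat(sprintf("  [%d pattern(s)] %s\n", length(nd$patterns), tag))
  }
})

## ---- BGP matching and joins ----------------------------------------------

emptyBindings <- function(vars) {
  df <- as.data.frame(stats::setNames(rep(list(character()), length(vars)),
                                      vars), stringsAsFactors = FALSE)
  df
}

matchPatternDF <- function(q, p) {
  keep <- rep(TRUE, nrow(q))
  pos <- c(s = "subject", p = "predicate", o = "object")
  varcols <- list()
  for (nm in names(pos)) {
    t <- p[[nm]]
    if (isVariable(t)) {
      v <- varName(t)
      varcols[[v]] <- c(varcols[[v]], pos[[nm]])
    } else keep <- keep & q[[pos[[nm]]]] == t
  }
  sub <- q[keep, , drop = FALSE]
  for (v in names(varcols)) {          # repeated variable within a pattern
    cols <- varcols[[v]]
    if (length(cols) > 1L)
      for (cl in cols[-1]) sub <- sub[sub[[cols[1]]] == sub[[cl]], , drop = FALSE]
  }
  if (!length(varcols))                 # ground pattern: one solution per match
    return(zeroColBindings(nrow(sub)))
  out <- emptyBindings(names(varcols))
  if (nrow(sub)) {
    out <- as.data.frame(stats::setNames(
      lapply(varcols, function(cols) sub[[cols[1]]]), names(varcols)),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  rownames(out) <- NULL
  out
}

zeroColBindings <- function(n) as.data.frame(matrix(nrow = n, ncol = 0))

rbindBindings <- function(parts) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(NULL)
  if (all(vapply(parts, ncol, integer(1)) == 0L))
    return(zeroColBindings(sum(vapply(parts, nrow, integer(1)))))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

crossJoin <- function(a, b) {
  if (!nrow(a) || !nrow(b)) {
    out <- cbind(a[integer(0), , drop = FALSE], b[integer(0), , drop = FALSE])
    return(out)
  }
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  out <- cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE])
  rownames(out) <- NULL
  out
}

joinBindings <- function(a, b) {
  if (is.null(a)) return(b)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(crossJoin(a, b))
  out <- merge(a, b, by = shared)
  rownames(out) <- NULL
  out
}

evalBGPOver <- function(q, patterns) {
  res <- NULL
  for (p in patterns) res <- joinBindings(res, matchPatternDF(q, p))
  res
}

#' Execute a query plan over a federation
#'
#' Each node is evaluated against its selected sources only (an exclusive
#' group runs as one sub-query on its single source; a multi-source node
#' runs per source and its bindings are unioned), then node results are
#' hash-joined on shared variables, smallest first, with deterministic
#' lexicographic tie-breaking. Filters, DISTINCT and projection are applied
#' at the mediator. The result multiset equals [evaluateUnionOracle()] on
#' the same query.
#'
#' @param plan a `QueryPlan`.
#' @param fed the `Federation` the plan was built for.
#' @return data.frame of solution bindings (canonical terms), with a
#'   `provenance` attribute listing contributing (endpoint, graph) pairs.
#' @export
executePlan <- function(plan, fed) {
  query <- plan@query
  nodeRes <- list()
  prov <- data.frame(endpoint = character(), graph = character())
  for (nd in plan@nodes) {
    vars <- unique(unlist(lapply(nd$patterns, patternVars)))
    if (nd$empty) {
      nodeRes[[length(nodeRes) + 1L]] <- emptyBindings(vars)
      next
    }
    parts <- lapply(seq_len(nrow(nd$sources)), function(k) {
      st <- endpointStore(fed, nd$sources$endpoint[k])
      q <- quads(st)
      q <- q[q$graph == nd$sources$graph[k], , drop = FALSE]
      evalBGPOver(q, nd$patterns)
    })
    contributed <- vapply(parts, nrow, integer(1)) > 0
    prov <- rbind(prov, nd$sources[contributed, , drop = FALSE])
    nodeRes[[length(nodeRes) + 1L]] <- rbindBindings(parts)
  }
  bindings <- foldJoin(nodeRes)
  bindings <- applyFilters(bindings, query@filters)
  out <- projectBindings(bindings, query)
  attr(out, "provenance") <- unique(prov)
  out
}

# join node results smallest-first, preferring nodes sharing a variable
foldJoin <- function(nodeRes) {
  if (!length(nodeRes)) return(zeroColBindings(1L))  # join identity
  sizes <- vapply(nodeRes, nrow, integer(1))
  ord <- order(sizes, vapply(nodeRes, function(d)
    paste(sort(names(d)), collapse = ","), character(1)))
  pending <- nodeRes[ord]
  acc <- pending[[1]]
  pending <- pending[-1]
  while (length(pending)) {
    sharing <- which(vapply(pending, function(d)
      length(intersect(names(d), names(acc))) > 0, logical(1)))
    k <- if (length(sharing)) sharing[1] else 1L
    acc <- joinBindings(acc, pending[[k]])
    pending <- pending[-k]
  }
  acc
}

#' Select-plan-execute convenience wrapper
#'
#' @param fed a `Federation`.
#' @param query a `SparqlQuery` or SPARQL text.
#' @param explain also print selection and plan.
#' @return solution bindings data.frame (see [executePlan()]).
#' @export
runFederatedQuery <- function(fed, query, explain = FALSE) {
  if (is.character(query)) query <- parseSparql(query)
  index <- buildCapabilityIndex(fed)
  sel <- selectSources(query, index)
  plan <- planQuery(query, sel)
  if (explain) {
    show(plan)
    cat(sprintf("naive sub-queries: %d\n", naiveSubqueryCount(query, index)))
  }
  executePlan(plan, fed)
}

#' Union-store oracle evaluation
#'
#' Evaluates the BGP over the union of every graph of the federation plus
#' the links graph, with standard matching semantics, using a deliberately
#' simple nested-loop join independent of the plan-based engine. Used to
#' verify [executePlan()] results.
#'
#' @param query a `SparqlQuery` or SPARQL text.
#' @param x a `Federation` or `QuadStore`.
#' @return data.frame of solution bindings.
#' @export
evaluateUnionOracle <- function(query, x) {
  if (is.character(query)) query <- parseSparql(query)
  store <- if (is(x, "Federation")) unionStore(x) else x
  q <- quads(store)
  sols <- list(stats::setNames(list(), character(0)))   # one empty binding
  for (p in query@patterns) {
    nxt <- list()
    for (mu in sols) {
      for (i in seq_len(nrow(q))) {
        ext <- extendBinding(mu, p, q$subject[i], q$predicate[i], q$object[i])
        if (!is.null(ext)) nxt[[length(nxt) + 1L]] <- ext
      }
    }
    sols <- nxt
    if (!length(sols)) break
  }
  vars <- unique(unlist(lapply(query@patterns, patternVars)))
  out <- if (!length(sols)) emptyBindings(vars)
  else as.data.frame(do.call(rbind, lapply(sols, function(mu)
    vapply(vars, function(v) mu[[v]], character(1)))),
    stringsAsFactors = FALSE)
  names(out) <- vars
  rownames(out) <- NULL
  out <- applyFilters(out, query@filters)
  projectBindings(out, query)
}

extendBinding <- function(mu, p, s, pr, o) {
  vals <- c(s = s, p = pr, o = o)
  for (nm in c("s", "p", "o")) {
    t <- p[[nm]]
    if (isVariable(t)) {
      v <- varName(t)
      if (!is.null(mu[[v]])) {
        if (mu[[v]] != vals[[nm]]) return(NULL)
      } else mu[[v]] <- vals[[nm]]
    } else if (t != vals[[nm]]) return(NULL)
  }
  mu
}

#' Multiset equality of two solution sets
#'
#' @param a,b binding data.frames over the same variables.
#' @return TRUE iff they contain the same rows with the same
#'   multiplicities, in any order.
#' @export
sameSolutionMultiset <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  cols <- sort(names(a))
  if (!length(cols)) return(nrow(a) == nrow(b))
  can <- function(d) sort(do.call(paste, c(d[cols], sep = "\r")))
  identical(can(a), can(b))
}
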