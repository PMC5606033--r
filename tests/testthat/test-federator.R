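# Capability index, two-level source selection, exclusive-group planning
# and plan execution against the union-store oracle.

twoSourceFed <- function() {
  ex <- function(x) iriTerm(paste0("http://f.org/", x))
  a <- QuadStore(ex(c("s1", "s1", "s2")),
                 ex(c("pA", "shared", "pA")),
                 c(plainLiteral("1"), ex("k1"), plainLiteral("2")),
                 ex(rep("gA", 3)))
  b <- QuadStore(ex(c("t1", "t1")),
                 ex(c("pB", "shared")),
                 c(plainLiteral("9"), ex("k1")),
                 ex(rep("gB", 2)))
  Federation(list(epA = a, epB = b))
}

test_that("the capability index records exact per-predicate membership", {
  emptyFed <- Federation(list(e = QuadStore()))
  expect_equal(nrow(capabilityIndex(buildCapabilityIndex(emptyFed))), 0L)

  idx <- capabilityIndex(buildCapabilityIndex(twoSourceFed()))
  ex <- function(x) iriTerm(paste0("http://f.org/", x))
  expect_equal(idx$endpoint[idx$predicate == ex("pA")], "epA")
  expect_equal(idx$endpoint[idx$predicate == ex("pB")], "epB")
  expect_setequal(idx$endpoint[idx$predicate == ex("shared")],
                  c("epA", "epB"))
  # counts are exact
  expect_equal(idx$n[idx$predicate == ex("pA")], 2L)
  # no false positives: every (predicate, endpoint, graph) row has triples
  fed <- twoSourceFed()
  for (i in seq_len(nrow(idx))) {
    q <- quads(endpointStore(fed, idx$endpoint[i]))
    expect_gte(sum(q$predicate == idx$predicate[i] & q$graph == idx$graph[i]),
               1L)
  }
})

test_that("source selection is recall-preserving and prunes bound predicates", {
  fed <- twoSourceFed()
  idx <- buildCapabilityIndex(fed)
  ex <- function(x) iriTerm(paste0("http://f.org/", x))
  q <- bgpQuery(list(tp("?s", ex("pA"), "?v"),
                     tp("?s", ex("shared"), "?k"),
                     tp("?s", "?p", "?o")))
  sel <- selectSources(q, idx)
  expect_equal(sel[[1]]$endpoint, "epA")              # exclusive predicate
  expect_setequal(sel[[2]]$endpoint, c("epA", "epB")) # shared predicate
  # variable predicate: all (endpoint, graph) pairs, no pruning possible
  expect_equal(nrow(sel[[3]]), nrow(unique(capabilityIndex(idx)[
    c("endpoint", "graph")])))

  # recall: every (endpoint, graph) contributing a match is selected
  for (i in seq_along(q@patterns)) {
    p <- q@patterns[[i]]
    for (id in endpointIds(fed)) {
      qq <- quads(endpointStore(fed, id))
      for (g in unique(qq$graph)) {
        sub <- qq[qq$graph == g, , drop = FALSE]
        keep <- rep(TRUE, nrow(sub))
        if (!isVariable(p$p)) keep <- keep & sub$predicate == p$p
        if (!isVariable(p$s)) keep <- keep & sub$subject == p$s
        if (!isVariable(p$o)) keep <- keep & sub$object == p$o
        if (any(keep))
          expect_true(any(sel[[i]]$endpoint == id & sel[[i]]$graph == g),
                      info = paste("pattern", i, id, g))
      }
    }
  }
})

test_that("plans form maximal exclusive groups and mediator sameAs joins", {
  fx <- paperFixture()
  fed <- fx$federation
  idx <- buildCapabilityIndex(fed)

  # all patterns on one source: a single exclusive group, no mediator join
  cg <- function(r) vocabIRI("cosmic", r)
  q1 <- bgpQuery(list(tp("?m", cg("sample"), "?s"),
                      tp("?m", cg("mutation_type"), "?t")))
  pl1 <- planQuery(q1, selectSources(q1, idx))
  groups <- planNodes(pl1)
  expect_false(any(vapply(groups, `[[`, logical(1), "sameAs")))
  # cosmic:mutation_type is graph-exclusive and forms a single-source group;
  # cosmic:sample occurs in the mutation and methylation graphs, so its
  # pattern becomes a union node over those two cosmic graphs
  expect_true(any(vapply(groups, function(nd)
    nrow(nd$sources) == 1L && all(nd$sources$endpoint == "cosmic"),
    logical(1))))
  expect_true(all(unlist(lapply(groups, function(nd) nd$sources$endpoint))
                  == "cosmic"))

  # when every pattern is answerable by one graph only, the plan is a
  # single maximal exclusive group
  qx <- bgpQuery(list(tp("?m", cg("mutation_type"), "?t"),
                      tp("?m", cg("ensembl"), "?p")))
  plx <- planQuery(qx, selectSources(qx, idx))
  expect_length(planNodes(plx), 1L)
  expect_length(planNodes(plx)[[1]]$patterns, 2L)
  expect_equal(planSubqueryCount(plx), 1L)

  # the mutation-loci template: cosmic group(s), tcga group(s), one sameAs
  # mediator join
  q2 <- bankQuery("loci", "MYH7")
  pl2 <- planQuery(q2, selectSources(q2, idx))
  nds <- planNodes(pl2)
  sameAsNodes <- Filter(function(nd) nd$sameAs, nds)
  expect_length(sameAsNodes, 1)
  expect_equal(sameAsNodes[[1]]$sources$endpoint, ".links")
  eps <- unlist(lapply(Filter(function(nd) !nd$sameAs, nds),
                       function(nd) nd$sources$endpoint))
  expect_setequal(unique(eps), c("cosmic", "tcga"))

  # a pattern matched nowhere yields an empty-result marker, not an error
  q3 <- bgpQuery(list(tp("?s", iriTerm("http://nowhere/p"), "?o")))
  pl3 <- planQuery(q3, selectSources(q3, idx))
  expect_true(planNodes(pl3)[[1]]$empty)
  expect_equal(nrow(executePlan(pl3, fed)), 0L)
})

test_that("execution equals hand enumeration on the ten-triple store", {
  h <- handStore()
  fed <- Federation(list(h = h))
  ex <- function(x) iriTerm(paste0("http://h.org/", x))

  # ?x knows ?y . ?y age ?a  -> (a,b,25), (b,c,? none: c has no age) ...
  q <- bgpQuery(list(tp("?x", ex("knows"), "?y"), tp("?y", ex("age"), "?a")),
                select = c("x", "y", "a"))
  got <- runFederatedQuery(fed, q)
  expect_equal(nrow(got), 3L)
  expect_setequal(
    paste(got$x, got$y, termNumber(got$a)),
    c(paste(ex("a"), ex("b"), 25),
      paste(ex("c"), ex("a"), 30),
      paste(ex("e"), ex("a"), 30)))
  oracle <- evaluateUnionOracle(q, fed)
  expect_true(sameSolutionMultiset(got, oracle))

  # ground pattern present: one solution; absent: none
  qg <- bgpQuery(list(tp(ex("a"), ex("age"), intLiteral(30))))
  expect_equal(nrow(evaluateUnionOracle(qg, fed)), 1L)
  expect_equal(nrow(runFederatedQuery(fed, qg)), 1L)
  qa <- bgpQuery(list(tp(ex("a"), ex("age"), intLiteral(31))))
  expect_equal(nrow(evaluateUnionOracle(qa, fed)), 0L)
  expect_equal(nrow(runFederatedQuery(fed, qa)), 0L)

  # FILTER comparison restricts solutions
  qf <- bgpQuery(list(tp("?x", ex("age"), "?a")), select = "x",
                 filters = list(list(var = "a", op = ">", value = 28)))
  gotF <- runFederatedQuery(fed, qf)
  expect_setequal(gotF$x, c(ex("a"), ex("d")))
  expect_true(sameSolutionMultiset(gotF, evaluateUnionOracle(qf, fed)))
})

test_that("federated execution is oracle-equal on random federations and queries", {
  for (seed in 1:6) {
    g <- generateFederation(synthSpec(nGenes = 8L, nSamples = 5L,
                                      nCnvSegments = 8L, nMethylSites = 10L,
                                      seed = seed))
    for (tmpl in c("loci", "meth", "go", "pathway")) {
      q <- bankQuery(tmpl)
      got <- runFederatedQuery(g$federation, q)
      want <- evaluateUnionOracle(q, g$federation)
      expect_true(sameSolutionMultiset(got, want),
                  info = paste("seed", seed, tmpl))
    }
    # grounded on a shared and an absent gene
    shared <- g$groundTruth$sharedGenes[1]
    for (gene in c(shared, "NOSUCHGENE")) {
      q <- bankQuery("meth", gene)
      expect_true(sameSolutionMultiset(runFederatedQuery(g$federation, q),
                                       evaluateUnionOracle(q, g$federation)),
                  info = paste("seed", seed, gene))
    }
  }
})

test_that("identical inputs give identical results and plans are frugal", {
  fx <- paperFixture()
  q <- bankQuery("loci", "MYH7")
  r1 <- runFederatedQuery(fx$federation, q)
  r2 <- runFederatedQuery(fx$federation, q)
  expect_identical(r1[order(do.call(paste, r1)), , drop = FALSE],
                   r2[order(do.call(paste, r2)), , drop = FALSE])

  idx <- buildCapabilityIndex(fx$federation)
  plan <- planQuery(q, selectSources(q, idx))
  # with source-exclusive predicates the plan beats the naive all-sources plan
  expect_lt(planSubqueryCount(plan), naiveSubqueryCount(q, idx))
  expect_lte(planSubqueryCount(plan),
             length(q@patterns) * nrow(unique(capabilityIndex(idx)[
               c("endpoint", "graph")])))
})

test_that("union oracle multiset semantics keep duplicate solutions", {
  ex <- function(x) iriTerm(paste0("http://d.org/", x))
  # the same (s,p,o) in two graphs of one endpoint: multiplicity two
  st <- QuadStore(rep(ex("s"), 2), rep(ex("p"), 2), rep(ex("o"), 2),
                  ex(c("g1", "g2")))
  fed <- Federation(list(e = st))
  q <- bgpQuery(list(tp("?s", ex("p"), "?o")))
  got <- runFederatedQuery(fed, q)
  want <- evaluateUnionOracle(q, fed)
  expect_equal(nrow(got), 2L)
  expect_true(sameSolutionMultiset(got, want))
  # DISTINCT collapses them
  qd <- bgpQuery(list(tp("?s", ex("p"), "?o")), distinct = TRUE)
  expect_equal(nrow(runFederatedQuery(fed, qd)), 1L)
})
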