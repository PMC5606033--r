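# owl:sameAs link discovery: normalization policies, exact-key and
# positional rules against brute-force oracles, region-to-gene mapping.

test_that("key normalization policies behave as declared and are idempotent", {
  expect_equal(normalizeKey("TCGA-13-0920-01A", "tcga_patient_barcode"),
               "TCGA-13-0920")
  expect_equal(normalizeKey("Myh7", "case_fold"), "MYH7")
  expect_equal(normalizeKey("anything at all", "verbatim"), "anything at all")
  expect_equal(normalizeKey("", "case_fold"), "")

  withr::local_seed(5)
  for (policy in c("verbatim", "case_fold", "tcga_patient_barcode")) {
    raw <- replicate(25, paste(sample(c(LETTERS, letters, 0:9, "-", "_"),
                                      sample(1:12, 1), replace = TRUE),
                               collapse = ""))
    once <- normalizeKey(raw, policy)
    expect_identical(normalizeKey(once, policy), once, info = policy)
  }
})

# two tiny single-graph stores with chosen keys under one predicate
keyStore <- function(graph, keys, pred = "http://v/key", resource = TRUE) {
  n <- length(keys)
  if (n == 0L) return(QuadStore())
  obj <- if (resource)
    vapply(keys, function(k) mintIRI("http://d/", "k", k), character(1))
    else plainLiteral(keys)
  QuadStore(iriTerm(paste0(sub("[<>]", "", graph), "/s", seq_len(n))),
            rep(iriTerm(pred), n), obj, rep(iriTerm(graph), n))
}

test_that("exact-key discovery equals exhaustive pairwise comparison", {
  gA <- "http://g/A"; gB <- "http://g/B"
  rule <- exactKeyRule(iriTerm(gA), iriTerm("http://v/key"),
                       iriTerm(gB), iriTerm("http://v/key"))
  # disjoint keys: no links
  expect_warning(
    l0 <- discoverExactLinks(keyStore(gA, c("a", "b")),
                             keyStore(gB, character(0)), rule),
    "no links")
  expect_equal(nrow(l0), 0L)
  l1 <- discoverExactLinks(keyStore(gA, c("a", "b")),
                           keyStore(gB, c("c", "d")), rule)
  expect_equal(nrow(l1), 0L)

  # planted overlap: 17 shared gene symbols among 50 and 60 resources
  withr::local_seed(21)
  shared <- sprintf("SHARED%02d", 1:17)
  keysA <- c(shared, sprintf("A%02d", 1:33))
  keysB <- c(shared, sprintf("B%02d", 1:43))
  links <- discoverExactLinks(keyStore(gA, keysA), keyStore(gB, keysB), rule)
  expect_equal(nrow(links), 17L)
  expect_equal(nrow(links), bruteExactPairs(keysA, keysB))
  expect_equal(nrow(unique(links[c("subject", "object")])), nrow(links))

  # normalization-dependent matches, random cases vs brute force
  for (seed in 1:3) {
    withr::local_seed(seed)
    ka <- paste0(sample(c("tcga-13-0920", "TCGA-13-0920", "x", "y", "z"),
                        12, replace = TRUE))
    kb <- paste0(sample(c("TCGA-13-0920", "X", "y", "w"), 9, replace = TRUE))
    got <- discoverExactLinks(
      keyStore(gA, unique(ka)), keyStore(gB, unique(kb)),
      exactKeyRule(iriTerm(gA), iriTerm("http://v/key"),
                   iriTerm(gB), iriTerm("http://v/key"),
                   normalizer = "case_fold"))
    expect_equal(nrow(got),
                 bruteExactPairs(unique(ka), unique(kb), toupper))
  }
})

test_that("swapping rule direction yields the mirrored link set", {
  gA <- "http://g/A"; gB <- "http://g/B"
  sa <- keyStore(gA, c("k1", "k2", "k3"))
  sb <- keyStore(gB, c("k2", "k3", "k9"))
  fwd <- discoverExactLinks(sa, sb, exactKeyRule(
    iriTerm(gA), iriTerm("http://v/key"), iriTerm(gB), iriTerm("http://v/key")))
  rev <- discoverExactLinks(sb, sa, exactKeyRule(
    iriTerm(gB), iriTerm("http://v/key"), iriTerm(gA), iriTerm("http://v/key")))
  expect_setequal(paste(fwd$subject, fwd$object),
                  paste(rev$object, rev$subject))
})

lociStore <- function(graph, df, vocab = "http://v/") {
  n <- nrow(df)
  s <- iriTerm(paste0(sub("[<>]", "", graph), "/r", seq_len(n)))
  g <- rep(iriTerm(graph), n)
  bindStores(
    QuadStore(s, rep(iriTerm(paste0(vocab, "chr")), n),
              plainLiteral(df$chrom), g),
    QuadStore(s, rep(iriTerm(paste0(vocab, "start")), n),
              intLiteral(df$start), g),
    QuadStore(s, rep(iriTerm(paste0(vocab, "end")), n),
              intLiteral(df$end), g))
}

posPreds <- c(chrom = "<http://v/chr>", start = "<http://v/start>",
              end = "<http://v/end>")

test_that("positional discovery matches the quadratic oracle", {
  gA <- "http://g/cnvA"; gB <- "http://g/cnvB"
  mkLoci <- function(n, seed) {
    withr::local_seed(seed, .local_envir = parent.frame())
    start <- sample.int(5000, n, replace = TRUE)
    data.frame(chrom = as.character(sample.int(3, n, replace = TRUE)),
               start = start, end = start + sample.int(300, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  # identical segment lists: every segment linked to its twin (exact mode)
  la <- mkLoci(20, 31)
  ruleE <- positionalRule(iriTerm(gA), posPreds, iriTerm(gB), posPreds,
                          mode = "exact")
  same <- discoverPositionalLinks(lociStore(gA, la), lociStore(gB, la), ruleE)
  expect_gte(nrow(same), 20L)
  expect_equal(nrow(same), bruteOverlapPairs(la, la, exact = TRUE))

  # published chr14 locus present in both stores, exact mode -> 1 link
  t3 <- data.frame(chrom = "14", start = 23857092L, end = 23886486L)
  other <- data.frame(chrom = c("14", "5"), start = c(23857082L, 100L),
                      end = c(23886607L, 200L))
  one <- discoverPositionalLinks(lociStore(gA, t3),
                                 lociStore(gB, rbind(t3, other)), ruleE)
  expect_equal(nrow(one), 1L)

  # random 200x200, overlap mode, tolerances 0 and 10 vs quadratic oracle
  la <- mkLoci(200, 32); lb <- mkLoci(200, 33)
  for (tol in c(0L, 10L)) {
    ruleO <- positionalRule(iriTerm(gA), posPreds, iriTerm(gB), posPreds,
                            mode = "overlap", toleranceBp = tol)
    got <- discoverPositionalLinks(lociStore(gA, la), lociStore(gB, lb), ruleO)
    expect_equal(nrow(got), bruteOverlapPairs(la, lb, tol = tol),
                 info = paste("tol", tol))
  }
})

test_that("region-to-gene mapping uses >=1 bp overlap on the same chromosome", {
  ann <- data.frame(
    gene_symbol = c("INSIDE", "SPANS", "OTHERCHR", "BEFORE", "TOUCH"),
    chrom = c("14", "14", "2", "14", "14"),
    start = c(150L, 50L, 150L, 10L, 300L),
    end = c(180L, 400L, 180L, 99L, 350L))
  got <- mapRegionToGenes("chr14", 100, 300, ann)
  expect_equal(got, c("INSIDE", "SPANS", "TOUCH"))

  # 500 random gene intervals vs brute-force overlap scan
  withr::local_seed(77)
  ann <- data.frame(
    gene_symbol = sprintf("G%03d", 1:500),
    chrom = as.character(sample.int(4, 500, replace = TRUE)),
    start = sample.int(10000, 500, replace = TRUE))
  ann$end <- ann$start + sample.int(500, 500, replace = TRUE)
  q <- list(chrom = "2", start = 2000L, end = 4000L)
  brute <- sort(unique(ann$gene_symbol[
    ann$chrom == q$chrom & ann$start <= q$end & q$start <= ann$end]))
  expect_equal(mapRegionToGenes(q$chrom, q$start, q$end, ann), brute)
})

test_that("link statistics count deduplicated pairs per source pair", {
  expect_equal(linkStats(list(data.frame(subject = character(),
                                         object = character(),
                                         rule = character())),
                         "A|B")$links, 0L)
  l1 <- data.frame(subject = paste0("s", 1:3), object = paste0("o", 1:3),
                   rule = "r1")
  l2 <- data.frame(subject = paste0("s", 4:7), object = paste0("o", 4:7),
                   rule = "r2")
  st <- linkStats(list(l1, l2), c("A|B", "A|B"))
  expect_equal(st$links, 7L)
  # the same pair emitted by both rules counts once
  st2 <- linkStats(list(l1, rbind(l2, l1[1, ])), c("A|B", "A|B"))
  expect_equal(st2$links, 7L)
})

test_that("planted links in synthetic federations are recovered exactly", {
  g <- generateFederation(synthSpec(nGenes = 10L, sharedGeneFraction = 1,
                                    seed = 3))
  mp <- g$mappings
  cosmic <- endpointStore(g$federation, "cosmic")
  tcga <- endpointStore(g$federation, "tcga")
  rule <- exactKeyRule(graphIRI(mp$cosmicExpr),
                       mp$cosmicExpr@predicateMap[["gene_symbol"]],
                       graphIRI(mp$tcgaExpr),
                       mp$tcgaExpr@predicateMap[["gene_symbol"]],
                       normalizer = "case_fold", id = "gene")
  links <- discoverExactLinks(cosmic, tcga, rule)
  # shared_gene_fraction 1.0, n_genes 10 -> exactly 10 links
  expect_equal(nrow(links), 10L)
  truth <- g$groundTruth$links$gene
  expect_setequal(paste(links$subject, links$object),
                  paste(truth$subject, truth$object))

  # positional rule recovers the planted CNV twins (precision and recall 1)
  posRule <- positionalRule(
    graphIRI(mp$cosmicCnv),
    c(chrom = mp$cosmicCnv@predicateMap[["chrom"]],
      start = mp$cosmicCnv@predicateMap[["start"]],
      end = mp$cosmicCnv@predicateMap[["end"]]),
    graphIRI(mp$tcgaCnv),
    c(chrom = mp$tcgaCnv@predicateMap[["chrom"]],
      start = mp$tcgaCnv@predicateMap[["start"]],
      end = mp$tcgaCnv@predicateMap[["end"]]), mode = "exact")
  posLinks <- discoverPositionalLinks(cosmic, tcga, posRule)
  posTruth <- g$groundTruth$links$cnv_position
  expect_setequal(paste(posLinks$subject, posLinks$object),
                  paste(posTruth$subject, posTruth$object))

  # all fractions zero: no links anywhere
  g0 <- generateFederation(synthSpec(sharedGeneFraction = 0,
                                     sharedSampleFraction = 0,
                                     sharedPositionFraction = 0, seed = 4))
  expect_equal(sum(vapply(g0$groundTruth$links, nrow, integer(1))), 0L)
  expect_equal(nquads(linksStore(g0$federation)), 0L)
})
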