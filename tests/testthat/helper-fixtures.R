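# Shared test helpers: programmatic fixtures and independent brute-force
# oracles. The oracles here are deliberately naive (double loops, distinct
# counts on pasted keys) and share no code with the implementations they
# check.

randomQuadStore <- function(n, nGraphs = 2, seed = 1) {
  withr::local_seed(seed)
  QuadStore(
    subject = iriTerm(paste0("http://ex.org/s", sample.int(max(n %/% 2, 1), n,
                                                           replace = TRUE))),
    predicate = iriTerm(paste0("http://ex.org/p", sample.int(5, n,
                                                             replace = TRUE))),
    object = ifelse(runif(n) < 0.5,
                    iriTerm(paste0("http://ex.org/o", sample.int(n, n,
                                                                 replace = TRUE))),
                    ifelse(runif(n) < 0.5,
                           plainLiteral(paste0("lit ", sample.int(n, n,
                                                                  replace = TRUE))),
                           intLiteral(sample.int(1000, n, replace = TRUE)))),
    graph = iriTerm(paste0("http://ex.org/g", sample.int(nGraphs, n,
                                                         replace = TRUE))))
}

# brute-force distinct counts over a quad data.frame
bruteStats <- function(store) {
  q <- quads(store)
  keys <- unique(paste(q$subject, q$predicate, q$object, q$graph, sep = "\x01"))
  parts <- strsplit(keys, "\x01", fixed = TRUE)
  list(nTriples = length(keys),
       nSubjects = length(unique(vapply(parts, `[[`, "", 1))),
       nPredicates = length(unique(vapply(parts, `[[`, "", 2))),
       nObjects = length(unique(vapply(parts, `[[`, "", 3))))
}

# brute-force exact-key linking over two key vectors (returns pair count
# over distinct normalized keys)
bruteExactPairs <- function(keysA, keysB, normalize = identity) {
  ka <- unique(keysA); kb <- unique(keysB)
  out <- 0L
  for (a in ka) for (b in kb)
    if (nzchar(normalize(a)) && normalize(a) == normalize(b)) out <- out + 1L
  out
}

# brute-force interval linking between two loci data.frames
bruteOverlapPairs <- function(la, lb, tol = 0L, exact = FALSE) {
  hits <- 0L
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(lb))) {
    if (la$chrom[i] != lb$chrom[j]) next
    if (exact) {
      if (la$start[i] == lb$start[j] && la$end[i] == lb$end[j])
        hits <- hits + 1L
    } else {
      if (la$start[i] - tol <= lb$end[j] + tol &&
          lb$start[j] - tol <= la$end[i] + tol)
        hits <- hits + 1L
    }
  }
  hits
}

writeTSV <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# ten-triple store whose BGP answers are enumerable by hand
handStore <- function() {
  ex <- function(x) iriTerm(paste0("http://h.org/", x))
  QuadStore(
    subject = ex(c("a", "a", "a", "b", "b", "c", "c", "d", "d", "e")),
    predicate = ex(c("knows", "age", "name", "knows", "age", "knows", "name",
                     "age", "name", "knows")),
    object = c(ex("b"), intLiteral(30), plainLiteral("Ann"), ex("c"),
               intLiteral(25), ex("a"), plainLiteral("Cid"), intLiteral(40),
               plainLiteral("Dee"), ex("a")),
    graph = rep(ex("g1"), 10))
}
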