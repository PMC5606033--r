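# Synthetic multi-source federations with planted links and known ground
# truth. The generator emulates the schema and key structure of the real
# federation: a COSMIC-shaped endpoint (expression, mutation, CNV,
# methylation graphs), a TCGA-shaped endpoint (CNV, expression, methylation
# graphs) and an annotation endpoint (GOA, KEGG, REACTOME graphs). Key
# overlap between the sources is planted exactly (floor(fraction * n));
# ground-truth links come from an exhaustive key/position comparison that
# is independent of the link-discovery code under test.

#' Specification of a synthetic federation
#'
#' Numeric values are drawn from simple declared distributions: coordinates
#' uniform within chromosome-scale bounds, beta values uniform in [-1, 1],
#' RPKM log-uniform over [0.01, 100]. Identical spec + seed always yields
#' identical output.
#'
#' @param nGenes genes per source; `floor(sharedGeneFraction * nGenes)` of
#'   them are shared between COSMIC and TCGA (and annotated in GOA).
#' @param nSamples samples per source; shared fraction analogous. COSMIC
#'   sample ids are patient-level; TCGA barcodes carry an aliquot suffix,
#'   matched through the tcga_patient_barcode normalizer.
#' @param nCnvSegments CNV segments per source; shared fraction of loci
#'   planted identically in both.
#' @param nMethylSites methylation rows per source (genes assigned
#'   round-robin so shared genes are covered on both sides).
#' @param sharedGeneFraction,sharedSampleFraction,sharedPositionFraction
#'   planted overlap fractions in [0, 1].
#' @param goPerGene GO annotations per shared gene.
#' @param pathwayPerGo REACTOME and KEGG cross-references per GO id.
#' @param keyNoise inject case variants into COSMIC gene keys (exercises
#'   the case_fold normalizer); off by default.
#' @param seed integer seed.
#' @return a `synthSpec` list.
#' @export
synthSpec <- function(nGenes = 12L, nSamples = 8L, nCnvSegments = 15L,
                      nMethylSites = 15L, sharedGeneFraction = 0.5,
                      sharedSampleFraction = 0.5,
                      sharedPositionFraction = 0.4, goPerGene = 2L,
                      pathwayPerGo = 1L, keyNoise = FALSE, seed = 1L) {
  fr <- c(sharedGeneFraction, sharedSampleFraction, sharedPositionFraction)
  if (any(fr < 0 | fr > 1)) stop("spec error: fractions must be in [0, 1]")
  if (any(c(nGenes, nSamples, nCnvSegments, nMethylSites) < 0))
    stop("spec error: counts must be >= 0")
  structure(list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
                 nCnvSegments = as.integer(nCnvSegments),
                 nMethylSites = as.integer(nMethylSites),
                 sharedGeneFraction = sharedGeneFraction,
                 sharedSampleFraction = sharedSampleFraction,
                 sharedPositionFraction = sharedPositionFraction,
                 goPerGene = as.integer(goPerGene),
                 pathwayPerGo = as.integer(pathwayPerGo),
                 keyNoise = isTRUE(keyNoise), seed = as.integer(seed)),
            class = "synthSpec")
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

splitShared <- function(universe, n, shared) {
  list(shared = universe[seq_len(shared)],
       a = universe[seq_len(n)],
       b = c(universe[seq_len(shared)],
             universe[n + seq_len(n - shared)]))
}

#' Generate a synthetic federation with planted links
#'
#' @param spec a [synthSpec()].
#' @return list with elements:
#'   \describe{
#'     \item{federation}{`Federation` (links graph populated from the
#'       ground truth).}
#'     \item{records}{named list of the `OmicsTable`s behind each graph.}
#'     \item{mappings}{named list of the `MappingConfig`s used.}
#'     \item{groundTruth}{planted link sets per rule (brute-force computed)
#'       and the shared key sets.}
#'   }
#' @export
generateFederation <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  withSeed(spec$seed, {
    nG <- spec$nGenes; nS <- spec$nSamples
    shG <- floor(spec$sharedGeneFraction * nG)
    shS <- floor(spec$sharedSampleFraction * nS)
    shP <- floor(spec$sharedPositionFraction * spec$nCnvSegments)

    geneU <- sprintf("GENE%03d", seq_len(max(2L * nG - shG, 0L)))
    genes <- splitShared(geneU, nG, shG)
    patientU <- sprintf("TCGA-%02d-%04d", (seq_len(max(2L * nS - shS, 0L)) %% 36) + 10,
                        1000 + seq_len(max(2L * nS - shS, 0L)))
    pats <- splitShared(patientU, nS, shS)
    cosmicSamples <- pats$a
    tcgaBarcodes <- paste0(pats$b, "-01A")

    rloc <- function(n) {
      chrom <- as.character(sample(1:22, n, replace = TRUE))
      start <- sample.int(5e7, n)
      list(chrom = chrom, start = start, end = start + sample.int(5e4, n))
    }

    # COSMIC mutation: 2 rows per gene
    mutGenes <- rep(genes$a, each = 2)
    ml <- rloc(length(mutGenes))
    mutKeys <- if (spec$keyNoise)
      ifelse(stats::runif(length(mutGenes)) < 0.5, tolower(mutGenes), mutGenes)
      else mutGenes
    cosmicMut <- asOmicsTable("mutation", data.frame(
      sample_id = sample(cosmicSamples, length(mutGenes), replace = TRUE),
      gene_symbol = mutKeys,
      chrom = ml$chrom, start = ml$start, end = ml$end,
      mutation_type = sample(mutationVocabulary()[1:5], length(mutGenes),
                             replace = TRUE),
      stringsAsFactors = FALSE))

    # CNV per source with planted identical loci
    sharedLoc <- rloc(shP)
    mkCnv <- function(samples, n) {
      extra <- rloc(n - shP)
      asOmicsTable("cnv", data.frame(
        sample_id = sample(samples, n, replace = TRUE),
        chrom = c(sharedLoc$chrom, extra$chrom),
        start = c(sharedLoc$start, extra$start),
        end = c(sharedLoc$end, extra$end),
        cnv_type = sample(c("GAIN", "LOSS"), n, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    cosmicCnv <- mkCnv(cosmicSamples, spec$nCnvSegments)
    tcgaCnv <- mkCnv(tcgaBarcodes, spec$nCnvSegments)

    # methylation per source, genes round-robin so shared genes hit both
    mkMeth <- function(geneSet, samples, n) {
      if (n == 0L) return(asOmicsTable("methylation", data.frame(
        gene_symbol = character(), beta_value = numeric())))
      gs <- geneSet[(seq_len(n) - 1L) %% length(geneSet) + 1L]
      loc <- rloc(n)
      asOmicsTable("methylation", data.frame(
        gene_symbol = gs,
        sample_id = sample(samples, n, replace = TRUE),
        composite_element_ref = sprintf("cg%08d", sample.int(1e7, n)),
        chrom = loc$chrom, start = loc$start, end = loc$end,
        beta_value = round(stats::runif(n, -1, 1), 6),
        stringsAsFactors = FALSE))
    }
    cosmicMeth <- mkMeth(genes$a, cosmicSamples, spec$nMethylSites)
    tcgaMeth <- mkMeth(genes$b, tcgaBarcodes, spec$nMethylSites)

    mkExpr <- function(geneSet) {
      tissues <- c("heart", "ovary", "kidney")
      asOmicsTable("expression", data.frame(
        gene_symbol = rep(geneSet, each = length(tissues)),
        tissue = rep(tissues, length(geneSet)),
        value = round(10^stats::runif(length(geneSet) * length(tissues), -2, 2), 4),
        regulation = sample(c("over", "under", "normal"),
                            length(geneSet) * length(tissues), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    cosmicExpr <- mkExpr(genes$a)
    tcgaExpr <- mkExpr(genes$b)

    goIds <- sprintf("GO:%07d", seq_len(max(shG * spec$goPerGene, 1L)))
    goa <- asOmicsTable("annotation", data.frame(
      gene_symbol = rep(genes$shared, each = spec$goPerGene),
      go_id = goIds[seq_len(shG * spec$goPerGene)],
      go_process = sprintf("process %s", goIds[seq_len(shG * spec$goPerGene)]),
      stringsAsFactors = FALSE))
    usedGo <- unique(omicsData(goa)$go_id)
    kegg <- asOmicsTable("annotation", data.frame(
      go_id = rep(usedGo, each = spec$pathwayPerGo),
      kegg_id = sprintf("hsa%05d", seq_len(length(usedGo) * spec$pathwayPerGo)),
      stringsAsFactors = FALSE))
    reactome <- asOmicsTable("annotation", data.frame(
      go_id = rep(usedGo, each = spec$pathwayPerGo),
      reactome_id = sprintf("R-HSA-%d",
                            seq_len(length(usedGo) * spec$pathwayPerGo)),
      stringsAsFactors = FALSE))

    mp <- list(
      cosmicExpr = defaultMapping("expression", "cosmic", "ALL"),
      cosmicMut = defaultMapping("mutation", "cosmic", "ALL"),
      cosmicCnv = defaultMapping("cnv", "cosmic", "ALL"),
      cosmicMeth = defaultMapping("methylation", "cosmic", "ALL"),
      tcgaCnv = defaultMapping("cnv", "tcga", "OV"),
      tcgaExpr = defaultMapping("expression", "tcga", "OV"),
      tcgaMeth = defaultMapping("methylation", "tcga", "OV"),
      goa = defaultMapping("annotation", "goa", "ALL"),
      kegg = defaultMapping("annotation", "kegg", "ALL"),
      reactome = defaultMapping("annotation", "reactome", "ALL"))
    rec <- list(cosmicExpr = cosmicExpr, cosmicMut = cosmicMut,
                cosmicCnv = cosmicCnv, cosmicMeth = cosmicMeth,
                tcgaCnv = tcgaCnv, tcgaExpr = tcgaExpr, tcgaMeth = tcgaMeth,
                goa = goa, kegg = kegg, reactome = reactome)

    cosmicStore <- buildDataset(lapply(
      c("cosmicExpr", "cosmicMut", "cosmicCnv", "cosmicMeth"),
      function(k) list(records = rec[[k]], mapping = mp[[k]])))$store
    tcgaStore <- buildDataset(lapply(
      c("tcgaCnv", "tcgaExpr", "tcgaMeth"),
      function(k) list(records = rec[[k]], mapping = mp[[k]])))$store
    annotStore <- buildDataset(lapply(
      c("goa", "kegg", "reactome"),
      function(k) list(records = rec[[k]], mapping = mp[[k]])))$store

    gt <- syntheticGroundTruth(rec, mp)
    fed <- Federation(
      list(cosmic = cosmicStore, tcga = tcgaStore, annot = annotStore),
      links = linksAsQuads(do.call(rbind, unname(gt$links))))
    list(federation = fed, records = rec, mappings = mp,
         groundTruth = gt)
  })
}

# exhaustive (brute-force) planted-link computation on the record tables;
# deliberately independent of discover*Links
syntheticGroundTruth <- function(rec, mp) {
  pairKeys <- function(keysA, mapA, roleA, keysB, mapB, roleB, norm, rule) {
    out <- emptyLinks()
    for (ka in unique(keysA)) for (kb in unique(keysB)) {
      if (normalizeKey(ka, norm) == normalizeKey(kb, norm))
        out <- rbind(out, data.frame(
          subject = keyIRI(mapA, roleA, ka), object = keyIRI(mapB, roleB, kb),
          rule = rule, stringsAsFactors = FALSE))
    }
    unique(out)
  }
  geneL <- pairKeys(
    c(omicsData(rec$cosmicMut)$gene_symbol, omicsData(rec$cosmicMeth)$gene_symbol,
      omicsData(rec$cosmicExpr)$gene_symbol),
    mp$cosmicMut, "gene_symbol",
    c(omicsData(rec$tcgaMeth)$gene_symbol, omicsData(rec$tcgaExpr)$gene_symbol),
    mp$tcgaMeth, "gene_symbol", "case_fold", "gene")
  geneGoaL <- pairKeys(
    c(omicsData(rec$cosmicMut)$gene_symbol, omicsData(rec$cosmicMeth)$gene_symbol,
      omicsData(rec$cosmicExpr)$gene_symbol),
    mp$cosmicMut, "gene_symbol",
    omicsData(rec$goa)$gene_symbol, mp$goa, "gene_symbol",
    "case_fold", "gene_goa")
  sampleL <- pairKeys(
    unique(c(omicsData(rec$cosmicMut)$sample_id,
             omicsData(rec$cosmicCnv)$sample_id)),
    mp$cosmicMut, "sample_id",
    unique(c(omicsData(rec$tcgaCnv)$sample_id,
             omicsData(rec$tcgaMeth)$sample_id)),
    mp$tcgaCnv, "sample_id", "tcga_patient_barcode", "sample")
  ca <- omicsData(rec$cosmicCnv); cb <- omicsData(rec$tcgaCnv)
  pos <- emptyLinks()
  for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
    if (ca$chrom[i] == cb$chrom[j] && ca$start[i] == cb$start[j] &&
        ca$end[i] == cb$end[j])
      pos <- rbind(pos, data.frame(
        subject = iriTerm(paste0(mp$cosmicCnv@recordNs, "r", i)),
        object = iriTerm(paste0(mp$tcgaCnv@recordNs, "r", j)),
        rule = "cnv_position", stringsAsFactors = FALSE))
  }
  list(links = list(gene = geneL, gene_goa = geneGoaL, sample = sampleL,
                    cnv_position = unique(pos)),
       sharedGenes = intersect(
         toupper(omicsData(rec$cosmicExpr)$gene_symbol),
         toupper(omicsData(rec$tcgaExpr)$gene_symbol)))
}

#' Oracle-computed expected answers
#'
#' Delegates to [evaluateUnionOracle()]: the ground-truth answer for any
#' query over a federation, computed from the union store and never from
#' the plan-based engine under test.
#'
#' @param fed a `Federation`.
#' @param query a `SparqlQuery` or SPARQL text.
#' @return data.frame of solution bindings.
#' @export
expectedAnswers <- function(fed, query) evaluateUnionOracle(query, fed)
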