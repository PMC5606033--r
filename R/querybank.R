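# Parameterized federated query templates over the COSMIC/TCGA/annotation
# federation, plus the RPKM and mutation-frequency gene prioritisation
# filters. Templates are plain BGP SELECT queries built against the default
# vocabulary of defaultMapping(); substituting a gene symbol grounds the
# gene positions and the owl:sameAs mediator pattern, so a gene absent from
# a source yields an empty result, never an error.

bankPrefixes <- function(base = FED_BASE) c(
  cosmic = paste0(sourceBase("cosmic", base), "vocab#"),
  tcga = paste0(sourceBase("tcga", base), "vocab#"),
  goa = paste0(sourceBase("goa", base), "vocab#"),
  kegg = paste0(sourceBase("kegg", base), "vocab#"),
  reactome = paste0(sourceBase("reactome", base), "vocab#"),
  owl = "http://www.w3.org/2002/07/owl#")

prefixBlock <- function(base) {
  p <- bankPrefixes(base)
  paste(sprintf("PREFIX %s: <%s>", names(p), unname(p)), collapse = "\n")
}

geneIRIOf <- function(source, geneSymbol, base = FED_BASE) {
  mintIRI(sourceBase(source, base), "gene", geneSymbol)
}

cgIRIOf <- function(source, ref, base = FED_BASE) {
  mintIRI(sourceBase(source, base), "cg", ref)
}

#' Build one of the federated query templates
#'
#' Five templates: "loci" (mutation loci from COSMIC joined with TCGA
#' positions through the gene sameAs link), "meth" (promoter beta values
#' from both methylation sources), "go" (methylation from both sources with
#' GO processes), "pathway" (gene to GO process to REACTOME and KEGG
#' pathways), "ploc" (promoter location for a gene, composite element REF
#' and chromosome). With `geneSymbol = NULL` the gene positions stay
#' variables (?gene_c, ?gene_t, ...).
#'
#' @param template template id.
#' @param geneSymbol optional gene symbol to ground the query on.
#' @param compositeRef composite element REF (cg id), "ploc" only.
#' @param chrom chromosome label, "ploc" only.
#' @param base federation base IRI.
#' @return a `SparqlQuery`.
#' @export
bankQuery <- function(template = c("loci", "meth", "go", "pathway", "ploc"),
                      geneSymbol = NULL, compositeRef = NULL, chrom = NULL,
                      base = FED_BASE) {
  template <- match.arg(template)
  g <- function(source, var) {
    if (is.null(geneSymbol)) var else geneIRIOf(source, geneSymbol, base)
  }
  gc <- g("cosmic", "?gene_c"); gt <- g("tcga", "?gene_t")
  gg <- g("goa", "?gene_g")
  body <- switch(template,
    loci = sprintf(
      "SELECT * WHERE {
         ?m cosmic:sample ?sample_c .
         ?m cosmic:gene %s .
         ?m cosmic:start ?start_c .
         ?m cosmic:mutation_type ?mutation_type .
         ?r tcga:hybrid_ref ?sample_t .
         ?r tcga:gene %s .
         ?r tcga:start ?start_t .
         %s owl:sameAs %s .
       }", gc, gt, gc, gt),
    meth = sprintf(
      "SELECT * WHERE {
         ?mc cosmic:gene %s .
         ?mc cosmic:composite_element_ref ?ref_c .
         ?mc cosmic:beta_value ?beta_c .
         ?mt tcga:gene %s .
         ?mt tcga:composite_element_ref ?ref_t .
         ?mt tcga:beta_value ?beta_t .
         %s owl:sameAs %s .
       }", gc, gt, gc, gt),
    go = sprintf(
      "SELECT * WHERE {
         ?mc cosmic:gene %s .
         ?mc cosmic:composite_element_ref ?ref_c .
         ?mc cosmic:beta_value ?beta_c .
         ?mt tcga:gene %s .
         ?mt tcga:beta_value ?beta_t .
         %s owl:sameAs %s .
         %s owl:sameAs %s .
         ?an goa:gene %s .
         ?an goa:go_process ?go_process .
       }", gc, gt, gc, gt, gc, gg, gg),
    pathway = sprintf(
      "SELECT * WHERE {
         ?mt tcga:gene %s .
         ?mt tcga:composite_element_ref ?ref_t .
         ?mt tcga:beta_value ?beta_t .
         %s owl:sameAs %s .
         %s owl:sameAs %s .
         ?an goa:gene %s .
         ?an goa:go_id ?go .
         ?an goa:go_process ?go_process .
         ?re reactome:go_id ?go .
         ?re reactome:reactome_id ?reactome .
         ?ke kegg:go_id ?go .
         ?ke kegg:kegg_id ?kegg .
       }", gt, gc, gt, gc, gg, gg),
    ploc = {
      stopifnot(!is.null(geneSymbol), !is.null(compositeRef), !is.null(chrom))
      ch <- plainLiteral(normalizeChrom(chrom))
      sprintf(
        "SELECT ?start_c ?start_t WHERE {
           ?mc cosmic:gene %s .
           ?mc cosmic:composite_element_ref %s .
           ?mc cosmic:chr %s .
           ?mc cosmic:start ?start_c .
           ?mt tcga:gene %s .
           ?mt tcga:composite_element_ref %s .
           ?mt tcga:chr %s .
           ?mt tcga:start ?start_t .
           %s owl:sameAs %s .
         }", gc, cgIRIOf("cosmic", compositeRef, base), ch,
        gt, cgIRIOf("tcga", compositeRef, base), ch, gc, gt)
    })
  parseSparql(paste(prefixBlock(base), body, sep = "\n"))
}

#' Federated query templates
#'
#' Convenience runners: build the template with [bankQuery()] and answer it
#' over the federation with [runFederatedQuery()]. All of them return the
#' mediator's solution bindings; `qPromoterLocation` additionally reshapes
#' the two per-source start variables into long form with a `source`
#' column, one solution per source.
#'
#' @param fed a `Federation`.
#' @param geneSymbol gene symbol (optional except for `qPromoterLocation`).
#' @param base federation base IRI.
#' @return data.frame of solutions.
#' @export
qMutationLoci <- function(fed, geneSymbol = NULL, base = FED_BASE) {
  runFederatedQuery(fed, bankQuery("loci", geneSymbol, base = base))
}

#' @rdname qMutationLoci
#' @export
qPromoterMethylation <- function(fed, geneSymbol = NULL, base = FED_BASE) {
  runFederatedQuery(fed, bankQuery("meth", geneSymbol, base = base))
}

#' @rdname qMutationLoci
#' @export
qMethylationGO <- function(fed, geneSymbol = NULL, base = FED_BASE) {
  runFederatedQuery(fed, bankQuery("go", geneSymbol, base = base))
}

#' @rdname qMutationLoci
#' @export
qGenePathwayProcess <- function(fed, geneSymbol = NULL, base = FED_BASE) {
  runFederatedQuery(fed, bankQuery("pathway", geneSymbol, base = base))
}

#' @rdname qMutationLoci
#' @param compositeRef composite element REF (cg id).
#' @param chrom chromosome label.
#' @export
qPromoterLocation <- function(fed, geneSymbol, compositeRef, chrom,
                              base = FED_BASE) {
  wide <- runFederatedQuery(
    fed, bankQuery("ploc", geneSymbol, compositeRef, chrom, base = base))
  if (!nrow(wide))
    return(data.frame(source = character(), start = numeric(),
                      gene_symbol = character(),
                      composite_element_ref = character(),
                      stringsAsFactors = FALSE))
  long <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    data.frame(source = c("COSMIC", "TCGA"),
               start = c(termNumber(wide$start_c[i]),
                         termNumber(wide$start_t[i])),
               gene_symbol = geneSymbol,
               composite_element_ref = compositeRef,
               stringsAsFactors = FALSE)
  }))
  attr(long, "provenance") <- attr(wide, "provenance")
  long
}

#' Filter genes by RPKM cutoff across required tissues
#'
#' A gene is retained iff, for every tissue in `requireAllTissues`, its
#' expression level in that tissue is strictly greater than `cutoff`
#' (several records per gene and tissue are summarized by their minimum).
#' With an empty tissue requirement, any gene with at least one value above
#' the cutoff is kept. Genes missing a required tissue are excluded and
#' reported in the `excluded` attribute. Output is ordered by descending
#' minimum-across-tissues value, ties broken lexicographically, and is
#' invariant to the row order of the input.
#'
#' @param x expression `OmicsTable` or data.frame with columns gene_symbol,
#'   tissue, value.
#' @param cutoff non-negative RPKM cutoff (strict ">").
#' @param requireAllTissues character vector of tissues that must all pass.
#' @return ordered character vector of gene symbols, with attribute
#'   `excluded` (data.frame gene_symbol, reason).
#' @export
filterGenesByRPKM <- function(x, cutoff, requireAllTissues = character()) {
  stopifnot(cutoff >= 0)
  df <- if (is(x, "OmicsTable")) omicsData(x) else x
  if (!nrow(df)) return(structure(character(0),
    excluded = data.frame(gene_symbol = character(), reason = character())))
  per <- stats::aggregate(value ~ gene_symbol + tissue, data = df, FUN = min)
  genes <- sort(unique(df$gene_symbol))
  excluded <- data.frame(gene_symbol = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- logical(length(genes)); score <- numeric(length(genes))
  for (i in seq_along(genes)) {
    sub <- per[per$gene_symbol == genes[i], , drop = FALSE]
    if (length(requireAllTissues)) {
      miss <- setdiff(requireAllTissues, sub$tissue)
      if (length(miss)) {
        excluded <- rbind(excluded, data.frame(
          gene_symbol = genes[i],
          reason = paste("missing tissue:", paste(miss, collapse = ",")),
          stringsAsFactors = FALSE))
        next
      }
      vals <- sub$value[sub$tissue %in% requireAllTissues]
      keep[i] <- all(vals > cutoff)
      score[i] <- min(vals)
    } else {
      keep[i] <- any(sub$value > cutoff)
      score[i] <- min(sub$value)
    }
  }
  kept <- genes[keep]
  ord <- order(-score[keep], kept)
  structure(kept[ord], excluded = excluded)
}

#' Rank genes by non-synonymous mutation frequency
#'
#' Orders genes by descending count of their non-synonymous mutation
#' records, ties broken lexicographically, and returns the first `topK`.
#'
#' @param x mutation `OmicsTable` or data.frame with gene_symbol and
#'   mutation_type columns.
#' @param topK number of genes to return (>= 1).
#' @param ns non-synonymous vocabulary.
#' @return character vector of at most `topK` gene symbols.
#' @export
rankGenesByMutationFrequency <- function(x, topK, ns = nsMutationTypes()) {
  stopifnot(topK >= 1)
  df <- if (is(x, "OmicsTable")) omicsData(x) else x
  df <- df[df$mutation_type %in% ns, , drop = FALSE]
  if (!nrow(df)) return(character(0))
  cnt <- table(df$gene_symbol)
  genes <- names(cnt)
  ord <- order(-as.integer(cnt), genes)
  utils::head(genes[ord], topK)
}
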