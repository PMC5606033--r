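# The worked-example fixture: a small two-source-plus-annotation federation
# carrying, verbatim, the published record values used by the worked
# queries — the two COSMIC-sample/TCGA-barcode identities (TCGA-13-0920,
# TCGA-24-1850), the MYH7/cg05744229 promoter rows on chromosome 14 with
# their per-source start coordinates (COSMIC 23435469, TCGA 23904678), the
# MYH7 methylation row with beta value 0.041999536 and tumour purity
# 773.555, and the chr14 CNV loci (23857092-23886486 in both sources).
# Gene intervals and pathway accessions are illustrative fixture values
# (the source tables publish none); coordinate pairs printed with start and
# end transposed are swapped to satisfy the locus invariant.

#' Gene intervals used by the fixture for region-to-gene mapping
#'
#' Approximate hg19 intervals for the chr14 myosin locus and ACTA1;
#' illustrative, chosen so the chr14 CNV region overlaps MYH6 and MYH7.
#'
#' @return data.frame with columns gene_symbol, chrom, start, end.
#' @export
fixtureGeneAnnotation <- function() {
  data.frame(
    gene_symbol = c("MYH6", "MYH7", "TG", "ACTA1"),
    chrom = c("14", "14", "8", "1"),
    start = c(23851199L, 23881947L, 133879200L, 229566993L),
    end = c(23877486L, 23904870L, 134151000L, 229569845L),
    stringsAsFactors = FALSE)
}

fixtureRecords <- function() {
  cosmicMut <- asOmicsTable("mutation", data.frame(
    sample_id = c("TCGA-13-0920", "TCGA-24-1850", "TCGA-13-0920"),
    gene_symbol = c("MYH7", "MYH7", "TG"),
    ensembl_id = c("ENSMUSP00000018795", "ENSMUSP00000018795", NA),
    chrom = c("14", "14", "8"),
    start = c(23886490L, 23894010L, 133948000L),
    end = c(23886490L, 23894010L, 133948000L),
    mutation_type = c("missense", "nonsense", "missense"),
    pmid = c("1398522", "1398522", NA),
    stringsAsFactors = FALSE))

  # chr14 row of the published CNV loci table in both sources (exact-mode
  # positional link); transposed printed pairs are swapped
  cosmicCnv <- asOmicsTable("cnv", data.frame(
    sample_id = c("TCGA-13-0920", "TCGA-13-0920", "TCGA-13-0920"),
    chrom = c("14", "9", "5"),
    start = c(23857092L, 4069657L, 24132L),
    end = c(23886486L, 4684967L, 515532L),
    cnv_type = c("LOSS", "LOSS", "GAIN"),
    stringsAsFactors = FALSE))
  tcgaCnv <- asOmicsTable("cnv", data.frame(
    sample_id = c("TCGA-13-0920-01A", "TCGA-24-1850-01A"),
    chrom = c("14", "14"),
    start = c(23857092L, 23857082L),
    end = c(23886486L, 23886607L),
    cnv_type = c("LOSS", "LOSS"),
    stringsAsFactors = FALSE))

  cosmicMeth <- asOmicsTable("methylation", data.frame(
    gene_symbol = c("MYH7", "MYH6"),
    sample_id = c("TCGA-13-0920", "TCGA-24-1850"),
    composite_element_ref = c("cg05744229", "cg00000292"),
    chrom = c("14", "14"),
    start = c(23435469L, 23470000L),
    end = c(23435969L, 23470500L),
    beta_value = c(0.041999536, 0.12),
    tumour_purity = c(773.555, NA),
    pmid = c("1398522", NA),
    stringsAsFactors = FALSE))
  tcgaMeth <- asOmicsTable("methylation", data.frame(
    gene_symbol = c("MYH7", "MYH6"),
    sample_id = c("TCGA-13-0920-01A", "TCGA-24-1850-01A"),
    composite_element_ref = c("cg05744229", "cg00000292"),
    chrom = c("14", "14"),
    start = c(23904678L, 23910000L),
    end = c(23905178L, 23910500L),
    beta_value = c(-0.773, 0.2),
    stringsAsFactors = FALSE))

  cosmicExpr <- asOmicsTable("expression", data.frame(
    gene_symbol = c("MYH7", "MYH7", "TG", "TG"),
    tissue = c("heart", "skeletal muscle", "thyroid", "heart"),
    value = c(1520.4, 980.2, 310.8, 0.21),
    regulation = c("over", "over", "over", "normal"),
    stringsAsFactors = FALSE))
  tcgaExpr <- asOmicsTable("expression", data.frame(
    gene_symbol = c("MYH7", "TG"),
    tissue = c("OV", "OV"),
    value = c(2.4, 0.9),
    regulation = c("under", "under"),
    stringsAsFactors = FALSE))

  goa <- asOmicsTable("annotation", data.frame(
    gene_symbol = c("MYH7", "MYH7", "ACTA1"),
    ensembl_id = c("ENSMUSP00000018795", "ENSMUSP00000018795", NA),
    go_id = c("GO:0030049", "GO:0002376", "GO:0030049"),
    go_process = c("muscle filament sliding", "acute inflammatory response",
                   "muscle filament sliding"),
    stringsAsFactors = FALSE))
  kegg <- asOmicsTable("annotation", data.frame(
    go_id = c("GO:0030049", "GO:0002376"),
    kegg_id = c("hsa04260", "hsa04610"),
    stringsAsFactors = FALSE))
  reactome <- asOmicsTable("annotation", data.frame(
    go_id = c("GO:0030049", "GO:0002376"),
    reactome_id = c("R-HSA-390522", "R-HSA-168256"),
    stringsAsFactors = FALSE))

  list(cosmicMut = cosmicMut, cosmicCnv = cosmicCnv, cosmicMeth = cosmicMeth,
       cosmicExpr = cosmicExpr, tcgaCnv = tcgaCnv, tcgaMeth = tcgaMeth,
       tcgaExpr = tcgaExpr, goa = goa, kegg = kegg, reactome = reactome)
}

fixtureMappings <- function() {
  list(cosmicMut = defaultMapping("mutation", "cosmic", "ALL"),
       cosmicCnv = defaultMapping("cnv", "cosmic", "ALL"),
       cosmicMeth = defaultMapping("methylation", "cosmic", "ALL"),
       cosmicExpr = defaultMapping("expression", "cosmic", "ALL"),
       tcgaCnv = defaultMapping("cnv", "tcga", "OV"),
       tcgaMeth = defaultMapping("methylation", "tcga", "OV"),
       tcgaExpr = defaultMapping("expression", "tcga", "OV"),
       goa = defaultMapping("annotation", "goa", "ALL"),
       kegg = defaultMapping("annotation", "kegg", "ALL"),
       reactome = defaultMapping("annotation", "reactome", "ALL"))
}

#' Link rules connecting the fixture sources
#'
#' Gene-symbol and composite-element-REF exact-key rules between the two
#' methylation graphs, the sample/barcode rule (patient-level barcode
#' truncation) between the mutation and CNV graphs, the gene rule into
#' GOA, and the exact positional rule between the CNV graphs.
#'
#' @param mp mappings as returned by the fixture (internal default).
#' @return named list of `LinkRule`s.
#' @export
fixtureLinkRules <- function(mp = fixtureMappings()) {
  pm <- function(m, role) m@predicateMap[[role]]
  list(
    gene = exactKeyRule(graphIRI(mp$cosmicMeth), pm(mp$cosmicMeth, "gene_symbol"),
                        graphIRI(mp$tcgaMeth), pm(mp$tcgaMeth, "gene_symbol"),
                        normalizer = "case_fold", id = "gene"),
    sample = exactKeyRule(graphIRI(mp$cosmicMut), pm(mp$cosmicMut, "sample_id"),
                          graphIRI(mp$tcgaCnv), pm(mp$tcgaCnv, "sample_id"),
                          normalizer = "tcga_patient_barcode", id = "sample"),
    cg = exactKeyRule(graphIRI(mp$cosmicMeth),
                      pm(mp$cosmicMeth, "composite_element_ref"),
                      graphIRI(mp$tcgaMeth),
                      pm(mp$tcgaMeth, "composite_element_ref"),
                      id = "cg"),
    gene_goa = exactKeyRule(graphIRI(mp$cosmicMeth),
                            pm(mp$cosmicMeth, "gene_symbol"),
                            graphIRI(mp$goa), pm(mp$goa, "gene_symbol"),
                            normalizer = "case_fold", id = "gene_goa"),
    cnv_position = positionalRule(
      graphIRI(mp$cosmicCnv),
      c(chrom = pm(mp$cosmicCnv, "chrom"), start = pm(mp$cosmicCnv, "start"),
        end = pm(mp$cosmicCnv, "end")),
      graphIRI(mp$tcgaCnv),
      c(chrom = pm(mp$tcgaCnv, "chrom"), start = pm(mp$tcgaCnv, "start"),
        end = pm(mp$tcgaCnv, "end")),
      mode = "exact", id = "cnv_position"))
}

#' Build the worked-example federation
#'
#' Three endpoints (cosmic, tcga, annot) whose graphs carry the published
#' record values described above, with the links graph populated by running
#' the fixture link rules.
#'
#' @return list with elements federation, records, mappings, rules, links
#'   (the discovered link data.frame).
#' @export
paperFixture <- function() {
  rec <- fixtureRecords()
  mp <- fixtureMappings()
  cosmic <- buildDataset(lapply(c("cosmicMut", "cosmicCnv", "cosmicMeth",
                                  "cosmicExpr"),
    function(k) list(records = rec[[k]], mapping = mp[[k]])))$store
  tcga <- buildDataset(lapply(c("tcgaCnv", "tcgaMeth", "tcgaExpr"),
    function(k) list(records = rec[[k]], mapping = mp[[k]])))$store
  annot <- buildDataset(lapply(c("goa", "kegg", "reactome"),
    function(k) list(records = rec[[k]], mapping = mp[[k]])))$store
  rules <- fixtureLinkRules(mp)
  links <- rbind(
    discoverExactLinks(cosmic, tcga, rules$gene),
    discoverExactLinks(cosmic, tcga, rules$sample),
    discoverExactLinks(cosmic, tcga, rules$cg),
    discoverExactLinks(cosmic, annot, rules$gene_goa),
    discoverPositionalLinks(cosmic, tcga, rules$cnv_position))
  fed <- Federation(list(cosmic = cosmic, tcga = tcga, annot = annot),
                    links = linksAsQuads(links))
  list(federation = fed, records = rec, mappings = mp, rules = rules,
       links = links)
}
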