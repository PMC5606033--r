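# omicsFed

Cancer multi-omics data live in isolated repositories with incompatible
schemas: somatic mutations and expression in COSMIC-style exports, CNV and
promoter methylation in TCGA-style matrices, pathway and process
annotation in GOA/KEGG/REACTOME. Answering a question such as *"where is
this gene mutated, how does its promoter methylation change, and which
pathways does that touch?"* requires joining records across all of them.

`omicsFed` is an R toolkit for doing this with linked-data machinery at
desk scale, aimed at bioinformaticians integrating tabular omics exports:

1. **RDFization** — typed readers for tab-separated omics tables
   (mutation, CNV, expression, methylation, annotation) with row-level
   validation, and a deterministic converter to RDF quads. Each logical
   dataset `(source, data type, cancer type)` becomes its own named graph;
   each record becomes one row resource with an `rdf:type` quad plus one
   quad per non-null field, so the triple count obeys the closed form
   `n_triples = Σ_records (1 + #non-null fields)`. Shared keys (gene
   symbol, sample barcode, ENSEMBL id, composite element REF, GO id) are
   minted as resources so links and joins operate on IRIs.
2. **Link discovery** — `owl:sameAs` links between sources by exact-key
   rules (with `verbatim`, `case_fold` and `tcga_patient_barcode`
   normalization policies) and by the genomic-position rule for CNV
   segments: same normalized chromosome and identical `(start, end)` in
   exact mode, or interval overlap after symmetric extension by a
   tolerance. Links are materialized in a dedicated links graph, and a
   region-to-gene mapper (≥ 1 bp overlap) connects CNV loci to gene
   symbols.
3. **Federated querying** — SPARQL `SELECT` over basic graph patterns,
   answered across a `Federation` of sources by triple-pattern-wise
   two-level source selection (endpoints, then named graphs, via an exact
   predicate capability index that never sacrifices recall), maximal
   exclusive-group planning, and sameAs-aware mediator hash joins. Every
   result is verifiable against a union-store oracle
   (`evaluateUnionOracle`), and a synthetic federation generator with
   planted links (`generateFederation`) provides ground truth for testing.

Five query templates (`bankQuery`) cover the standard questions: mutation
loci across sources, promoter methylation beta values, methylation with GO
processes, gene–pathway–process chains through REACTOME and KEGG, and
promoter location by gene/probe/chromosome. Gene prioritisation helpers
implement the strict RPKM filter (`value > cutoff` in every required
tissue) and non-synonymous mutation-frequency ranking.

## Worked example

The package ships a fixture federation (`paperFixture()`) whose records
carry the published worked-example values: two COSMIC sample ids identical
to the TCGA patient barcodes `TCGA-13-0920` and `TCGA-24-1850`, and MYH7
promoter methylation rows for probe `cg05744229` on chromosome 14 in both
sources.

```r
library(omicsFed)
fx <- paperFixture()

# sample-identity linking (barcode truncated to patient level)
links <- discoverExactLinks(endpointStore(fx$federation, "cosmic"),
                            endpointStore(fx$federation, "tcga"),
                            fx$rules$sample)
nrow(links)
#> [1] 2

# federated promoter location for (MYH7, cg05744229, chr14)
qPromoterLocation(fx$federation, "MYH7", "cg05744229", "14")
#>   source    start gene_symbol composite_element_ref
#> 1 COSMIC 23435469        MYH7            cg05744229
#> 2   TCGA 23904678        MYH7            cg05744229

# federated promoter methylation for MYH7 (COSMIC-side beta value)
m <- qPromoterMethylation(fx$federation, "MYH7")
termNumber(m$beta_c)
#> [1] 0.041999536
```

The two `start` values are the promoter starts each source reports for
the probe; the beta value is the COSMIC methylation level for MYH7 that
the federated join carries through the gene `owl:sameAs` link. Every
federated answer can be cross-checked:

```r
q <- bankQuery("meth", "MYH7")
sameSolutionMultiset(runFederatedQuery(fx$federation, q),
                     evaluateUnionOracle(q, fx$federation))
#> [1] TRUE
```

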