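---
title: "Linking and federated querying of multi-omics datasets with omicsFed"
author: "omicsFed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking and federated querying of multi-omics datasets with omicsFed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsFed)
```

## The integration model

`omicsFed` treats each omics dataset as a named RDF graph and each
cross-dataset correspondence as an explicit `owl:sameAs` assertion, so
that questions spanning mutation, copy-number, expression, methylation and
pathway annotation become basic-graph-pattern (BGP) SPARQL queries over a
federation of sources. Three assumptions shape the design:

* **Keys identify entities.** A gene symbol, a sample barcode, an ENSEMBL
  id, a CpG probe id (composite element REF) or a GO id names the same
  biological entity wherever it appears; sources differ only in spelling
  conventions, which a small set of normalization policies absorbs.
* **CNV segments have no gene key.** Copy-number rows are located only by
  `(chromosome, start, end)`, so they are linked positionally and mapped
  to genes by interval overlap.
* **Links are data, not inference.** `owl:sameAs` links live in their own
  named graph and are joined explicitly by queries; no rewriting or
  transitive-closure semantics is applied. This keeps federated answers
  verifiable: every result must equal the evaluation of the same BGP over
  the union of all graphs plus the links graph.

## From tables to quads

Records are validated at construction (`readOmicsTable`, `asOmicsTable`):
coordinates are 1-based inclusive with `start ≥ 1` and `end ≥ start`,
beta values satisfy `|beta| ≤ 1` (negative values are legal, since
methylation *changes* are signed), `cnv_type` is `GAIN`/`LOSS`, probe ids
match `^cg[0-9]+$`, and mutation types come from a declared vocabulary.
Invalid rows are rejected with their row number and reason — reported,
never silently dropped — and `strict = TRUE` turns the first reject into
an error. Chromosome labels are normalized once at ingestion (strip
`chr`, uppercase `X/Y/MT`); all internal comparisons use that form.

`rdfizeTable` is deterministic: row resources are minted from the row
index under a per-graph namespace, so the same table and mapping always
produce the identical quad multiset. Each record yields one `rdf:type`
quad plus exactly one quad per non-null mapped field, giving the count law
`n_triples = Σ (1 + #non-null fields)` that the tests assert. Shared-key
fields are emitted as *resource* objects — IRIs whose percent-encoded last
path segment is the key text — because link discovery and sameAs joins
operate on resources; all other fields are literals (coordinates as
`xsd:integer`, expression/beta/purity as `xsd:double`, the rest plain).
Emitting the key once, as a resource, keeps the count law exact while
remaining lossless: `unrdfizeTable` recovers every mapped field.
Serialization is N-Quads rather than N3 so the named-graph partition that
source selection depends on survives a round trip.

Two pragmatic extensions to the methylation schema: an optional
`sample_id` role (methylation matrices are per-aliquot, and the barcode is
needed for sample-level joins) and an optional `pmid` role for literature
provenance.

## Link rules and their parameters

* **Exact-key rules** compare the normalized key text of the key resources
  under one predicate per side. Policies: `verbatim` (identity),
  `case_fold` (uppercase), `tcga_patient_barcode` (truncate to the first
  three dash-separated fields, i.e. patient level — sample ids on the
  COSMIC side are patient-level strings, so this is the granularity at
  which the two vocabularies meet). All policies are idempotent, which the
  tests check property-style.
* **Positional rules** (CNV) default to *exact* mode — same normalized
  chromosome, identical `(start, end)` — because segment linking by
  position is specified without slack. Real segmentations disagree at
  boundaries, so *overlap* mode extends both intervals symmetrically by
  `tolerance_bp` (default 0) on each side and links on ≥ 1 bp overlap.
  `tolerance_bp` must be 0 in exact mode.
* **Region-to-gene mapping** uses ≥ 1 bp overlap rather than containment,
  so genes spanning a segment boundary are retained.

Link sets are deduplicated pairs stored once in rule direction; swapping
the rule's sides yields exactly the mirrored set. `linkStats` counts
deduplicated pairs per source pair (two rules finding the same pair count
it once) — the counting unit is sameAs *pairs*, not linkable resources.

## Federated query answering

The supported query fragment is `SELECT` (optionally `DISTINCT`) over
BGPs with bound or variable predicates plus simple `FILTER` comparisons
— sufficient for every template in the bank; anything else is rejected
with an "unsupported fragment" error rather than silently mis-answered.

Source selection is triple-pattern-wise and two-level: level 1 chooses
endpoints, level 2 named graphs within them, both driven by an exact
predicate-occurrence capability index (predicate → set of
`(endpoint, graph)` cells with per-cell counts). Exactness makes the
selection recall-preserving by construction — a cell is selected iff it
holds at least one triple with the pattern's predicate — and pruning
effective whenever predicates are source-exclusive, which per-source
vocabularies make the common case. Variable-predicate patterns select
every cell; no pruning is possible without risking recall.

Planning groups patterns whose selection is a single cell into maximal
exclusive groups (one sub-query each); a pattern selected in several
cells becomes a union node evaluated per cell; `owl:sameAs` patterns
resolve against the dedicated links store and act as mediator joins. A
pattern with an empty selection produces an empty-result marker — the
query answer is empty, not an error. Execution hash-joins node results on
shared variables, smallest relation first, ties broken lexicographically
for determinism; filters, `DISTINCT` and projection apply at the
mediator. Bindings-passing to sources is deliberately absent: at desk
scale correctness and verifiability outrank data transfer.

Results are multisets (duplicates per standard BGP semantics; a triple
present in two graphs contributes two solutions unless `DISTINCT`).
`evaluateUnionOracle` implements the same semantics by brute-force
nested-loop extension over the union store — a deliberately independent
code path used by the tests and the synthetic ground truth, never by the
engine.

## The synthetic generator and what passing tests mean

`generateFederation(synthSpec(...))` emulates the *schema and key
structure* of the real federation: per-source gene/sample universes with
exactly `floor(fraction × n)` planted shared keys, CNV segments with
planted identical loci, methylation sites assigned round-robin so shared
genes are covered on both sides, and GO/KEGG/REACTOME chains with
configurable fan-out. Values are drawn from simple declared
distributions — coordinates uniform, beta uniform in `[-1, 1]`, RPKM
log-uniform over `[0.01, 100]` — because they only need to exercise
filters and joins. Generation is seed-deterministic down to byte-identical
N-Quads. Optional key noise (case variants) exercises the normalizers and
is off by default.

The generator does *not* emulate biologically realistic mutation spectra,
methylation profiles, linkage disequilibrium between omics layers, or the
scale and vocabulary of the real repositories. Green tests therefore
establish engine correctness (oracle equivalence, planted-link recovery,
selection recall) on schema-faithful data, not biological validity of any
particular integration result, and desk-scale results do not reproduce
repository-scale link counts or triple statistics.

Default test problem sizes — federations of 6–12 genes, 4–8 samples,
6–15 CNV segments and 8–15 methylation sites per source, 50 seeded
federations for the oracle-equivalence sweep, 100×200-segment interval
sets against the quadratic oracle — were chosen so the whole suite
exercises every code path at sizes where brute-force oracles are exact
and fast.

## The worked-example fixture

`paperFixture()` builds a three-endpoint federation whose records carry
published worked-example values verbatim: the two COSMIC-sample ↔ TCGA
patient-barcode identities (`TCGA-13-0920`, `TCGA-24-1850`), MYH7
methylation rows for probe `cg05744229` on chromosome 14 with promoter
starts 23435469 (COSMIC) and 23904678 (TCGA), the COSMIC MYH7 beta value
0.041999536 with tumour purity 773.555, and the chr14 CNV locus
23857092–23886486 present in both CNV graphs (the exact-mode positional
link). Where a published coordinate pair is printed with start and end
transposed, the fixture swaps it to satisfy the locus invariant; the TCGA
side beta for the probe, which is not published, uses −0.773, the
reported mode of extreme beta-value changes. Gene intervals for
region-to-gene mapping (MYH6/MYH7/TG/ACTA1) are illustrative
approximately-hg19 coordinates chosen so the chr14 region overlaps the
two myosin genes; pathway accessions in the annotation graphs are
plausible-shaped fixture values.

## Gene prioritisation

`filterGenesByRPKM` keeps a gene iff its expression is *strictly* greater
than the cutoff in every required tissue (several records per gene and
tissue summarize by their minimum — the conservative choice); genes
missing a required tissue are excluded and reported. Output is ordered by
descending minimum-across-tissues value with lexicographic ties, making
it invariant to input row order. Ranking by descending minimum (rather
than mean) is this package's documented default for selecting a top-k
panel; the cutoff itself (e.g. the 0.3747 used in the tests) is an input
parameter, not a derived quantity. `rankGenesByMutationFrequency` counts
non-synonymous records per gene with the same tie rule. The
non-synonymous vocabulary defaults to `missense`, `nonsense`,
`frameshift`, `splice-site` and is configurable, since which labels count
as non-synonymous is a per-source convention.

## Numerical and degenerate-input choices

Terms are carried as canonical N-Triples tokens, so join equality is
exact string equality; numeric literal lexicals are fixed (no scientific
notation, trailing zeros trimmed) so equal values always compare equal.
Comparisons in `FILTER` are numeric when the operand is a number. Empty
tables, empty graphs, empty federations, empty link sets and queries on
absent genes all yield empty results rather than errors; duplicate graph
IRIs across tables and unmapped data roles are configuration errors.
Interval extension in overlap mode may push starts below 1; intervals are
compared as plain integer ranges, so this affects nothing.

## Known limitations

* Query fragment only: no `OPTIONAL`, `UNION`, property paths,
  aggregates, or full SPARQL 1.1.
* In-memory client-mode sources only; no HTTP endpoint hosting and no
  cost-based optimisation beyond smallest-first counts.
* No transitive closure over sameAs chains across more than two sources;
  multi-hop joins must be written explicitly (as the pathway template
  does).
* No probabilistic record linkage; keys either match after normalization
  or they do not.
* Access control between sources is out of scope by design.
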