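# Deterministic conversion of omics records into named-graph quads.
# Per record: one row resource, one rdf:type quad, and exactly one quad per
# non-null mapped field, all inside the mapping's named graph. Shared-key
# roles (gene symbol, sample/barcode, ENSEMBL id, composite element REF,
# GO id) are emitted as resource objects — minted key IRIs whose last path
# segment carries the key text — because sameAs link discovery and
# federated joins operate on resources. Coordinates become xsd:integer
# literals, expression/beta/purity xsd:double, everything else plain
# literals.

FED_BASE <- "http://omics-federation.org/"

#' Source namespaces and vocabulary IRIs
#'
#' Each source (cosmic, tcga, goa, kegg, reactome) gets its own namespace
#' under a common base; predicates live at `<source>/vocab#<role>`. GO-id
#' keys share one `annot` namespace across the annotation sources so that
#' GOA/KEGG/REACTOME rows join directly on the GO resource.
#'
#' @param source source label.
#' @param base federation base IRI.
#' @return plain IRI string (`sourceBase`) or IRI term (`vocabIRI`).
#' @export
sourceBase <- function(source, base = FED_BASE) paste0(base, source, "/")

#' @rdname sourceBase
#' @param role semantic role name.
#' @export
vocabIRI <- function(source, role, base = FED_BASE) {
  iriTerm(paste0(sourceBase(source, base), "vocab#", role))
}

# roles emitted as minted key resources rather than literals
KEY_ROLES <- c("gene_symbol", "sample_id", "ensembl_id",
               "composite_element_ref", "go_id")

keyKindOf <- c(gene_symbol = "gene", sample_id = "sample",
               ensembl_id = "ensembl", composite_element_ref = "cg",
               go_id = "go")

#' MappingConfig: how one table becomes one named graph
#'
#' @slot kind record kind being mapped.
#' @slot source source label (cosmic, tcga, goa, kegg, reactome, ...).
#' @slot baseIri source namespace (plain IRI string).
#' @slot graphIri named-graph IRI term, unique per logical dataset.
#' @slot typeIri class IRI term for the row resources.
#' @slot recordNs namespace under which row resources are minted.
#' @slot predicateMap named character, role -> predicate IRI term
#'   (injective per record kind).
#' @slot keyRoles roles emitted as key resources.
#' @slot keyBases named character, role -> namespace for its key IRIs
#'   (defaults to baseIri; GO ids share the annot namespace).
#' @slot integerRoles,doubleRoles roles emitted as typed numeric literals.
#' @export
setClass("MappingConfig",
         representation(kind = "character", source = "character",
                        baseIri = "character", graphIri = "character",
                        typeIri = "character", recordNs = "character",
                        predicateMap = "character", keyRoles = "character",
                        keyBases = "character", integerRoles = "character",
                        doubleRoles = "character"))

setValidity("MappingConfig", function(object) {
  if (anyDuplicated(object@predicateMap))
    return("predicateMap must be injective (distinct predicate per role)")
  if (!isIRITerm(object@graphIri)) return("graphIri must be an IRI term")
  TRUE
})

#' Default mapping for a (source, kind, cancer type) dataset
#'
#' Mints the named-graph IRI from the three labels — one graph per logical
#' dataset, mirroring per-cancer-type endpoint hosting. The TCGA sample
#' role is named `hybrid_ref` (hybridization REF barcode); COSMIC's is
#' `sample`.
#'
#' @param kind record kind.
#' @param source source label.
#' @param cancerType cancer-type label (e.g. "OV"), part of the graph IRI.
#' @param base federation base IRI.
#' @return a `MappingConfig`.
#' @export
defaultMapping <- function(kind, source, cancerType = "OV", base = FED_BASE) {
  kind <- match.arg(kind, OMICS_KINDS)
  roles <- kindRoles(kind)$roles
  pname <- stats::setNames(roles, roles)
  if (source == "tcga") pname["sample_id"] <- "hybrid_ref"
  pname[pname == "sample_id"] <- "sample"
  pname[pname == "gene_symbol"] <- "gene"
  pname[pname == "ensembl_id"] <- "ensembl"
  pname[pname == "chrom"] <- "chr"
  pname[pname == "value"] <- "rpkm"
  pmap <- vapply(pname, function(p) vocabIRI(source, p, base), character(1))
  names(pmap) <- roles
  bIri <- sourceBase(source, base)
  kb <- stats::setNames(rep(bIri, length(KEY_ROLES)), KEY_ROLES)
  kb["go_id"] <- sourceBase("annot", base)
  methods::new("MappingConfig",
    kind = kind, source = source, baseIri = bIri,
    graphIri = iriTerm(paste0(base, "graph/", source, "/", kind, "/", cancerType)),
    typeIri = iriTerm(paste0(bIri, "vocab#", toupper(substring(kind, 1, 1)),
                             substring(kind, 2), "Record")),
    recordNs = paste0(bIri, "record/", kind, "/", cancerType, "/"),
    predicateMap = pmap,
    keyRoles = intersect(roles, KEY_ROLES),
    keyBases = kb,
    integerRoles = intersect(roles, c("start", "end")),
    doubleRoles = intersect(roles, c("value", "beta_value", "tumour_purity")))
}

#' @rdname MappingConfig-class
#' @param x a `MappingConfig`.
#' @export
graphIRI <- function(x) x@graphIri

#' Mint the key IRI a shared-key value maps to under a mapping
#'
#' @param mapping a `MappingConfig`.
#' @param role key role (e.g. "gene_symbol").
#' @param value key text.
#' @return IRI term.
#' @export
keyIRI <- function(mapping, role, value) {
  base <- if (role %in% names(mapping@keyBases)) mapping@keyBases[[role]]
          else mapping@baseIri
  mintIRI(base, keyKindOf[[role]], value)
}

setMethod("show", "MappingConfig", function(object) {
  cat(sprintf("MappingConfig<%s/%s> -> %s (%d mapped roles)\n", object@source,
              object@kind, object@graphIri, length(object@predicateMap)))
})

#' Convert records to named-graph quads
#'
#' Deterministic: the same records and mapping always produce the identical
#' quad multiset (row resources are minted from the row index, no
#' timestamps or randomness). Quad count obeys the closed form
#' `sum over records of (1 + number of non-null mapped fields)`.
#'
#' @param x an `OmicsTable` (or plain data.frame of that kind's roles).
#' @param mapping a `MappingConfig` of the same kind.
#' @return a `QuadStore` whose quads all live in `graphIRI(mapping)`.
#' @export
rdfizeTable <- function(x, mapping) {
  df <- if (is(x, "OmicsTable")) {
    stopifnot(omicsKind(x) == mapping@kind)
    omicsData(x)
  } else x
  unmapped <- setdiff(names(df), names(mapping@predicateMap))
  if (length(unmapped))
    stop("mapping error: role(s) present in data but absent from predicate_map: ",
         paste(unmapped, collapse = ", "))
  n <- nrow(df)
  if (n == 0L) return(QuadStore())
  subj <- iriTerm(paste0(mapping@recordNs, "r", seq_len(n)))
  parts <- list(quadDF(subj, iriTerm(RDF_TYPE),
                       rep(mapping@typeIri, n), rep(mapping@graphIri, n)))
  for (role in intersect(names(mapping@predicateMap), names(df))) {
    v <- df[[role]]
    ok <- which(!is.na(v))
    if (!length(ok)) next
    obj <- if (role %in% mapping@keyRoles) {
      vapply(as.character(v[ok]), function(k) keyIRI(mapping, role, k),
             character(1), USE.NAMES = FALSE)
    } else if (role %in% mapping@integerRoles) {
      intLiteral(v[ok])
    } else if (role %in% mapping@doubleRoles) {
      dblLiteral(v[ok])
    } else plainLiteral(v[ok])
    parts[[length(parts) + 1L]] <-
      quadDF(subj[ok], rep(mapping@predicateMap[[role]], length(ok)), obj,
             rep(mapping@graphIri, length(ok)))
  }
  QuadStore(do.call(rbind, parts))
}

#' Build a multi-graph dataset from several tables
#'
#' @param tables list of `list(records = OmicsTable, mapping = MappingConfig)`.
#' @return list with elements `store` (union `QuadStore`) and `stats`
#'   (named list of `DatasetStats`, one per graph IRI).
#' @export
buildDataset <- function(tables) {
  giris <- vapply(tables, function(t) t$mapping@graphIri, character(1))
  if (anyDuplicated(giris))
    stop("configuration error: duplicate graph IRI across tables: ",
         giris[duplicated(giris)][1])
  stores <- lapply(tables, function(t) rdfizeTable(t$records, t$mapping))
  store <- do.call(bindStores, stores)
  stats <- lapply(stores, datasetStats)
  names(stats) <- giris
  list(store = store, stats = stats)
}

#' Recover mapped field values from a graph (inverse mapping)
#'
#' Reads back the records of one graph produced by [rdfizeTable()]:
#' key-resource objects are decoded to their key text, typed literals to
#' numbers. Used to verify losslessness of the conversion.
#'
#' @param store a `QuadStore`.
#' @param mapping the `MappingConfig` used to produce the graph.
#' @return data.frame of recovered records (row order by minted row index).
#' @export
unrdfizeTable <- function(store, mapping) {
  q <- quads(subsetGraph(store, mapping@graphIri))
  q <- q[q$predicate != iriTerm(RDF_TYPE), , drop = FALSE]
  if (!nrow(q)) return(data.frame())
  roleOf <- stats::setNames(names(mapping@predicateMap), mapping@predicateMap)
  idx <- as.integer(sub(".*/r([0-9]+)>$", "\\1", q$subject))
  n <- max(idx)
  out <- list()
  for (role in unique(roleOf[q$predicate])) {
    col <- rep(NA_character_, n)
    sel <- roleOf[q$predicate] == role
    val <- if (role %in% mapping@keyRoles) keyTextFromIRI(q$object[sel])
           else vapply(termValue(q$object[sel]), as.character, character(1))
    col[idx[sel]] <- val
    out[[role]] <- col
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  co <- coerceRoles(mapping@kind, df)
  co$df
}
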