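# Typed in-memory model of the omics tables. Records live in an OmicsTable:
# a validated data.frame of one record kind plus the rows rejected during
# validation (with row numbers and reasons). Coordinates are 1-based
# inclusive throughout (COSMIC convention); chromosome labels are normalized
# once at ingestion (leading "chr" stripped, X/Y/MT uppercased).

OMICS_KINDS <- c("mutation", "cnv", "expression", "methylation", "annotation")

# role layout per record kind; integer/numeric roles drive coercion
kindRoles <- function(kind) {
  switch(kind,
    mutation = list(
      roles = c("sample_id", "gene_symbol", "ensembl_id", "chrom", "start",
                "end", "mutation_type", "pmid"),
      required = c("sample_id", "gene_symbol", "chrom", "start", "end",
                   "mutation_type"),
      integer = c("start", "end")),
    cnv = list(
      roles = c("sample_id", "chrom", "start", "end", "cnv_type"),
      required = c("sample_id", "chrom", "start", "end", "cnv_type"),
      integer = c("start", "end")),
    expression = list(
      roles = c("gene_symbol", "tissue", "value", "regulation"),
      required = c("gene_symbol", "tissue", "value"),
      numeric = "value"),
    methylation = list(
      roles = c("gene_symbol", "sample_id", "composite_element_ref", "chrom",
                "start", "end", "beta_value", "tumour_purity", "pmid"),
      required = c("gene_symbol", "beta_value"),
      integer = c("start", "end"),
      numeric = c("beta_value", "tumour_purity")),
    annotation = list(
      roles = c("gene_symbol", "ensembl_id", "go_id", "go_process",
                "kegg_id", "reactome_id"),
      required = character(0)),
    stop("unknown record kind: ", kind))
}

#' Normalize a chromosome label
#'
#' Strips a leading "chr" prefix and uppercases X/Y/MT, so "chr14", "14"
#' and "Chr14" all compare equal.
#'
#' @param x character vector of chromosome labels.
#' @return normalized labels.
#' @export
normalizeChrom <- function(x) {
  x <- sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
  toupper(x)
}

#' Mutation-type vocabularies
#'
#' `mutationVocabulary` is the declared controlled vocabulary for
#' mutation_type; `nsMutationTypes` is the default non-synonymous subset
#' used by [filterNonsynonymous()] and the mutation-frequency ranking. Both
#' are configurable at every call site.
#'
#' @return character vector of mutation_type labels.
#' @export
mutationVocabulary <- function() {
  c("missense", "nonsense", "silent", "frameshift", "splice-site",
    "GAIN", "LOSS")
}

#' @rdname mutationVocabulary
#' @export
nsMutationTypes <- function() c("missense", "nonsense", "frameshift", "splice-site")

#' OmicsTable: validated records of one omics kind
#'
#' @slot kind one of mutation, cnv, expression, methylation, annotation.
#' @slot data data.frame of accepted records (role-named columns).
#' @slot rejects data.frame with columns row, reason for rejected rows.
#' @export
setClass("OmicsTable",
         representation(kind = "character", data = "data.frame",
                        rejects = "data.frame"))

setValidity("OmicsTable", function(object) {
  if (!object@kind %in% OMICS_KINDS) return("unknown record kind")
  spec <- kindRoles(object@kind)
  if (nrow(object@data) && !all(spec$required %in% names(object@data)))
    return("data is missing required role columns")
  TRUE
})

#' @rdname OmicsTable-class
#' @param x an `OmicsTable`.
#' @export
omicsKind <- function(x) x@kind
#' @rdname OmicsTable-class
#' @export
omicsData <- function(x) x@data
#' @rdname OmicsTable-class
#' @export
rejects <- function(x) x@rejects
#' @rdname OmicsTable-class
#' @export
recordCount <- function(x) nrow(x@data)

setMethod("show", "OmicsTable", function(object) {
  cat(sprintf("OmicsTable<%s>: %d records (%d rejected)\n", object@kind,
              nrow(object@data), nrow(object@rejects)))
})

# per-row validation; returns character reason or NA
rowProblems <- function(kind, df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- msg
  }
  has <- function(role) role %in% names(df)
  blank <- function(v) is.na(v) | !nzchar(trimws(as.character(v)))
  spec <- kindRoles(kind)
  for (role in intersect(spec$required, names(df)))
    flag(blank(df[[role]]), paste0("missing ", role))
  if (has("start")) flag(!is.na(df$start) & df$start < 1, "start < 1")
  if (has("start") && has("end"))
    flag(!is.na(df$start) & !is.na(df$end) & df$end < df$start, "end < start")
  if (kind == "mutation")
    flag(!df$mutation_type %in% mutationVocabulary(),
         "mutation_type outside declared vocabulary")
  if (kind == "cnv")
    flag(!df$cnv_type %in% c("GAIN", "LOSS"), "cnv_type not GAIN/LOSS")
  if (kind == "expression")
    flag(!is.na(df$value) & df$value < 0, "negative expression value")
  if (kind == "methylation") {
    flag(!is.na(df$beta_value) & abs(df$beta_value) > 1,
         "|beta_value| > 1")
    if (has("composite_element_ref"))
      flag(!blank(df$composite_element_ref) &
             !grepl("^cg[0-9]+$", df$composite_element_ref),
           "composite_element_ref does not match cg-pattern")
    if (has("tumour_purity"))
      flag(!is.na(df$tumour_purity) & df$tumour_purity < 0,
           "negative tumour_purity")
  }
  if (kind == "annotation") {
    idcols <- intersect(c("gene_symbol", "ensembl_id", "go_id", "kegg_id",
                          "reactome_id"), names(df))
    allMissing <- Reduce(`&`, lapply(idcols, function(cl) blank(df[[cl]])),
                         rep(TRUE, n))
    flag(allMissing, "no identifier field set")
  }
  reason
}

coerceRoles <- function(kind, df) {
  spec <- kindRoles(kind)
  bad <- rep(NA_character_, nrow(df))
  for (role in intersect(spec$integer, names(df))) {
    v <- suppressWarnings(as.integer(df[[role]]))
    miss <- !is.na(df[[role]]) & nzchar(trimws(df[[role]])) & is.na(v)
    bad[miss & is.na(bad)] <- paste0("unparseable coordinate in ", role)
    df[[role]] <- v
  }
  for (role in intersect(spec$numeric, names(df))) {
    v <- suppressWarnings(as.numeric(df[[role]]))
    miss <- !is.na(df[[role]]) & nzchar(trimws(df[[role]])) & is.na(v)
    bad[miss & is.na(bad)] <- paste0("unparseable number in ", role)
    df[[role]] <- v
  }
  if ("chrom" %in% names(df)) df$chrom <- normalizeChrom(df$chrom)
  list(df = df, bad = bad)
}

#' Build an OmicsTable from an in-memory data.frame
#'
#' Validates record invariants (coordinate ordering, beta range, controlled
#' vocabularies, cg-pattern) and splits the input into accepted records and
#' rejects carrying row provenance.
#'
#' @param kind record kind.
#' @param df data.frame with role-named columns.
#' @param strict error on the first invalid row instead of rejecting it.
#' @return an `OmicsTable`.
#' @export
asOmicsTable <- function(kind, df, strict = FALSE) {
  kind <- match.arg(kind, OMICS_KINDS)
  rn <- seq_len(nrow(df))
  for (cl in names(df)) if (is.character(df[[cl]])) {
    df[[cl]][!is.na(df[[cl]]) & !nzchar(trimws(df[[cl]]))] <- NA_character_
  }
  co <- coerceRoles(kind, df)
  reason <- co$bad
  chk <- rowProblems(kind, co$df)
  reason[is.na(reason)] <- chk[is.na(reason)]
  badIdx <- which(!is.na(reason))
  if (strict && length(badIdx))
    stop(sprintf("row %d: %s", rn[badIdx[1]], reason[badIdx[1]]))
  rej <- data.frame(row = rn[badIdx], reason = reason[badIdx],
                    stringsAsFactors = FALSE)
  ok <- co$df[setdiff(rn, badIdx), , drop = FALSE]
  rownames(ok) <- NULL
  methods::new("OmicsTable", kind = kind, data = ok, rejects = rej)
}

#' Default table schema for a record kind
#'
#' A schema maps semantic roles to column names of a TSV file. Defaults use
#' the role names themselves; pass `columns` overrides for source-specific
#' headers (e.g. `c(sample_id = "Sample name")`).
#'
#' @param kind record kind.
#' @param columns named character vector role -> column name (overrides).
#' @return a schema list with elements kind and columns.
#' @export
tableSchema <- function(kind, columns = character(0)) {
  kind <- match.arg(kind, OMICS_KINDS)
  roles <- kindRoles(kind)$roles
  cols <- stats::setNames(roles, roles)
  cols[names(columns)] <- columns
  list(kind = kind, columns = cols)
}

#' Read an omics TSV table
#'
#' Reads a tab-separated table with a header row, maps columns to semantic
#' roles via the schema, coerces and validates each row. Rows failing
#' validation are reported in `rejects(x)` with their (1-based, data) row
#' number and reason, not silently dropped.
#'
#' @param path TSV file path.
#' @param schema a schema from [tableSchema()], or a kind name.
#' @param strict error on first invalid row (default: reject and report).
#' @return an `OmicsTable`.
#' @export
readOmicsTable <- function(path, schema, strict = FALSE) {
  if (is.character(schema)) schema <- tableSchema(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  spec <- kindRoles(schema$kind)
  req <- schema$columns[spec$required]
  missing <- req[!req %in% names(raw)]
  if (length(missing))
    stop("schema error: required column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  present <- schema$columns[schema$columns %in% names(raw)]
  df <- stats::setNames(raw[unname(present)], names(present))
  asOmicsTable(schema$kind, df, strict = strict)
}

#' Keep only non-synonymous mutation records
#'
#' Filters a mutation `OmicsTable` to records whose mutation_type is in the
#' non-synonymous vocabulary. Records whose type is outside the declared
#' vocabulary are excluded and reported in `rejects()` of the result.
#'
#' @param x mutation `OmicsTable`.
#' @param ns non-synonymous vocabulary (non-empty character vector).
#' @param known full declared mutation_type vocabulary.
#' @return filtered `OmicsTable`; unknown-type rows appear in its rejects.
#' @export
filterNonsynonymous <- function(x, ns = nsMutationTypes(),
                                known = mutationVocabulary()) {
  stopifnot(is(x, "OmicsTable"), omicsKind(x) == "mutation", length(ns) > 0)
  df <- omicsData(x)
  unknown <- which(!df$mutation_type %in% known)
  keep <- which(df$mutation_type %in% ns)
  rej <- data.frame(row = unknown,
                    reason = rep("unknown mutation_type", length(unknown)),
                    stringsAsFactors = FALSE)
  out <- df[setdiff(keep, unknown), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("OmicsTable", kind = "mutation", data = out, rejects = rej)
}
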