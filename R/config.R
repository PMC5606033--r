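# YAML configuration surface: a federation registry (endpoint ids and
# N-Quads files, plus an optional links file), link-rule configs, and
# table-schema configs mapping column headers to semantic roles.

#' Read a federation registry config
#'
#' YAML layout:
#' \preformatted{
#' endpoints:
#'   - id: cosmic
#'     files: [cosmic.nq]
#' links: links.nq
#' }
#' File paths are resolved relative to the config file.
#'
#' @param path YAML file path.
#' @return a `Federation`.
#' @export
readFederationConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(dir, f)
  eps <- lapply(cfg$endpoints, function(e) {
    stores <- lapply(e$files, function(f) readNQuads(resolve(f)))
    do.call(bindStores, stores)
  })
  names(eps) <- vapply(cfg$endpoints, `[[`, character(1), "id")
  links <- if (!is.null(cfg$links)) readNQuads(resolve(cfg$links))
           else QuadStore()
  Federation(eps, links = links)
}

#' Write a federation to a directory with a registry config
#'
#' One N-Quads file per endpoint plus `links.nq` and `federation.yaml`,
#' readable back with [readFederationConfig()].
#'
#' @param fed a `Federation`.
#' @param dir output directory (created if needed).
#' @return the config path, invisibly.
#' @export
writeFederationDir <- function(fed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eps <- lapply(endpointIds(fed), function(id) {
    f <- paste0(id, ".nq")
    writeNQuads(endpointStore(fed, id), file.path(dir, f))
    list(id = id, files = list(f))
  })
  writeNQuads(linksStore(fed), file.path(dir, "links.nq"))
  cfg <- list(endpoints = eps, links = "links.nq")
  path <- file.path(dir, "federation.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read link rules from a YAML config
#'
#' Each entry needs `kind` (exact_key or positional), `id`, `left`/`right`
#' (graph plus key predicate(s)) and, for exact rules, an optional
#' `normalizer`; positional rules take `mode` and `tolerance_bp`.
#'
#' @param path YAML file path.
#' @return named list of `LinkRule`s.
#' @export
readLinkRulesConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- lapply(cfg$rules, function(r) {
    if (r$kind == "exact_key") {
      exactKeyRule(iriTerm(r$left$graph), iriTerm(r$left$predicate),
                   iriTerm(r$right$graph), iriTerm(r$right$predicate),
                   normalizer = if (is.null(r$normalizer)) "verbatim"
                                else r$normalizer,
                   id = r$id)
    } else {
      preds <- function(side) c(chrom = iriTerm(side$chrom),
                                start = iriTerm(side$start),
                                end = iriTerm(side$end))
      positionalRule(iriTerm(r$left$graph), preds(r$left),
                     iriTerm(r$right$graph), preds(r$right),
                     mode = if (is.null(r$mode)) "exact" else r$mode,
                     toleranceBp = if (is.null(r$tolerance_bp)) 0L
                                   else r$tolerance_bp,
                     id = r$id)
    }
  })
  names(rules) <- vapply(cfg$rules, `[[`, character(1), "id")
  rules
}

#' Read a table schema from a YAML config
#'
#' Layout: `kind` plus a `columns` mapping of role to column header.
#'
#' @param path YAML file path.
#' @return a schema list usable with [readOmicsTable()].
#' @export
readSchemaConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  tableSchema(cfg$kind, columns = unlist(cfg$columns))
}
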