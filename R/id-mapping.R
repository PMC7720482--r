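# Identifier translation between namespaces from user-supplied lookup
# tables (TSV with a header of namespace names, e.g. ENTREZID, SYMBOL,
# UNIPROT, ENSEMBL, REFSEQ for genes/proteins; HMDB, CHEBI, KEGGCOMP, CID,
# SID, CAS, DTXSID, DTXCID for metabolites). Matching is case-sensitive
# exact string comparison; no prefix normalisation is attempted, so e.g.
# "HMDB00001" and "HMDB0000001" are distinct identifiers.

#' Load an identifier mapping table from TSV
#'
#' The first line is a header of namespace names; every following line is a
#' record of co-identifiers, any cell possibly empty. Empty cells become
#' `NA`; values are stored verbatim (case-sensitive).
#'
#' @param path path to a tab-separated file.
#' @return a `data.frame` with one column per namespace.
#' @export
load_mapping <- function(path) {
  if (!file.exists(path)) abort("mapping file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2L) abort("mapping table needs a header and >= 1 data row")
  split_row <- function(line) {
    # field count is tabs + 1 (strsplit drops trailing empty fields)
    m <- gregexpr("\t", line, fixed = TRUE)[[1L]]
    n <- if (m[1L] == -1L) 1L else length(m) + 1L
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    c(fields, rep("", n - length(fields)))
  }
  header <- split_row(lines[1L])
  if (length(header) < 2L) abort("mapping table needs at least 2 namespace columns")
  if (anyDuplicated(header)) {
    abort("duplicate namespace in header: ", header[duplicated(header)][1L])
  }
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    fields <- split_row(lines[i + 1L])
    if (length(fields) != length(header)) {
      abort("ragged mapping row at line ", i + 1L, ": expected ",
            length(header), " fields, found ", length(fields))
    }
    rows[[i]] <- fields
  }
  mat <- do.call(rbind, rows)
  mat[mat == ""] <- NA_character_
  if (any(rowSums(!is.na(mat)) == 0L)) {
    abort("mapping table contains an entirely empty row")
  }
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(tab) <- header
  rownames(tab) <- NULL
  tab
}

#' Translate identifiers between two namespaces
#'
#' Each input identifier maps to the set of distinct non-missing `target`
#' values found in rows where the `source` column equals it exactly. The
#' one-to-many `policy` resolves multiplicity:
#' \describe{
#'   \item{all}{keep every target identifier (default; conservative for
#'     set-based enrichment).}
#'   \item{first-sorted}{keep the lexicographically smallest target.}
#'   \item{drop-ambiguous}{drop inputs with more than one target, recording
#'     them and emitting a warning.}
#' }
#' Inputs with no target value are reported as unmapped, never silently
#' dropped.
#'
#' @param ids character vector of identifiers in the `source` namespace.
#' @param table mapping `data.frame` from [load_mapping()].
#' @param source,target distinct namespace (column) names.
#' @param policy one of `"all"`, `"first-sorted"`, `"drop-ambiguous"`.
#' @return a list with `map` (named list: input id -> character vector of
#'   translations), `unmapped` and `dropped` (character vectors). Every
#'   input id lands in exactly one of the three.
#' @export
translate <- function(ids, table, source, target,
                      policy = c("all", "first-sorted", "drop-ambiguous")) {
  policy <- match.arg(policy)
  if (!is.data.frame(table)) abort("mapping table must be a data.frame")
  if (identical(source, target)) abort("source and target namespaces must differ")
  for (ns in c(source, target)) {
    if (!ns %in% names(table)) abort("unknown namespace: ", ns)
  }
  ids <- as.character(ids)
  src <- table[[source]]
  tgt <- table[[target]]
  map <- list()
  unmapped <- character(0)
  dropped <- character(0)
  for (id in unique(ids)) {
    hits <- !is.na(src) & src == id
    values <- unique(tgt[hits])
    values <- values[!is.na(values)]
    if (length(values) == 0L) {
      unmapped <- c(unmapped, id)
    } else if (policy == "drop-ambiguous" && length(values) > 1L) {
      dropped <- c(dropped, id)
    } else {
      if (policy == "first-sorted") values <- sort_c(values)[1L]
      map[[id]] <- values
    }
  }
  if (length(dropped) > 0L) {
    warn(length(dropped), " identifier(s) dropped as ambiguous (", source,
         " -> ", target, "): ", paste(utils::head(dropped, 5L), collapse = ", "))
  }
  list(map = map, unmapped = unmapped, dropped = dropped)
}

#' Translate every feature set of one layer in a pathway collection
#'
#' Applies [translate()] per pathway; resulting sets are deduplicated.
#' Per-pathway mapping-loss statistics (input set size vs. number of inputs
#' that mapped) are recorded in `collection$mapping_stats[[layer]]`.
#'
#' @inheritParams translate
#' @param collection an `mo_pathways` object.
#' @param layer layer whose feature sets to translate.
#' @return the collection with the layer's sets translated.
#' @export
map_collection <- function(collection, layer, table, source, target,
                           policy = "all") {
  stopifnot(inherits(collection, "mo_pathways"))
  if (!layer %in% collection$layers) abort("unknown layer: ", layer)
  stats_rows <- vector("list", length(collection$pathways))
  for (i in seq_along(collection$pathways)) {
    nm <- names(collection$pathways)[i]
    feats <- pathway_features(collection, nm, layer)
    tr <- suppressWarnings(translate(feats, table, source, target, policy))
    mapped <- unique(unlist(tr$map, use.names = FALSE))
    if (is.null(mapped)) mapped <- character(0)
    collection$pathways[[nm]]$features[[layer]] <- mapped
    stats_rows[[i]] <- data.frame(
      pathway = nm,
      input_size = length(feats),
      mapped_inputs = length(tr$map),
      mapped_size = length(mapped),
      unmapped = length(tr$unmapped),
      dropped = length(tr$dropped),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(collection$mapping_stats)) collection$mapping_stats <- list()
  collection$mapping_stats[[layer]] <- do.call(rbind, stats_rows)
  collection
}
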