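# Multi-layer pathway collections and GMT input/output.
#
# A collection holds named pathways, each with one feature *set* per omics
# layer (transcriptome / proteome / metabolome or any user-chosen layer
# names). GMT files (Broad dialect: name TAB description TAB members...)
# carry one layer each; collections for several layers are merged by exact
# pathway name.

#' Construct a multi-omics pathway collection
#'
#' @param layers character vector of distinct layer names.
#' @param pathways named list; each element is a list with fields `source`
#'   (character scalar, free-form database label) and `features` (named list
#'   mapping a layer name to a character vector of feature identifiers,
#'   duplicate-free).
#' @return an object of class `mo_pathways`.
#' @export
pathway_collection <- function(layers, pathways = list()) {
  layers <- as.character(layers)
  if (anyDuplicated(layers)) abort("layer names must be distinct")
  nm <- names(pathways)
  if (length(pathways) > 0L && (is.null(nm) || any(!nzchar(nm)))) {
    abort("every pathway must have a non-empty name")
  }
  if (anyDuplicated(nm)) {
    abort("duplicate pathway name: ", nm[duplicated(nm)][1L])
  }
  pathways <- lapply(pathways, function(pw) {
    feats <- pw$features
    extra <- setdiff(names(feats), layers)
    if (length(extra) > 0L) {
      abort("pathway features refer to unknown layer: ", extra[1L])
    }
    list(
      source = if (is.null(pw$source)) "" else as.character(pw$source)[1L],
      features = lapply(feats, function(x) unique(as.character(x)))
    )
  })
  structure(
    list(layers = layers, pathways = pathways, untestable = list()),
    class = "mo_pathways"
  )
}

#' @export
print.mo_pathways <- function(x, ...) {
  cat(
    "Multi-omics pathway collection:", length(x$pathways), "pathways,",
    "layers:", paste(x$layers, collapse = ", "), "\n"
  )
  invisible(x)
}

#' Feature set of one pathway in one layer
#'
#' @param collection an `mo_pathways` object.
#' @param pathway pathway name.
#' @param layer layer name.
#' @return character vector (possibly empty).
#' @export
pathway_features <- function(collection, pathway, layer) {
  stopifnot(inherits(collection, "mo_pathways"))
  if (!layer %in% collection$layers) abort("unknown layer: ", layer)
  pw <- collection$pathways[[pathway]]
  if (is.null(pw)) abort("unknown pathway: ", pathway)
  feats <- pw$features[[layer]]
  if (is.null(feats)) character(0) else feats
}

#' Read one layer of pathway definitions from a GMT file
#'
#' Each non-empty line must have at least three tab-separated fields:
#' pathway name, description (stored as `source`, never interpreted) and one
#' or more member identifiers. Duplicate members within a line are collapsed
#' to a set; member order is not preserved.
#'
#' @param path path to a GMT file (UTF-8, no header line).
#' @param layer layer name the file describes.
#' @return an `mo_pathways` collection with this single layer populated.
#' @export
read_gmt <- function(path, layer) {
  if (!file.exists(path)) abort("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(lines)
  pathways <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort("malformed GMT line ", i, " in ", path,
            ": expected >= 3 tab-separated fields, found ", length(fields))
    }
    name <- fields[1L]
    if (!is.null(pathways[[name]])) {
      abort("duplicate pathway name '", name, "' at line ", i, " in ", path)
    }
    members <- unique(fields[-c(1L, 2L)])
    members <- members[nzchar(members)]
    pathways[[name]] <- list(
      source = fields[2L],
      features = stats::setNames(list(members), layer)
    )
  }
  pathway_collection(layer, pathways)
}

#' Merge single-layer collections into one multi-layer collection
#'
#' Pathways are matched across layers by exact name. A pathway absent from
#' one layer's input receives an empty feature set for that layer; the union
#' of all pathway names is retained, ordered by first appearance.
#'
#' @param collections list of `mo_pathways` objects covering distinct layers.
#' @return a merged `mo_pathways` collection.
#' @export
merge_layers <- function(collections) {
  if (length(collections) == 0L) abort("no collections to merge")
  stopifnot(all(vapply(collections, inherits, logical(1), "mo_pathways")))
  layers <- unlist(lapply(collections, `[[`, "layers"))
  if (anyDuplicated(layers)) {
    abort("duplicate layer across inputs: ", layers[duplicated(layers)][1L])
  }
  merged <- list()
  for (coll in collections) {
    for (name in names(coll$pathways)) {
      pw <- coll$pathways[[name]]
      if (is.null(merged[[name]])) {
        merged[[name]] <- list(source = pw$source, features = pw$features)
      } else {
        merged[[name]]$features <- c(merged[[name]]$features, pw$features)
        if (!nzchar(merged[[name]]$source)) merged[[name]]$source <- pw$source
      }
    }
  }
  merged <- lapply(merged, function(pw) {
    missing_layers <- setdiff(layers, names(pw$features))
    pw$features[missing_layers] <- list(character(0))
    pw$features <- pw$features[layers]
    pw
  })
  pathway_collection(layers, merged)
}

#' Flag pathways untestable in a layer by measured-feature overlap
#'
#' For GSEA in a given layer only the overlap between a pathway's feature
#' set and the *measured* features matters. Pathways whose overlap falls
#' outside `[min_size, max_size]` are flagged as untestable in that layer;
#' they stay in the collection and appear in results with missing
#' statistics.
#'
#' @param collection an `mo_pathways` object.
#' @param layer layer to gate.
#' @param measured character vector of measured feature identifiers.
#' @param min_size,max_size inclusive overlap bounds
#'   (defaults 5 and 500, standard GSEA practice).
#' @return the collection with `untestable[[layer]]` set to the flagged
#'   pathway names.
#' @export
filter_pathways <- function(collection, layer, measured,
                            min_size = 5L, max_size = 500L) {
  stopifnot(inherits(collection, "mo_pathways"))
  if (!layer %in% collection$layers) abort("unknown layer: ", layer)
  if (min_size < 1L) abort("min_size must be >= 1")
  if (min_size > max_size) abort("min_size must not exceed max_size")
  measured <- unique(as.character(measured))
  ov <- vapply(
    names(collection$pathways),
    function(nm) sum(pathway_features(collection, nm, layer) %in% measured),
    integer(1)
  )
  flagged <- names(ov)[ov < min_size | ov > max_size]
  collection$untestable[[layer]] <- flagged
  collection
}

#' Write one layer of a collection to a GMT file
#'
#' Members are written lexicographically sorted (C locale) so output is
#' byte-stable; pathways with an empty feature set in the layer are
#' omitted. Round-tripping through [read_gmt()] reproduces the feature sets
#' exactly.
#'
#' @param collection an `mo_pathways` object.
#' @param layer layer whose feature sets to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, layer, path) {
  stopifnot(inherits(collection, "mo_pathways"))
  if (!layer %in% collection$layers) abort("unknown layer: ", layer)
  lines <- character(0)
  for (nm in names(collection$pathways)) {
    feats <- pathway_features(collection, nm, layer)
    if (length(feats) == 0L) next
    src <- collection$pathways[[nm]]$source
    if (!nzchar(src)) src <- "na"
    lines <- c(lines, paste(c(nm, src, sort_c(feats)), collapse = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
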