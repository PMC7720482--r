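# End-to-end orchestration: load & map pathway definitions, rank each
# layer, run per-layer enrichment, combine across layers, write the result
# table and a run manifest. Every run is reproducible from its manifest
# alone (resolved configuration + seed).

#' Build a run configuration
#'
#' @param layers named list, layer name -> list with `table` (path to the
#'   differential-statistics TSV), `gmt` (path to the layer's GMT file) and
#'   optional `mapping` = list(table=, from=, to=, policy=).
#' @param rank_metric ranking metric (see [rank_features()]).
#' @param n_perm,exponent,min_size,max_size,share_null GSEA parameters
#'   (see [run_layer()]).
#' @param seed integer seed; always recorded in the manifest.
#' @param combine_method,weights,missing_policy,adjust_combined
#'   combination parameters (see [combine_table()]).
#' @param out_dir output directory for `results.tsv` and
#'   `run_manifest.yaml`; `NULL` skips file output.
#' @return a `run_config` list.
#' @export
run_config <- function(layers, rank_metric = "signed_log_p",
                       n_perm = 1000L, exponent = 1, min_size = 5L,
                       max_size = 500L, share_null = FALSE, seed = 1L,
                       combine_method = "stouffer", weights = NULL,
                       missing_policy = "available-layers",
                       adjust_combined = TRUE, out_dir = NULL) {
  if (length(layers) < 1L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    abort("at least one named layer must be configured")
  }
  structure(
    list(layers = layers, rank_metric = rank_metric, n_perm = as.integer(n_perm),
         exponent = exponent, min_size = as.integer(min_size),
         max_size = as.integer(max_size), share_null = isTRUE(share_null),
         seed = as.integer(seed), combine_method = combine_method,
         weights = weights, missing_policy = missing_policy,
         adjust_combined = isTRUE(adjust_combined), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments; unspecified fields take the
#' same defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$layers)) abort("config must define layers")
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  if (!is.null(args$weights)) args$weights <- unlist(args$weights)
  do.call(run_config, args)
}

#' Run the full multi-omics enrichment pipeline
#'
#' Executes load & map -> per-layer ranking and GSEA -> cross-layer
#' combination. Per-layer permutation streams are derived from the run
#' seed and the layer name, so the run is fully deterministic and layers
#' do not share randomness. When `out_dir` is set, writes `results.tsv`
#' (one row per pathway in the union of the layer GMTs) and
#' `run_manifest.yaml` (resolved configuration, package version, feature
#' and pathway counts, mapping losses, untestable and clamping tallies).
#' Nothing is written if any step fails.
#'
#' @param config a `run_config` (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return the combined result `data.frame`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  layers <- names(config$layers)

  collections <- lapply(layers, function(ly) {
    read_gmt(config$layers[[ly]]$gmt, ly)
  })
  collection <- merge_layers(collections)

  mapping_loss <- list()
  for (ly in layers) {
    mp <- config$layers[[ly]]$mapping
    if (is.null(mp)) next
    table <- load_mapping(mp$table)
    policy <- if (is.null(mp$policy)) "all" else mp$policy
    collection <- map_collection(collection, ly, table, mp$from, mp$to, policy)
    st <- collection$mapping_stats[[ly]]
    mapping_loss[[ly]] <- list(
      inputs = sum(st$input_size), mapped = sum(st$mapped_inputs),
      unmapped = sum(st$unmapped), dropped = sum(st$dropped)
    )
  }

  layer_results <- list()
  n_features <- list()
  for (ly in layers) {
    tab <- read_omics_table(config$layers[[ly]]$table, ly)
    n_features[[ly]] <- nrow(tab)
    ranked <- rank_features(tab, config$rank_metric)
    layer_results[[ly]] <- run_layer(
      ranked, collection, ly,
      n_perm = config$n_perm, exponent = config$exponent,
      seed = derive_seed(config$seed, paste0("gsea.", ly)),
      min_size = config$min_size, max_size = config$max_size,
      share_null = config$share_null
    )
  }

  # clamping is tallied in the manifest, so the warning is muffled here
  result <- withCallingHandlers(
    combine_table(
      layer_results, method = config$combine_method,
      weights = config$weights, missing_policy = config$missing_policy,
      adjust_combined = config$adjust_combined
    ),
    warning = function(w) {
      if (grepl("clamped", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  n_clamped <- attr(result, "n_clamped")
  if (is.null(n_clamped)) n_clamped <- 0L

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(result, file.path(config$out_dir, "results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    manifest <- list(
      package_version = as.character(utils::packageVersion("mogsea")),
      seed = config$seed,
      rank_metric = config$rank_metric,
      gsea = list(n_perm = config$n_perm, exponent = config$exponent,
                  min_size = config$min_size, max_size = config$max_size,
                  share_null = config$share_null),
      combine = list(method = config$combine_method,
                     weights = as.list(config$weights),
                     missing_policy = config$missing_policy,
                     adjust_combined = config$adjust_combined),
      layers = lapply(stats::setNames(layers, layers), function(ly) {
        list(
          table = config$layers[[ly]]$table,
          gmt = config$layers[[ly]]$gmt,
          n_features = n_features[[ly]],
          n_untestable = sum(layer_results[[ly]]$status == "untestable")
        )
      }),
      n_pathways = length(collection$pathways),
      mapping_loss = mapping_loss,
      n_clamped_pvalues = n_clamped
    )
    yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))
  }
  invisible(result)
}
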