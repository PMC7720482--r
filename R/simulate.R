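# Self-contained synthetic multi-omics study generator. Emulates the
# summary-statistic interface the enrichment pipeline consumes: per-layer
# differential tables with uniform null p-values, pathway definitions, and
# an identifier mapping table. Planted pathways receive p-values drawn from
# the power-of-uniform alternative p = U^(1 + shift), a family that is
# exactly uniform at shift = 0 (continuity with the null) and concentrates
# towards 0 as the shift grows, with positively signed fold changes.
# Features are drawn independently: realistic within-pathway correlation is
# deliberately absent, since the downstream combiners themselves assume
# independent layers.

#' Configuration for a synthetic multi-omics study
#'
#' Defaults describe the reference study used throughout the package's
#' calibration and recovery analyses: three layers of 2000 features, 50
#' pathways with per-layer sizes uniform in \[15, 60\], and one pathway
#' planted in all three layers at shift 4.
#'
#' @param n_features_per_layer named integer vector, layer -> feature
#'   count.
#' @param n_pathways number of pathways.
#' @param pathway_size_range inclusive bounds on per-layer pathway size.
#' @param planted_pathways list of `list(name=, layers=, effect_shift=)`
#'   entries; names must be among the generated pathway names (`PW01`,
#'   `PW02`, ... zero-padded).
#' @param de_fraction_background fraction of non-planted features drawn
#'   from the alternative (random sign), in \[0, 1).
#' @param background_shift power-of-uniform shift for background
#'   differential features.
#' @param seed integer; the sole source of randomness. Per-layer draws use
#'   seed streams derived from it, so adding a layer leaves the other
#'   layers' tables unchanged.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_features_per_layer = c(transcriptome = 2000L,
                                                       proteome = 2000L,
                                                       metabolome = 2000L),
                              n_pathways = 50L,
                              pathway_size_range = c(15L, 60L),
                              planted_pathways = list(
                                list(name = "PW01",
                                     layers = c("transcriptome", "proteome",
                                                "metabolome"),
                                     effect_shift = 4)
                              ),
                              de_fraction_background = 0,
                              background_shift = 2,
                              seed = 1L) {
  layers <- names(n_features_per_layer)
  if (is.null(layers) || any(!nzchar(layers))) {
    abort("n_features_per_layer must be named by layer")
  }
  if (n_pathways < 1L) abort("n_pathways must be >= 1")
  if (pathway_size_range[1L] < 1L ||
      pathway_size_range[1L] > pathway_size_range[2L]) {
    abort("invalid pathway_size_range")
  }
  if (any(pathway_size_range[2L] > n_features_per_layer)) {
    abort("pathway size range exceeds the feature count of a layer")
  }
  if (de_fraction_background < 0 || de_fraction_background >= 1) {
    abort("de_fraction_background must lie in [0, 1)")
  }
  pw_names <- sprintf("PW%02d", seq_len(n_pathways))
  for (pl in planted_pathways) {
    if (!pl$name %in% pw_names) {
      abort("planted pathway name not among generated names: ", pl$name)
    }
    if (!all(pl$layers %in% layers)) abort("planted pathway names an unknown layer")
    if (!is.finite(pl$effect_shift) || pl$effect_shift <= 0) {
      abort("effect_shift must be finite and > 0")
    }
  }
  structure(
    list(
      layers = layers,
      n_features_per_layer = n_features_per_layer,
      n_pathways = as.integer(n_pathways),
      pathway_names = pw_names,
      pathway_size_range = as.integer(pathway_size_range),
      planted_pathways = planted_pathways,
      de_fraction_background = de_fraction_background,
      background_shift = background_shift,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# p from the alternative: U^(1 + shift), concentrated towards 0.
r_alternative_p <- function(n, shift) runif(n)^(1 + shift)

#' Generate a synthetic multi-omics study
#'
#' Produces one differential-statistics table per layer, a matching
#' pathway collection, and a bijective two-namespace identifier mapping
#' table, all deterministic under the configuration seed. Null features
#' get `p ~ Uniform(0, 1)` and `logFC ~ N(0, 1)`; planted pathway members
#' in affected layers get `p = U^(1 + effect_shift)` and a positive fold
#' change `|N(1, 0.5)|`.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return a list of class `mo_study` with elements `tables` (named list
#'   of per-layer data.frames with `feature_id`, `log_fold_change`,
#'   `p_value`), `collection` (an `mo_pathways`), `mapping` (a 2-column
#'   data.frame, namespaces `FEATURE` and `ALIAS`) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layers <- config$layers
  feature_ids <- lapply(layers, function(ly) {
    prefix <- toupper(substr(ly, 1L, 2L))
    sprintf("%s_%05d", prefix, seq_len(config$n_features_per_layer[[ly]]))
  })
  names(feature_ids) <- layers

  # pathway membership: per-layer seed stream
  membership <- list()
  for (ly in layers) {
    membership[[ly]] <- local_seed(
      derive_seed(config$seed, paste0("members.", ly)), {
        sizes <- sample(
          seq(config$pathway_size_range[1L], config$pathway_size_range[2L]),
          config$n_pathways, replace = TRUE
        )
        lapply(seq_len(config$n_pathways), function(i) {
          sample(feature_ids[[ly]], sizes[i])
        })
      }
    )
  }
  pathways <- stats::setNames(
    lapply(seq_len(config$n_pathways), function(i) {
      list(
        source = "synthetic",
        features = stats::setNames(
          lapply(layers, function(ly) membership[[ly]][[i]]), layers
        )
      )
    }),
    config$pathway_names
  )
  collection <- pathway_collection(layers, pathways)

  # differential statistics: per-layer seed stream; nulls first, then
  # background DE, then planted overrides in pathway-name order
  tables <- list()
  for (ly in layers) {
    n <- config$n_features_per_layer[[ly]]
    tables[[ly]] <- local_seed(derive_seed(config$seed, paste0("stats.", ly)), {
      p <- runif(n)
      lfc <- rnorm(n)
      if (config$de_fraction_background > 0) {
        bg <- which(runif(n) < config$de_fraction_background)
        if (length(bg) > 0L) {
          p[bg] <- r_alternative_p(length(bg), config$background_shift)
          lfc[bg] <- sample(c(-1, 1), length(bg), replace = TRUE) *
            abs(rnorm(length(bg), mean = 1, sd = 0.5))
        }
      }
      planted <- Filter(function(pl) ly %in% pl$layers, config$planted_pathways)
      planted <- planted[order_c(vapply(planted, `[[`, "", "name"))]
      for (pl in planted) {
        idx <- match(membership[[ly]][[match(pl$name, config$pathway_names)]],
                     feature_ids[[ly]])
        p[idx] <- r_alternative_p(length(idx), pl$effect_shift)
        lfc[idx] <- abs(rnorm(length(idx), mean = 1, sd = 0.5))
      }
      data.frame(
        feature_id = feature_ids[[ly]],
        log_fold_change = lfc,
        p_value = pmax(p, .Machine$double.xmin),
        stringsAsFactors = FALSE
      )
    })
    attr(tables[[ly]], "layer") <- ly
  }

  all_ids <- unlist(feature_ids, use.names = FALSE)
  mapping <- data.frame(
    FEATURE = all_ids,
    ALIAS = paste0("x", all_ids),
    stringsAsFactors = FALSE
  )
  structure(
    list(tables = tables, collection = collection, mapping = mapping,
         config = config),
    class = "mo_study"
  )
}

#' Write a synthetic study to disk
#'
#' Emits one TSV differential table and one GMT file per layer, the mapping
#' TSV, and a YAML manifest echoing the configuration. File contents are
#' byte-identical across runs with the same configuration.
#'
#' @param study an `mo_study` from [simulate_study()].
#' @param dir output directory (created if absent).
#' @return named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mo_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ly in study$config$layers) {
    tab <- study$tables[[ly]]
    out <- data.frame(
      feature_id = tab$feature_id,
      logFC = tab$log_fold_change,
      pvalue = tab$p_value,
      stringsAsFactors = FALSE
    )
    paths[[paste0(ly, "_table")]] <- file.path(dir, paste0(ly, ".tsv"))
    write.table(out, paths[[paste0(ly, "_table")]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths[[paste0(ly, "_gmt")]] <- file.path(dir, paste0(ly, ".gmt"))
    write_gmt(study$collection, ly, paths[[paste0(ly, "_gmt")]])
  }
  paths$mapping <- file.path(dir, "mapping.tsv")
  write.table(study$mapping, paths$mapping, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$manifest <- file.path(dir, "manifest.yaml")
  cfg <- study$config
  manifest <- list(
    layers = as.list(stats::setNames(
      as.integer(cfg$n_features_per_layer), cfg$layers
    )),
    n_pathways = cfg$n_pathways,
    pathway_size_range = as.integer(cfg$pathway_size_range),
    planted_pathways = lapply(cfg$planted_pathways, function(pl) {
      list(name = pl$name, layers = as.list(pl$layers),
           effect_shift = pl$effect_shift)
    }),
    de_fraction_background = cfg$de_fraction_background,
    background_shift = cfg$background_shift,
    seed = cfg$seed
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
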