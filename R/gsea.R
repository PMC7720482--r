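# Per-layer gene set enrichment: weighted Kolmogorov-Smirnov running-sum
# statistic (Subramanian et al. 2005), feature-set permutation null,
# normalized enrichment score, permutation p-value with the add-one
# estimator, and Benjamini-Hochberg adjustment within the layer.
#
# The null is built by sampling random feature sets of the observed overlap
# size, not by sample permutation: the method sees only summary statistics
# per feature, so phenotype permutation is impossible. Null pools may be
# shared between pathways of equal overlap size (`share_null`), the same
# reuse idea that makes fgsea fast; results are statistically equivalent to
# independent sampling.

#' Weighted KS enrichment score with full running sum
#'
#' Walking the ranked list, a member ("hit") at position i adds
#' `|s_i|^exponent / N_R` (`N_R` = sum of `|s|^exponent` over hits) and a
#' non-member adds `-1/(N - N_H)`. The enrichment score is the running-sum
#' value of maximal absolute magnitude, signed; an exact tie between the
#' positive and negative extreme resolves to the positive one. If all hit
#' statistics are zero the hits contribute uniformly `1/N_H`. The walk ends
#' at zero (total hit mass 1 minus total miss mass 1) up to floating-point
#' rounding.
#'
#' An empty or full overlap makes the pathway untestable: the result
#' carries `status = "untestable"` and a missing score instead of an error.
#'
#' @param ranked a `ranked_features` data.frame from [rank_features()] (or
#'   any data.frame with `feature_id` and `statistic` in ranked order).
#' @param members character vector of pathway feature identifiers.
#' @param exponent GSEA weight exponent, >= 0. 1 (default) is the weighted
#'   statistic; 0 gives the classical Kolmogorov-Smirnov form.
#' @return a list with `es`, `running_sum` (numeric, one value per ranked
#'   position), `overlap` (hit count) and `status`.
#' @export
enrichment_score <- function(ranked, members, exponent = 1) {
  stopifnot(is.data.frame(ranked), exponent >= 0)
  n <- nrow(ranked)
  is_hit <- ranked$feature_id %in% members
  k <- sum(is_hit)
  if (k == 0L || k == n) {
    return(list(es = NA_real_, running_sum = NULL, overlap = k,
                status = "untestable"))
  }
  w <- abs(ranked$statistic)^exponent
  nr <- 0
  for (i in seq_len(n)) if (is_hit[i]) nr <- nr + w[i]
  miss_inc <- 1 / (n - k)
  run <- numeric(n)
  cum <- 0
  max_p <- 0
  min_p <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cum <- cum + (if (nr > 0) w[i] / nr else 1 / k)
    } else {
      cum <- cum - miss_inc
    }
    run[i] <- cum
    if (cum > max_p) max_p <- cum
    if (cum < min_p) min_p <- cum
  }
  es <- if (max_p >= -min_p) max_p else min_p
  list(es = es, running_sum = run, overlap = k, status = "tested")
}

# Observed and null scores through the compiled walk; identical arithmetic
# to enrichment_score().
es_at_positions <- function(statistics, positions, exponent) {
  cpp_es_batch(statistics, matrix(as.integer(positions), nrow = 1L), exponent)
}

# p-value / NES from an observed score and a vector of null scores.
# Same-sign conditioning: the p-value compares the observed score only with
# null scores of the same sign (common GSEA practice), with the add-one
# estimator so p >= 1/(n_same_sign + 1) > 0 and downstream log/probit
# combiners never see p = 0. NES = es / mean(|null es| of the same sign),
# missing when no same-sign nulls exist. A zero observed score gets p = 1.
summarise_null <- function(es, null_es) {
  if (is.na(es) || es == 0) {
    return(list(p_value = 1, nes = NA_real_))
  }
  same <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  m <- length(same)
  extreme <- if (es > 0) sum(same >= es) else sum(same <= es)
  p <- (1 + extreme) / (1 + m)
  nes <- if (m > 0) es / mean(abs(same)) else NA_real_
  list(p_value = p, nes = nes)
}

# nperm random k-subsets of seq_len(n) as an nperm x k matrix, drawn from
# the current RNG stream.
null_index_matrix <- function(n, k, n_perm) {
  idx <- matrix(0L, nrow = n_perm, ncol = k)
  for (i in seq_len(n_perm)) idx[i, ] <- sample.int(n, k)
  idx
}

#' Permutation test for one pathway in one layer
#'
#' Scores the observed member set, then `n_perm` random feature sets of the
#' same size drawn without replacement from the ranked features. The
#' p-value uses the add-one estimator over same-sign null scores,
#' `p = (1 + #extreme) / (1 + #same-sign)`, so its floor is
#' `1/(n_perm + 1)`; NES rescales the observed score by the mean magnitude
#' of same-sign null scores.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of random feature sets, >= 1.
#' @param seed integer seed; identical seeds give identical results and the
#'   caller's RNG state is left untouched.
#' @return a list with `es`, `nes`, `p_value`, `overlap`.
#' @export
permutation_test <- function(ranked, members, n_perm = 1000L, exponent = 1,
                             seed) {
  if (n_perm < 1L) abort("n_perm must be >= 1")
  if (missing(seed)) abort("seed is required for reproducibility")
  n <- nrow(ranked)
  positions <- which(ranked$feature_id %in% members)
  k <- length(positions)
  if (k == 0L || k == n) {
    abort("overlap must be a non-empty strict subset of the ranked features")
  }
  es <- es_at_positions(ranked$statistic, positions, exponent)
  null_es <- local_seed(seed, {
    idx <- null_index_matrix(n, k, n_perm)
    cpp_es_batch(ranked$statistic, idx, exponent)
  })
  s <- summarise_null(es, null_es)
  list(es = es, nes = s$nes, p_value = s$p_value, overlap = k)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; thin validated wrapper over
#' `stats::p.adjust(method = "BH")` kept as the module surface used by the
#' enrichment and combination steps.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  check_pvec(p_values, "bh_adjust")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment analysis of every pathway in one layer
#'
#' Applies the overlap size gate (see [filter_pathways()]), scores each
#' testable pathway with the permutation test, and BH-adjusts p-values
#' within the layer over tested pathways only. Untestable pathways stay in
#' the output with missing statistics.
#'
#' @inheritParams permutation_test
#' @param collection an `mo_pathways` object.
#' @param layer layer to analyse.
#' @param min_size,max_size inclusive bounds on the measured-feature
#'   overlap.
#' @param share_null reuse one null score pool per distinct overlap size
#'   across pathways (fgsea-style speedup) instead of sampling a fresh pool
#'   per pathway. Deterministic under `seed` either way.
#' @return a `data.frame`, one row per pathway: `pathway`, `layer`,
#'   `overlap`, `es`, `nes`, `p_value`, `padj`, `status`.
#' @export
run_layer <- function(ranked, collection, layer, n_perm = 1000L,
                      exponent = 1, seed, min_size = 5L, max_size = 500L,
                      share_null = FALSE) {
  stopifnot(inherits(collection, "mo_pathways"))
  if (nrow(ranked) == 0L) abort("ranked feature list is empty")
  if (n_perm < 1L) abort("n_perm must be >= 1")
  if (missing(seed)) abort("seed is required for reproducibility")
  collection <- filter_pathways(collection, layer, ranked$feature_id,
                                min_size, max_size)
  flagged <- collection$untestable[[layer]]
  n <- nrow(ranked)
  nms <- names(collection$pathways)
  pos_list <- lapply(nms, function(nm) {
    which(ranked$feature_id %in% pathway_features(collection, nm, layer))
  })
  overlaps <- lengths(pos_list)
  testable <- !(nms %in% flagged) & overlaps > 0L & overlaps < n

  es <- nes <- p <- rep(NA_real_, length(nms))
  local_seed(seed, {
    if (share_null) {
      sizes <- sort(unique(overlaps[testable]))
      pools <- list()
      for (k in sizes) {
        idx <- null_index_matrix(n, k, n_perm)
        pools[[as.character(k)]] <- cpp_es_batch(ranked$statistic, idx, exponent)
      }
      for (i in which(testable)) {
        es[i] <- es_at_positions(ranked$statistic, pos_list[[i]], exponent)
        s <- summarise_null(es[i], pools[[as.character(overlaps[i])]])
        nes[i] <- s$nes
        p[i] <- s$p_value
      }
    } else {
      for (i in which(testable)) {
        es[i] <- es_at_positions(ranked$statistic, pos_list[[i]], exponent)
        null_es <- cpp_es_batch(
          ranked$statistic,
          null_index_matrix(n, overlaps[i], n_perm),
          exponent
        )
        s <- summarise_null(es[i], null_es)
        nes[i] <- s$nes
        p[i] <- s$p_value
      }
    }
  })

  padj <- rep(NA_real_, length(nms))
  if (any(testable)) padj[testable] <- bh_adjust(p[testable])
  data.frame(
    pathway = nms,
    layer = layer,
    overlap = as.integer(overlaps),
    es = es,
    nes = nes,
    p_value = p,
    padj = padj,
    status = ifelse(testable, "tested", "untestable"),
    stringsAsFactors = FALSE
  )
}
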