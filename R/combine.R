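# Aggregation of per-layer pathway p-values into one multi-omics p-value.
#
# Three families, following Loughin's guidance on when each is apt:
# Fisher's combined probability test emphasizes small p-values, Stouffer's
# Z-transform treats them evenly, Edgington's additive method emphasizes
# large ones. All assume independent tests across layers.

#' Fisher's combined probability test
#'
#' Statistic `X2 = -2 * sum(log(p_i))`, referred to the upper tail of the
#' chi-square distribution with `2k` degrees of freedom (the classical
#' reference distribution for k independent uniform p-values). Asymmetric:
#' one very small p-value can dominate even when the others are near 1.
#'
#' @param p numeric vector of k >= 1 p-values in (0, 1].
#' @return the combined p-value in (0, 1].
#' @export
fisher_combine <- function(p) {
  check_pvec(p, "fisher_combine", open_left = TRUE, open_right = FALSE)
  stat <- -2 * sum(log(p))
  out <- stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  min(max(out, .Machine$double.xmin), 1)
}

#' Stouffer's Z-transform test, optionally weighted
#'
#' Each p-value is converted to a standard normal deviate
#' `Z_i = qnorm(p_i)` (small p maps to negative Z). Unweighted,
#' `Z_s = sum(Z_i) / sqrt(k)`; weighted,
#' `Z_s = sum(w_i Z_i) / sqrt(sum(w_i^2))`. The combined p-value is the
#' lower normal tail `pnorm(Z_s)`. Equal weights reduce exactly to the
#' unweighted form (the weight scale cancels), which the implementation
#' exploits so the two calls are bitwise identical. When weighting, weights
#' proportional to the square root of per-layer sample sizes are the usual
#' recommendation; they must be supplied by the user.
#'
#' @param p numeric vector of k >= 1 p-values, strictly inside (0, 1)
#'   (`qnorm` diverges at the endpoints; clamp upstream, as
#'   [combine_table()] does).
#' @param weights optional positive weights, one per p-value.
#' @return the combined p-value in (0, 1].
#' @export
stouffer_combine <- function(p, weights = NULL) {
  check_pvec(p, "stouffer_combine", open_left = TRUE, open_right = TRUE)
  z <- stats::qnorm(p)
  if (!is.null(weights)) {
    if (length(weights) != length(p)) {
      abort("stouffer_combine: weights must match p in length")
    }
    if (!is.numeric(weights) || anyNA(weights) || any(weights <= 0)) {
      abort("stouffer_combine: weights must all be positive")
    }
    if (all(weights == weights[1L])) {
      weights <- NULL # scale-free: equal weights are the unweighted case
    }
  }
  zs <- if (is.null(weights)) {
    sum(z) / sqrt(length(p))
  } else {
    sum(weights * z) / sqrt(sum(weights^2))
  }
  out <- stats::pnorm(zs)
  min(max(out, .Machine$double.xmin), 1)
}

#' Edgington's additive combination
#'
#' With `S = sum(p_i)` and k p-values, the combined p-value is the
#' alternating series
#' `sum_{j=0}^{floor(S)} (-1)^j * choose(k, j) * (S - j)^k / k!`,
#' which equals the probability that a sum of k independent Uniform(0,1)
#' variables is at most S (the Irwin-Hall CDF). For `S <= 1` only the first
#' term `S^k / k!` survives. Conservative for small p-values, sensitive to
#' large ones.
#'
#' @param p numeric vector of k >= 1 p-values in \[0, 1\].
#' @return the combined p-value in (0, 1].
#' @export
edgington_combine <- function(p) {
  check_pvec(p, "edgington_combine", open_left = FALSE, open_right = FALSE)
  k <- length(p)
  s <- sum(p)
  j <- 0:min(floor(s), k)
  out <- sum((-1)^j * choose(k, j) * (s - j)^k) / factorial(k)
  min(max(out, .Machine$double.xmin), 1)
}

#' Combine per-layer enrichment results into a multi-omics table
#'
#' Collects, per pathway, the available (tested) per-layer permutation
#' p-values, combines them with the chosen method, and BH-adjusts the
#' combined p-values across pathways. Raw (not BH-adjusted) per-layer
#' p-values enter the combination; adjusting before combining would
#' penalize multiplicity twice. Before Fisher or Stouffer, p-values are
#' clamped to `[1e-15, 1 - 1e-15]` with a warning — the permutation floor
#' `1/(n_perm + 1)` normally keeps them away from the boundary.
#'
#' @param layer_results named list (layer name -> [run_layer()] result
#'   data.frame), one entry per omics layer; pathway universes may differ.
#' @param method `"stouffer"` (default, no bias towards small or large
#'   p-values), `"fisher"`, `"edgington"` or `"weighted_stouffer"`.
#' @param weights for `"weighted_stouffer"`: positive weights named by
#'   layer, or in `layer_results` order.
#' @param missing_policy `"available-layers"` (default) combines whatever
#'   layers tested the pathway, reporting `k_used`; `"require-all"` leaves
#'   the combined p-value missing unless every layer tested it (the row is
#'   retained either way).
#' @param adjust_combined BH-adjust combined p-values across pathways
#'   (default TRUE).
#' @return a `data.frame`, one row per pathway in the union of the layers'
#'   universes: `pathway`, per layer `<layer>_p`, `<layer>_padj`,
#'   `<layer>_es`, `<layer>_nes`, `<layer>_overlap`, then `k_used`,
#'   `combined_p`, `combined_padj`, `method`.
#' @export
combine_table <- function(layer_results,
                          method = c("stouffer", "fisher", "edgington",
                                     "weighted_stouffer"),
                          weights = NULL,
                          missing_policy = c("available-layers", "require-all"),
                          adjust_combined = TRUE) {
  method <- match.arg(method)
  missing_policy <- match.arg(missing_policy)
  if (!is.list(layer_results) || length(layer_results) == 0L ||
      is.null(names(layer_results)) || any(!nzchar(names(layer_results)))) {
    abort("layer_results must be a non-empty named list of run_layer() tables")
  }
  layers <- names(layer_results)
  if (method == "weighted_stouffer") {
    if (is.null(weights)) abort("weighted_stouffer requires weights")
    if (!is.null(names(weights))) {
      if (!all(layers %in% names(weights))) {
        abort("weights must cover every layer")
      }
      weights <- weights[layers]
    } else if (length(weights) != length(layers)) {
      abort("weights must have one entry per layer")
    }
    if (any(weights <= 0)) abort("weights must all be positive")
  }

  pathways <- unique(unlist(lapply(layer_results, `[[`, "pathway")))
  out <- data.frame(pathway = pathways, stringsAsFactors = FALSE)
  for (ly in layers) {
    res <- layer_results[[ly]]
    i <- match(pathways, res$pathway)
    out[[paste0(ly, "_p")]] <- res$p_value[i]
    out[[paste0(ly, "_padj")]] <- res$padj[i]
    out[[paste0(ly, "_es")]] <- res$es[i]
    out[[paste0(ly, "_nes")]] <- res$nes[i]
    out[[paste0(ly, "_overlap")]] <- res$overlap[i]
  }

  eps <- 1e-15
  n_clamped <- 0L
  scalar_combine <- function(pv, w) {
    switch(method,
      fisher = fisher_combine(pmin(pmax(pv, eps), 1 - eps)),
      stouffer = stouffer_combine(pmin(pmax(pv, eps), 1 - eps)),
      weighted_stouffer = stouffer_combine(pmin(pmax(pv, eps), 1 - eps), w),
      edgington = edgington_combine(pv)
    )
  }

  p_cols <- paste0(layers, "_p")
  k_used <- integer(length(pathways))
  combined <- rep(NA_real_, length(pathways))
  for (r in seq_along(pathways)) {
    pv <- as.numeric(out[r, p_cols])
    avail <- !is.na(pv)
    k_used[r] <- sum(avail)
    if (k_used[r] == 0L) next
    if (missing_policy == "require-all" && k_used[r] < length(layers)) next
    pvv <- pv[avail]
    if (method %in% c("fisher", "stouffer", "weighted_stouffer")) {
      n_clamped <- n_clamped + sum(pvv < eps | pvv > 1 - eps)
    }
    w <- if (method == "weighted_stouffer") weights[avail] else NULL
    combined[r] <- scalar_combine(pvv, w)
  }
  if (n_clamped > 0L) {
    warn("clamped ", n_clamped, " per-layer p-value(s) to [1e-15, 1 - 1e-15] ",
         "before combination")
  }
  out$k_used <- k_used
  out$combined_p <- combined
  out$combined_padj <- NA_real_
  if (adjust_combined && any(!is.na(combined))) {
    out$combined_padj[!is.na(combined)] <- bh_adjust(combined[!is.na(combined)])
  }
  out$method <- method
  attr(out, "n_clamped") <- n_clamped
  out
}
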