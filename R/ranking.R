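# Per-layer feature ranking from externally computed differential
# statistics (log fold change + p-value). Differential testing itself is
# out of scope; the tables are the interface.

#' Read a per-layer differential-statistics table
#'
#' Tab-separated with header columns `feature_id`, `logFC`, `pvalue`.
#'
#' @param path TSV file path.
#' @param layer layer name to attach.
#' @return a validated `data.frame` with columns `feature_id`,
#'   `log_fold_change`, `p_value` and attribute `layer`.
#' @export
read_omics_table <- function(path, layer) {
  if (!file.exists(path)) abort("omics table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "logFC", "pvalue")
  if (!all(need %in% names(raw))) {
    abort("omics table ", path, " must have columns: ",
          paste(need, collapse = ", "))
  }
  tab <- data.frame(
    feature_id = as.character(raw$feature_id),
    log_fold_change = as.numeric(raw$logFC),
    p_value = as.numeric(raw$pvalue),
    stringsAsFactors = FALSE
  )
  validate_omics_table(tab)
  attr(tab, "layer") <- layer
  tab
}

validate_omics_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("feature_id", "log_fold_change", "p_value") %in% names(tab)))
  if (anyDuplicated(tab$feature_id)) {
    abort("duplicate feature_id: ", tab$feature_id[duplicated(tab$feature_id)][1L])
  }
  bad <- !is.finite(tab$log_fold_change)
  if (any(bad)) {
    abort("non-finite log_fold_change for feature ", tab$feature_id[bad][1L])
  }
  bad <- !is.finite(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1
  if (any(bad)) {
    abort("p_value must lie in (0, 1]; offending feature ",
          tab$feature_id[bad][1L], " (p = ", format(tab$p_value[bad][1L]), ")")
  }
  invisible(tab)
}

#' Rank features of one omics layer
#'
#' The default metric is the signed log-transformed p-value,
#' `sign(logFC) * (-log10 p)`, so strongly up-regulated significant features
#' rank at the top and strongly down-regulated ones at the bottom. A zero
#' fold change is treated as positive sign, so a zero-change feature with a
#' small p-value still ranks by significance; `p = 1` yields statistic 0
#' regardless of sign. Metric choice can strongly affect enrichment
#' outcomes (Zyla et al. 2017), so alternates are exposed:
#' `log_fold_change` ranks by the fold change itself, and
#' `signed_neg_log10_p` is an explicit-name alias of the default.
#'
#' Ties are broken by feature identifier (C-locale lexicographic order), so
#' the ranking is a deterministic function of the table contents regardless
#' of input row order.
#'
#' @param table a `data.frame` with columns `feature_id`,
#'   `log_fold_change`, `p_value` (see [read_omics_table()]). `p_value = 0`
#'   is rejected; pre-clamp upstream if a tool reports exact zeros.
#' @param metric ranking metric name.
#' @return a `data.frame` of class `ranked_features` with columns
#'   `feature_id` and `statistic`, sorted by decreasing statistic.
#' @export
rank_features <- function(table,
                          metric = c("signed_log_p", "log_fold_change",
                                     "signed_neg_log10_p")) {
  metric <- match.arg(metric)
  validate_omics_table(table)
  sgn <- ifelse(table$log_fold_change >= 0, 1, -1)
  statistic <- switch(metric,
    signed_log_p = ,
    signed_neg_log10_p = sgn * (-log10(table$p_value)),
    log_fold_change = table$log_fold_change
  )
  ord <- order(-statistic, table$feature_id, method = "radix")
  out <- data.frame(
    feature_id = table$feature_id[ord],
    statistic = statistic[ord],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "layer") <- attr(table, "layer")
  attr(out, "metric") <- metric
  class(out) <- c("ranked_features", "data.frame")
  out
}
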