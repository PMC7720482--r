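# In-code fixture builders; everything is generated at test time.

write_gmt_lines <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = env)
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines, fileext = ".tsv", env = parent.frame()) {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = env)
  writeLines(lines, path)
  path
}

# A ranked list with the given statistics (descending) and ids f01, f02, ...
make_ranked <- function(statistics) {
  data.frame(
    feature_id = sprintf("f%02d", seq_along(statistics)),
    statistic = statistics,
    stringsAsFactors = FALSE
  )
}

# Small differential table with arbitrary values.
make_table <- function(ids, lfc, p, layer = "transcriptome") {
  tab <- data.frame(
    feature_id = ids, log_fold_change = lfc, p_value = p,
    stringsAsFactors = FALSE
  )
  attr(tab, "layer") <- layer
  tab
}

# Minimal run_layer-shaped result table for combine_table tests.
make_layer_result <- function(pathways, p, layer, status = "tested") {
  status <- rep_len(status, length(pathways))
  p[status != "tested"] <- NA_real_
  data.frame(
    pathway = pathways, layer = layer,
    overlap = ifelse(status == "tested", 10L, 2L),
    es = ifelse(status == "tested", 0.5, NA_real_),
    nes = ifelse(status == "tested", 1.2, NA_real_),
    p_value = p,
    padj = ifelse(status == "tested", pmin(1, p * 2), NA_real_),
    status = status,
    stringsAsFactors = FALSE
  )
}
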