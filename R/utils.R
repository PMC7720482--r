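# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never observe a side effect on the stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a stream seed from a base seed and a text label
#'
#' Deterministic splitting of one user seed into independent-looking streams,
#' one per (layer, purpose) label, so that adding a layer or a pipeline stage
#' never perturbs the draws of another. Plain polynomial string hash folded
#' with the base seed modulo a Mersenne prime; the result is always a valid
#' 32-bit R integer.
#'
#' @param seed single integer.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h + (as.numeric(seed) %% m) * 69069) %% m)
}

# Single-string stop()/warning() without call noise.
abort <- function(...) stop(..., call. = FALSE)
warn <- function(...) warning(..., call. = FALSE)

# C-locale lexicographic sort/order, stable across platforms.
sort_c <- function(x) x[order_c(x)]
order_c <- function(...) order(..., method = "radix")

# Validate a probability vector; `open_left`/`open_right` control endpoint
# admissibility. Returns invisibly or aborts with `what` in the message.
check_pvec <- function(p, what, open_left = TRUE, open_right = FALSE) {
  if (length(p) < 1L) abort(what, ": at least one p-value is required")
  if (!is.numeric(p) || anyNA(p)) abort(what, ": p-values must be numeric and non-missing")
  lo_bad <- if (open_left) p <= 0 else p < 0
  hi_bad <- if (open_right) p >= 1 else p > 1
  if (any(lo_bad | hi_bad)) {
    rng <- paste0(
      if (open_left) "(" else "[", "0, 1",
      if (open_right) ")" else "]"
    )
    abort(what, ": p-values must lie in ", rng,
          " (offending value: ", format(p[which(lo_bad | hi_bad)[1L]]), ")")
  }
  invisible(p)
}
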