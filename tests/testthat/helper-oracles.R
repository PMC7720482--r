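# Independent oracles used to verify the package's statistics. These stay
# deliberately separate from the implementation paths they check.

# Naive enrichment running-sum walk over every position.
naive_walk <- function(statistics, is_hit, exponent = 1) {
  n <- length(statistics)
  k <- sum(is_hit)
  stopifnot(k > 0L, k < n)
  w <- abs(statistics)^exponent
  nr <- 0
  for (i in seq_len(n)) if (is_hit[i]) nr <- nr + w[i]
  miss <- 1 / (n - k)
  run <- numeric(n)
  cum <- 0
  for (i in seq_len(n)) {
    cum <- cum + (if (is_hit[i]) (if (nr > 0) w[i] / nr else 1 / k) else -miss)
    run[i] <- cum
  }
  max_p <- max(0, run)
  min_p <- min(0, run)
  es <- if (max_p >= -min_p) max_p else min_p
  list(es = es, run = run)
}

# Fisher: upper chi-square tail at -2*sum(log p) with 2k df, evaluated via
# the closed-form Erlang survival function (even df), independent of pchisq.
fisher_oracle <- function(p) {
  x <- -2 * sum(log(p))
  k <- length(p)
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Stouffer: normal lower tail of the printed Z_s expression, with the tail
# evaluated through the incomplete-gamma identity
# pnorm(-|z|) = pgamma(z^2/2, 1/2, lower = FALSE) / 2 instead of pnorm.
stouffer_oracle <- function(p, w = NULL) {
  z <- qnorm(p)
  zs <- if (is.null(w)) sum(z) / sqrt(length(p)) else sum(w * z) / sqrt(sum(w^2))
  tail <- pgamma(zs^2 / 2, shape = 0.5, lower.tail = FALSE) / 2
  if (zs < 0) tail else 1 - tail
}

# Edgington: Irwin-Hall CDF (probability that a sum of k independent
# uniforms is <= S), log-space terms via lchoose/lgamma.
irwin_hall_oracle <- function(p) {
  k <- length(p)
  s <- sum(p)
  if (s >= k) return(1)
  j <- 0:floor(s)
  terms <- exp(lchoose(k, j) + k * log(s - j) - lgamma(k + 1))
  terms[s - j == 0] <- 0 # log(0) guard; a zero base contributes nothing
  sum((-1)^j * terms)
}

# Benjamini-Hochberg step-up, written out directly.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- running_min
  }
  adj
}

# Kolmogorov-Smirnov distance of a sample from Uniform(0, 1).
ks_uniform_distance <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(abs(seq_len(n) / n - x), abs((seq_len(n) - 1) / n - x))
}
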