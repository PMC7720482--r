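test_that("the running sum matches the hand-walked weighted example", {
  # statistics (4, 3, 2, 1), members = top 2, exponent 1:
  # hits add 4/7 then 3/7 (N_R = 7), misses add -1/2 each
  ranked <- make_ranked(c(4, 3, 2, 1))
  res <- enrichment_score(ranked, c("f01", "f02"), exponent = 1)
  expect_equal(res$running_sum, c(4 / 7, 1, 1 / 2, 0))
  expect_equal(res$es, 1)
  expect_identical(res$overlap, 2L)
})

test_that("a single bottom hit with equal statistics gives es = -1 at exponent 0", {
  ranked <- make_ranked(c(2, 2, 2))
  res <- enrichment_score(ranked, "f03", exponent = 0)
  expect_equal(res$running_sum, c(-1 / 2, -1, 0))
  expect_equal(res$es, -1)
})

test_that("all-zero hit statistics fall back to uniform hit increments", {
  ranked <- make_ranked(c(5, 0, 0, -5))
  res <- enrichment_score(ranked, c("f02", "f03"), exponent = 1)
  expect_equal(res$running_sum, c(-1 / 2, 0, 1 / 2, 0))
  expect_equal(res$es, 1 / 2)
})

test_that("empty and full overlaps signal untestable instead of erroring", {
  ranked <- make_ranked(c(3, 2, 1))
  none <- enrichment_score(ranked, "absent")
  expect_identical(none$status, "untestable")
  expect_true(is.na(none$es))
  all_in <- enrichment_score(ranked, c("f01", "f02", "f03"))
  expect_identical(all_in$status, "untestable")
})

test_that("the running sum always ends at zero (mass conservation)", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    ranked <- make_ranked(sort(rnorm(n), decreasing = TRUE))
    k <- sample(seq_len(n - 1), 1)
    members <- sample(ranked$feature_id, k)
    for (expo in c(0, 1, 2)) {
      res <- enrichment_score(ranked, members, exponent = expo)
      expect_lt(abs(res$running_sum[n]), 1e-12)
      expect_lte(abs(res$es), 1)
    }
  }
})

test_that("score and compiled batch walk agree exactly with the naive oracle", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    stats_vec <- sort(rnorm(n), decreasing = TRUE)
    ranked <- make_ranked(stats_vec)
    k <- sample(seq_len(n - 1), 1)
    pos <- sort(sample.int(n, k))
    expo <- sample(c(0, 0.5, 1, 2), 1)
    oracle <- naive_walk(stats_vec, seq_len(n) %in% pos, expo)
    r_res <- enrichment_score(ranked, ranked$feature_id[pos], exponent = expo)
    cpp_res <- mogsea:::es_at_positions(stats_vec, pos, expo)
    expect_identical(r_res$es, oracle$es)
    expect_identical(cpp_res, oracle$es)
    expect_equal(r_res$running_sum, oracle$run)
  }
})

test_that("reversing the ranked list negates the score at exponent 0", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    ranked <- make_ranked(sort(rnorm(n), decreasing = TRUE))
    k <- sample(seq_len(n - 1), 1)
    members <- sample(ranked$feature_id, k)
    fwd <- enrichment_score(ranked, members, exponent = 0)
    rev_ranked <- ranked[rev(seq_len(n)), , drop = FALSE]
    bwd <- enrichment_score(rev_ranked, members, exponent = 0)
    expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
  }
})

test_that("relabeling non-member features with equal statistics changes nothing", {
  ranked <- make_ranked(c(3, 2, 2, 2, 1))
  members <- c("f01", "f05")
  base <- enrichment_score(ranked, members)
  relabeled <- ranked
  relabeled$feature_id[2:4] <- c("x1", "x2", "x3")
  expect_identical(enrichment_score(relabeled, members)$es, base$es)
})

test_that("the enrichment score agrees with fgsea's statistic on random data", {
  set.seed(37)
  stats_vec <- sort(rnorm(500), decreasing = TRUE)
  ranked <- make_ranked(stats_vec)
  for (k in c(5, 20, 80)) {
    pos <- sort(sample.int(500, k))
    ours <- enrichment_score(ranked, ranked$feature_id[pos], exponent = 1)$es
    theirs <- fgsea::calcGseaStat(stats_vec, pos, gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("permutation tests are deterministic under a seed and floored at 1/(m+1)", {
  set.seed(61)
  ranked <- make_ranked(sort(rnorm(100), decreasing = TRUE))
  members <- ranked$feature_id[1:10] # extreme positive set
  a <- permutation_test(ranked, members, n_perm = 199, seed = 17)
  b <- permutation_test(ranked, members, n_perm = 199, seed = 17)
  expect_identical(a, b)
  # the top-10 set beats every same-sign null: p attains the add-one floor
  null_es <- local({
    ranked_stats <- ranked$statistic
    mogsea:::local_seed(17, {
      idx <- mogsea:::null_index_matrix(100, 10, 199)
      mogsea:::cpp_es_batch(ranked_stats, idx, 1)
    })
  })
  m <- sum(null_es > 0)
  expect_equal(a$p_value, 1 / (m + 1))
  expect_gte(a$p_value, 1 / 200)
  expect_gt(a$nes, 1)
})

test_that("permutation_test validates its inputs", {
  ranked <- make_ranked(c(2, 1))
  expect_error(permutation_test(ranked, "f01", n_perm = 0, seed = 1), "n_perm")
  expect_error(permutation_test(ranked, "nope", seed = 1), "overlap")
  expect_error(permutation_test(ranked, c("f01", "f02"), seed = 1), "overlap")
})

test_that("bh_adjust matches hand-computed values and stays monotone", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(19)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_oracle(p))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("run_layer gates, scores and adjusts within the layer", {
  set.seed(83)
  n <- 200
  ranked <- make_ranked(sort(rnorm(n), decreasing = TRUE))
  coll <- pathway_collection("transcriptome", list(
    TOP = list(source = "s",
               features = list(transcriptome = ranked$feature_id[1:12])),
    RAND = list(source = "s",
                features = list(transcriptome = sample(ranked$feature_id, 15))),
    TINY = list(source = "s",
                features = list(transcriptome = ranked$feature_id[c(3, 9)]))
  ))
  res <- run_layer(ranked, coll, "transcriptome", n_perm = 99, seed = 5)
  expect_identical(res$pathway, c("TOP", "RAND", "TINY"))
  expect_identical(res$status, c("tested", "tested", "untestable"))
  expect_true(all(is.na(res[res$status == "untestable",
                            c("es", "nes", "p_value", "padj")])))
  tested <- res[res$status == "tested", ]
  expect_equal(tested$padj, bh_adjust(tested$p_value))
  expect_true(all(tested$p_value >= 1 / 100))
})

test_that("run_layer with a single testable pathway leaves p unadjusted", {
  ranked <- make_ranked(sort(rnorm(60), decreasing = TRUE))
  coll <- pathway_collection("proteome", list(
    ONLY = list(source = "s", features = list(proteome = ranked$feature_id[1:8]))
  ))
  res <- run_layer(ranked, coll, "proteome", n_perm = 99, seed = 2)
  expect_equal(res$padj, res$p_value)
})

test_that("shared null pools are deterministic and calibrated like fresh pools", {
  set.seed(97)
  ranked <- make_ranked(sort(rnorm(300), decreasing = TRUE))
  pws <- stats::setNames(
    lapply(1:6, function(i) list(
      source = "s",
      features = list(transcriptome = sample(ranked$feature_id, 20))
    )),
    sprintf("P%d", 1:6)
  )
  coll <- pathway_collection("transcriptome", pws)
  a <- run_layer(ranked, coll, "transcriptome", n_perm = 299, seed = 31,
                 share_null = TRUE)
  b <- run_layer(ranked, coll, "transcriptome", n_perm = 299, seed = 31,
                 share_null = TRUE)
  expect_identical(a, b)
  fresh <- run_layer(ranked, coll, "transcriptome", n_perm = 299, seed = 31)
  expect_identical(a$es, fresh$es) # observed scores identical
  # p-values differ only by null-sampling noise
  expect_lt(max(abs(a$p_value - fresh$p_value)), 0.2)
})
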