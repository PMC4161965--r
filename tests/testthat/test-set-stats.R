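test_that("weighted KS matches hand enumeration on the 5-gene example", {
  scores <- c(5, 4, 3, 2, 1)
  top2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(weighted_ks(scores, top2, 1), 1.0)
  bottom2 <- rev(top2)
  expect_equal(weighted_ks(scores, bottom2, 1),
               oracle_ks(scores, bottom2, 1))
  expect_lt(weighted_ks(scores, bottom2, 1), 0)
  expect_error(weighted_ks(scores, rep(TRUE, 5)), "all genes")
})

test_that("weighted KS equals the running-sum oracle and fgsea on random data", {
  set.seed(41)
  for (i in 1:25) {
    G <- sample(10:40, 1)
    scores <- rnorm(G)
    k <- sample(2:(G - 2), 1)
    members <- logical(G); members[sample(G, k)] <- TRUE
    expect_equal(weighted_ks(scores, members, 1),
                 oracle_ks(scores, members, 1), tolerance = 1e-12)
  }
  # independent external implementation of the same statistic
  scores <- sort(rnorm(50), decreasing = TRUE)
  members <- logical(50); members[c(2, 5, 9, 30, 44)] <- TRUE
  ref <- fgsea::calcGseaStat(scores, selectedStats = which(members),
                             gseaParam = 1, scoreType = "std")
  expect_equal(weighted_ks(scores, members, 1), ref, tolerance = 1e-10)
})

test_that("weighted KS is scale invariant and centered for flat scores", {
  set.seed(42)
  scores <- rnorm(30)
  members <- logical(30); members[sample(30, 6)] <- TRUE
  expect_equal(weighted_ks(scores * 7.5, members, 1),
               weighted_ks(scores, members, 1))
  es <- replicate(400, {
    m <- logical(40); m[sample(40, 8)] <- TRUE
    weighted_ks(rep(1, 40), m, 1)
  })
  expect_lt(abs(mean(es)), 0.05)
})

test_that("simple set statistics match their closed forms", {
  expect_equal(l2norm(c(3, 4)), 5)
  expect_equal(l2norm(c(0, 0)), 0)
  expect_equal(l2norm(c(3, -4)), l2norm(c(3, 4)))
  expect_equal(mean_abs(c(1, -3)), 2)
  expect_equal(mean_abs(rep(2, 5)), 2)
  expect_equal(sig_ratio(c(0.01, 0.2, 0.04, 0.5), 0.05), 0.5)
  expect_equal(sig_ratio(c(0.2, 0.5), 0.05), 0)
  expect_equal(sig_ratio(c(0.01, 0.02), 0.05), 1)
  expect_equal(weighted_sig_ratio(c(2, 4), c(0.01, 0.5), 0.05), 1.0)
  expect_equal(weighted_sig_ratio(c(2, 4), c(0.5, 0.5), 0.05), 0)
  expect_equal(weighted_sig_ratio(c(2, 4) * 3, c(0.01, 0.5), 0.05), 3.0)
  expect_equal(geometric_mean_p(c(0.01, 1)), 0.1)
  expect_equal(geometric_mean_p(rep(0.3, 4)), 0.3)
  expect_lte(geometric_mean_p(c(0.2, 0.6)), 0.6)
  expect_equal(truncated_product(c(0.01, 0.2), 0.05), 0.01)
  expect_equal(truncated_product(c(0.2, 0.6), 0.05), 1)
  expect_equal(truncated_product(c(0.01, 0.04), 0.05), 4e-4)
  expect_equal(fisher_method(c(0.1, 0.1)), -2 * 2 * log(0.1))
  expect_equal(fisher_method(c(1, 1)), 0)
  expect_equal(fisher_method(c(0.2, 1)), fisher_method(0.2))
  expect_equal(min_p(c(0.3, 0.02, 0.5)), 0.02)
  expect_equal(min_p(0.7), 0.7)
  expect_equal(rank_sum(1:10, c(rep(TRUE, 3), rep(FALSE, 7))), 6)
  expect_equal(rank_sum(gsaperm:::sig_ranks(rep(0.1, 10), rep(1, 10)),
                        rep(TRUE, 10)), 10 * 11 / 2)
})

test_that("rank sum uses average ranks for tied significance", {
  p <- c(0.01, 0.02, 0.03, 0.5, 0.5, 0.9)
  s <- c(5, 4, 3, 2, 2, 1)
  r <- gsaperm:::sig_ranks(p, s)
  members <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(r[4], 4.5)
  expect_equal(rank_sum(r, members), 9)
})

test_that("the vectorized AS matrix equals per-set naive references", {
  set.seed(43)
  for (i in 1:20) {
    G <- sample(12:20, 1)
    C <- sample(2:6, 1)
    scores <- matrix(rnorm(G * C), G)
    pvals <- matrix(runif(G * C), G)
    m <- sample(2:4, 1)
    sets_idx <- lapply(seq_len(m), function(j) sample(G, sample(2:6, 1)))
    names(sets_idx) <- sprintf("S%d", seq_len(m))
    for (stat in gsaperm:::SET_STATS) {
      got <- gsaperm:::compute_as_matrix(stat, sets_idx, scores = scores,
                                         pvalues = pvals)
      want <- sapply(seq_len(C), function(cc) {
        vapply(sets_idx, function(ix) {
          members <- logical(G); members[ix] <- TRUE
          oracle_as(stat, scores[, cc], pvals[, cc], members)
        }, 0)
      })
      expect_equal(unname(got), unname(want), tolerance = 1e-10,
                   info = stat)
    }
  }
})

test_that("score statistics are homogeneous; p-value statistics ignore scores", {
  set.seed(44)
  G <- 30
  scores <- matrix(rnorm(G), G)
  pvals <- matrix(runif(G), G)
  sets_idx <- list(a = 1:6, b = c(2, 9, 15, 22))
  for (stat in c("l2norm", "mean", "weighted_sig_ratio")) {
    a1 <- gsaperm:::compute_as_matrix(stat, sets_idx, scores = scores,
                                      pvalues = pvals)
    a3 <- gsaperm:::compute_as_matrix(stat, sets_idx, scores = scores * 3,
                                      pvalues = pvals)
    expect_equal(a3, a1 * 3, info = stat)
  }
  for (stat in c("sig_ratio", "geometric_mean", "truncated_product",
                 "fisher", "min_p")) {
    a1 <- gsaperm:::compute_as_matrix(stat, sets_idx, scores = scores,
                                      pvalues = pvals)
    a2 <- gsaperm:::compute_as_matrix(stat, sets_idx, scores = scores * -2,
                                      pvalues = pvals)
    expect_equal(a2, a1, info = stat)
  }
})
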