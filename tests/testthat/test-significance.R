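test_that("permutation plans are deterministic and preserve class sizes", {
  l <- factor(rep(c("A", "B"), c(6, 4)), levels = c("A", "B"))
  p1 <- make_permutations(l, 20, seed = 99)
  p2 <- make_permutations(l, 20, seed = 99)
  expect_identical(p1, p2)
  for (j in seq_len(ncol(p1$idx)))
    expect_identical(as.vector(table(l[p1$idx[, j]])), c(6L, 4L))
  expect_error(make_permutations(l, 0), "at least 1")
  # each sample lands in class 1 with frequency ~ n1/n over many shuffles
  pbig <- make_permutations(l, 4000, seed = 7)
  freq <- rowMeans(apply(pbig$idx, 2, function(ix) (l == "A")[ix]))
  expect_true(all(abs(freq - 0.6) < 0.05))
})

test_that("NAS normalizes by the (same-signed) null mean", {
  expect_equal(nas(4, c(1, 2, 3)), 2)
  expect_equal(nas(2, rep(2, 5)), 1)
  expect_equal(nas(-0.4, c(0.5, -0.1, -0.3), signed = TRUE), -2)
  expect_warning(z <- nas(1, c(0, 0, 0)), "NAS")
  expect_equal(z, 0)
  expect_warning(zs <- nas(-1, c(0.2, 0.4), signed = TRUE), "NAS")
  expect_equal(zs, 0)
})

test_that("empirical set p-values count ties into the stated tail", {
  expect_equal(empirical_p(5, 1:10, "greater"), 6 / 10)
  expect_equal(empirical_p(0, 1:10, "greater"), 1.0)
  expect_equal(empirical_p(1, 1:10, "smaller"), 1 / 10)
})

test_that("FDR and FWER equal the naive loop oracles on small instances", {
  set.seed(51)
  for (i in 1:40) {
    m <- sample(1:5, 1); N <- sample(2:10, 1)
    nas_obs <- round(rnorm(m), 2)
    nas_null <- matrix(round(rnorm(m * N), 2), m)
    if (i %% 3 == 0) nas_null[1, 1] <- nas_obs[1]  # ties exercised
    for (tail in c("greater", "smaller")) {
      expect_equal(perm_fdr(nas_obs, nas_null, tail),
                   oracle_fdr(nas_obs, nas_null, tail), tolerance = 1e-12)
      expect_identical(perm_fwer(nas_obs, nas_null, tail),
                       oracle_fwer(nas_obs, nas_null, tail))
      p <- vapply(seq_len(m), function(s)
        empirical_p(nas_obs[s], nas_null[s, ], tail), 0)
      po <- vapply(seq_len(m), function(s)
        oracle_empirical_p(nas_obs[s], nas_null[s, ], tail), 0)
      expect_identical(p, po)
    }
  }
})

test_that("FDR boundary behavior matches the formula", {
  expect_equal(perm_fdr(3, matrix(c(1, 2, 2.5), 1), "greater"), 0)
  # null distribution equal to the observed multiset: median set has FDR ~ 1
  obs <- c(1, 2, 3, 4, 5)
  null <- matrix(rep(obs, 4), 5)
  fdr <- perm_fdr(obs, null, "greater")
  expect_equal(fdr[3], 1)
  fwer <- perm_fwer(obs, null, "greater")
  expect_equal(fwer, rep(1, 5))  # every permutation max reaches every obs
})

test_that("FWER is monotone in NAS extremity; p of the top set bounds it", {
  set.seed(52)
  nas_obs <- rnorm(8)
  nas_null <- matrix(rnorm(8 * 30), 8)
  fwer <- perm_fwer(nas_obs, nas_null, "greater")
  o <- order(-nas_obs)
  expect_true(all(diff(fwer[o]) >= 0))
  top <- o[1]
  p_top <- empirical_p(nas_obs[top], nas_null[top, ], "greater")
  expect_gte(fwer[top], p_top)
})

test_that("the full pipeline is deterministic and alignment invariant", {
  d <- tiny_dataset()
  base <- run_gsa(d$counts, d$labels, d$sets, n_perm = 30, seed = 3,
                  min_size = 5, max_size = 50)
  again <- run_gsa(d$counts, d$labels, d$sets, n_perm = 30, seed = 3,
                   min_size = 5, max_size = 50)
  expect_identical(base$table, again$table)
  perm <- sample(ncol(d$counts))
  shuf <- run_gsa(d$counts[, perm], d$labels[perm], d$sets, n_perm = 30,
                  seed = 3, min_size = 5, max_size = 50)
  expect_equal(shuf$table, base$table)
})

test_that("gene and sample permutation share the observed AS column", {
  d <- tiny_dataset()
  rs <- run_gsa(d$counts, d$labels, d$sets, set_stat = "fisher",
                n_perm = 25, seed = 3, min_size = 5, max_size = 50)
  rg <- run_gsa(d$counts, d$labels, d$sets, set_stat = "fisher",
                n_perm = 25, seed = 3, perm_type = "gene",
                min_size = 5, max_size = 50)
  # same sets, same observed AS, but different null-derived quantities
  o <- order(rs$table$NAME); og <- order(rg$table$NAME)
  expect_equal(rg$table$NAME[og], rs$table$NAME[o])
  expect_false(isTRUE(all.equal(rg$table$AS[og], rs$table$AS[o])))
  # score-family AS is identical across modes (same observed scores)
  rs2 <- run_gsa(d$counts, d$labels, d$sets, set_stat = "l2norm",
                 n_perm = 25, seed = 3, min_size = 5, max_size = 50)
  rg2 <- run_gsa(d$counts, d$labels, d$sets, set_stat = "l2norm",
                 n_perm = 25, seed = 3, perm_type = "gene",
                 min_size = 5, max_size = 50)
  o <- order(rs2$table$NAME); og <- order(rg2$table$NAME)
  expect_equal(rg2$table$AS[og], rs2$table$AS[o])
})

test_that("signed KS significance works within same-sign groups", {
  as_mat <- rbind(c(0.6, 0.3, -0.2, 0.3, -0.4, 0.2),
                  c(-0.5, 0.1, -0.25, 0.2, -0.25, 0.15))
  rownames(as_mat) <- c("up", "dn")
  sig <- gsaperm:::set_significance(as_mat, tail = "greater", signed = TRUE)
  # up set: positive null {0.3, 0.3, 0.2}, mean 0.2667
  expect_equal(sig["up", "NAS"], 0.6 / mean(c(0.3, 0.3, 0.2)))
  expect_equal(sig["up", "PVALUE"], 0)
  # dn set: negative null {-0.2... } for the dn row: {-0.25, -0.25}
  expect_equal(sig["dn", "NAS"], -0.5 / mean(c(0.25, 0.25)))
  expect_equal(sig["dn", "PVALUE"], 0)
  expect_true(all(sig$FDR >= 0 & sig$FDR <= 1))
})
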