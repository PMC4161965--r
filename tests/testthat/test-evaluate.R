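fake_table <- function(names, fdr, nas = NULL, p = NULL) {
  n <- length(names)
  data.frame(NAME = names, SIZE = rep(20L, n), AS = seq_len(n),
             NAS = if (is.null(nas)) rev(seq_len(n)) else nas,
             PVALUE = if (is.null(p)) fdr / 2 else p, FDR = fdr,
             FWER = pmin(fdr * 2, 1), stringsAsFactors = FALSE)
}

test_that("recognition rate counts FDR-rank-1 replicates", {
  hit <- fake_table(c("causal", "other"), c(0.01, 0.5))
  miss <- fake_table(c("causal", "other"), c(0.5, 0.01))
  expect_equal(recognition_rate(list(hit, hit, hit, miss), "causal"), 0.75)
  expect_equal(recognition_rate(list(hit, hit), "causal"), 1)
  expect_error(recognition_rate(list(hit), "absent"), "missing")
})

test_that("FDR ties are resolved by NAS extremity before deciding rank 1", {
  tied <- fake_table(c("causal", "other"), c(0.1, 0.1), nas = c(2.0, 1.5))
  tied_rev <- fake_table(c("causal", "other"), c(0.1, 0.1),
                         nas = c(1.5, 2.0))
  expect_equal(recognition_rate(list(tied), "causal"), 1)
  expect_equal(recognition_rate(list(tied_rev), "causal"), 0)
})

test_that("power uses a strict threshold on the causal set p-value", {
  tabs <- lapply(c(0.01, 0.049, 0.05, 0.2), function(p)
    fake_table(c("causal", "other"), c(0.1, 0.2), p = c(p, 0.5)))
  expect_equal(gsa_power(tabs, "causal"), 0.5)
  expect_equal(gsa_power(tabs, "causal", threshold = 1.1), 1)
  expect_equal(gsa_power(tabs, "causal", threshold = 0.001), 0)
  summ <- evaluation_summary(tabs, "causal")
  expect_equal(summ$n_replicates, 4L)
  expect_equal(summ$mean_p, mean(c(0.01, 0.049, 0.05, 0.2)))
})

test_that("rank-matrix aggregation reproduces NOC and average-rank rules", {
  ranks <- rbind(A = c(1, 2, 7, 1, 15, 1, 1, 2),
                 B = c(0, 10, 1, 0, 0, 8, 6, 8),
                 C = c(0, 0, 0, 2, 3, 0, 0, 0))
  colnames(ranks) <- sprintf("m%d", 1:8)
  agg <- aggregate_rank_matrix(ranks, min_methods = 4)
  expect_identical(agg$Pathway, c("A", "B"))  # C has NOC 2 -> dropped
  expect_equal(agg$NOC, c(8, 5))
  expect_equal(agg$Avg, c(3.75, 6.6))
  expect_identical(agg$Index, c("G1", "G2"))
})

test_that("top-K aggregation from result tables is method-order invariant", {
  set.seed(61)
  mk <- function(perm) fake_table(sprintf("P%02d", perm),
                                  fdr = seq(0.01, 0.2, length.out = 10))
  tables <- list(a = mk(1:10), b = mk(c(2:6, 1, 7:10)),
                 c = mk(10:1), d = mk(c(1, 3, 2, 4:10)),
                 e = mk(sample(10)))
  agg <- aggregate_ranks(tables, top_k = 5, min_methods = 3)
  agg_rev <- aggregate_ranks(rev(tables), top_k = 5, min_methods = 3)
  expect_equal(agg[, c("Pathway", "NOC", "Avg")],
               agg_rev[, c("Pathway", "NOC", "Avg")])
  expect_true(all(agg$NOC >= 3))
  # per-method rank columns permute with the method order
  expect_equal(agg[, rev(names(tables))], agg_rev[, rev(names(tables))])
  # ranks within one method are the positions in its sorted top list
  row_a <- agg[agg$Pathway == "P02", ]
  expect_equal(row_a$a, 2)  # P02 is second in method a's top list
  expect_equal(row_a$b, 1)  # and first in method b's
})

test_that("published-style rank fixtures round-trip through the TSV reader", {
  f <- system.file("extdata", "kidney_liver_top_pathway_ranks.tsv",
                   package = "gsaperm")
  ranks <- read_rank_matrix(f)
  expect_identical(dim(ranks), c(10L, 8L))
  expect_true("BIOCARTA AMI PATHWAY" %in% rownames(ranks))
})
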