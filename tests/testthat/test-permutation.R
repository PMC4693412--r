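test_that("status shuffling preserves the label multiset and is seed-reproducible", {
  status <- rep(c("case", "control"), c(37, 63))
  p1 <- permute_status(status, seed = 5)
  expect_equal(sort(p1), sort(status))
  expect_equal(sum(p1 == "case"), 37)
  expect_identical(p1, permute_status(status, seed = 5))
  expect_false(identical(p1, permute_status(status, seed = 6)))
  expect_identical(permute_status("case", seed = 1), "case")
})

test_that("seed fan-out is deterministic, stage-separated and in integer range", {
  expect_identical(fan_seed(42, "permutation", 7), fan_seed(42, "permutation", 7))
  expect_false(fan_seed(42, "permutation", 7) == fan_seed(42, "permutation", 8))
  expect_false(fan_seed(42, "permutation", 7) == fan_seed(42, "phenotype", 7))
  s <- vapply(1:500, function(i) fan_seed(2^30, "permutation", i), numeric(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_error(fan_seed(1, "nonsense"), "unknown stage")
})

test_that("empirical p-values follow the exceedance convention with tie handling", {
  expect_equal(format_pvalue(0, 1000)$display, "<0.001")
  expect_equal(format_pvalue(0, 1000)$p, 0)
  expect_equal(format_pvalue(0, 1)$display, "<1")
  expect_equal(format_pvalue(500, 1000)$p, 0.5)
  expect_error(format_pvalue(5, 4), "\\[0, R\\]")

  # crafted null: observed above all -> "< 1/R"; below all -> 1; ties count
  sc <- make_scores(c("x", "y"),
                    data.frame(snp_a = "x", snp_b = "y", ig = 0.5),
                    mi = c(x = 0.2, y = 0.0))
  null <- list(mi_null = cbind(seq(0.01, 0.1, length.out = 10),
                               seq(0.01, 0.1, length.out = 10)),
               ig_null = cbind(c(rep(0.1, 9), 0.5)),
               snp_ids = c("x", "y"),
               pair_ids = "x,y", seed = 1)
  pv <- per_statistic_pvalues(sc, null)
  expect_equal(pv$mi$p, c(0, 1))
  expect_equal(pv$mi$p_display[1], "<0.1")
  expect_equal(pv$pairs$p, 0.1)     # the tied replicate counts as an exceedance
  pv2 <- per_statistic_pvalues(sc, null, method = "add_one")
  expect_equal(pv2$mi$p, c(1 / 11, 11 / 11))
  null$snp_ids <- c("x", "z")
  expect_error(per_statistic_pvalues(sc, null), "different SNP set")
})

test_that("shuffled-data IG values are exchangeable with the permutation null", {
  coh <- small_cohort(seed = 41, n = 250, m = 12)
  g <- impute_mode(coh$genotypes)
  # two independent shuffles act as two draws from the same null
  s1 <- permute_status(coh$status, seed = 101)
  s2 <- permute_status(coh$status, seed = 202)
  ig1 <- pairwise_ig_scan(g, s1)$pairs$ig
  ig2 <- pairwise_ig_scan(g, s2)$pairs$ig
  ks <- suppressWarnings(ks.test(ig1, ig2))
  expect_gt(ks$p.value, 0.01)
})

test_that("p-values are stable under doubling R within the Monte-Carlo bound", {
  coh <- small_cohort(seed = 43, n = 200, m = 8)
  g <- impute_mode(coh$genotypes)
  n100 <- null_score_distribution(g, coh$status, R = 100, seed = 7)
  n200 <- null_score_distribution(g, coh$status, R = 200, seed = 7)
  sc <- pairwise_ig_scan(g, coh$status)
  p100 <- per_statistic_pvalues(sc, n100)$pairs$p
  p200 <- per_statistic_pvalues(sc, n200)$pairs$p
  bound <- 2 * sqrt(pmax(p200 * (1 - p200), 0.25 / 200) / 100) + 1e-9
  expect_true(all(abs(p200 - p100) <= bound + 0.02))
})

test_that("null distributions persist as long-format audit TSV", {
  coh <- small_cohort(seed = 45, n = 100, m = 5)
  g <- impute_mode(coh$genotypes)
  null <- null_score_distribution(g, coh$status, R = 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_distribution(null, f, what = "ig")
  tab <- read.delim(f)
  expect_equal(names(tab), c("replicate", "statistic", "value"))
  expect_equal(nrow(tab), 10 * choose(5, 2))
  expect_equal(tab$value[tab$statistic == null$pair_ids[1]],
               null$ig_null[, 1])
})

test_that("null network statistics reuse fixed thresholds and validate input", {
  coh <- small_cohort(seed = 47, n = 150, m = 10,
                      pairs = list(list(snp_a = 2, snp_b = 7,
                                        penetrance = xor_penetrance(0.8, 0.2))))
  g <- impute_mode(coh$genotypes)
  sc <- pairwise_ig_scan(g, coh$status)
  th <- as.numeric(percolation_threshold(sc))
  res <- null_network_statistics(g, coh$status, thresholds = c(th * 2, th),
                                 R = 30, seed = 13)
  expect_length(res, 2)
  expect_s3_class(res[[1]]$lcc_size, "permutation_null")
  expect_length(res[[1]]$lcc_size$null_values, 30)
  expect_true(all(vapply(res, function(x) x$n_nodes$p_value, numeric(1)) >= 0))
  expect_s3_class(attr(res, "observed"), "data.frame")
  # determinism across calls
  res2 <- null_network_statistics(g, coh$status, thresholds = c(th * 2, th),
                                  R = 30, seed = 13)
  expect_identical(res[[1]]$lcc_size$null_values, res2[[1]]$lcc_size$null_values)
  expect_error(null_network_statistics(g, coh$status, th, R = 0), "R must be")
})
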