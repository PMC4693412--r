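test_that("BMI arithmetic and dichotomization follow the strict cut", {
  expect_equal(compute_bmi(81, 1.8), 25)
  expect_equal(compute_bmi(97.2, 1.8), 30)
  expect_error(compute_bmi(72, 0), "height")
  expect_error(compute_bmi(-1, 1.7), "weight")
  expect_true(dichotomize_bmi(30.1))
  expect_false(dichotomize_bmi(29.9))
  expect_false(dichotomize_bmi(30))   # boundary goes to the control side
  expect_error(dichotomize_bmi(NA_real_), "finite")
})

test_that("deviance-residual classification is concordant with the obese indicator", {
  set.seed(21)
  n <- 400
  ph <- phenotype_table(
    individual_id = paste0("i", 1:n),
    age = runif(n, 29, 61),
    sex = sample(c("male", "female"), n, TRUE),
    bmi = runif(n, 22, 38)
  )
  out <- adjust_and_classify(ph)
  expect_equal(attr(out, "concordance"), 1.0)
  expect_identical(out$status == "case", out$obese)
  # constant outcome is degenerate
  ph_all <- ph
  ph_all$bmi <- 35
  ph_all$obese <- TRUE
  expect_error(adjust_and_classify(ph_all), "constant")
})

test_that("individuals with missing covariates are dropped with a message", {
  ph <- phenotype_table(
    individual_id = paste0("i", 1:10),
    age = c(NA, runif(9, 30, 60)),
    sex = rep(c("male", "female"), 5),
    bmi = c(25, 35, 25, 35, 25, 35, 25, 35, 25, 35)
  )
  expect_message(out <- adjust_and_classify(ph), "dropping 1")
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("MAF filter excludes strictly below threshold and all-missing SNPs", {
  n <- 100
  vals <- cbind(
    low = c(rep(1L, 8), rep(0L, 92)),        # MAF 0.04
    edge = c(rep(1L, 10), rep(0L, 90)),      # MAF exactly 0.05
    mono = rep(0L, 100),                     # MAF 0
    common = rep(c(0L, 1L, 2L), length.out = 100),
    gone = rep(NA_integer_, 100)
  )
  g <- genotype_matrix(vals)
  expect_message(out <- filter_maf(g), "all calls missing")
  expect_setequal(out$snp_ids, c("edge", "common"))
  expect_setequal(attr(out, "dropped"), c("low", "mono", "gone"))
  # missing calls are ignored in the frequency computation
  vals2 <- cbind(a = c(rep(1L, 10), rep(0L, 80), rep(NA_integer_, 10)))
  expect_equal(unname(snp_maf(genotype_matrix(vals2))), 10 / 180)
})

test_that("greedy LD pruning removes the later SNP of each high-r2 pair", {
  set.seed(5)
  n <- 200
  A <- sample(0:2, n, TRUE, prob = c(.36, .48, .16))
  B <- A; B[1:8] <- (B[1:8] + 1L) %% 3L              # near-duplicate of A
  C <- A; C[sample(n, 110)] <- sample(0:2, 110, TRUE) # weakly related to A
  stopifnot(cor(A, B)^2 > 0.8, cor(A, C)^2 < 0.8)
  g <- genotype_matrix(cbind(A = A, B = B, C = C),
                       chrom = c("1", "1", "1"), pos = c(100L, 200L, 300L))
  out <- ld_prune(g)
  expect_setequal(out$snp_ids, c("A", "C"))
  expect_equal(attr(out, "dropped"), "B")
  # duplicated column: r2 = 1, second copy removed
  g2 <- genotype_matrix(cbind(A = A, A2 = A), chrom = c("1", "1"),
                        pos = c(1L, 2L))
  expect_equal(ld_prune(g2)$snp_ids, "A")
  # different chromosomes are never compared
  g3 <- genotype_matrix(cbind(A = A, A2 = A), chrom = c("1", "2"),
                        pos = c(1L, 2L))
  expect_equal(ncol(ld_prune(g3)$values), 2)
})

test_that("no independent SNPs are pruned and survivors satisfy the r2 bound", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 12, ld_rho = 0,
                    main_effect_snps = data.frame(snp = integer(0), beta = numeric(0)),
                    epistatic_pairs = list(), missing_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  out <- ld_prune(g)
  expect_equal(length(attr(out, "dropped")), 0)
  # survivors of a correlated cohort never exceed the threshold pairwise
  cfg2 <- sim_config(n_individuals = 800, n_snps = 24, ld_rho = 0.98,
                     ld_block_size = 4,
                     main_effect_snps = data.frame(snp = integer(0), beta = numeric(0)),
                     epistatic_pairs = list(), missing_rate = 0, seed = 32)
  out2 <- ld_prune(simulate_genotypes(cfg2))
  for (chr in unique(out2$chrom)) {
    idx <- which(out2$chrom == chr)
    if (length(idx) < 2) next
    r2 <- cor(out2$values[, idx])^2
    expect_lte(max(r2[upper.tri(r2)]), 0.8)
  }
})

test_that("mode imputation fills with the modal genotype, ties to lowest dosage", {
  col1 <- c(rep(0L, 50), rep(1L, 30), rep(2L, 18), NA, NA)
  col2 <- c(rep(0L, 40), rep(1L, 40), rep(2L, 18), NA, NA)
  col3 <- rep(c(0L, 1L), 50)
  g <- genotype_matrix(cbind(a = col1, b = col2, c = col3))
  out <- impute_mode(g)
  expect_false(anyNA(out$values))
  expect_equal(out$values[99:100, "a"], c(0L, 0L), ignore_attr = TRUE)
  expect_equal(out$values[99:100, "b"], c(0L, 0L), ignore_attr = TRUE)  # tie -> lowest dosage
  expect_identical(out$values[, "c"], g$values[, "c"])                  # identity when complete
  g_bad <- genotype_matrix(cbind(a = col1, z = rep(NA_integer_, 100)))
  expect_error(impute_mode(g_bad), "no observed genotypes")
})

test_that("SNP-to-gene mapping uses closed padded windows and allows multi-labels", {
  ann <- gene_annotation(gene = c("G1", "G2"), chrom = c("1", "1"),
                         start = c(2e6, 2.4e6), end = c(2.1e6, 2.5e6),
                         window_pad = 5e5)
  g <- genotype_matrix(
    matrix(sample(0:2, 5 * 4, TRUE), 5, 4),
    snp_ids = c("at_edge", "in_both", "outside", "other_chr"),
    chrom = c("1", "1", "1", "2"),
    pos = c(1.5e6, 2.05e6, 9e6, 2.05e6)   # 1.5e6 == start - pad exactly
  )
  expect_warning(mem <- map_snps_to_genes(g, ann), "unlabeled")
  expect_true(mem["at_edge", "G1"])
  expect_false(mem["at_edge", "G2"])
  expect_true(all(mem["in_both", ]))       # overlapping windows, two labels
  expect_false(any(mem["outside", ]))
  expect_false(any(mem["other_chr", ]))
})
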