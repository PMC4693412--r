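no_effects <- list(
  main_effect_snps = data.frame(snp = integer(0), beta = numeric(0)),
  epistatic_pairs = list()
)

test_that("config validation names the offending field", {
  expect_error(sim_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(sim_config(ld_block_size = 0), "ld_block_size")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_snps = 50,
                          epistatic_pairs = list(list(snp_a = 3, snp_b = 3,
                                                      penetrance = xor_penetrance()))),
               "distinct")
  expect_error(sim_config(n_snps = 50,
                          epistatic_pairs = list(list(snp_a = 3, snp_b = 99,
                                                      penetrance = xor_penetrance()))),
               "out of range")
  bad_pen <- xor_penetrance(); bad_pen[1, 1] <- 1.2
  expect_error(sim_config(n_snps = 50,
                          epistatic_pairs = list(list(snp_a = 3, snp_b = 9,
                                                      penetrance = bad_pen))),
               "\\[0, 1\\]")
  expect_error(sim_config(n_snps = 50,
                          main_effect_snps = data.frame(snp = 99, beta = 1)),
               "main_effect_snps")
})

test_that("genotypes follow Hardy-Weinberg proportions at the requested MAF", {
  cfg <- do.call(sim_config, c(list(n_individuals = 10000, n_snps = 4,
                                    maf_range = c(0.3, 0.3), ld_rho = 0,
                                    missing_rate = 0, seed = 2), no_effects))
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$values) / 2
  expect_true(all(abs(freq - 0.3) < 0.01))
  # genotype class proportions near (q^2, 2pq, p^2)
  tab <- tabulate(g$values[, 1] + 1L, 3L) / 10000
  expect_equal(tab, c(0.49, 0.42, 0.09), tolerance = 0.02)
})

test_that("ld_rho = 0 yields independent SNPs; ld_rho > 0 correlates neighbors", {
  cfg0 <- do.call(sim_config, c(list(n_individuals = 5000, n_snps = 10,
                                     ld_rho = 0, missing_rate = 0, seed = 3),
                                no_effects))
  g0 <- simulate_genotypes(cfg0)
  cm <- cor(g0$values)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)

  one_gene <- gene_annotation("G1", "1", 1e6, 2e6)
  cfg1 <- do.call(sim_config, c(list(n_individuals = 5000, n_snps = 12,
                                     ld_rho = 0.9, ld_block_size = 3,
                                     gene_windows = one_gene, prop_in_genes = 1,
                                     missing_rate = 0, seed = 3),
                                no_effects))
  g1 <- simulate_genotypes(cfg1)
  within <- cor(g1$values[, 1], g1$values[, 2])
  expect_gt(within, 0.5)
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_individuals = 150, n_snps = 25, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$values, c2$genotypes$values)
  expect_identical(c1$phenotypes, c2$phenotypes)
  cfg2 <- sim_config(n_individuals = 150, n_snps = 25, seed = 10)
  expect_false(identical(simulate_genotypes(cfg2)$values, c1$genotypes$values))
})

test_that("XOR penetrance is purely epistatic: no marginal MI, positive pair IG", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 6,
                    main_effect_snps = data.frame(snp = integer(0), beta = numeric(0)),
                    epistatic_pairs = list(list(snp_a = 2, snp_b = 5,
                                                penetrance = xor_penetrance(0.6, 0.4))),
                    covariate_model = c(intercept = 0, age = 0, age2 = 0, sex = 0),
                    missing_rate = 0, seed = 4)
  coh <- simulate_cohort(cfg)
  y <- attr(coh$phenotypes, "sim_truth")$latent_case
  mi_a <- mutual_information(table(coh$genotypes$values[, 2], y))
  mi_b <- mutual_information(table(coh$genotypes$values[, 5], y))
  ig <- information_gain(coh$genotypes$values[, 2], coh$genotypes$values[, 5], y)
  expect_lt(mi_a, 0.003)
  expect_lt(mi_b, 0.003)
  expect_gt(ig, 0.005)
})

test_that("with all effects zero the case fraction is logistic(intercept)", {
  cfg <- do.call(sim_config, c(list(
    n_individuals = 5000, n_snps = 4,
    covariate_model = c(intercept = -0.5, age = 0, age2 = 0, sex = 0),
    missing_rate = 0, seed = 5), no_effects))
  coh <- simulate_cohort(cfg)
  frac <- mean(attr(coh$phenotypes, "sim_truth")$latent_case)
  p0 <- plogis(-0.5)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 5000))
})

test_that("a flat penetrance table carries no interaction signal", {
  flat <- matrix(0.5, 3, 3)
  cfg <- sim_config(n_individuals = 5000, n_snps = 6,
                    main_effect_snps = data.frame(snp = integer(0), beta = numeric(0)),
                    epistatic_pairs = list(list(snp_a = 1, snp_b = 4, penetrance = flat)),
                    covariate_model = c(intercept = 0, age = 0, age2 = 0, sex = 0),
                    missing_rate = 0, seed = 6)
  coh <- simulate_cohort(cfg)
  y <- attr(coh$phenotypes, "sim_truth")$latent_case
  ig <- information_gain(coh$genotypes$values[, 1], coh$genotypes$values[, 4], y)
  expect_lt(abs(ig), 0.01)
})

test_that("phenotypes respect cohort design: ages, BMI consistency, dimensions", {
  coh <- small_cohort(seed = 8, n = 400, m = 10)
  ph <- coh$phenotypes
  expect_true(all(ph$age >= 29 & ph$age <= 61))
  expect_equal(ph$bmi, ph$weight / ph$height^2, tolerance = 1e-12)
  expect_equal(ph$obese, ph$bmi > 30)
  # case/control split near 50/50 under the default covariate model
  expect_gt(mean(ph$status == "case"), 0.35)
  expect_lt(mean(ph$status == "case"), 0.65)
  # mismatched dimensions are rejected
  cfg_small <- sim_config(n_individuals = 100, n_snps = 10, seed = 1)
  expect_error(simulate_phenotype(coh$genotypes, cfg_small), "declares")
})

test_that("SNPs land in gene windows so multi-gene labels occur", {
  cfg <- sim_config(n_individuals = 50, n_snps = 240, seed = 12)
  g <- simulate_genotypes(cfg)
  mem <- suppressWarnings(map_snps_to_genes(g, cfg$gene_windows))
  expect_gt(sum(rowSums(mem) > 0), 0.8 * 240 * cfg$prop_in_genes * 0.9)
  expect_gt(sum(rowSums(mem) >= 2), 0)   # overlapping windows produce 2-label SNPs
  expect_gt(sum(rowSums(mem) == 0), 0)   # and some SNPs stay intergenic
})
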