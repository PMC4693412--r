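# Synthetic genotype/phenotype/annotation generator.
#
# Emulates the statistical structure the analysis assumes: Hardy-Weinberg
# genotypes with block LD (Gaussian copula over a latent AR(1) process),
# SNPs placed inside padded gene windows (some overlapping, so SNPs can
# carry several gene labels), a dichotomous phenotype driven by covariates,
# additive main effects and purely epistatic penetrance tables, and BMI
# values straddling the 30 kg/m^2 cut so dichotomization and covariate
# adjustment are exercised downstream.

#' XOR-style pure-epistasis penetrance table
#'
#' A 3x3 case-probability table with checkerboard structure
#' (`high`/`low`/`high` alternating). At minor allele frequency 0.5 the
#' genotype-weighted row and column margins are uniform, so neither SNP has
#' a marginal effect while the pair is jointly informative.
#'
#' @param high,low case probabilities on the two checkerboard cell classes.
#' @return A 3x3 numeric matrix (rows: genotype of SNP A; columns: SNP B).
#' @export
xor_penetrance <- function(high = 0.6, low = 0.4) {
  matrix(c(high, low, high,
           low, high, low,
           high, low, high), 3, 3, byrow = TRUE)
}

# Default 12-gene annotation with synthetic coordinates; the BDNF/MTCH2
# padded windows on chromosome 11 overlap, so SNPs there carry two labels.
default_gene_windows <- function(window_pad = 5e5) {
  gene_annotation(
    gene = c("NEGR1", "SEC16B", "TMEM18", "ETV5", "GNPDA2", "BDNF",
             "MTCH2", "FAIM2", "FTO", "SH2B1", "MC4R", "KCTD15"),
    chrom = c("1", "1", "2", "3", "4", "11", "11", "12", "16", "16", "18", "19"),
    start = c(72.0e6, 177.9e6, 0.60e6, 185.8e6, 44.7e6, 27.6e6,
              28.4e6, 50.2e6, 53.7e6, 28.8e6, 58.0e6, 34.2e6),
    end = c(72.8e6, 178.0e6, 0.65e6, 185.9e6, 44.8e6, 27.7e6,
            28.5e6, 50.3e6, 54.1e6, 28.9e6, 58.1e6, 34.3e6),
    window_pad = window_pad
  )
}

.default_main_effects <- function(n_snps, n = 5, beta = 0.4) {
  if (n == 0) return(data.frame(snp = integer(0), beta = numeric(0)))
  idx <- unique(pmax(1, round(n_snps * seq(0.10, 0.90, length.out = n))))
  data.frame(snp = idx, beta = beta)
}

.default_epistatic_pairs <- function(n_snps, n = 5, penetrance = xor_penetrance()) {
  if (n == 0) return(list())
  fa <- c(0.05, 0.20, 0.25, 0.40, 0.15)[seq_len(n)]
  fb <- c(0.45, 0.60, 0.65, 0.80, 0.85)[seq_len(n)]
  lapply(seq_len(n), function(i) {
    list(snp_a = max(1, round(n_snps * fa[i])),
         snp_b = max(1, round(n_snps * fb[i])),
         penetrance = penetrance)
  })
}

#' Simulation configuration
#'
#' Collects and validates all generator settings. Defaults emulate the
#' study design the pipeline targets: ~1141 individuals x 1191 SNPs across
#' twelve gene windows, MAF in `[0.05, 0.5]`, block LD, five main-effect
#' SNPs and five purely epistatic SNP pairs, and a covariate model on age,
#' age^2 and sex.
#'
#' @param n_individuals,n_snps cohort dimensions.
#' @param maf_range minor-allele-frequency range (within `[0.05, 0.5]`),
#'   sampled uniformly per SNP.
#' @param ld_block_size SNPs per correlated block (blocks never span gene
#'   boundaries).
#' @param ld_rho latent AR(1) correlation within a block, in `[0, 1)`.
#' @param gene_windows a [gene_annotation()] table (defaults to twelve
#'   synthetic obesity-candidate windows, two of them overlapping).
#' @param main_effect_snps data frame `snp` (index), `beta` (log-odds per
#'   minor allele); `NULL` for the default five.
#' @param epistatic_pairs list of `list(snp_a, snp_b, penetrance)` with a
#'   3x3 case-probability table; `NULL` for five default XOR pairs.
#' @param covariate_model named numeric `c(intercept, age, age2, sex)`;
#'   age terms apply to age centered at 45 years, sex to (male - 0.5).
#' @param main_effect_maf MAF assigned to main-effect SNPs (common-variant
#'   regime; default 0.3).
#' @param epistatic_maf MAF assigned to SNPs in epistatic pairs (0.5 keeps
#'   XOR-style tables margin-free, i.e. purely epistatic).
#' @param missing_rate fraction of genotype calls set missing.
#' @param prop_in_genes fraction of SNPs placed inside gene windows (the
#'   rest land on an unannotated chromosome).
#' @param bmi_case_mean,bmi_control_mean,bmi_sd BMI distribution by latent
#'   case status (overlapping normals across the 30 kg/m^2 cut).
#' @param seed integer root seed; identical seeds give bit-identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1141, n_snps = 1191,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 3, ld_rho = 0.95,
                       gene_windows = default_gene_windows(),
                       main_effect_snps = NULL,
                       epistatic_pairs = NULL,
                       covariate_model = c(intercept = 0, age = 0.02,
                                           age2 = -5e-4, sex = 0.3),
                       main_effect_maf = 0.3, epistatic_maf = 0.5,
                       missing_rate = 0.01, prop_in_genes = 0.9,
                       bmi_case_mean = 33.5, bmi_control_mean = 26.5,
                       bmi_sd = 2, seed = 1) {
  if (n_individuals < 2) stop("invalid n_individuals: need at least 2")
  if (n_snps < 2) stop("invalid n_snps: need at least 2")
  if (length(maf_range) != 2 || any(maf_range < 0.05) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("invalid maf_range: must be an increasing pair within [0.05, 0.5]")
  }
  if (ld_block_size < 1) stop("invalid ld_block_size: must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("invalid ld_rho: must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (prop_in_genes < 0 || prop_in_genes > 1) stop("invalid prop_in_genes")
  if (is.null(main_effect_snps)) {
    main_effect_snps <- .default_main_effects(n_snps)
  }
  if (is.null(epistatic_pairs)) {
    epistatic_pairs <- .default_epistatic_pairs(n_snps)
  }
  if (nrow(main_effect_snps) > 0 &&
      (any(main_effect_snps$snp < 1) || any(main_effect_snps$snp > n_snps))) {
    stop("invalid main_effect_snps: SNP index out of range")
  }
  for (p in epistatic_pairs) {
    if (p$snp_a == p$snp_b) stop("invalid epistatic_pairs: indices must be distinct")
    if (any(c(p$snp_a, p$snp_b) < 1) || any(c(p$snp_a, p$snp_b) > n_snps)) {
      stop("invalid epistatic_pairs: SNP index out of range")
    }
    if (!all(dim(p$penetrance) == c(3, 3))) {
      stop("invalid epistatic_pairs: penetrance must be a 3x3 table")
    }
    if (any(p$penetrance < 0) || any(p$penetrance > 1)) {
      stop("invalid epistatic_pairs: penetrance entries must be in [0, 1]")
    }
  }
  req <- c("intercept", "age", "age2", "sex")
  if (!all(req %in% names(covariate_model))) {
    stop("invalid covariate_model: need named coefficients ",
         paste(req, collapse = ", "))
  }
  structure(
    list(n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
         maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
         ld_rho = ld_rho, gene_windows = gene_windows,
         main_effect_snps = main_effect_snps, epistatic_pairs = epistatic_pairs,
         covariate_model = covariate_model,
         main_effect_maf = main_effect_maf, epistatic_maf = epistatic_maf,
         missing_rate = missing_rate, prop_in_genes = prop_in_genes,
         bmi_case_mean = bmi_case_mean, bmi_control_mean = bmi_control_mean,
         bmi_sd = bmi_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a genotype matrix
#'
#' Each SNP is drawn under Hardy-Weinberg proportions at its MAF. SNPs
#' within an LD block share a latent AR(1) Gaussian variable (Gaussian
#' copula) thresholded at the HWE quantiles, so neighboring genotypes are
#' correlated at roughly `ld_rho` without haplotype machinery; blocks never
#' span gene boundaries. SNP positions are placed inside the declared gene
#' windows (a `prop_in_genes` fraction) with the remainder on an
#' unannotated chromosome.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] with attribute `maf` (the generating
#'   frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  ann <- config$gene_windows
  with_seed(fan_seed(config$seed, "genotype"), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    if (nrow(config$main_effect_snps) > 0) {
      maf[config$main_effect_snps$snp] <- config$main_effect_maf
    }
    for (p in config$epistatic_pairs) maf[c(p$snp_a, p$snp_b)] <- config$epistatic_maf

    # positions: contiguous runs of SNPs per gene, remainder intergenic
    n_in <- round(m * config$prop_in_genes)
    ngene <- nrow(ann)
    per_gene <- rep(n_in %/% ngene, ngene)
    if (n_in %% ngene > 0) per_gene[seq_len(n_in %% ngene)] <- per_gene[seq_len(n_in %% ngene)] + 1
    group <- c(rep(seq_len(ngene), per_gene), rep(0L, m - n_in))
    chrom <- character(m)
    pos <- integer(m)
    for (k in seq_len(ngene)) {
      idx <- which(group == k)
      if (!length(idx)) next
      pad <- ann$window_pad[k]
      lo <- max(1, ann$start[k] - pad)
      hi <- ann$end[k] + pad
      chrom[idx] <- ann$chrom[k]
      pos[idx] <- sort(as.integer(stats::runif(length(idx), lo, hi)))
    }
    inter <- which(group == 0L)
    if (length(inter)) {
      chrom[inter] <- "22"
      pos[inter] <- sort(as.integer(stats::runif(length(inter), 5e6, 15e6)))
    }

    # latent AR(1) within blocks, restarting at gene boundaries
    z <- matrix(stats::rnorm(n * m), n, m)
    rho <- config$ld_rho
    if (rho > 0 && config$ld_block_size > 1) {
      pos_in_block <- stats::ave(seq_len(m), group,
                                 FUN = function(i) (seq_along(i) - 1) %% config$ld_block_size)
      for (j in seq_len(m)[-1]) {
        if (group[j] == group[j - 1] && pos_in_block[j] > 0) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
    }
    u <- stats::pnorm(z)
    q0 <- (1 - maf)^2
    q1 <- 2 * maf * (1 - maf)
    vals <- (u > rep(q0, each = n)) + (u > rep(q0 + q1, each = n))
    storage.mode(vals) <- "integer"
    if (config$missing_rate > 0) {
      vals[stats::runif(n * m) < config$missing_rate] <- NA_integer_
    }
    g <- genotype_matrix(vals,
                         snp_ids = sprintf("snp%04d", seq_len(m)),
                         chrom = chrom, pos = pos,
                         individual_ids = sprintf("ind%04d", seq_len(n)))
    attr(g, "maf") <- maf
    g
  })
}

#' Simulate phenotypes for a genotype matrix
#'
#' Ages are uniform on 29 to 61 years, sex Bernoulli(0.5). The per-
#' individual case probability combines the covariate model log-odds
#' (centered age/age^2/sex terms), additive main effects (log-odds per
#' minor allele, dosage-centered), and for each epistatic pair the
#' log-odds implied by its 3x3 penetrance table. BMI is drawn from
#' overlapping normals around the 30 kg/m^2 cut given the latent case
#' status, and weight is derived from BMI and a sex-specific height, so
#' downstream dichotomization recovers the latent status up to realistic
#' misclassification near the cut.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return A [phenotype_table()] with attribute `sim_truth`
#'   (`latent_case`, `p_case`).
#' @export
simulate_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$values)
  if (n != config$n_individuals) {
    stop(sprintf("genotypes have %d individuals but config declares %d",
                 n, config$n_individuals))
  }
  vals <- genotypes$values
  # effects are computed on mode-filled dosages so missing calls don't propagate
  fill <- function(j) {
    x <- vals[, j]
    if (anyNA(x)) {
      mode_g <- which.max(tabulate(x[!is.na(x)] + 1L, 3L)) - 1L
      x[is.na(x)] <- mode_g
    }
    x
  }
  with_seed(fan_seed(config$seed, "phenotype"), {
    age <- stats::runif(n, 29, 61)
    male <- stats::rbinom(n, 1, 0.5)
    b <- config$covariate_model
    lin <- b[["intercept"]] + b[["age"]] * (age - 45) +
      b[["age2"]] * (age - 45)^2 + b[["sex"]] * (male - 0.5)
    if (nrow(config$main_effect_snps) > 0) {
      for (i in seq_len(nrow(config$main_effect_snps))) {
        dos <- fill(config$main_effect_snps$snp[i])
        lin <- lin + config$main_effect_snps$beta[i] * (dos - mean(dos))
      }
    }
    for (p in config$epistatic_pairs) {
      a <- fill(p$snp_a)
      bb <- fill(p$snp_b)
      pen <- pmin(pmax(p$penetrance, 1e-12), 1 - 1e-12)
      lin <- lin + stats::qlogis(pen[cbind(a + 1L, bb + 1L)])
    }
    p_case <- stats::plogis(lin)
    case <- stats::rbinom(n, 1, p_case)
    bmi <- stats::rnorm(n,
                        ifelse(case == 1, config$bmi_case_mean, config$bmi_control_mean),
                        config$bmi_sd)
    bmi <- pmax(bmi, 15)
    height <- stats::rnorm(n, ifelse(male == 1, 1.76, 1.63),
                           ifelse(male == 1, 0.07, 0.06))
    height <- pmax(height, 1.3)
    weight <- bmi * height^2
    pheno <- phenotype_table(
      individual_id = genotypes$individual_ids,
      age = age, sex = ifelse(male == 1, "male", "female"),
      weight = weight, height = height
    )
    attr(pheno, "sim_truth") <- list(latent_case = case, p_case = p_case)
    pheno
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper returning genotypes, phenotypes and the gene
#' annotation in one list.
#'
#' @param config a [sim_config()].
#' @return List with `genotypes`, `phenotypes`, `annotation`, `config`.
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  phenotypes <- simulate_phenotype(genotypes, config)
  list(genotypes = genotypes, phenotypes = phenotypes,
       annotation = config$gene_windows, config = config)
}
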