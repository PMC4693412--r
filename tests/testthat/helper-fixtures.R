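# In-code fixtures shared across test files.

# Hand-built epistasis_scores object with full control over pair IG values.
make_scores <- function(snp_ids, pairs, mi = NULL) {
  if (is.null(mi)) mi <- stats::setNames(rep(0.01, length(snp_ids)), snp_ids)
  structure(
    list(snp_ids = snp_ids, mi = mi, pairs = pairs,
         n_individuals = 100L, log_base = 2),
    class = "epistasis_scores"
  )
}

# Complete pair table over snp_ids with a constant background IG,
# overridden for selected pairs.
pair_table <- function(snp_ids, background = 0, override = NULL) {
  cmb <- t(utils::combn(snp_ids, 2))
  pairs <- data.frame(snp_a = cmb[, 1], snp_b = cmb[, 2], ig = background,
                      stringsAsFactors = FALSE)
  if (!is.null(override)) {
    for (i in seq_len(nrow(override))) {
      hit <- (pairs$snp_a == override$snp_a[i] & pairs$snp_b == override$snp_b[i]) |
        (pairs$snp_a == override$snp_b[i] & pairs$snp_b == override$snp_a[i])
      pairs$ig[hit] <- override$ig[i]
    }
  }
  pairs
}

# Small simulated cohort with the phenotype run through the full
# dichotomize + covariate-adjust chain.
small_cohort <- function(seed, n = 300, m = 20, mains = NULL, pairs = NULL,
                         missing_rate = 0, ...) {
  cfg <- sim_config(
    n_individuals = n, n_snps = m,
    main_effect_snps = if (is.null(mains)) data.frame(snp = integer(0), beta = numeric(0)) else mains,
    epistatic_pairs = if (is.null(pairs)) list() else pairs,
    missing_rate = missing_rate, seed = seed, ...
  )
  coh <- simulate_cohort(cfg)
  ph <- adjust_and_classify(coh$phenotypes)
  coh$status <- ph$status[match(coh$genotypes$individual_ids, ph$individual_id)]
  coh$phenotypes <- ph
  coh
}
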