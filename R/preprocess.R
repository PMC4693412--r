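# Data-preparation stages: BMI computation and dichotomization, covariate
# adjustment with deviance-residual classification, MAF filtering, LD
# pruning, mode imputation and SNP-to-gene window mapping.
#
# Pipeline order matters: filter_maf() then ld_prune() then impute_mode(),
# so allele frequencies and r2 are computed on pre-imputation calls.

#' Body mass index from weight and height
#'
#' `BMI = weight (kg) / height (m)^2`.
#'
#' @param weight body weight in kilograms (positive).
#' @param height standing height in metres (positive).
#' @return BMI in kg/m^2; vectorized.
#' @examples
#' compute_bmi(81, 1.8)    # 25
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height))) {
    stop("weight and height must be finite")
  }
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(height <= 0)) stop("height must be positive")
  weight / height^2
}

#' Dichotomize BMI into obese / non-obese
#'
#' Obese is defined strictly as BMI > 30 kg/m^2; a BMI of exactly 30 is
#' classified non-obese.
#'
#' @param bmi numeric BMI values (finite).
#' @param cut threshold in kg/m^2 (default 30).
#' @return Logical vector, `TRUE` = obese.
#' @export
dichotomize_bmi <- function(bmi, cut = 30) {
  if (any(!is.finite(bmi))) stop("bmi must be finite")
  bmi > cut
}

#' Phenotype table constructor
#'
#' Assembles per-individual phenotype data, deriving BMI from weight and
#' height when not supplied, and the obese indicator from BMI.
#'
#' @param individual_id unique identifiers.
#' @param age age in years.
#' @param sex `"male"` / `"female"`.
#' @param weight,height optional weight (kg) and height (m).
#' @param bmi optional BMI; computed from weight/height when `NULL`.
#' @return A data frame of class `phenotype_table` with columns
#'   `individual_id`, `weight`, `height`, `bmi`, `age`, `sex`, `obese`.
#' @export
phenotype_table <- function(individual_id, age, sex,
                            weight = NULL, height = NULL, bmi = NULL) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) stop("duplicate individual_id")
  n <- length(individual_id)
  if (is.null(bmi)) {
    if (is.null(weight) || is.null(height)) {
      stop("supply bmi, or both weight and height")
    }
    bmi <- compute_bmi(weight, height)
  }
  if (is.null(weight)) weight <- rep(NA_real_, n)
  if (is.null(height)) height <- rep(NA_real_, n)
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  out <- data.frame(
    individual_id = individual_id, weight = weight, height = height,
    bmi = bmi, age = age, sex = sex, obese = dichotomize_bmi(bmi),
    stringsAsFactors = FALSE
  )
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Covariate adjustment and deviance-residual classification
#'
#' Fits a binomial GLM (logit link) of the obese indicator on age, age^2 and
#' sex, then classifies individuals with deviance residual > 0 as cases and
#' the rest as controls. Because the sign of a binomial deviance residual
#' equals the sign of `y - fitted`, the classification is 100% concordant
#' with the obese indicator whenever fitted probabilities lie strictly in
#' (0, 1); the realized concordance is recorded on the result.
#'
#' Individuals with missing age, sex or obese status are dropped with a
#' message.
#'
#' @param pheno a [phenotype_table()] (columns `obese`, `age`, `sex`).
#' @return The phenotype table with an added `status` column
#'   (`"case"`/`"control"`) and attributes `concordance` (fraction agreeing
#'   with `obese`) and `n_dropped`.
#' @export
adjust_and_classify <- function(pheno) {
  req <- c("obese", "age", "sex")
  miss <- setdiff(req, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(pheno[, req])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("adjust_and_classify: dropping %d individuals with missing covariates", n_dropped))
    pheno <- pheno[keep, , drop = FALSE]
  }
  y <- pheno$obese
  if (length(unique(y)) < 2) {
    stop("obese indicator is constant; cannot fit covariate model")
  }
  dat <- data.frame(y = as.integer(y), age = pheno$age,
                    sex = as.integer(pheno$sex == "male"))
  fit <- stats::glm(y ~ age + I(age^2) + sex, family = stats::binomial(), data = dat)
  if (!fit$converged) {
    stop(sprintf("covariate GLM did not converge after %d IWLS iterations", fit$iter))
  }
  dr <- stats::residuals(fit, type = "deviance")
  status <- ifelse(dr > 0, "case", "control")
  pheno$status <- status
  attr(pheno, "concordance") <- mean((status == "case") == y)
  attr(pheno, "n_dropped") <- n_dropped
  pheno
}

#' Minor allele frequency per SNP
#'
#' `min(p, 1 - p)` with `p` the mean dosage over non-missing calls divided
#' by 2. SNPs with no non-missing calls get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector of MAFs.
#' @export
snp_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$values, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA_real_
  stats::setNames(maf, g$snp_ids)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF >= `threshold` (the exclusion rule is strict:
#' MAF < threshold is removed, so a SNP at exactly the threshold survives).
#' SNPs with all calls missing are excluded and reported.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF cutoff, default 0.05.
#' @return Filtered `genotype_matrix` with attribute `dropped` (SNP ids).
#' @export
filter_maf <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  maf <- snp_maf(g)
  all_missing <- is.na(maf)
  if (any(all_missing)) {
    message("filter_maf: excluding SNPs with all calls missing: ",
            paste(g$snp_ids[all_missing], collapse = ", "))
  }
  keep <- !all_missing & maf >= threshold
  out <- subset_snps(g, keep)
  attr(out, "dropped") <- g$snp_ids[!keep]
  out
}

#' Greedy LD pruning by pairwise r-squared
#'
#' SNPs are scanned in genomic order (chromosome, position). For each
#' surviving SNP, every later SNP on the same chromosome whose squared
#' Pearson correlation of dosages (pairwise-complete over non-missing
#' calls) exceeds `r2_threshold` is removed. Zero-variance SNPs have r2
#' defined as 0 against all partners and are never removed on LD grounds.
#'
#' @param g a [genotype_matrix()].
#' @param r2_threshold r^2 cutoff, default 0.8 (strictly greater is pruned).
#' @return Pruned `genotype_matrix`, SNPs in genomic order, with attribute
#'   `dropped`.
#' @export
ld_prune <- function(g, r2_threshold = 0.8) {
  stopifnot(inherits(g, "genotype_matrix"))
  ord <- order(g$chrom, g$pos)
  g <- subset_snps(g, ord)
  m <- ncol(g$values)
  removed <- logical(m)
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(g$values[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0   # zero-variance or no complete pairs
    r2 <- cm^2
    k <- length(idx)
    for (i in seq_len(k - 1)) {
      if (removed[idx[i]]) next
      later <- (i + 1):k
      hit <- later[!removed[idx[later]] & r2[i, later] > r2_threshold]
      removed[idx[hit]] <- TRUE
    }
  }
  out <- subset_snps(g, !removed)
  attr(out, "dropped") <- g$snp_ids[removed]
  out
}

#' Impute missing genotypes with the per-SNP modal genotype
#'
#' Every missing call is replaced by the most frequent genotype of that SNP
#' across all individuals; ties are broken toward the lowest dosage for
#' determinism.
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` with no missing entries.
#' @export
impute_mode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$values
  for (j in seq_len(ncol(vals))) {
    mis <- is.na(vals[, j])
    if (!any(mis)) next
    if (all(mis)) {
      stop(sprintf("SNP %s has no observed genotypes; drop it with filter_maf() first",
                   g$snp_ids[j]))
    }
    counts <- tabulate(vals[!mis, j] + 1L, nbins = 3L)
    vals[mis, j] <- which.max(counts) - 1L   # which.max takes the first (lowest dosage) on ties
  }
  genotype_matrix(vals, snp_ids = g$snp_ids, chrom = g$chrom, pos = g$pos,
                  individual_ids = g$individual_ids)
}

#' Gene annotation table
#'
#' Gene intervals on 1-based, fully closed coordinates. Each gene defines a
#' membership window `[start - pad, end + pad]` (clipped at 0); a SNP whose
#' position falls inside the window on the same chromosome carries that
#' gene's label.
#'
#' @param gene gene names (unique).
#' @param chrom chromosome per gene.
#' @param start,end 1-based interval ends, `start <= end`.
#' @param window_pad padding in bp added on each side (default 500,000).
#' @return A data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, chrom, start, end, window_pad = 5e5) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene names")
  if (any(start > end)) stop("gene intervals must have start <= end")
  out <- data.frame(gene = gene, chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    window_pad = as.numeric(window_pad),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Map SNPs to gene labels by padded windows
#'
#' A SNP receives gene label G iff its position lies in G's padded window
#' (closed interval, boundary positions included) on the same chromosome.
#' SNPs may carry multiple labels (overlapping windows) or none.
#'
#' @param g a [genotype_matrix()].
#' @param ann a [gene_annotation()] table.
#' @return Logical membership matrix, SNPs in rows (named by SNP id), genes
#'   in columns.
#' @export
map_snps_to_genes <- function(g, ann) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(c("gene", "chrom", "start", "end") %in% names(ann))) {
    stop("annotation must have columns gene, chrom, start, end")
  }
  pad <- if ("window_pad" %in% names(ann)) ann$window_pad else rep(5e5, nrow(ann))
  membership <- matrix(FALSE, ncol(g$values), nrow(ann),
                       dimnames = list(g$snp_ids, ann$gene))
  for (k in seq_len(nrow(ann))) {
    lo <- max(0, ann$start[k] - pad[k])
    hi <- ann$end[k] + pad[k]
    membership[, k] <- g$chrom == ann$chrom[k] & g$pos >= lo & g$pos <= hi
  }
  orphan_chr <- setdiff(unique(g$chrom), unique(ann$chrom))
  if (length(orphan_chr)) {
    warning("SNPs on chromosomes without annotation remain unlabeled: ",
            paste(orphan_chr, collapse = ", "))
  }
  membership
}
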