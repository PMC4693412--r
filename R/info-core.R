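# Plug-in information-theoretic estimators over categorical variables.
#
# All quantities are maximum-likelihood ("plug-in") estimates computed from
# empirical frequencies, reported in bits (log base 2) unless noted. No
# small-sample bias correction is applied.

#' Shannon entropy of a probability vector
#'
#' \eqn{H(X) = -\sum_x p(x) \log_2 p(x)}, with \eqn{0 \log 0 = 0}.
#'
#' @param p numeric vector of probabilities (non-negative, summing to 1
#'   within 1e-9).
#' @param base logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @return Entropy in the units implied by `base`.
#' @examples
#' entropy(c(0.5, 0.5))        # 1 bit
#' entropy(rep(1 / 3, 3))      # log2(3)
#' @export
entropy <- function(p, base = 2) {
  if (!is.numeric(p) || length(p) == 0) stop("p must be a non-empty numeric vector")
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1 (tolerance 1e-9)")
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Conditional entropy H(C | A) from a contingency table
#'
#' Computed from plug-in frequencies as `H(A, C) - H(A)`, with `A` on the
#' rows and `C` on the columns of the count table.
#'
#' @param joint two-dimensional matrix/table of non-negative counts with a
#'   positive total.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(joint) {
  joint <- .check_joint(joint)
  .count_entropy(joint) - .count_entropy(rowSums(joint))
}

#' Mutual information I(A; C) from a contingency table
#'
#' `H(C) - H(C | A)`, equivalently `H(A) + H(C) - H(A, C)`. Non-negative up
#' to rounding; tiny negative values (> -1e-12) are clipped to 0.
#'
#' @inheritParams conditional_entropy
#' @return Mutual information in bits.
#' @examples
#' mutual_information(matrix(c(30, 10, 10, 30), 2))
#' @export
mutual_information <- function(joint) {
  joint <- .check_joint(joint)
  mi <- .count_entropy(rowSums(joint)) + .count_entropy(colSums(joint)) -
    .count_entropy(joint)
  max(mi, 0)
}

.check_joint <- function(joint) {
  joint <- as.matrix(joint)
  if (length(dim(joint)) != 2) stop("joint must be a two-dimensional table")
  if (any(joint < 0)) stop("counts must be non-negative")
  if (sum(joint) <= 0) stop("empty contingency table")
  joint
}

#' Information gain of a SNP pair about a dichotomous phenotype
#'
#' `IG(A; B; C) = I(A,B; C) - I(A; C) - I(B; C)`: the mutual information of
#' the joint genotype (a 9-level composite of the two 3-level SNPs) with the
#' class, minus both marginal mutual informations. Positive values indicate
#' synergy (pure epistasis); negative values indicate redundancy.
#'
#' @param a,b genotype vectors with values in `{0, 1, 2}`.
#' @param c_class binary class vector (0/1, logical, or `"case"`/`"control"`).
#' @return Information gain in bits (may be negative).
#' @examples
#' a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
#' information_gain(a, b, xor(a, b))   # XOR synergy: 1 bit
#' @export
information_gain <- function(a, b, c_class) {
  if (length(a) != length(b) || length(a) != length(c_class)) {
    stop("a, b and c_class must have equal lengths")
  }
  a <- .check_geno_vec(a, "a")
  b <- .check_geno_vec(b, "b")
  y <- as_status01(c_class)
  n <- length(a)
  f_abc <- tabulate(a * 6L + b * 2L + y + 1L, nbins = 18L)
  f_ab <- tabulate(a * 3L + b + 1L, nbins = 9L)
  f_ac <- tabulate(a * 2L + y + 1L, nbins = 6L)
  f_bc <- tabulate(b * 2L + y + 1L, nbins = 6L)
  f_a <- tabulate(a + 1L, nbins = 3L)
  f_b <- tabulate(b + 1L, nbins = 3L)
  f_c <- tabulate(y + 1L, nbins = 2L)
  # IG = I(AB;C) - I(A;C) - I(B;C) written in terms of sum(n_cell log2 n_cell)
  (sum(plogp2(f_abc)) - sum(plogp2(f_ab)) - sum(plogp2(f_ac)) -
      sum(plogp2(f_bc)) + sum(plogp2(f_a)) + sum(plogp2(f_b)) +
      sum(plogp2(f_c))) / n - log2(n)
}

.check_geno_vec <- function(x, name) {
  if (anyNA(x)) stop(name, " contains missing genotypes")
  if (!all(x %in% c(0, 1, 2))) stop(name, " must contain only 0/1/2")
  as.integer(x)
}

#' Scan all SNP pairs for information gain about a phenotype
#'
#' Computes the mutual information of every SNP with the class and the
#' information gain of every unordered SNP pair, from 3x3x2 contingency
#' tables. Implemented with an indicator-matrix cross-product so all pair
#' tables are obtained from two matrix products; deterministic.
#'
#' @param g a [genotype_matrix()] (no missing entries; run [impute_mode()]
#'   first) or a plain integer matrix of 0/1/2 dosages.
#' @param status binary case/control vector, one entry per individual.
#' @param log_base 2 for bits (default) or `exp(1)` for nats.
#' @return An object of class `epistasis_scores`: list with `snp_ids`,
#'   `mi` (named numeric, per-SNP mutual information), `pairs` (data frame
#'   `snp_a`, `snp_b`, `ig`), `n_individuals`, `log_base`.
#' @export
pairwise_ig_scan <- function(g, status, log_base = 2) {
  if (inherits(g, "genotype_matrix")) {
    vals <- g$values
    ids <- g$snp_ids
  } else {
    vals <- as.matrix(g)
    ids <- colnames(vals)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(vals)))
  }
  if (anyNA(vals)) stop("genotypes contain missing values; run impute_mode() first")
  if (!all(vals %in% c(0L, 1L, 2L))) stop("genotype values must be 0/1/2")
  y <- as_status01(status)
  n <- nrow(vals)
  m <- ncol(vals)
  if (length(y) != n) stop("status length must equal the number of individuals")
  if (m < 2) stop("need at least two SNPs to scan pairs")
  n1 <- sum(y)
  if (n1 == 0 || n1 == n) stop("status must contain both cases and controls")

  # one-hot genotype indicators: n x 3m
  Z <- matrix(0, n, 3L * m)
  cols <- 3L * (rep(seq_len(m), each = n) - 1L) + as.vector(vals) + 1L
  Z[cbind(rep(seq_len(n), m), cols)] <- 1
  Z0 <- Z[y == 0L, , drop = FALSE]
  Z1 <- Z[y == 1L, , drop = FALSE]
  N0 <- crossprod(Z0)   # (snp level) x (snp level) co-counts among controls
  N1 <- crossprod(Z1)

  grp <- rep(seq_len(m), each = 3L)
  blocksum <- function(M) t(rowsum(t(rowsum(M, grp)), grp))  # 3x3 block sums
  F_abc <- blocksum(plogp2(N0)) + blocksum(plogp2(N1))
  F_ab <- blocksum(plogp2(N0 + N1))
  c0 <- colSums(Z0)
  c1 <- colSums(Z1)
  F_ac <- rowsum(plogp2(c0) + plogp2(c1), grp)[, 1]
  F_a <- rowsum(plogp2(c0 + c1), grp)[, 1]
  F_c <- plogp2(n - n1) + plogp2(n1)

  mi <- pmax(log2(n) + (F_ac - F_a - F_c) / n, 0)
  IG <- -log2(n) +
    (F_abc - F_ab - outer(F_ac, F_ac, "+") + outer(F_a, F_a, "+") + F_c) / n

  if (any(!is.finite(mi)) || any(!is.finite(IG[upper.tri(IG)]))) {
    bad <- which(!is.finite(IG) & upper.tri(IG), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite score for pair (%s, %s)", ids[bad[1]], ids[bad[2]]))
  }

  ut <- which(upper.tri(IG), arr.ind = TRUE)
  pairs <- data.frame(
    snp_a = ids[ut[, 1]], snp_b = ids[ut[, 2]],
    ig = IG[ut], stringsAsFactors = FALSE
  )
  scale <- if (isTRUE(all.equal(log_base, 2))) 1 else log(2, base = log_base)
  structure(
    list(snp_ids = ids, mi = stats::setNames(mi * scale, ids),
         pairs = transform(pairs, ig = ig * scale),
         n_individuals = n, log_base = log_base),
    class = "epistasis_scores"
  )
}

#' @export
print.epistasis_scores <- function(x, ...) {
  cat(sprintf("<epistasis_scores> %d SNPs, %d pairs (n = %d individuals)\n",
              length(x$snp_ids), nrow(x$pairs), x$n_individuals))
  cat(sprintf("  MI  range: [%.5f, %.5f]\n", min(x$mi), max(x$mi)))
  cat(sprintf("  IG  range: [%.5f, %.5f]\n", min(x$pairs$ig), max(x$pairs$ig)))
  invisible(x)
}

#' Export epistasis scores as node and edge tables
#'
#' Writes a two-column node table (`snp`, `mi_bits`) and a three-column edge
#' table (`snp_a`, `snp_b`, `ig_bits`), tab-separated.
#'
#' @param scores an `epistasis_scores` object.
#' @param node_path,edge_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_scores <- function(scores, node_path, edge_path) {
  stopifnot(inherits(scores, "epistasis_scores"))
  nodes <- data.frame(snp = scores$snp_ids, mi_bits = unname(scores$mi))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- scores$pairs
  names(edges) <- c("snp_a", "snp_b", "ig_bits")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
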