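# Phenotype-shuffle permutation engine: null distributions for per-SNP MI,
# per-pair IG, and whole-network size statistics.
#
# Replicate r of a run with root seed s uses fan_seed(s, "permutation", r),
# so results are invariant to execution order and any subset of replicates
# can be reproduced in isolation.

#' Shuffle a case/control status vector
#'
#' Uniformly random permutation of the entries; case/control counts are
#' preserved exactly.
#'
#' @param status binary status vector (0/1, logical or `"case"`/`"control"`).
#' @param seed integer seed making the shuffle reproducible.
#' @return A vector of the same type and multiset of values, permuted.
#' @export
permute_status <- function(status, seed) {
  n <- length(status)
  idx <- with_seed(seed, sample.int(n))
  status[idx]
}

# One permutation_null record.
permutation_null <- function(statistic_name, observed, null_values, seed,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  R <- length(null_values)
  count <- if (tail == "upper") sum(null_values >= observed) else sum(null_values <= observed)
  pv <- format_pvalue(count, R)
  structure(
    list(statistic_name = statistic_name, observed = observed,
         null_values = null_values, p_value = pv$p, p_display = pv$display,
         R = R, seed = seed, tail = tail),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %s: observed %.6g, p %s (R = %d, %s tail)\n",
              x$statistic_name, x$observed, x$p_display, x$R, x$tail))
  invisible(x)
}

#' Null distribution of per-SNP MI and per-pair IG under phenotype shuffling
#'
#' Re-runs [pairwise_ig_scan()] on `R` phenotype-shuffled copies of the
#' data. Nulls are pooled per statistic (the same SNP or pair recomputed
#' under each shuffle), not across statistics.
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param status binary case/control vector.
#' @param R number of replicates.
#' @param seed root seed (fanned out per replicate).
#' @return List with `mi_null` (R x n_snps matrix) and `ig_null`
#'   (R x n_pairs matrix, columns in [pairwise_ig_scan()] pair order),
#'   plus `pair_ids` and `snp_ids`.
#' @export
null_score_distribution <- function(g, status, R, seed) {
  if (R < 1) stop("R must be >= 1")
  obs <- pairwise_ig_scan(g, status)
  mi_null <- matrix(NA_real_, R, length(obs$snp_ids))
  ig_null <- matrix(NA_real_, R, nrow(obs$pairs))
  for (r in seq_len(R)) {
    st <- permute_status(status, fan_seed(seed, "permutation", r))
    sc <- pairwise_ig_scan(g, st)
    mi_null[r, ] <- sc$mi
    ig_null[r, ] <- sc$pairs$ig
  }
  list(mi_null = mi_null, ig_null = ig_null,
       snp_ids = obs$snp_ids,
       pair_ids = paste(obs$pairs$snp_a, obs$pairs$snp_b, sep = ","),
       seed = seed)
}

#' Permutation significance of network size statistics
#'
#' For each replicate, shuffles the phenotype, rescans all pairs and
#' rebuilds networks at the fixed thresholds from the real-data sweep,
#' recording node count and largest-component size. Upper-tail p-values
#' are reported for the real network's statistics, with ties counted as
#' exceedances.
#'
#' @inheritParams null_score_distribution
#' @param thresholds thresholds from the real-data sweep (strictly
#'   decreasing).
#' @return A list with one element per threshold, each holding
#'   `permutation_null` records `n_nodes` and `lcc_size`, plus the observed
#'   sweep as attribute `observed`.
#' @export
null_network_statistics <- function(g, status, thresholds, R = 1000, seed = 1) {
  if (R < 1) stop("R must be >= 1")
  obs_scores <- pairwise_ig_scan(g, status)
  obs_series <- network_series(obs_scores, thresholds)
  nt <- length(thresholds)
  nodes_null <- matrix(NA_real_, R, nt)
  lcc_null <- matrix(NA_real_, R, nt)
  for (r in seq_len(R)) {
    st <- permute_status(status, fan_seed(seed, "permutation", r))
    sc <- pairwise_ig_scan(g, st)
    ser <- network_series(sc, thresholds)
    nodes_null[r, ] <- ser$n_nodes
    lcc_null[r, ] <- ser$lcc_size
  }
  out <- lapply(seq_len(nt), function(i) {
    list(
      threshold = thresholds[i],
      n_nodes = permutation_null(
        sprintf("n_nodes@%.6g", thresholds[i]),
        obs_series$n_nodes[i], nodes_null[, i], seed, tail = "upper"),
      lcc_size = permutation_null(
        sprintf("lcc_size@%.6g", thresholds[i]),
        obs_series$lcc_size[i], lcc_null[, i], seed, tail = "upper")
    )
  })
  attr(out, "observed") <- obs_series
  out
}

#' Per-statistic empirical p-values from a phenotype-shuffle null
#'
#' Upper-tail exceedance fraction for each SNP's MI and each pair's IG,
#' with ties counted as exceedances (conservative) and zero counts
#' displayed as `"< 1/R"`.
#'
#' @param scores observed `epistasis_scores`.
#' @param null a null distribution from [null_score_distribution()]
#'   computed on the identical SNP set.
#' @param method `"exceedance"` (r/R, default) or `"add_one"`
#'   ((r+1)/(R+1)).
#' @return List of data frames `mi` (`snp`, `mi`, `p`, `p_display`) and
#'   `pairs` (`snp_a`, `snp_b`, `ig`, `p`, `p_display`).
#' @export
per_statistic_pvalues <- function(scores, null, method = c("exceedance", "add_one")) {
  stopifnot(inherits(scores, "epistasis_scores"))
  method <- match.arg(method)
  if (!identical(scores$snp_ids, null$snp_ids)) {
    stop("null distribution was computed on a different SNP set")
  }
  R <- nrow(null$mi_null)
  pcalc <- function(counts) {
    if (method == "add_one") {
      p <- (counts + 1) / (R + 1)
      list(p = p, display = format(p, scientific = FALSE, trim = TRUE))
    } else {
      res <- lapply(counts, format_pvalue, R = R)
      list(p = vapply(res, `[[`, numeric(1), "p"),
           display = vapply(res, `[[`, character(1), "display"))
    }
  }
  mi_counts <- colSums(sweep(null$mi_null, 2, scores$mi, ">=") * 1)
  ig_counts <- colSums(sweep(null$ig_null, 2, scores$pairs$ig, ">=") * 1)
  pm <- pcalc(mi_counts)
  pg <- pcalc(ig_counts)
  list(
    mi = data.frame(snp = scores$snp_ids, mi = unname(scores$mi),
                    p = pm$p, p_display = pm$display, stringsAsFactors = FALSE),
    pairs = data.frame(snp_a = scores$pairs$snp_a, snp_b = scores$pairs$snp_b,
                       ig = scores$pairs$ig, p = pg$p, p_display = pg$display,
                       stringsAsFactors = FALSE)
  )
}

#' Persist null distributions for audit
#'
#' Long-format TSV with columns `replicate`, `statistic`, `value`.
#'
#' @param null result of [null_score_distribution()].
#' @param path output TSV path.
#' @param what `"ig"` (default) or `"mi"`.
#' @return Invisibly, `path`.
#' @export
write_null_distribution <- function(null, path, what = c("ig", "mi")) {
  what <- match.arg(what)
  mat <- if (what == "ig") null$ig_null else null$mi_null
  ids <- if (what == "ig") null$pair_ids else null$snp_ids
  long <- data.frame(
    replicate = rep(seq_len(nrow(mat)), times = ncol(mat)),
    statistic = rep(ids, each = nrow(mat)),
    value = as.vector(mat)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
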