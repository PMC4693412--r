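#' Genotype matrix container
#'
#' Individuals-by-SNPs matrix of additively coded genotypes (minor-allele
#' dosage 0/1/2, `NA` for missing calls) together with SNP identifiers and
#' genomic loci. All preprocessing and scanning functions operate on this
#' container.
#'
#' @param values integer matrix, individuals in rows, SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   column names).
#' @param chrom chromosome name per SNP.
#' @param pos 1-based base-pair position per SNP.
#' @param individual_ids unique individual identifiers (defaults to row
#'   names, else `ind1..indN`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snp_ids`, `chrom`, `pos`, `individual_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                      snp_ids = c("rs1", "rs2"),
#'                      chrom = c("1", "1"), pos = c(100L, 200L))
#' g
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values),
                            chrom = NULL, pos = NULL,
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  m <- ncol(values)
  n <- nrow(values)
  ok <- values %in% c(0L, 1L, 2L) | is.na(values)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid genotype value '%s' at row %d, column %d (allowed: 0, 1, 2, NA)",
                 values[bad], (bad - 1) %% n + 1, (bad - 1) %/% n + 1))
  }
  storage.mode(values) <- "integer"
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  snp_ids <- as.character(snp_ids)
  individual_ids <- as.character(individual_ids)
  if (length(snp_ids) != m) stop("snp_ids length must equal ncol(values)")
  if (length(individual_ids) != n) stop("individual_ids length must equal nrow(values)")
  if (anyDuplicated(snp_ids)) stop("duplicate snp_ids")
  if (anyDuplicated(individual_ids)) stop("duplicate individual_ids")
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (length(chrom) != m || length(pos) != m) {
    stop("chrom and pos must have one entry per SNP")
  }
  dimnames(values) <- list(individual_ids, snp_ids)
  structure(
    list(values = values, snp_ids = snp_ids, chrom = as.character(chrom),
         pos = as.integer(pos), individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs", nrow(x$values), ncol(x$values)))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf(" (%d missing calls)", nmiss))
  cat("\n")
  chr <- unique(x$chrom)
  cat("  chromosomes:", paste(utils::head(chr, 8), collapse = ", "),
      if (length(chr) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# Keep a subset of SNPs (logical or integer index over columns).
subset_snps <- function(g, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  genotype_matrix(g$values[, idx, drop = FALSE],
                  snp_ids = g$snp_ids[idx],
                  chrom = g$chrom[idx], pos = g$pos[idx],
                  individual_ids = g$individual_ids)
}

# Keep a subset of individuals (logical or integer index over rows).
subset_individuals <- function(g, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  genotype_matrix(g$values[idx, , drop = FALSE],
                  snp_ids = g$snp_ids,
                  chrom = g$chrom, pos = g$pos,
                  individual_ids = g$individual_ids[idx])
}
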