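# Internal numerics, RNG plumbing and small shared helpers.

# x * log2(x) with the 0 * log 0 = 0 convention; preserves dim().
plogp2 <- function(x) {
  out <- x
  nz <- !is.na(x) & x > 0
  out[nz] <- x[nz] * log2(x[nz])
  out[!nz] <- 0
  out
}

# Plug-in entropy (bits) from a vector/array of counts.
.count_entropy <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("empty contingency table")
  log2(n) - sum(plogp2(counts)) / n
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Stage codes for the seed fan-out scheme (documented in fan_seed()).
.STAGE <- c(
  genotype = 1L, phenotype = 2L, permutation = 3L,
  label_permutation = 4L, pipeline = 5L
)

#' Derive a per-stage, per-replicate seed from a root seed
#'
#' A single root seed is fanned out deterministically so that permutation
#' replicates are independent of execution order: the seed for stage `s`,
#' replicate `i` is `(root * 21893 + s * 7919 + i) mod 2147483629`.
#'
#' @param root integer root seed.
#' @param stage stage name (`"genotype"`, `"phenotype"`, `"permutation"`,
#'   `"label_permutation"`, `"pipeline"`) or an integer stage code.
#' @param index replicate counter (0-based).
#' @return An integer seed suitable for [set.seed()].
#' @export
fan_seed <- function(root, stage, index = 0L) {
  if (is.character(stage)) {
    if (!stage %in% names(.STAGE)) stop("unknown stage: ", stage)
    stage <- .STAGE[[stage]]
  }
  as.integer((as.numeric(root) * 21893 + as.numeric(stage) * 7919 +
                as.numeric(index)) %% 2147483629)
}

#' Format an empirical permutation p-value
#'
#' Exceedance fraction `count / R`, displayed as `"< 1/R"` when no null value
#' reaches the observed statistic (the convention used for permutation tables,
#' e.g. `"<0.001"` at R = 1000).
#'
#' @param count number of null replicates at or beyond the observed value.
#' @param R number of permutation replicates.
#' @return A list with numeric `p` and character `display`.
#' @export
format_pvalue <- function(count, R) {
  if (R < 1) stop("R must be >= 1")
  if (count < 0 || count > R) stop("count must be in [0, R]")
  p <- count / R
  display <- if (count == 0) {
    paste0("<", format(1 / R, scientific = FALSE, trim = TRUE))
  } else {
    format(p, scientific = FALSE, trim = TRUE)
  }
  list(p = p, display = display)
}

# Coerce a case/control status vector to integer 0/1 (1 = case).
as_status01 <- function(status) {
  if (is.logical(status)) return(as.integer(status))
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    bad <- setdiff(unique(status), c("case", "control"))
    if (length(bad)) {
      stop("status values must be 'case'/'control'; found: ",
           paste(bad, collapse = ", "))
    }
    return(as.integer(status == "case"))
  }
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1))) stop("numeric status must be 0/1")
    return(as.integer(status))
  }
  stop("unsupported status type: ", class(status)[1])
}
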