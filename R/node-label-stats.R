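# Dyadicity and heterophilicity of binary node labels on a network, with
# analytic expectations under uniform random label placement and a
# structure-preserving label-permutation significance test.

#' Count same-label and mixed-label dyads
#'
#' `m11` is the number of edges whose two endpoints both carry the label;
#' `m10` the number with exactly one labeled endpoint.
#'
#' @param net a `sen_network` or igraph object.
#' @param label logical vector named by node id (or in vertex order)
#'   giving the binary node property; must be defined for every node.
#' @return Named integer vector `c(m11, m10)`.
#' @export
dyad_counts <- function(net, label) {
  gr <- .as_igraph(net)
  label <- .node_label(gr, label)
  el <- igraph::as_edgelist(gr, names = TRUE)
  l1 <- label[el[, 1]]
  l2 <- label[el[, 2]]
  c(m11 = sum(l1 & l2), m10 = sum(xor(l1, l2)))
}

.as_igraph <- function(net) {
  if (inherits(net, "sen_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("net must be a sen_network or igraph object")
}

.node_label <- function(gr, label) {
  nodes <- igraph::V(gr)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(gr)))
  if (!is.null(names(label))) {
    missing <- setdiff(nodes, names(label))
    if (length(missing)) {
      stop("no label defined for node(s): ", paste(utils::head(missing, 5), collapse = ", "))
    }
    label <- label[nodes]
  } else if (length(label) != length(nodes)) {
    stop("unnamed label vector must have one entry per node")
  }
  if (anyNA(label)) stop("labels contain NA")
  stats::setNames(as.logical(label), nodes)
}

#' Expected dyad counts under uniform random label placement
#'
#' With `n1` labels placed uniformly at random on `N` slots in a network of
#' `M` edges, the expected counts are
#' \deqn{\bar m_{11} = M \frac{n_1 (n_1 - 1)}{N (N - 1)}, \qquad
#'       \bar m_{10} = M \frac{2 n_1 (N - n_1)}{N (N - 1)}.}
#'
#' @param N label-universe size (>= 2).
#' @param M edge count.
#' @param n1 number of labeled slots, `0 <= n1 <= N`.
#' @return Named numeric vector `c(m11_expected, m10_expected)`.
#' @examples
#' expected_dyads(N = 2139, M = 1241, n1 = 222)
#' @export
expected_dyads <- function(N, M, n1) {
  if (N < 2) stop("N must be >= 2")
  if (M < 0) stop("M must be >= 0")
  if (n1 < 0 || n1 > N) stop("n1 must be in [0, N]")
  c(m11_expected = M * n1 * (n1 - 1) / (N * (N - 1)),
    m10_expected = M * 2 * n1 * (N - n1) / (N * (N - 1)))
}

#' Dyadicity and heterophilicity ratios
#'
#' `D = m11 / m11_expected`, `H = m10 / m10_expected`. `D > 1` marks a
#' dyadic labeling (same-label nodes connect more than expected at random);
#' `H > 1` a heterophilic one. A zero expectation makes the ratio
#' undefined; `NA` is returned with a warning.
#'
#' @param m11,m10 observed dyad counts.
#' @param m11_expected,m10_expected expectations from [expected_dyads()].
#' @return Named numeric vector `c(D, H)`.
#' @export
dyadicity_heterophilicity <- function(m11, m10, m11_expected, m10_expected) {
  m11 <- unname(m11); m10 <- unname(m10)
  m11_expected <- unname(m11_expected); m10_expected <- unname(m10_expected)
  D <- if (m11_expected > 0) m11 / m11_expected else {
    warning("m11_expected is 0; dyadicity undefined")
    NA_real_
  }
  H <- if (m10_expected > 0) m10 / m10_expected else {
    warning("m10_expected is 0; heterophilicity undefined")
    NA_real_
  }
  c(D = D, H = H)
}

#' Label-permutation significance of dyadicity and heterophilicity
#'
#' Holds the network structure and the number of labeled slots `n1` fixed,
#' reassigns the labels uniformly at random over the `N`-slot universe `R`
#' times, and compares the observed dyad counts with the permuted ones.
#' With `alternative = "auto"` (default) the tail follows the observed
#' deviation (upper when D > 1, lower when D < 1; analogously for H); ties
#' count toward rejection. Fixed tails are available for calibration work.
#'
#' When `N` exceeds the node count the graph's nodes occupy `vcount` of the
#' `N` slots and labels landing on off-graph slots touch no edge, matching
#' the analytic expectations for that universe.
#'
#' @param net a `sen_network` or igraph.
#' @param label binary node property (see [dyad_counts()]).
#' @param R permutation replicates (default 1000).
#' @param seed root seed.
#' @param N label-universe size; defaults to the node count.
#' @param n1 labeled-slot count; defaults to the number of labeled nodes.
#' @param alternative `"auto"`, `"greater"` or `"less"`.
#' @return A one-row data frame (class `dyad_report`) with columns `n1`,
#'   `N`, `M`, `m11_expected`, `m10_expected`, `m11`, `m10`, `D`, `H`,
#'   `p_D`, `p_H`, `p_D_display`, `p_H_display`; the permuted `m11`/`m10`
#'   draws are attached as attribute `null`.
#' @export
label_permutation_significance <- function(net, label, R = 1000, seed = 1,
                                           N = NULL, n1 = NULL,
                                           alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  gr <- .as_igraph(net)
  lab <- .node_label(gr, label)
  nv <- igraph::vcount(gr)
  M <- igraph::ecount(gr)
  if (is.null(N)) N <- nv
  if (is.null(n1)) n1 <- sum(lab)
  if (N < nv) stop("label universe N cannot be smaller than the node count")
  if (n1 > N) stop("n1 cannot exceed N")
  if (n1 == 0 || n1 == N) {
    stop("degenerate labeling (n1 = 0 or n1 = N); dyadicity not applicable")
  }
  obs <- dyad_counts(gr, lab)
  exp_ <- expected_dyads(N, M, n1)
  DH <- dyadicity_heterophilicity(obs["m11"], obs["m10"],
                                  exp_["m11_expected"], exp_["m10_expected"])

  el <- igraph::as_edgelist(gr, names = FALSE)
  null_m11 <- integer(R)
  null_m10 <- integer(R)
  for (r in seq_len(R)) {
    slots <- with_seed(fan_seed(seed, "label_permutation", r), sample.int(N, n1))
    pl <- logical(nv)
    on_graph <- slots[slots <= nv]
    pl[on_graph] <- TRUE
    e1 <- pl[el[, 1]]
    e2 <- pl[el[, 2]]
    null_m11[r] <- sum(e1 & e2)
    null_m10[r] <- sum(xor(e1, e2))
  }
  tail_for <- function(ratio) {
    switch(alternative,
           auto = if (is.na(ratio) || ratio >= 1) "upper" else "lower",
           greater = "upper", less = "lower")
  }
  pD <- permutation_null("m11", unname(obs["m11"]), null_m11, seed, tail_for(DH["D"]))
  pH <- permutation_null("m10", unname(obs["m10"]), null_m10, seed, tail_for(DH["H"]))
  out <- data.frame(
    n1 = n1, N = N, M = M,
    m11_expected = unname(exp_["m11_expected"]),
    m10_expected = unname(exp_["m10_expected"]),
    m11 = unname(obs["m11"]), m10 = unname(obs["m10"]),
    D = unname(DH["D"]), H = unname(DH["H"]),
    p_D = pD$p_value, p_H = pH$p_value,
    p_D_display = pD$p_display, p_H_display = pH$p_display,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dyad_report", "data.frame")
  attr(out, "null") <- list(m11 = null_m11, m10 = null_m10)
  out
}

#' Per-gene dyadicity/heterophilicity report
#'
#' Runs [label_permutation_significance()] once per gene, treating each
#' gene's membership as an independent binary labeling (multi-gene SNPs
#' contribute to every gene they belong to). Genes whose labeling is
#' degenerate on the chosen universe are reported with `NA` statistics and
#' a `note`.
#'
#' @param net a `sen_network`.
#' @param membership logical SNP-by-gene matrix from [map_snps_to_genes()].
#' @param R,seed see [label_permutation_significance()].
#' @param universe `"network"` (N = nodes of the analyzed network,
#'   default), `"snps"` (N = all SNPs in the dataset, n1 = the gene's SNP
#'   count), or `"slots"` (N = total gene-membership slots, n1 = the gene's
#'   slot count).
#' @param alternative tail convention, see
#'   [label_permutation_significance()].
#' @return A `dyad_report` data frame, one row per gene.
#' @export
dyadicity_report <- function(net, membership, R = 1000, seed = 1,
                             universe = c("network", "snps", "slots"),
                             alternative = "auto") {
  universe <- match.arg(universe)
  gr <- .as_igraph(net)
  nodes <- igraph::V(gr)$name
  missing <- setdiff(nodes, rownames(membership))
  if (length(missing)) {
    stop("membership matrix lacks rows for network nodes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rows <- vector("list", ncol(membership))
  for (k in seq_len(ncol(membership))) {
    lab <- membership[nodes, k]
    names(lab) <- nodes
    n1 <- switch(universe,
                 network = sum(lab),
                 snps = sum(membership[, k]),
                 slots = sum(membership[, k]))
    N <- switch(universe,
                network = length(nodes),
                snps = nrow(membership),
                slots = sum(membership))
    row <- tryCatch(
      cbind(gene = colnames(membership)[k],
            label_permutation_significance(gr, lab, R = R,
                                           seed = fan_seed(seed, "label_permutation", k * 100000L),
                                           N = N, n1 = n1, alternative = alternative),
            note = ""),
      error = function(e) {
        data.frame(gene = colnames(membership)[k], n1 = n1, N = N,
                   M = igraph::ecount(gr), m11_expected = NA_real_,
                   m10_expected = NA_real_, m11 = NA_integer_, m10 = NA_integer_,
                   D = NA_real_, H = NA_real_, p_D = NA_real_, p_H = NA_real_,
                   p_D_display = NA_character_, p_H_display = NA_character_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      }
    )
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dyad_report", "data.frame")
  out
}
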