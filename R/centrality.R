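# Degree, betweenness and closeness centrality over a connected component,
# plus ranked key-node reports.

#' Centrality table for a connected network
#'
#' Unweighted (hop-count) centralities per node: degree; betweenness (sum
#' over distinct node pairs of the fraction of shortest paths through the
#' node, endpoints excluded), both raw and normalized by
#' `(n - 1)(n - 2) / 2`; closeness, both raw (`1 / sum of distances`) and
#' normalized (`(n - 1) / sum of distances`). Edge weights are ignored for
#' path computations. Rank columns (1 = highest) break ties by node id.
#'
#' @param net a `sen_network` or igraph; must be connected (use
#'   [largest_component()] first).
#' @return Data frame with columns `node`, `degree`, `betweenness_raw`,
#'   `betweenness`, `closeness_raw`, `closeness`, and
#'   `rank_degree`/`rank_betweenness`/`rank_closeness`.
#' @export
centrality_table <- function(net) {
  gr <- .as_igraph(net)
  n <- igraph::vcount(gr)
  if (n == 0) stop("empty network")
  if (!igraph::is_connected(gr)) {
    stop("network is disconnected; extract a component with largest_component() first")
  }
  nodes <- igraph::V(gr)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- igraph::degree(gr)
  btw_raw <- igraph::betweenness(gr, directed = FALSE, weights = NA)
  btw <- if (n > 2) btw_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  clo_raw <- igraph::closeness(gr, weights = NA)
  clo <- clo_raw * (n - 1)
  rk <- function(x) rank_with_id_ties(x, nodes)
  out <- data.frame(
    node = nodes, degree = as.integer(deg),
    betweenness_raw = unname(btw_raw), betweenness = unname(btw),
    closeness_raw = unname(clo_raw), closeness = unname(clo),
    rank_degree = rk(deg), rank_betweenness = rk(btw), rank_closeness = rk(clo),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Dense rank: 1 = largest value; ties broken by node id (lexicographic).
rank_with_id_ties <- function(x, ids) {
  ord <- order(-x, ids)
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

#' Top-k nodes per centrality measure
#'
#' Ranks nodes by degree, betweenness and closeness (ties broken by node
#' id), reports the top `k` for each measure with optional gene labels,
#' and flags nodes appearing in all three lists.
#'
#' @param tab a [centrality_table()] result.
#' @param k list length per measure (default 5); truncated with a warning
#'   when it exceeds the node count.
#' @param gene_labels optional named character vector (or list of label
#'   vectors) keyed by node id.
#' @return A list with data frames `degree`, `betweenness`, `closeness`
#'   and the character vector `in_all_three`.
#' @export
top_k_report <- function(tab, k = 5, gene_labels = NULL) {
  if (k < 1) stop("k must be >= 1")
  n <- nrow(tab)
  if (k > n) {
    warning(sprintf("k = %d exceeds the node count (%d); returning the full ranking", k, n))
    k <- n
  }
  pick <- function(rank_col) {
    sel <- tab[order(tab[[rank_col]]), , drop = FALSE][seq_len(k), ]
    sel$gene <- if (is.null(gene_labels)) NA_character_ else {
      vapply(sel$node, function(id) {
        lb <- gene_labels[[id]]
        if (is.null(lb) || !length(lb)) NA_character_ else paste(lb, collapse = ";")
      }, character(1))
    }
    rownames(sel) <- NULL
    sel[, c("node", "gene", "degree", "betweenness", "closeness")]
  }
  top <- list(degree = pick("rank_degree"),
              betweenness = pick("rank_betweenness"),
              closeness = pick("rank_closeness"))
  top$in_all_three <- Reduce(intersect, lapply(top[1:3], `[[`, "node"))
  top
}
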