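# Thresholded network series, percolation threshold and largest component.

#' Build a statistical epistasis network at an edge-weight threshold
#'
#' Edges are all SNP pairs with information gain strictly greater than
#' `threshold`; nodes are the endpoints of surviving edges, carrying their
#' mutual information as node weight. Isolated SNPs are excluded. The graph
#' is undirected with no self-loops or multi-edges.
#'
#' @param scores an `epistasis_scores` object from [pairwise_ig_scan()].
#' @param threshold edge-weight cutoff in the score units (bits by default).
#' @return An object of class `sen_network`: list with `graph` (igraph,
#'   vertex attribute `mi`, edge attribute `weight` = IG), `threshold`,
#'   `n_total_snps` (SNPs in the scanned dataset) and `provenance`.
#' @export
build_network <- function(scores, threshold) {
  stopifnot(inherits(scores, "epistasis_scores"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  keep <- scores$pairs$ig > threshold
  edges <- scores$pairs[keep, , drop = FALSE]
  nodes <- sort(unique(c(edges$snp_a, edges$snp_b)))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = edges$snp_a, to = edges$snp_b, weight = edges$ig),
    directed = FALSE,
    vertices = data.frame(name = nodes, mi = unname(scores$mi[nodes]))
  )
  structure(
    list(graph = gr, threshold = threshold,
         n_total_snps = length(scores$snp_ids),
         provenance = list(n_individuals = scores$n_individuals,
                           log_base = scores$log_base)),
    class = "sen_network"
  )
}

#' @export
print.sen_network <- function(x, ...) {
  cat(sprintf("<sen_network> %d nodes, %d edges (threshold %.6g; %d SNPs scanned)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$n_total_snps))
  invisible(x)
}

#' Network summaries over a descending threshold sweep
#'
#' One row per threshold: node count, edge count and largest-connected-
#' component size. Node and LCC counts are non-decreasing as the threshold
#' decreases.
#'
#' @inheritParams build_network
#' @param thresholds strictly decreasing numeric vector.
#' @return Data frame with columns `threshold`, `n_nodes`, `n_edges`,
#'   `lcc_size`.
#' @export
network_series <- function(scores, thresholds) {
  stopifnot(inherits(scores, "epistasis_scores"))
  if (length(thresholds) < 1) stop("need at least one threshold")
  if (any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing (duplicates not allowed)")
  }
  rows <- lapply(thresholds, function(t) {
    net <- build_network(scores, t)
    comp <- igraph::components(net$graph)
    data.frame(threshold = t,
               n_nodes = igraph::vcount(net$graph),
               n_edges = igraph::ecount(net$graph),
               lcc_size = if (comp$no == 0) 0L else max(comp$csize))
  })
  do.call(rbind, rows)
}

# Candidate thresholds realizing every distinct network in the sweep:
# midpoints between consecutive distinct IG values (descending), plus one
# below the minimum so the densest network is reachable.
.candidate_thresholds <- function(ig_values) {
  v <- sort(unique(ig_values), decreasing = TRUE)
  if (length(v) == 1) return(v - max(1e-9, abs(v) * 1e-9))
  mid <- (v[-length(v)] + v[-1]) / 2
  gap <- min(abs(diff(v))) / 2
  c(mid, v[length(v)] - gap)
}

#' Percolation threshold of the IG score distribution
#'
#' Sweeps candidate thresholds (midpoints between consecutive distinct IG
#' values, descending, so every network in the sweep is realizable and the
#' strict/non-strict edge rule is immaterial) and returns the largest
#' threshold at which the largest connected component exceeds half the
#' nodes - by default half of all scanned SNPs (`denominator = "all"`), or
#' half of the nodes present at that threshold (`denominator = "present"`).
#'
#' @inheritParams build_network
#' @param n_total_snps denominator for the "all" criterion; defaults to the
#'   number of scanned SNPs recorded in `scores`.
#' @param denominator `"all"` (default) or `"present"`.
#' @return The percolation threshold (numeric) with attribute `series`, the
#'   sweep summary up to the returned threshold.
#' @seealso [network_series()]
#' @export
percolation_threshold <- function(scores, n_total_snps = length(scores$snp_ids),
                                  denominator = c("all", "present")) {
  stopifnot(inherits(scores, "epistasis_scores"))
  denominator <- match.arg(denominator)
  if (nrow(scores$pairs) < 1) stop("no scored pairs")
  cand <- .candidate_thresholds(scores$pairs$ig)
  rows <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    net <- build_network(scores, cand[i])
    comp <- igraph::components(net$graph)
    lcc <- if (comp$no == 0) 0L else max(comp$csize)
    nn <- igraph::vcount(net$graph)
    rows[[i]] <- data.frame(threshold = cand[i], n_nodes = nn,
                            n_edges = igraph::ecount(net$graph), lcc_size = lcc)
    half <- if (denominator == "all") n_total_snps / 2 else nn / 2
    if (lcc > half) {
      out <- cand[i]
      attr(out, "series") <- do.call(rbind, rows[seq_len(i)])
      return(out)
    }
  }
  series <- do.call(rbind, rows)
  stop(errorCondition(
    sprintf("no percolation: the largest connected component never exceeded half of %s",
            if (denominator == "all") sprintf("all %d SNPs", n_total_snps) else "the nodes present"),
    series = series, class = c("senet_no_percolation", "error", "condition")
  ))
}

#' Largest connected component of a network
#'
#' Induced subgraph on the largest connected node set; ties between equal-
#' size components are broken toward the component containing the
#' lexicographically smallest node id.
#'
#' @param net a `sen_network`.
#' @return A `sen_network` restricted to the largest component (empty
#'   network maps to itself).
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "sen_network"))
  if (igraph::vcount(net$graph) == 0) return(net)
  comp <- igraph::components(net$graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(net$graph)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  sub <- igraph::induced_subgraph(net$graph, which(comp$membership == best))
  out <- net
  out$graph <- sub
  out
}
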