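# Literal brute-force oracles, kept independent of the package's
# estimator code paths: probabilities and Kullback-Leibler sums written
# out directly, and centralities via explicit BFS shortest-path counting.

oracle_entropy <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log2(x)
  h
}

# MI by the direct double sum over cells: sum p_ij log2(p_ij / (p_i p_j)).
oracle_mi_tab <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) mi <- mi + pij * log2(pij / (pr[i] * pc[j]))
    }
  }
  unname(mi)
}

oracle_ig <- function(a, b, y) {
  joint <- table(paste(a, b), y)
  oracle_mi_tab(joint) - oracle_mi_tab(table(a, y)) - oracle_mi_tab(table(b, y))
}

# Random 3x3x2 contingency table expanded to genotype/class vectors.
random_abc_vectors <- function(max_count = 10) {
  counts <- array(sample.int(max_count + 1, 18, replace = TRUE) - 1L, c(3, 3, 2))
  if (sum(counts) == 0) counts[1, 1, 1] <- 1L
  cells <- expand.grid(a = 0:2, b = 0:2, y = 0:1)
  idx <- rep(seq_len(nrow(cells)), times = as.vector(counts))
  list(a = cells$a[idx], b = cells$b[idx], y = cells$y[idx])
}

# --- graph oracles ---------------------------------------------------------

oracle_adj <- function(gr) {
  as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE)) > 0
}

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ])
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# Number of shortest paths from s to every node, by dynamic programming in
# order of BFS distance.
oracle_sigma <- function(adj, s) {
  d <- oracle_bfs_dist(adj, s)
  n <- nrow(adj)
  sigma <- rep(0, n)
  sigma[s] <- 1
  for (dist in sort(unique(d[is.finite(d) & d > 0]))) {
    for (v in which(d == dist)) {
      pred <- which(adj[v, ] & d == dist - 1)
      sigma[v] <- sum(sigma[pred])
    }
  }
  sigma
}

# Betweenness: for every unordered pair (s, t), the fraction of shortest
# s-t paths passing through v (endpoints excluded).
oracle_betweenness <- function(gr, normalized = TRUE) {
  adj <- oracle_adj(gr)
  n <- nrow(adj)
  d <- t(sapply(seq_len(n), function(s) oracle_bfs_dist(adj, s)))
  sig <- lapply(seq_len(n), function(s) oracle_sigma(adj, s))
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sig[[s]][v] * sig[[t]][v] / sig[[s]][t]
        }
      }
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

oracle_closeness <- function(gr, normalized = TRUE) {
  adj <- oracle_adj(gr)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    tot <- sum(oracle_bfs_dist(adj, v)[-v])
    if (normalized) (n - 1) / tot else 1 / tot
  }, numeric(1))
}

oracle_dyads <- function(gr, label) {
  el <- igraph::as_edgelist(gr, names = TRUE)
  m11 <- 0
  m10 <- 0
  m00 <- 0
  for (e in seq_len(nrow(el))) {
    s <- label[[el[e, 1]]]
    t <- label[[el[e, 2]]]
    if (s && t) m11 <- m11 + 1
    else if (s || t) m10 <- m10 + 1
    else m00 <- m00 + 1
  }
  c(m11 = m11, m10 = m10, m00 = m00)
}

# Small named random graph.
random_named_graph <- function(n, m, seed) {
  set.seed(seed)
  gr <- igraph::sample_gnm(n, m)
  igraph::V(gr)$name <- sprintf("n%03d", seq_len(n))
  gr
}
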