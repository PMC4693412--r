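test_that("network construction keeps edges strictly above threshold", {
  ids <- paste0("s", 1:5)
  pairs <- pair_table(ids)[1:5, ]
  pairs$ig <- c(.01, .02, .03, .04, .05)
  sc <- make_scores(ids, pairs)
  net <- build_network(sc, 0.025)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_true(all(igraph::E(net$graph)$weight > 0.025))
  # nodes are exactly the endpoints of surviving edges
  expect_setequal(igraph::V(net$graph)$name,
                  unique(unlist(pairs[pairs$ig > 0.025, c("snp_a", "snp_b")])))
  # threshold above max -> empty; below min -> complete graph
  expect_equal(igraph::ecount(build_network(sc, 1)$graph), 0)
  full <- build_network(make_scores(ids, pair_table(ids, background = 0.5)), 0.1)
  expect_equal(igraph::ecount(full$graph), choose(5, 2))
  expect_error(build_network(sc, Inf), "finite")
})

test_that("threshold series is monotone and rejects unsorted input", {
  set.seed(17)
  ids <- paste0("s", 1:12)
  pairs <- pair_table(ids)
  pairs$ig <- runif(nrow(pairs))
  sc <- make_scores(ids, pairs)
  ser <- network_series(sc, seq(0.9, 0.1, by = -0.2))
  expect_true(all(diff(ser$n_nodes) >= 0))
  expect_true(all(diff(ser$n_edges) >= 0))
  expect_true(all(diff(ser$lcc_size) >= 0))
  expect_error(network_series(sc, c(0.1, 0.5)), "decreasing")
  expect_error(network_series(sc, c(0.5, 0.5)), "decreasing")
  expect_equal(nrow(network_series(sc, 0.5)), 1)
  # thresholds straddling one IG value differ by its multiplicity
  sc2 <- make_scores(ids[1:4], pair_table(ids[1:4], background = 0.3))
  ser2 <- network_series(sc2, c(0.31, 0.29))
  expect_equal(ser2$n_edges, c(0, 6))
})

test_that("percolation threshold is found by the descending sweep", {
  # star: hub connected to 9 leaves at IG .05, all other pairs at 0
  ids <- c("hub", paste0("leaf", 1:9))
  override <- data.frame(snp_a = "hub", snp_b = paste0("leaf", 1:9), ig = 0.05)
  sc <- make_scores(ids, pair_table(ids, background = 0, override = override))
  th <- percolation_threshold(sc)
  expect_equal(as.numeric(th), 0.025)   # midpoint candidate below .05
  net <- build_network(sc, as.numeric(th))
  comp <- igraph::components(net$graph)
  expect_gt(max(comp$csize), length(ids) / 2)
  expect_s3_class(attr(th, "series"), "data.frame")

  # all pairs equal IG: single candidate below that value, full graph
  sc_eq <- make_scores(ids[1:6], pair_table(ids[1:6], background = 0.04))
  th_eq <- percolation_threshold(sc_eq)
  expect_lt(as.numeric(th_eq), 0.04)
  expect_equal(igraph::vcount(build_network(sc_eq, as.numeric(th_eq))$graph), 6)
})

test_that("no-percolation raises a condition carrying the sweep series", {
  # two disjoint 2-cliques among 8 scanned SNPs: LCC never exceeds 4
  ids <- paste0("s", 1:8)
  pairs <- data.frame(snp_a = c("s1", "s3", "s3"), snp_b = c("s2", "s4", "s5"),
                      ig = c(0.05, 0.05, 0.05))
  sc <- make_scores(ids, pairs)
  err <- tryCatch(percolation_threshold(sc), error = identity)
  expect_s3_class(err, "senet_no_percolation")
  expect_s3_class(err$series, "data.frame")
  # the self-referential "present" denominator percolates immediately
  # (LCC of 3 among the 5 nodes present, but not among all 8 SNPs)
  th_p <- percolation_threshold(sc, denominator = "present")
  expect_lt(as.numeric(th_p), 0.05)
  expect_equal(igraph::ecount(build_network(sc, as.numeric(th_p))$graph), 3)
})

test_that("percolation criterion holds at the threshold and fails one step higher", {
  set.seed(23)
  ids <- paste0("s", 1:15)
  pairs <- pair_table(ids)
  pairs$ig <- round(runif(nrow(pairs)), 2)
  sc <- make_scores(ids, pairs)
  th <- as.numeric(percolation_threshold(sc))
  lcc_at <- function(t) {
    comp <- igraph::components(build_network(sc, t)$graph)
    if (comp$no == 0) 0 else max(comp$csize)
  }
  expect_gt(lcc_at(th), length(ids) / 2)
  ser <- attr(percolation_threshold(sc), "series")
  if (nrow(ser) > 1) {
    expect_lte(lcc_at(ser$threshold[nrow(ser) - 1]), length(ids) / 2)
  }
})

test_that("largest component extraction breaks size ties lexicographically", {
  ids <- c("a", "b", "c", "d", "e", "f", "g")
  pairs <- data.frame(snp_a = c("e", "e", "a"), snp_b = c("f", "g", "b"),
                      ig = 0.1)
  sc <- make_scores(ids, pairs)
  net <- build_network(sc, 0.05)
  lcc <- largest_component(net)
  expect_setequal(igraph::V(lcc$graph)$name, c("e", "f", "g"))
  # tie between {a,b} and {c,d}: the component holding "a" wins
  pairs2 <- data.frame(snp_a = c("a", "c"), snp_b = c("b", "d"), ig = 0.1)
  lcc2 <- largest_component(build_network(make_scores(ids, pairs2), 0.05))
  expect_setequal(igraph::V(lcc2$graph)$name, c("a", "b"))
  # a connected network maps to itself
  lcc3 <- largest_component(lcc)
  expect_equal(igraph::vcount(lcc3$graph), 3)
})
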