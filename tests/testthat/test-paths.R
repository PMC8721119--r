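test_that("region membership follows the sphere-occupancy rule", {
  # residue 2 coincides with the anchor; residue 3 fixed at 6.5 A; residue 4
  # inside 6 A in 80% of frames
  frames <- lapply(1:10, function(f) {
    rbind(
      c(0, 0, 0),
      c(0, 0, 0),
      c(6.5, 0, 0),
      c(if (f <= 8) 4 else 9, 0, 0)
    )
  })
  region <- define_region(bead_traj(frames), "A:1")
  expect_setequal(region$members, c("A:1", "A:2", "A:4"))
  expect_error(define_region(bead_traj(frames), "Z:9"),
               class = "allopath_lookup_error")
})

test_that("shortest_path solves the triangle example and zero-length overlaps", {
  edges <- tibble::tibble(
    res_i = c("a", "b", "a"), res_j = c("b", "c", "c"),
    weight = c(1, 1, 2.5)
  )
  net <- test_network(edges)
  p <- shortest_path(net, "a", "c")
  expect_equal(p$residues, c("a", "b", "c"))
  expect_equal(p$length, 2)
  expect_equal(p$weights, c(1, 1))
  overlap <- shortest_path(net, c("a", "b"), c("b", "c"))
  expect_equal(overlap$residues, "b")
  expect_equal(overlap$length, 0)
})

test_that("disconnected regions raise a disconnection error listing components", {
  edges <- tibble::tibble(res_i = c("a", "c"), res_j = c("b", "d"),
                          weight = c(1, 1))
  net <- test_network(edges)
  expect_error(shortest_path(net, "a", "d"),
               regexp = "components",
               class = "allopath_disconnection_error")
})

test_that("ties break toward the lexicographically smallest residue sequence", {
  edges <- tibble::tibble(
    res_i = c("s", "s", "x", "m"), res_j = c("x", "m", "t", "t"),
    weight = c(1, 1, 1, 1)
  )
  net <- test_network(edges)
  p <- shortest_path(net, "s", "t")
  expect_equal(p$residues, c("s", "m", "t"))
})

test_that("path totals equal the sum of their edge weights", {
  withr::local_seed(42)
  for (rep in 1:25) {
    edges <- random_graph_edges(sample(4:9, 1))
    net <- test_network(edges)
    nodes <- net$residues
    p <- shortest_path(net, nodes[1], nodes[length(nodes)])
    expect_equal(p$length, sum(p$weights), tolerance = 1e-10)
    expect_true(all(p$weights >= 0))
  }
})

test_that("Dijkstra agrees with exhaustive simple-path enumeration on random graphs", {
  withr::local_seed(1)
  for (rep in 1:60) {
    edges <- random_graph_edges(sample(4:9, 1))
    net <- test_network(edges)
    nodes <- net$residues
    src <- sample(nodes, 2)
    snk <- sample(setdiff(nodes, src), 2)
    oracle <- brute_shortest(edges, src, snk)
    p <- shortest_path(net, src, snk)
    expect_equal(p$length, oracle$length, tolerance = 1e-9)
  }
})

test_that("removing an edge never shortens the shortest path", {
  withr::local_seed(11)
  for (rep in 1:20) {
    edges <- random_graph_edges(7)
    net <- test_network(edges)
    base <- shortest_path(net, "n01", "n07")$length
    drop <- sample(nrow(edges), 1)
    pruned <- test_network(edges[-drop, ], nodes = net$residues)
    after <- tryCatch(
      shortest_path(pruned, "n01", "n07")$length,
      allopath_disconnection_error = function(e) Inf
    )
    expect_gte(after, base - 1e-12)
  }
})

test_that("average_path_length is the family mean and validates its input", {
  mk <- function(len, fam) allopath:::new_path_result(
    c("a", "b"), len, fam, "A"
  )
  expect_equal(average_path_length(list(mk(1, "VSD-SF"), mk(1, "VSD-SF"),
                                        mk(1, "VSD-SF"), mk(1, "VSD-SF"))), 1)
  expect_equal(average_path_length(list(mk(0.8, "PD-SF"), mk(1.0, "PD-SF"),
                                        mk(1.0, "PD-SF"), mk(1.2, "PD-SF"))), 1)
  expect_error(average_path_length(list()), class = "allopath_argument_error")
  expect_error(average_path_length(list(mk(1, "VSD-SF"), mk(1, "PD-SF"))),
               class = "allopath_argument_error")
})

test_that("restricted betweenness matches its definition on small motifs", {
  # path graph s - b - t
  chain <- test_network(tibble::tibble(
    res_i = c("s", "b"), res_j = c("b", "t"), weight = c(1, 1)
  ))
  b <- path_betweenness(chain, "s", "t")
  expect_equal(b$betweenness[b$residue == "b"], 1)
  # node off every shortest path scores zero
  extra <- test_network(tibble::tibble(
    res_i = c("s", "b", "s", "q"), res_j = c("b", "t", "q", "t"),
    weight = c(1, 1, 3, 3)
  ))
  b2 <- path_betweenness(extra, "s", "t")
  expect_equal(b2$betweenness[b2$residue == "q"], 0)
  # two equal-length routes split the flow
  twin <- test_network(tibble::tibble(
    res_i = c("s", "b", "s", "c"), res_j = c("b", "t", "c", "t"),
    weight = c(1, 1, 1, 1)
  ))
  b3 <- path_betweenness(twin, "s", "t")
  expect_equal(b3$betweenness[b3$residue %in% c("b", "c")], c(0.5, 0.5))
})

test_that("restricted betweenness matches brute-force enumeration on random graphs", {
  withr::local_seed(23)
  for (rep in 1:25) {
    edges <- random_graph_edges(sample(5:9, 1))
    net <- test_network(edges)
    nodes <- net$residues
    src <- sample(nodes, 2)
    snk <- sample(setdiff(nodes, src), 2)
    got <- path_betweenness(net, src, snk)
    want <- brute_betweenness(edges, src, snk, nodes)
    expect_equal(setNames(got$betweenness, got$residue), want[got$residue],
                 tolerance = 1e-9)
  }
})

test_that("centrality index counts near-optimal path membership", {
  # unique short path s-v-t; detour s-a-b-t exceeds the slack
  g1 <- test_network(tibble::tibble(
    res_i = c("s", "v", "s", "a", "b"), res_j = c("v", "t", "a", "b", "t"),
    weight = c(0.5, 0.5, 1, 1, 1)
  ))
  ci1 <- centrality_index(g1, "s", "t", epsilon = 1)
  expect_equal(ci1$ci[ci1$residue == "v"], 1)
  expect_equal(ci1$ci[ci1$residue == "a"], 0)
  # two disjoint equal-length routes: interior nodes appear in half the paths
  g2 <- test_network(tibble::tibble(
    res_i = c("s", "b", "s", "c"), res_j = c("b", "t", "c", "t"),
    weight = c(1, 1, 1, 1)
  ))
  ci2 <- centrality_index(g2, "s", "t", epsilon = 0.5)
  expect_equal(ci2$ci[ci2$residue %in% c("b", "c")], c(0.5, 0.5))
  expect_equal(ci2$ci[ci2$residue %in% c("s", "t")], c(1, 1))
})

test_that("exhausting k_max warns and still returns the enumerated set", {
  # a dense lattice with many near-equal paths
  withr::local_seed(2)
  edges <- random_graph_edges(9, p = 1)
  edges$weight <- 0.2 + 0.01 * seq_len(nrow(edges)) / nrow(edges)
  net <- test_network(edges)
  expect_warning(
    paths <- suboptimal_paths(net, "n01", "n09", epsilon = 5, k_max = 10),
    "k_max"
  )
  expect_equal(nrow(paths), 10L)
})

test_that("centrality and betweenness are invariant under residue relabeling", {
  withr::local_seed(5)
  edges <- random_graph_edges(7)
  net <- test_network(edges)
  perm <- setNames(sprintf("m%02d", sample(7)), sprintf("n%02d", 1:7))
  redges <- edges
  redges$res_i <- unname(perm[edges$res_i])
  redges$res_j <- unname(perm[edges$res_j])
  rnet <- test_network(redges)
  b <- path_betweenness(net, c("n01", "n02"), c("n06", "n07"))
  rb <- path_betweenness(rnet, unname(perm[c("n01", "n02")]),
                         unname(perm[c("n06", "n07")]))
  expect_equal(setNames(rb$betweenness, rb$residue)[unname(perm[b$residue])],
               setNames(b$betweenness, unname(perm[b$residue])),
               tolerance = 1e-12)
  ci <- centrality_index(net, "n01", "n07")
  rci <- centrality_index(rnet, unname(perm["n01"]), unname(perm["n07"]))
  expect_equal(setNames(rci$ci, rci$residue)[unname(perm[ci$residue])],
               setNames(ci$ci, unname(perm[ci$residue])),
               tolerance = 1e-12)
})

test_that("betweenness bands follow the low/medium/high legend", {
  expect_equal(as.character(band_betweenness(0.5, 9)), "low")
  expect_equal(as.character(band_betweenness(4, 9)), "medium")
  expect_equal(as.character(band_betweenness(4.01, 9)), "high")
  z <- band_betweenness(c(0, 2), 9)
  expect_equal(as.character(z), c("low", "medium"))
  expect_equal(attr(z, "zero"), c(TRUE, FALSE))
  expect_error(band_betweenness(10, 9), class = "allopath_argument_error")
})
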