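mkNet <- function(weights) {
  n <- length(weights)
  GeneNetwork(data.frame(from = sprintf("a%03d", seq_len(n)),
                         to = sprintf("b%03d", seq_len(n)),
                         weight = weights))
}

test_that("top-edge filtering keeps the strongest edges, ties included", {
  set.seed(4)
  net <- mkNet(sample(seq(0.01, 1, length.out = 100)))
  f5 <- filterTopEdges(net, 0.05)
  expect_equal(nrow(networkEdges(f5)), 5L)
  expect_setequal(networkEdges(f5)$weight,
                  sort(networkEdges(net)$weight, decreasing = TRUE)[1:5])
  expect_identical(networkEdges(filterTopEdges(net, 1)), networkEdges(net))
  expect_setequal(networkNodes(f5), networkNodes(net))  # isolates retained

  # ties at the cutoff weight are all kept
  tied <- mkNet(c(5, 4, 3, 3, 3, 2, 1, 1, 1, 1))
  f3 <- filterTopEdges(tied, 0.3)        # ceiling(3) -> cutoff weight 3
  expect_equal(sort(networkEdges(f3)$weight), c(3, 3, 3, 4, 5))

  # nested as the fraction decreases
  key <- function(n) paste(networkEdges(n)$from, networkEdges(n)$to)
  for (fr in c(0.8, 0.5, 0.2))
    expect_true(all(key(filterTopEdges(net, fr * 0.5)) %in%
                    key(filterTopEdges(net, fr))))
})

test_that("weight-to-distance transform is max_w / w", {
  expect_equal(edgeDistance(4, 4), 1)
  expect_equal(edgeDistance(2, 4), 2)
  set.seed(11)
  w <- sort(runif(20, 0.1, 5))
  d <- edgeDistance(w, max(w))
  expect_true(all(diff(d) <= 0))          # monotone decreasing in w
  expect_true(all(d >= 1))
  expect_error(edgeDistance(0, 4), "positive")
  expect_error(edgeDistance(5, 4), "exceed")
})

test_that("subnetwork selection matches the all-pairs shortest-path oracle", {
  # path graph, k larger than the component: everyone included, no sink
  path <- GeneNetwork(data.frame(from = c("a", "b", "c", "d"),
                                 to = c("b", "c", "d", "e"),
                                 weight = c(1, 2, 1, 2)))
  sub <- buildSubnetwork(path, "c", k_sub = 30)
  expect_setequal(subnetworkMembers(sub), c("a", "b", "c", "d", "e"))
  expect_length(sinkNode(sub), 0)

  # boundary gene keeps the summed weight of its removed edges on the sink
  star <- GeneNetwork(data.frame(from = c("q", "a", "a"),
                                 to = c("a", "b", "c"),
                                 weight = c(4, 1.5, 2.5)))
  sub2 <- buildSubnetwork(star, "q", k_sub = 1)
  expect_setequal(subnetworkMembers(sub2), c("q", "a"))
  se <- networkEdges(sub2)
  expect_equal(se$weight[se$to == ".sink"], 4.0)

  # isolated query
  iso <- GeneNetwork(data.frame(from = "a", to = "b", weight = 1),
                     nodes = c("a", "b", "z"))
  sub3 <- buildSubnetwork(iso, "z")
  expect_identical(subnetworkMembers(sub3), "z")
  expect_length(sinkNode(sub3), 0)

  # random graphs vs Floyd-Warshall
  for (seed in 1:10) {
    net <- randomNetwork(12, seed)
    e <- networkEdges(net)
    D <- oracleFloydWarshall(networkNodes(net), e,
                             maxEdgeWeight(net) / e$weight)
    q <- networkNodes(net)[1]
    sub <- buildSubnetwork(net, q, k_sub = 5)
    got <- sort(unname(dijkstraDistances(sub)[setdiff(subnetworkMembers(sub), q)]))
    dq <- sort(D[q, setdiff(colnames(D), q)])
    dq <- dq[is.finite(dq)]
    expect_equal(got, unname(dq[seq_along(got)]))    # the 5 nearest
    expect_equal(unname(dijkstraDistances(sub)[q]), 0)
  }
})

test_that("random-walk probabilities match a dense direct solve", {
  single <- GeneNetwork(data.frame(from = "q", to = "a", weight = 2))
  r1 <- randomWalkRanks(buildSubnetwork(single, "q"))
  expect_identical(neighborRanks(r1), c(a = 1L))

  # two symmetric neighbors: equal probability, deterministic tie-break
  sym <- GeneNetwork(data.frame(from = c("q", "q"), to = c("a", "b"),
                                weight = c(2, 2)))
  r2 <- randomWalkRanks(buildSubnetwork(sym, "q"))
  p <- walkProbabilities(r2)
  expect_equal(p[["a"]], p[["b"]], tolerance = 1e-9)
  expect_identical(neighborRanks(r2), c(a = 1L, b = 2L))

  for (seed in 1:8) {
    net <- randomNetwork(8, seed)
    sub <- buildSubnetwork(net, networkNodes(net)[2], k_sub = 6)
    sub <- randomWalkRanks(sub)
    p <- walkProbabilities(sub)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    oracle <- oracleWalkSolve(sub)
    expect_equal(p[names(oracle)], oracle, tolerance = 1e-8)
    # ranks are a permutation ordered by probability
    r <- neighborRanks(sub)
    expect_setequal(r, seq_along(r))
    expect_true(all(diff(p[names(sort(r))]) <= 1e-12))
  }

  lonely <- buildSubnetwork(GeneNetwork(data.frame(from = "a", to = "b",
                                                   weight = 1),
                                        nodes = c("a", "b", "z")), "z")
  expect_error(randomWalkRanks(lonely), "non-query")
})

test_that("neighbor weights are max_w over Dijkstra distance", {
  net <- GeneNetwork(data.frame(from = c("q", "a"), to = c("a", "b"),
                                weight = c(4, 2)))
  sub <- buildSubnetwork(net, "q")
  expect_equal(neighborWeight(sub, "a"), 4)        # d = 1 on the max edge
  expect_equal(neighborWeight(sub, "b"), 4 / 3)    # d = 1 + 2
  expect_error(neighborWeight(sub, "zz"), "not a neighbor")

  for (seed in 1:5) {
    netr <- randomNetwork(10, seed)
    subr <- buildSubnetwork(netr, networkNodes(netr)[1], k_sub = 6)
    nb <- setdiff(subnetworkMembers(subr), queryGene(subr))
    d <- dijkstraDistances(subr)[nb]
    w <- vapply(nb, function(g) neighborWeight(subr, g), numeric(1))
    expect_equal(unname(w[order(d)]), unname(sort(w, decreasing = TRUE)))
  }
})
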