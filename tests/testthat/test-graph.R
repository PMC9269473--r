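test_that("cost thresholding implements the magnitude rule", {
  set.seed(81)
  W <- matrix(runif(100, 0, 0.6), 10, 10); diag(W) <- 0
  W[2, 3] <- 0.6                              # pin the maximum
  net <- costThreshold(W, 21)
  cut <- (1 - 21 / 100) * 0.6
  expect_equal(cut, 0.474)
  expect_equal(unname(net@binary), unname(W >= cut & W > 0))
  # 100% keeps every nonzero edge
  all100 <- costThreshold(W, 100)
  expect_equal(sum(all100@binary), sum(W > 0))
  # a single edge survives any cost
  single <- matrix(0, 3, 3); single[1, 2] <- 0.2
  expect_equal(sum(costThreshold(single, 1)@binary), 1)
  expect_error(costThreshold(matrix(0, 3, 3), 50), "all-zero")
})

test_that("basic measures count degrees, density and strength", {
  C <- matrix(1, 4, 4); diag(C) <- 0
  b <- basicMeasures(costThreshold(C, 100))
  expect_equal(b$density, 100)
  expect_equal(b$nodes$degree, rep(6, 4))
  expect_equal(b$nodes$inDegree, rep(3, 4))
  # N = 62 complete graph has N(N-1) = 3782 edges
  C62 <- matrix(0.5, 62, 62); diag(C62) <- 0
  n62 <- costThreshold(C62, 100)
  expect_equal(sum(n62@binary), 3782)
  expect_equal(basicMeasures(n62)$density, 100)
  # an edgeless network has density 0
  empty <- new("DirectedNetwork", weights = matrix(0, 4, 4),
               binary = matrix(FALSE, 4, 4), cost = 100,
               labels = paste0("n", 1:4))
  expect_equal(basicMeasures(empty)$density, 0)
})

test_that("integration measures equal the Floyd-Warshall oracle", {
  C <- matrix(1, 4, 4); diag(C) <- 0
  it <- integrationMeasures(costThreshold(C, 100))
  expect_equal(it$charPathLength, 1)
  expect_equal(it$globalEfficiency, 1)
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  itc <- integrationMeasures(costThreshold(chain, 100))
  expect_equal(itc$charPathLength, (1 + 1 + 2) / 3)
  expect_equal(itc$globalEfficiency, (1 + 1 + 0.5) / 6)
  set.seed(82)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    A <- matrix(rbinom(n * n, 1, runif(1, 0.2, 0.7)), n, n); diag(A) <- 0
    if (all(A == 0)) next
    expectGraphMatchesOracle(A)
  }
})

test_that("segregation measures match enumeration on canonical motifs", {
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  sg <- segregationMeasures(costThreshold(cyc, 100))
  expect_equal(sg$clustering, oracleClustering(cyc))
  expect_true(all(sg$clustering > 0))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1    # hub with silent leaves
  sgs <- segregationMeasures(costThreshold(star, 100))
  expect_equal(sgs$clustering[1], 0)
  C <- matrix(1, 5, 5); diag(C) <- 0
  sgc <- segregationMeasures(costThreshold(C, 100))
  expect_equal(sgc$clustering, rep(1, 5))
  expect_equal(sgc$localEfficiency, rep(1, 5))
})

test_that("betweenness counts mediated shortest paths", {
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  b <- betweennessCentrality(costThreshold(chain, 100))
  expect_equal(unname(b), c(0, 0.5, 0))
  C <- matrix(1, 5, 5); diag(C) <- 0
  expect_equal(unname(betweennessCentrality(costThreshold(C, 100))),
               rep(0, 5))
})

test_that("every measure agrees with the oracles on all small digraphs", {
  for (A in allDigraphs(3)) expectGraphMatchesOracle(A)
})

test_that("edge count grows with cost and efficiency with edges", {
  set.seed(83)
  W <- matrix(runif(64, 0, 1), 8, 8); diag(W) <- 0
  prevEdges <- -1; prevEff <- -1
  for (cost in c(5, 20, 40, 60, 80, 100)) {
    net <- costThreshold(W, cost)
    e <- sum(net@binary)
    expect_gte(e, prevEdges)
    eff <- integrationMeasures(net)$globalEfficiency
    expect_gte(eff + 1e-12, prevEff)        # subgraph monotonicity
    prevEdges <- e; prevEff <- eff
  }
  expect_equal(basicMeasures(costThreshold(W, 100))$density,
               100 * sum(W > 0) / (8 * 7))
})

test_that("the cost report carries every measure per cost level", {
  set.seed(84)
  W <- matrix(runif(36, 0, 0.6), 6, 6); diag(W) <- 0
  rep3 <- metricsReport(W, c(21, 30, 51))
  expect_length(rep3, 3)
  expect_named(rep3, c("cost_21", "cost_30", "cost_51"))
  expect_true(all(c("density", "nodes", "charPathLength",
                    "globalEfficiency") %in% names(rep3[[1]])))
  expect_warning(dup <- metricsReport(W, c(100, 100)), "duplicate")
  expect_length(dup, 1)
  expect_error(metricsReport(W, numeric()), "nonempty")
})
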