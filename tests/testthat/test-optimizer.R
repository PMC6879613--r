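test_that("power optimisation normalises, concentrates and flattens", {
  w <- c(0.1, 0.2, 0.3)
  expect_equal(powerOptimise(w, 1), w / sum(w))
  ## direct element-wise evaluation at eta = 10
  expect_equal(powerOptimise(w, 10), w^10 / sum(w^10), tolerance = 1e-12)
  ## eta -> 0 approaches uniform over the support
  p <- powerOptimise(c(0.1, 0, 0.3, 0.2), 1e-8)
  expect_equal(p, c(1, 0, 1, 1) / 3, tolerance = 1e-6)
  ## zero entries never gain mass, sums stay 1 under random inputs
  set.seed(5)
  for (i in 1:50) {
    w <- stats::runif(8) * stats::rbinom(8, 1, 0.7)
    if (sum(w) == 0) w[1] <- 0.5
    eta <- stats::runif(1, 0.01, 30)
    p <- powerOptimise(w, eta)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p[w == 0] == 0))
  }
  expect_error(powerOptimise(c(0, 0), 1), "positive sum")
  expect_error(powerOptimise(w, 0), "eta")
})

test_that("input-vector combination stays on the simplex", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0.5, 0.5); p3 <- c(0.2, 0.3, 0.5)
  expect_equal(combineInputVectors(list(p1), 7), p1)
  expect_equal(combineInputVectors(list(p1, p2), c(1, 1)), (p1 + p2) / 2)
  r <- c(1, 2, 4)
  want <- (p1 / 1 + p2 / 2 + p3 / 4) / (1 + 1 / 2 + 1 / 4)
  expect_equal(combineInputVectors(list(p1, p2, p3), r), want,
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    t <- sample(1:5, 1)
    ps <- lapply(seq_len(t), function(.) { x <- stats::runif(6); x / sum(x) })
    r <- stats::runif(t, 1e-3, 1e3)
    expect_equal(sum(combineInputVectors(ps, r)), 1, tolerance = 1e-10)
  }
  expect_error(combineInputVectors(list(), 1), "at least one")
})

test_that("preselection keeps a lone community with full mass and splits
           mass over symmetric components", {
  g <- generateKNNR(30, 4, seed = 3)
  cs <- detectCDI(g, m = 1)
  if (nCommunities(cs) == 1) {
    sel <- leaderPreselect(laplacianMatrix(g), cs,
                           basisVectors(cs@basis)[, 1])
    expect_identical(sel$kept, 1L)
    expect_equal(sel$mass, 1)
  }
  ## two identical disconnected components share the mass equally
  A1 <- matrix(0, 4, 4); A1[1, 2] <- A1[2, 3] <- A1[3, 4] <- A1[4, 1] <- 1
  A <- rbind(cbind(A1, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), A1))
  vL1 <- rep(1 / sqrt(8), 8)
  cset <- makeCommunitySet(c(1, 5), rep(1:2, each = 4), vL1)
  L <- Matrix::Diagonal(x = rowSums(A)) - A
  sel <- leaderPreselect(L, cset, vL1)
  expect_setequal(sel$kept, 1:2)
  expect_equal(sel$mass, c(0.5, 0.5), tolerance = 0.02)
})

test_that("a community whose influence is dominated by another's is
           discarded", {
  ## star: every leaf observes the centre, so the centre is the sole
  ## effective influencer; a leaf community gains nothing from mass
  A <- matrix(0, 6, 6)
  A[2:6, 1] <- 1
  L <- Matrix::Diagonal(x = rowSums(A)) - A
  vL1 <- c(1, 0, 0, 0, 0, 0)
  cset <- makeCommunitySet(c(1, 6), c(1, 1, 1, 1, 1, 2), vL1)
  ## grid oracle over the 2-simplex: all mass on the centre dominates
  rates <- sapply(seq(0, 1, by = 0.05), function(a) {
    c0 <- numeric(6); c0[1] <- a; c0[6] <- 1 - a
    bruteRate(L, c0)
  })
  expect_equal(which.max(rates), length(rates))
  sel <- leaderPreselect(L, cset, vL1)
  expect_identical(sel$kept, 1L)
  expect_equal(sel$mass, 1)
})

test_that("the staged optimiser returns simplex allocations with a
           non-decreasing accepted-stage rate trace", {
  for (seed in 1:5) {
    g <- generateKNNR(60, 6, seed = seed + 10)
    cs <- detectCDI(g, m = 3)
    res <- optimisePerturbation(g, cs)
    expect_true(isSimplexAllocation(res@allocation, tol = 1e-10))
    expect_true(all(diff(res@stages$rate) > -1e-12))
    expect_gte(res@rate, max(res@stages$rate) - 1e-12)
    ## dominates the plain vL1 allocation
    expect_gte(res@rate, res@baselineRate * (1 - 1e-9))
  }
})

test_that("the final rate is permutation-equivariant", {
  g <- generateKNNR(40, 5, seed = 31)
  cs <- detectCDI(g, m = 2)
  res <- optimisePerturbation(g, cs)
  set.seed(99)
  perm <- sample(40)
  A <- as.matrix(adjacencyMatrix(g))
  gp <- DirectedGraph(adjacency = A[perm, perm])
  csp <- detectCDI(gp, m = 2)
  resp <- optimisePerturbation(gp, csp)
  ## the staged maximiser is deterministic but follows label-dependent
  ## tie-breaks, so equivariance of the achieved rate holds to the
  ## optimiser's own resolution rather than to machine precision
  expect_equal(resp@rate, res@rate, tolerance = 0.01)
})

test_that("small problems reach the exhaustive grid-search optimum", {
  for (seed in c(2, 7)) {
    g <- randomDigraph(12, p = 0.3, seed = seed + 400)
    cs <- detectCDI(g, m = 2)
    res <- optimisePerturbation(g, cs, control = optimiserControl())
    L <- laplacianMatrix(g)
    vL1 <- basisVectors(cs@basis)[, 1]
    ids <- seq_len(min(nCommunities(cs), 2L))
    om <- cdinet:::communityInputVectors(cs, vL1, ids)
    etaGrid <- exp(seq(log(0.1), log(20), length.out = 16))
    best <- 0
    if (length(om) == 1L) {
      for (e1 in etaGrid)
        best <- max(best, bruteRate(L, powerOptimise(om[[1]], e1)))
    } else {
      rGrid <- exp(seq(log(1e-3), log(1e3), length.out = 16))
      for (e1 in etaGrid) for (e2 in etaGrid) for (rr in rGrid) {
        c0 <- combineInputVectors(list(powerOptimise(om[[1]], e1),
                                       powerOptimise(om[[2]], e2)),
                                  c(1, rr))
        best <- max(best, bruteRate(L, c0))
      }
    }
    expect_gte(res@rate, best * 0.98)
  }
})
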