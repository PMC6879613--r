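test_that("influence coordinates reproduce independent norm computations", {
  ic <- randomInfluence(50, 3, seed = 1)
  expect_equal(radii(ic), apply(ic@coords, 1, function(x) sqrt(sum(x^2))))
  ## m = 1: radii are absolute first-eigenvector entries
  g <- generateErdosRenyi(30, 5, seed = 2)
  b <- dominantLeftEigenvectors(g, m = 1)
  expect_equal(radii(influenceCoordinates(b)), abs(basisVectors(b)[, 1]))
})

test_that("leader detection agrees with the brute-force neighbour scan", {
  for (seed in 1:25) {
    n <- sample(10:50, 1)
    g <- randomDigraph(n, p = 0.12, weighted = seed %% 3 == 0,
                       seed = seed + 500)
    ic <- randomInfluence(n, sample(1:3, 1))
    got <- sort(findLeaders(g, ic))
    want <- sort(bruteLeaders(as.matrix(adjacencyMatrix(g)), radii(ic)))
    expect_identical(got, want)
  }
})

test_that("a vertex with no out-edges always leads; uniform radii make
           every vertex a leader", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  g <- DirectedGraph(adjacency = A)
  ic <- new("InfluenceCoordinates",
            coords = matrix(c(1, 2, 3, 4), 4, 1), radii = c(1, 2, 3, 4))
  expect_true(4 %in% findLeaders(g, ic))
  icu <- new("InfluenceCoordinates",
             coords = matrix(1, 4, 1), radii = rep(1, 4))
  expect_setequal(findLeaders(g, icu), 1:4)
})

test_that("community assignment matches the exhaustive increasing-path
           oracle", {
  for (seed in 1:25) {
    n <- sample(10:50, 1)
    g <- randomDigraph(n, p = 0.12, seed = seed + 900)
    ic <- randomInfluence(n, sample(1:3, 1))
    leaders <- findLeaders(g, ic)
    cs <- assignCommunities(g, ic, leaders)
    want <- bruteMembership(as.matrix(adjacencyMatrix(g)), ic@coords,
                            leaders)
    expect_identical(cs@membership, want)
    ## partition invariants
    expect_equal(sum(communitySizes(cs)), n)
    expect_equal(nCommunities(cs), length(leaders))
    expect_identical(cs@membership[leaders], seq_along(leaders))
  }
})

test_that("detectCDI composes the oracle-checked steps end to end", {
  for (seed in 1:10) {
    n <- sample(15:50, 1)
    m <- sample(1:3, 1)
    g <- randomDigraph(n, p = 0.15, seed = seed + 40)
    cs <- detectCDI(g, m = m)
    b <- dominantLeftEigenvectors(g, "laplacian", m = m)
    ic <- influenceCoordinates(b)
    leaders <- bruteLeaders(as.matrix(adjacencyMatrix(g)), radii(ic))
    leaders <- leaders[order(-b@vectors[leaders, 1], leaders)]
    expect_identical(communityLeaders(cs), as.integer(leaders))
    expect_identical(communityMembership(cs),
                     bruteMembership(as.matrix(adjacencyMatrix(g)),
                                     ic@coords, leaders))
  }
})

test_that("a single leader yields one community containing every vertex", {
  A <- matrix(0, 5, 5)
  for (i in 1:4) A[i, i + 1] <- 1
  g <- DirectedGraph(adjacency = A)
  ic <- new("InfluenceCoordinates",
            coords = matrix(1:5, 5, 1), radii = as.numeric(1:5))
  leaders <- findLeaders(g, ic)
  expect_identical(leaders, 5L)
  cs <- assignCommunities(g, ic, leaders)
  expect_equal(communityMembership(cs), rep(1L, 5))
})

test_that("membership is invariant to positive scaling of all columns and
           to sign flips of non-first columns", {
  for (seed in 1:6) {
    n <- 30
    g <- randomDigraph(n, p = 0.15, seed = seed + 300)
    ic <- randomInfluence(n, 3)
    leaders <- findLeaders(g, ic)
    cs <- assignCommunities(g, ic, leaders)
    ## positive scaling
    V2 <- ic@coords * 3.7
    ic2 <- new("InfluenceCoordinates", coords = V2,
               radii = sqrt(rowSums(V2^2)))
    expect_identical(findLeaders(g, ic2), leaders)
    expect_identical(assignCommunities(g, ic2, leaders)@membership,
                     cs@membership)
    ## sign flip of columns 2..m
    V3 <- ic@coords; V3[, 2:3] <- -V3[, 2:3]
    ic3 <- new("InfluenceCoordinates", coords = V3,
               radii = sqrt(rowSums(V3^2)))
    expect_identical(findLeaders(g, ic3), leaders)
    expect_identical(assignCommunities(g, ic3, leaders)@membership,
                     cs@membership)
  }
})

test_that("radii strictly increase along any increasing-edge path used for
           assignment", {
  g <- randomDigraph(40, p = 0.12, seed = 77)
  ic <- randomInfluence(40, 2, seed = 78)
  leaders <- findLeaders(g, ic)
  cs <- assignCommunities(g, ic, leaders)
  ## every non-leader vertex must have at least one strictly increasing
  ## out-edge (otherwise it would itself be a leader)
  A <- as.matrix(adjacencyMatrix(g))
  r <- radii(ic)
  for (v in setdiff(seq_len(40), leaders))
    expect_true(any(A[v, ] > 0 & r > r[v]))
})
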