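## Fixture builders and independent brute-force oracles used across the
## suite. Oracles deliberately use naive enumeration so they share no code
## with the implementation paths they check.

## random weighted digraph (Bernoulli edges, uniform weights)
randomDigraph <- function(n, p = 0.15, weighted = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n) * 1
  diag(A) <- 0
  if (weighted) A <- A * matrix(stats::runif(n * n, 0.2, 2), n, n)
  if (all(A == 0)) A[1, 2] <- 1
  DirectedGraph(adjacency = A)
}

## random coordinates + radii fixture in eigenvector space
randomInfluence <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- matrix(stats::rnorm(n * m), n, m)
  V[, 1] <- abs(V[, 1])
  new("InfluenceCoordinates", coords = V, radii = sqrt(rowSums(V^2)))
}

## oracle: k nearest neighbours by full distance-sort per vertex
bruteKnnAdjacency <- function(coords, k) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  A
}

## oracle: leader = no out-neighbour with strictly larger radius ("larger"
## carries the same 1e-9 relative tie tolerance the method defines)
fartherOracle <- function(rj, ri) rj - ri > 1e-9 * pmax(1, ri)

bruteLeaders <- function(A, r) {
  n <- nrow(A)
  out <- integer(0)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (!any(fartherOracle(r[nb], r[v]))) out <- c(out, v)
  }
  out
}

## oracle: all vertices with an increasing-radius directed path to `to`,
## by exhaustive depth-first search over the full edge set
bruteReaches <- function(A, r, to) {
  n <- nrow(A)
  canReach <- logical(n)
  canReach[to] <- TRUE
  repeat {
    grew <- FALSE
    for (v in seq_len(n)) {
      if (canReach[v]) next
      nb <- which(A[v, ] > 0 & fartherOracle(r, r[v]))
      if (any(canReach[nb])) { canReach[v] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  which(canReach)
}

## oracle: full community assignment by enumerating reachable leaders and
## resolving with the scalar product (ties to the more influential leader)
bruteMembership <- function(A, V, leaders) {
  n <- nrow(A)
  r <- sqrt(rowSums(V^2))
  reach <- sapply(leaders, function(u) seq_len(n) %in% bruteReaches(A, r, u))
  membership <- integer(n)
  for (v in seq_len(n)) {
    cand <- which(reach[v, ])
    if (length(cand) == 1L) { membership[v] <- cand; next }
    s <- vapply(cand, function(ci) sum(V[v, ] * V[leaders[ci], ]), 0)
    best <- cand[s >= max(s) - 1e-12 * max(1, abs(max(s)))]
    membership[v] <- best[1L]
  }
  membership
}

## oracle: rightmost eigenvalue of -(L + diag(c)) by dense full spectrum
bruteRate <- function(L, c) {
  ev <- eigen(-(as.matrix(L) + diag(c, nrow(L))), only.values = TRUE)$values
  max(0, -max(Re(ev)))
}

## oracle: nearest-neighbour overlap fraction by an all-pairs scan
bruteOverlap <- function(a, b, dmax = sqrt(3)) {
  va <- a@voxels; vb <- b@voxels
  if (nrow(va) > nrow(vb)) { tmp <- va; va <- vb; vb <- tmp }
  hits <- 0
  for (i in seq_len(nrow(va))) {
    d <- sqrt(colSums((t(vb) - va[i, ])^2))
    if (min(d) <= dmax + 1e-12) hits <- hits + 1
  }
  100 * hits / nrow(va)
}

## tiny helper: CommunitySet built by hand for optimiser tests
makeCommunitySet <- function(leaders, membership, vL1) {
  new("CommunitySet", leaders = as.integer(leaders),
      membership = as.integer(membership),
      leaderScore = vL1[leaders],
      radii = abs(vL1), basis = new("EigenBasis"))
}
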