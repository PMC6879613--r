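voxComm <- function(id, m) new("VoxelCommunity", id = as.integer(id),
                               voxels = m)

test_that("thresholding keeps exactly the high-entry vertices", {
  set.seed(12)
  n <- 100
  V <- matrix(stats::rnorm(n * 3, sd = 0.05), n, 3)
  basis <- new("EigenBasis", matrixKind = "adjacency",
               vectors = abs(V) * cbind(1, sign(V[, 2]), sign(V[, 3])),
               values = as.complex(1:3), skippedValues = complex())
  basis@vectors[, 1] <- abs(basis@vectors[, 1])
  coords <- matrix(sample(1:20, n * 3, replace = TRUE), n, 3)
  membership <- sample(1:4, n, replace = TRUE)
  cs <- makeCommunitySet(leaders = sapply(1:4, function(ci)
    which(membership == ci)[1]), membership = membership,
    vL1 = abs(V[, 1]))
  cs@membership <- membership  # leaders need not be argmax here
  vcs <- thresholdCommunities(cs, coords, basis, tau = 0.01)
  ## per-entry scan oracle
  keep <- apply(abs(basis@vectors) > 0.01, 1, any)
  for (vc in vcs) {
    want <- coords[keep & membership == vc@id, , drop = FALSE]
    expect_equal(unname(vc@voxels), unname(want))
  }
  kept_ids <- vapply(vcs, function(v) v@id, 1L)
  empty <- setdiff(1:4, kept_ids)
  for (ci in empty)
    expect_false(any(keep & membership == ci))
  ## tau = 0 keeps every vertex with any nonzero entry
  vcs0 <- thresholdCommunities(cs, coords, basis, tau = 0)
  expect_equal(sum(vapply(vcs0, function(v) nrow(v@voxels), 1L)),
               sum(apply(abs(basis@vectors) > 0, 1, any)))
})

test_that("overlap fraction identities hold", {
  line <- cbind(1:10, 1, 1)
  a <- voxComm(1, line)
  expect_equal(overlapFraction(a, a), 100)
  ## same line shifted by (1,1,1): every voxel within sqrt(3)
  b <- voxComm(2, line + 1)
  expect_equal(overlapFraction(a, b), 100)
  expect_equal(bruteOverlap(a, b), 100)
  ## far apart communities do not overlap
  c <- voxComm(3, line + 5)
  expect_equal(overlapFraction(a, c), 0)
  ## agreement with the brute-force nearest-neighbour scan
  set.seed(77)
  for (i in 1:10) {
    va <- voxComm(1, matrix(sample(1:12, 30, TRUE), ncol = 3))
    vb <- voxComm(2, matrix(sample(1:12, 45, TRUE), ncol = 3))
    expect_equal(overlapFraction(va, vb), bruteOverlap(va, vb))
    ## enlarging dmax never decreases the overlap
    expect_gte(overlapFraction(va, vb, dmax = 3),
               overlapFraction(va, vb))
  }
})

test_that("mean matching communities counts one-to-one pairs above each
           threshold", {
  base <- lapply(1:5, function(i)
    voxComm(i, cbind(1:10 + 20 * i, 1, 1)))
  ## identical scans: every community matches at 100%
  mr <- meanMatchingCommunities(base, base)
  expect_equal(meanMatches(mr), 5)
  expect_true(all(mr@perThreshold$matches == 5))
  ## fully disjoint scans match nothing
  far <- lapply(base, function(v) voxComm(v@id, v@voxels + 500))
  expect_equal(meanMatches(meanMatchingCommunities(base, far)), 0)
  ## constructed: 3 of 5 overlap at 100%, the rest at 20%
  part <- lapply(base, function(v) {
    vox <- v@voxels
    if (v@id <= 3) voxComm(v@id, vox) else
      voxComm(v@id, rbind(vox[1:2, , drop = FALSE], vox[3:10, ] + 100))
  })
  mr2 <- meanMatchingCommunities(base, part)
  expect_equal(meanMatches(mr2), 3)
  ## per-threshold counts never increase with the threshold
  expect_true(all(diff(mr2@perThreshold$matches) <= 0))
})

test_that("matching is symmetric and maximal on self-comparison", {
  set.seed(31)
  s1 <- lapply(1:4, function(i)
    voxComm(i, matrix(sample(1:15, 36, TRUE), ncol = 3) +
                 c(20 * i, 0, 0)))
  s2 <- lapply(1:4, function(i)
    voxComm(i, matrix(sample(1:15, 24, TRUE), ncol = 3) +
                 c(20 * i, 1, 0)))
  expect_equal(meanMatches(meanMatchingCommunities(s1, s2)),
               meanMatches(meanMatchingCommunities(s2, s1)))
  self1 <- meanMatches(meanMatchingCommunities(s1, s1))
  expect_gte(self1, meanMatches(meanMatchingCommunities(s1, s2)))
})

test_that("a one-voxel translation of a whole scan leaves matches
           unchanged", {
  set.seed(41)
  s1 <- lapply(1:3, function(i)
    voxComm(i, matrix(sample(1:10, 30, TRUE), ncol = 3) +
                 c(15 * i, 0, 0)))
  shifted <- lapply(s1, function(v) voxComm(v@id,
    sweep(v@voxels, 2, c(1, 0, 0), `+`)))
  expect_equal(meanMatches(meanMatchingCommunities(s1, shifted)),
               meanMatches(meanMatchingCommunities(s1, s1)))
})

test_that("scan pairs reproduce their ground truth under mild dropout and
           jitter", {
  sp0 <- generateScanPair(q = 4, dropout = 0, jitter = 0, seed = 5)
  expect_equal(meanMatches(meanMatchingCommunities(sp0$scan1, sp0$scan2)),
               4)
  sp <- generateScanPair(q = 4, dropout = 0.25, jitter = 1, seed = 6)
  mr <- meanMatchingCommunities(sp$scan1, sp$scan2)
  expect_equal(meanMatches(mr), sum(sp$truth$matched))
  ## heavy dropout destroys most communities and most matches
  spHeavy <- generateScanPair(q = 4, dropout = 0.99, jitter = 1, seed = 7)
  expect_lt(meanMatches(meanMatchingCommunities(spHeavy$scan1,
                                                spHeavy$scan2)), 4)
})
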