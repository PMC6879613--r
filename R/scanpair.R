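## Synthetic scan/rescan voxel fixtures: a first scan of q disjoint
## pathway-like communities on an integer grid, and a rescan obtained by
## per-voxel dropout (the density drop seen between repeated acquisitions)
## plus bounded integer jitter (small positional errors).

## grow a self-avoiding-ish lattice tube of ~len voxels from a start point
growTube <- function(start, len, nSide) {
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- start
  vox <- matrix(cur, 1, 3)
  while (nrow(vox) < len) {
    nxt <- cur + steps[sample.int(6, 1), ]
    nxt <- pmin(pmax(nxt, 1), nSide)
    cur <- nxt
    vox <- rbind(vox, nxt)
  }
  unique(vox)
}

#' Generate a paired scan/rescan voxel fixture
#'
#' Builds \code{q} disjoint pathway-like voxel communities (random lattice
#' tubes) in an \code{nSide}^3 grid as scan 1, then derives scan 2 by
#' dropping each voxel independently with probability \code{dropout} and
#' shifting each survivor by an integer jitter drawn uniformly from
#' \code{-jitter..jitter} per axis. With \code{jitter <= 1} every rescan
#' voxel stays within \code{sqrt(3)} mm of its origin, so every surviving
#' community pair overlaps fully from the rescan side; ground truth pairs
#' communities by identity.
#'
#' @param nSide grid side length.
#' @param q number of communities.
#' @param dropout per-voxel drop probability in [0, 1).
#' @param jitter maximum absolute per-axis voxel shift.
#' @param voxelsPerCommunity target tube length.
#' @param seed optional integer seed.
#' @param buildGraphs also wire each scan's voxels as a k-NNR digraph
#'   (\code{k = 6}) and return the graphs.
#' @return list with \code{scan1}, \code{scan2} (lists of
#'   \code{\linkS4class{VoxelCommunity}}), \code{truth} (data.frame of
#'   community ids expected to match), and optionally \code{graph1},
#'   \code{graph2}.
#' @examples
#' sp <- generateScanPair(q = 3, dropout = 0, jitter = 0, seed = 1)
#' meanMatches(meanMatchingCommunities(sp$scan1, sp$scan2))
#' @export
generateScanPair <- function(nSide = 40, q = 5, dropout = 0.2, jitter = 1,
                             voxelsPerCommunity = 60, seed = NULL,
                             buildGraphs = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (jitter < 0) stop("jitter must be nonnegative")
  ## spread the tube seeds over a coarse sub-lattice to keep communities
  ## disjoint and mutually distant
  grid <- as.matrix(expand.grid(x = seq(4, nSide - 3, by = 12),
                                y = seq(4, nSide - 3, by = 12),
                                z = seq(4, nSide - 3, by = 12)))
  if (nrow(grid) < q) stop("grid too small for q communities; raise nSide")
  starts <- grid[sample.int(nrow(grid), q), , drop = FALSE]
  scan1 <- list(); scan2 <- list()
  used <- matrix(numeric(), 0, 3)
  for (ci in seq_len(q)) {
    vox <- growTube(starts[ci, ], voxelsPerCommunity, nSide)
    scan1[[ci]] <- new("VoxelCommunity", id = ci, voxels = vox)
    keep <- stats::runif(nrow(vox)) >= dropout
    v2 <- vox[keep, , drop = FALSE]
    if (nrow(v2) && jitter > 0)
      v2 <- v2 + matrix(sample(seq(-jitter, jitter), 3 * nrow(v2),
                               replace = TRUE), ncol = 3)
    if (nrow(v2))
      scan2[[length(scan2) + 1L]] <-
        new("VoxelCommunity", id = ci, voxels = unique(v2))
  }
  truth <- data.frame(community1 = vapply(scan1, function(v) v@id, 1L),
                      matched = vapply(scan1, function(v) v@id, 1L) %in%
                                vapply(scan2, function(v) v@id, 1L))
  out <- list(scan1 = scan1, scan2 = scan2, truth = truth)
  if (buildGraphs) {
    pts1 <- do.call(rbind, lapply(scan1, function(v) v@voxels))
    pts2 <- do.call(rbind, lapply(scan2, function(v) v@voxels))
    out$graph1 <- knnGraphFromPoints(pts1, min(6, nrow(pts1) - 1))
    out$graph2 <- knnGraphFromPoints(pts2, min(6, nrow(pts2) - 1))
  }
  out
}
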