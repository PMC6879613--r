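## Community-overlap similarity between two voxel-embedded graphs.
## Communities are first reduced to their high-eigenvector-entry vertices,
## then compared by nearest-voxel overlap on the integer mm grid; matched
## one-to-one and counted over a range of overlap thresholds.

#' Threshold communities to their high-entry voxels
#'
#' Keeps a vertex in its community only if the magnitude of its entry
#' exceeds \code{tau} in at least one of the eigenvectors of the CDI
#' coordinate system (default threshold 0.01), and drops communities left
#' empty. Vertices must carry integer voxel coordinates.
#'
#' @param cs a \code{\linkS4class{CommunitySet}}.
#' @param coords integer voxel coordinate matrix (n x 3, 1 mm grid).
#' @param basis an \code{\linkS4class{EigenBasis}}; defaults to the basis
#'   stored in \code{cs}.
#' @param tau eigenvector entry threshold.
#' @return list of \code{\linkS4class{VoxelCommunity}} objects.
#' @export
thresholdCommunities <- function(cs, coords, basis = NULL, tau = 0.01) {
  if (is.null(basis)) basis <- cs@basis
  V <- basis@vectors
  if (!ncol(V)) stop("no eigenvector basis available")
  coords <- as.matrix(coords)
  if (nrow(coords) != length(cs@membership))
    stop("one coordinate row per vertex required")
  keep <- apply(abs(V) > tau, 1, any)
  out <- list()
  for (ci in seq_along(cs@leaders)) {
    sel <- keep & cs@membership == ci
    if (any(sel))
      out[[length(out) + 1L]] <-
        new("VoxelCommunity", id = as.integer(ci),
            voxels = round(coords[sel, , drop = FALSE]))
  }
  out
}

## encode integer voxel rows as scalar keys (collision-free within bbox)
voxelKeys <- function(v, origin, span) {
  (v[, 1] - origin[1]) + span * ((v[, 2] - origin[2]) +
                                   span * (v[, 3] - origin[3]))
}

#' Percentage overlap between two voxel communities
#'
#' The fraction (as a percentage) of the smaller community's voxels whose
#' nearest voxel in the other community lies within \code{dmax} (default
#' \code{sqrt(3)} mm, i.e. same voxel or any adjacent voxel, which also
#' absorbs small positional errors between scans). When both communities
#' have the same size, the larger of the two directional fractions is
#' taken so the measure is symmetric. \code{direction} overrides the
#' default smaller-community perspective.
#'
#' @param a,b \code{\linkS4class{VoxelCommunity}} objects.
#' @param dmax maximum overlapping voxel distance in mm.
#' @param direction \code{"smaller"} (default), \code{"larger"},
#'   \code{"a"} or \code{"b"}: whose voxels the fraction is computed over.
#' @return overlap percentage in [0, 100].
#' @export
overlapFraction <- function(a, b, dmax = sqrt(3),
                            direction = c("smaller", "larger", "a", "b")) {
  direction <- match.arg(direction)
  if (dmax < 0) stop("dmax must be nonnegative")
  frac <- function(from, to) {
    fa <- from@voxels; tb <- to@voxels
    rad <- floor(dmax)
    off <- as.matrix(expand.grid(dx = -rad:rad, dy = -rad:rad,
                                 dz = -rad:rad))
    off <- off[sqrt(rowSums(off^2)) <= dmax + 1e-12, , drop = FALSE]
    allv <- rbind(fa, tb)
    origin <- apply(allv, 2, min) - rad - 1
    span <- max(apply(allv, 2, max) - origin) + 2 * rad + 3
    bk <- voxelKeys(tb, origin, span)
    hit <- logical(nrow(fa))
    for (oi in seq_len(nrow(off))) {
      sh <- sweep(fa, 2, off[oi, ], `+`)
      hit <- hit | (voxelKeys(sh, origin, span) %in% bk)
      if (all(hit)) break
    }
    100 * mean(hit)
  }
  na <- nrow(a@voxels); nb <- nrow(b@voxels)
  switch(direction,
         a = frac(a, b),
         b = frac(b, a),
         larger = if (na >= nb) frac(a, b) else frac(b, a),
         smaller = if (na < nb) frac(a, b)
                   else if (nb < na) frac(b, a)
                   else max(frac(a, b), frac(b, a)))
}

#' Mean number of matching communities between two scans
#'
#' Computes all pairwise community overlaps between two scans, pairs
#' communities one-to-one greedily by descending overlap (any community
#' can belong to at most one matched pair), counts the pairs whose
#' overlap exceeds each threshold, and returns the mean count over the
#' thresholds (default 50\% to 90\% in 10\% steps) — the similarity
#' statistic used to recognise a subject from two scans of the same
#' brain.
#'
#' @param scan1,scan2 lists of \code{\linkS4class{VoxelCommunity}}.
#' @param thresholds overlap thresholds in percent.
#' @param dmax maximum overlapping voxel distance (mm).
#' @param direction overlap perspective, see
#'   \code{\link{overlapFraction}}.
#' @return a \code{\linkS4class{MatchResult}}.
#' @export
meanMatchingCommunities <- function(scan1, scan2,
                                    thresholds = c(50, 60, 70, 80, 90),
                                    dmax = sqrt(3),
                                    direction = "smaller") {
  n1 <- length(scan1); n2 <- length(scan2)
  O <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    O[i, j] <- overlapFraction(scan1[[i]], scan2[[j]], dmax, direction)
  ## greedy one-to-one pairing by descending overlap, ties by indices
  M <- O
  pairs <- data.frame(community1 = integer(), community2 = integer(),
                      overlap = numeric())
  for (p in seq_len(min(n1, n2))) {
    top <- max(M)
    best <- which(M == top, arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(community1 = unname(best[1]),
                                     community2 = unname(best[2]),
                                     overlap = top))
    M[best[1], ] <- -Inf
    M[, best[2]] <- -Inf
  }
  counts <- vapply(thresholds,
                   function(th) sum(pairs$overlap > th), numeric(1))
  new("MatchResult", overlap = O,
      pairs = pairs,
      perThreshold = data.frame(threshold = thresholds, matches = counts),
      meanMatches = mean(counts))
}

#' @describeIn meanMatchingCommunities mean match count accessor.
#' @param x a \code{MatchResult}.
#' @export
meanMatches <- function(x) x@meanMatches

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", nrow(object@overlap), "x", ncol(object@overlap),
      "communities compared\n")
  print(object@perThreshold, row.names = FALSE)
  cat("  mean number of matching communities:",
      format(object@meanMatches, digits = 4), "\n")
  invisible(object)
})
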