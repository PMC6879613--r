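#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix drop0 t rowSums colSums
NULL

#' Weighted directed graph
#'
#' Holds a weighted directed graph as a compressed sparse adjacency matrix
#' \code{A}, where \code{A[i, j] > 0} records an edge from vertex \code{i} to
#' vertex \code{j} of that weight. Vertices may optionally carry spatial
#' coordinates (2-D for planar geometric graphs, 3-D for flocks and voxel
#' graphs; mm units for voxel graphs). Self-loops are disallowed and weights
#' must be strictly positive.
#'
#' The outdegree of vertex \code{i} is the \code{i}-th row sum of \code{A};
#' the indegree of \code{j} is the \code{j}-th column sum.
#'
#' @slot adjacency a \code{\link[Matrix]{dgCMatrix-class}} adjacency matrix.
#' @slot coords numeric matrix of per-vertex coordinates with \code{n} rows
#'   and 2 or 3 columns, or a 0-row matrix when no geometry is attached.
#'
#' @seealso \code{\link{DirectedGraph}}, \code{\link{laplacianMatrix}},
#'   \code{\link{generateKNNR}}
#' @export
setClass("DirectedGraph",
  slots = c(adjacency = "dgCMatrix", coords = "matrix"))

setValidity("DirectedGraph", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A))
    msg <- c(msg, "adjacency matrix must be square")
  if (length(A@x) && any(A@x <= 0))
    msg <- c(msg, "edge weights must be strictly positive")
  if (nrow(A) > 0 && any(Matrix::diag(A) != 0))
    msg <- c(msg, "self-loops are not allowed")
  cc <- object@coords
  if (nrow(cc) > 0) {
    if (nrow(cc) != nrow(A))
      msg <- c(msg, "coords must have one row per vertex")
    if (!ncol(cc) %in% c(2L, 3L))
      msg <- c(msg, "coords must have 2 or 3 columns")
    if (anyNA(cc) || any(!is.finite(cc)))
      msg <- c(msg, "coords must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Selected dominant left eigenvectors of a graph matrix
#'
#' The influence coordinate system used by CDI: the real parts of the
#' \code{m} most dominant left eigenvectors of either the Laplacian
#' (\code{L = D - A}, dominance = real part closest to zero, starting from
#' the zero eigenvalue) or the adjacency matrix (dominance = descending real
#' part from the spectral radius). When a dominant eigenvalue belongs to a
#' complex-conjugate pair only one member of the pair is kept (their real
#' parts coincide) and the next non-conjugate eigenvector is taken instead;
#' the discarded eigenvalues are recorded in \code{skippedValues}.
#'
#' Columns are normalised to unit 2-norm. The first column is the Perron
#' direction and is sign-fixed to be entrywise nonnegative; later columns
#' have the sign of their largest-magnitude entry fixed positive so that
#' repeated runs are reproducible (downstream results are sign-invariant).
#'
#' @slot matrixKind \code{"laplacian"} or \code{"adjacency"}.
#' @slot vectors n x m real matrix; column j is the j-th dominant left
#'   eigenvector (real part, unit norm).
#' @slot values complex vector of the m retained eigenvalues.
#' @slot skippedValues complex eigenvalues discarded as conjugate twins.
#'
#' @seealso \code{\link{dominantLeftEigenvectors}}
#' @export
setClass("EigenBasis",
  slots = c(matrixKind = "character", vectors = "matrix",
            values = "complex", skippedValues = "complex"),
  prototype = prototype(matrixKind = "laplacian",
                        vectors = matrix(numeric(), 0, 0),
                        values = complex(), skippedValues = complex()))

setValidity("EigenBasis", function(object) {
  msg <- character()
  if (!object@matrixKind %in% c("laplacian", "adjacency"))
    msg <- c(msg, "matrixKind must be 'laplacian' or 'adjacency'")
  if (ncol(object@vectors) != length(object@values))
    msg <- c(msg, "one eigenvalue per eigenvector column required")
  if (ncol(object@vectors) > 0) {
    if (min(object@vectors[, 1]) < -1e-8)
      msg <- c(msg, "first column must be entrywise nonnegative (sign-fixed)")
    v <- object@values
    if (length(v) > 1) {
      for (i in seq_along(v)) for (j in seq_along(v)) {
        if (i < j && abs(v[i] - Conj(v[j])) < 1e-10 && abs(Im(v[i])) > 1e-10)
          msg <- c(msg, "retained eigenvalues contain a conjugate pair")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Vertex positions in the eigenvector coordinate system
#'
#' Each vertex is placed at the point whose j-th coordinate is its entry in
#' the j-th selected eigenvector; \code{radii} holds the Euclidean distance
#' of each vertex from the origin of this coordinate system.
#'
#' @slot coords n x m real matrix of vertex positions.
#' @slot radii numeric vector, \code{radii[i] = sqrt(sum(coords[i, ]^2))}.
#'
#' @seealso \code{\link{influenceCoordinates}}
#' @export
setClass("InfluenceCoordinates",
  slots = c(coords = "matrix", radii = "numeric"))

setValidity("InfluenceCoordinates", function(object) {
  if (nrow(object@coords) != length(object@radii))
    return("one radius per vertex required")
  r <- sqrt(rowSums(object@coords^2))
  if (length(r) && max(abs(r - object@radii)) > 1e-8 * (1 + max(r)))
    return("radii must equal row norms of coords")
  TRUE
})

#' Communities of Dynamical Influence
#'
#' A partition of the vertex set into communities, each anchored to a leader
#' vertex (a vertex with no outgoing edge towards any vertex lying farther
#' from the origin of the eigenvector coordinate system). Communities are
#' numbered 1, 2, ... in decreasing order of their leader's entry in the
#' first left eigenvector, i.e. community 1 is the most dynamically
#' influential.
#'
#' @slot leaders integer vector of leader vertices ordered by descending
#'   influence; \code{leaders[c]} anchors community \code{c}.
#' @slot membership integer vector, community id of every vertex.
#' @slot leaderScore first-left-eigenvector entry of each leader.
#' @slot radii per-vertex distance from the eigenvector-space origin.
#' @slot basis the \code{\linkS4class{EigenBasis}} the communities were
#'   computed from (kept for thresholding and reporting).
#'
#' @seealso \code{\link{detectCDI}}, \code{\link{assignCommunities}}
#' @export
setClass("CommunitySet",
  slots = c(leaders = "integer", membership = "integer",
            leaderScore = "numeric", radii = "numeric",
            basis = "EigenBasis"))

setValidity("CommunitySet", function(object) {
  msg <- character()
  t <- length(object@leaders)
  if (length(object@leaderScore) != t)
    msg <- c(msg, "one leader score per leader required")
  if (length(object@membership)) {
    if (!all(object@membership %in% seq_len(t)))
      msg <- c(msg, "membership ids must index the leader list")
    if (anyDuplicated(object@leaders))
      msg <- c(msg, "leaders must be distinct vertices")
    if (t && !all(object@membership[object@leaders] == seq_len(t)))
      msg <- c(msg, "each leader must belong to its own community")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the staged consensus-perturbation optimisation
#'
#' The simplex-constrained input allocation \code{c} (\code{sum(c) == 1},
#' \code{c >= 0}) produced by the staged optimiser, together with the
#' convergence rate it achieves, the accepted-stage rate trace, and the
#' power/weight variables of the retained community input vectors.
#'
#' @slot allocation length-n perturbation allocation on the simplex.
#' @slot rate achieved convergence rate, the magnitude of the rightmost
#'   eigenvalue of \code{-(L + diag(allocation))}.
#' @slot stages data.frame trace (stage label, description, rate) of every
#'   accepted optimisation stage; rates are non-decreasing.
#' @slot eta power variables of the retained input vectors.
#' @slot r weighting variables of the retained input vectors.
#' @slot communities community ids (in the input \code{CommunitySet})
#'   whose input vectors were retained.
#' @slot baselineRate rate of the plain first-left-eigenvector allocation
#'   \code{c = vL1 / sum(vL1)}, for reference.
#'
#' @seealso \code{\link{optimisePerturbation}}
#' @export
setClass("PerturbationResult",
  slots = c(allocation = "numeric", rate = "numeric", stages = "data.frame",
            eta = "numeric", r = "numeric", communities = "integer",
            baselineRate = "numeric"))

setValidity("PerturbationResult", function(object) {
  msg <- character()
  c0 <- object@allocation
  if (length(c0)) {
    if (abs(sum(c0) - 1) > 1e-8)
      msg <- c(msg, "allocation must sum to 1")
    if (min(c0) < -1e-10)
      msg <- c(msg, "allocation must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' A community embedded in an integer voxel grid
#'
#' The surviving vertices of one community after eigenvector-entry
#' thresholding, represented by their integer grid coordinates (1 mm
#' spacing for voxel-wise graphs).
#'
#' @slot id integer community id.
#' @slot voxels integer matrix with 3 columns (x, y, z), one row per voxel.
#'
#' @seealso \code{\link{thresholdCommunities}}, \code{\link{overlapFraction}}
#' @export
setClass("VoxelCommunity",
  slots = c(id = "integer", voxels = "matrix"))

setValidity("VoxelCommunity", function(object) {
  v <- object@voxels
  if (ncol(v) != 3) return("voxels must have 3 columns")
  if (nrow(v) == 0) return("voxel community must be nonempty")
  if (max(abs(v - round(v))) > 0) return("voxel coordinates must be integral")
  TRUE
})

#' Community-overlap match between two voxel-embedded graphs
#'
#' Pairwise best-overlap percentages between the communities of two scans,
#' the number of one-to-one matched pairs exceeding each overlap threshold,
#' and their mean — the \emph{mean number of matching communities}
#' similarity statistic.
#'
#' @slot overlap matrix of overlap percentages, rows = scan-1 communities,
#'   columns = scan-2 communities.
#' @slot pairs data.frame of the greedy one-to-one pairing (community1,
#'   community2, overlap).
#' @slot perThreshold data.frame with columns threshold, matches.
#' @slot meanMatches mean match count over the thresholds.
#'
#' @seealso \code{\link{meanMatchingCommunities}}
#' @export
setClass("MatchResult",
  slots = c(overlap = "matrix", pairs = "data.frame",
            perThreshold = "data.frame", meanMatches = "numeric"))

#' Recursive spectral-bisection partition
#'
#' Three levels of sign-based splits along the second dominant eigenvector
#' of each sub-community, producing 8 leaf communities.
#'
#' @slot membership integer vector assigning every vertex to a leaf 1..8.
#' @slot record data.frame with one row per internal node: node path,
#'   level, index of the eigenvector used for the split, sizes of the two
#'   halves, and whether the node was flagged (no splitting eigenvector
#'   found; community duplicated into one populated and one empty leaf).
#'
#' @seealso \code{\link{spectralBisect}}
#' @export
setClass("BisectionTree",
  slots = c(membership = "integer", record = "data.frame"))

setValidity("BisectionTree", function(object) {
  if (length(object@membership) &&
      !all(object@membership %in% 1:8))
    return("leaf ids must lie in 1..8")
  TRUE
})
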