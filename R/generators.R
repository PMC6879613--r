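## Synthetic network generators: k-nearest-neighbour geometric digraphs in a
## square plane, fixed/variable-outdegree random digraphs, and the
## rectangular-prism flock point cloud with k-NNR wiring.

resolveOutdegrees <- function(k, n) {
  if (length(k) == 1L) {
    k <- as.integer(k)
    if (k < 1L || k >= n) stop("need 1 <= k < n")
    rep(k, n)
  } else if (length(k) == 2L) {
    k <- as.integer(k)
    if (k[1] > k[2]) stop("k range must be (kmin, kmax) with kmin <= kmax")
    if (k[1] < 1L || k[2] >= n) stop("need 1 <= kmin <= kmax < n")
    sample(seq.int(k[1], k[2]), n, replace = TRUE)
  } else stop("k must be a single outdegree or a (kmin, kmax) range")
}

#' Wire a point cloud as a k-nearest-neighbour digraph
#'
#' Every vertex receives directed edges to its \code{k} nearest neighbours
#' by Euclidean distance. Distance ties are broken towards the lowest
#' vertex index, so the wiring is deterministic for a given point set.
#'
#' @param coords numeric matrix of point positions (rows = vertices).
#' @param k outdegree: a single integer, or a \code{c(kmin, kmax)} range
#'   from which each vertex's outdegree is drawn uniformly.
#' @param weight common edge weight (default 1).
#' @return a \code{\linkS4class{DirectedGraph}} retaining \code{coords}.
#' @seealso \code{\link{generateKNNR}}, \code{\link{generateFlock}}
#' @export
knnGraphFromPoints <- function(coords, k, weight = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  kk <- resolveOutdegrees(k, n)
  d <- as.matrix(stats::dist(coords))
  src <- integer(0); tgt <- integer(0)
  idx <- seq_len(n)
  for (i in idx) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- idx[order(di, idx)][seq_len(kk[i])]
    src <- c(src, rep.int(i, kk[i]))
    tgt <- c(tgt, nb)
  }
  DirectedGraph(data.frame(source = src, target = tgt,
                           weight = rep(weight, length(src))),
                n = n, coords = coords)
}

#' Generate a k-NNR geometric digraph in the unit square
#'
#' Vertices are placed uniformly at random in a square plane and each
#' vertex connects to its \code{k} nearest neighbours by Euclidean
#' distance. With a \code{c(kmin, kmax)} range, each vertex's outdegree is
#' sampled uniformly from the integers in the range (the variable-outdegree
#' variant).
#'
#' @param n number of vertices (must exceed \code{max(k)}).
#' @param k outdegree or \code{c(kmin, kmax)} range.
#' @param weight common edge weight; lowering it below 1 throttles the
#'   information flow along every edge.
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called first so the same seed reproduces the same graph.
#' @return a \code{\linkS4class{DirectedGraph}} with 2-D coords attached.
#' @examples
#' g <- generateKNNR(100, 10, seed = 1)
#' table(outDegrees(g))
#' @export
generateKNNR <- function(n, k, weight = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < max(k) + 1) stop("need n >= k + 1")
  pts <- cbind(stats::runif(n), stats::runif(n))
  colnames(pts) <- c("x", "y")
  knnGraphFromPoints(pts, k, weight)
}

#' Generate a fixed-outdegree random digraph
#'
#' Each vertex emits \code{k} edges to distinct targets chosen uniformly at
#' random among the other vertices (the directed, fixed-outdegree
#' Erdos-Renyi-style model). With a range, per-vertex outdegrees are drawn
#' uniformly from the integers in the range.
#'
#' @inheritParams generateKNNR
#' @return a \code{\linkS4class{DirectedGraph}} without coordinates.
#' @examples
#' g <- generateErdosRenyi(50, 10, seed = 1)
#' all(outDegrees(g) == 10)
#' @export
generateErdosRenyi <- function(n, k, weight = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("need n >= 2")
  kk <- resolveOutdegrees(k, n)
  src <- integer(0); tgt <- integer(0)
  for (i in seq_len(n)) {
    pool <- seq_len(n)[-i]
    nb <- if (length(pool) == kk[i]) pool else sample(pool, kk[i])
    src <- c(src, rep.int(i, kk[i]))
    tgt <- c(tgt, nb)
  }
  DirectedGraph(data.frame(source = src, target = tgt,
                           weight = rep(weight, length(src))), n = n)
}

#' Sample flock positions in a rectangular prism
#'
#' Points are distributed uniformly within a box with sides
#' \code{(1, 1, thickness)}, so the ratio of the smallest to largest side
#' equals \code{thickness} — the flock-thickness convention (starling
#' flocks measure 0.13–0.27; the model default is 0.2).
#'
#' @param n number of birds.
#' @param thickness smallest:largest side ratio in (0, 1].
#' @param seed optional integer seed.
#' @return n x 3 matrix of positions.
#' @export
flockPoints <- function(n, thickness = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (thickness <= 0 || thickness > 1) stop("thickness must be in (0, 1]")
  pts <- cbind(stats::runif(n), stats::runif(n), stats::runif(n) * thickness)
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Generate a prism flock k-NNR digraph
#'
#' Distributes \code{n} birds uniformly in a rectangular prism of thickness
#' \code{thickness} and wires each bird to its \code{k} nearest neighbours
#' in 3-D. The representative flock model uses 1200 birds, thickness 0.2
#' and outdegrees between 5 and 50.
#'
#' @inheritParams generateKNNR
#' @param thickness smallest:largest prism side ratio in (0, 1].
#' @return a \code{\linkS4class{DirectedGraph}} with 3-D coords attached.
#' @examples
#' g <- generateFlock(200, 7, seed = 1)
#' all(outDegrees(g) == 7)
#' @export
generateFlock <- function(n, k, thickness = 0.2, weight = 1, seed = NULL) {
  pts <- flockPoints(n, thickness, seed)
  knnGraphFromPoints(pts, k, weight)
}
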