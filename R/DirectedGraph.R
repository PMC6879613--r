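#' Construct a DirectedGraph
#'
#' Builds a \code{\linkS4class{DirectedGraph}} either from an edge table
#' (1-based \code{source}, \code{target} vertex indices and positive
#' \code{weight}) or directly from a square adjacency matrix. On-disk
#' formats use 0-based indices (see \code{\link{readGraph}}); inside R all
#' vertex indices are 1-based.
#'
#' @param edges data.frame with columns \code{source}, \code{target} and
#'   optionally \code{weight} (default 1), or \code{NULL} when
#'   \code{adjacency} is given.
#' @param n vertex count; defaults to the largest index referenced.
#' @param adjacency square matrix (dense, sparse, or coercible) with
#'   \code{adjacency[i, j] > 0} meaning an edge i -> j.
#' @param coords optional per-vertex coordinate matrix (2 or 3 columns).
#'
#' @return a \code{DirectedGraph}.
#' @examples
#' g <- DirectedGraph(data.frame(source = 1, target = 2, weight = 1), n = 2)
#' outDegrees(g)
#' @export
DirectedGraph <- function(edges = NULL, n = NULL, adjacency = NULL,
                          coords = NULL) {
  if (is.null(adjacency)) {
    stopifnot(is.data.frame(edges) || is.matrix(edges))
    edges <- as.data.frame(edges)
    if (!all(c("source", "target") %in% names(edges)))
      stop("edge table needs 'source' and 'target' columns")
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    if (is.null(n)) n <- if (nrow(edges)) max(edges$source, edges$target) else 0L
    adjacency <- Matrix::sparseMatrix(i = edges$source, j = edges$target,
                                      x = w, dims = c(n, n))
  } else {
    adjacency <- as(as(as(adjacency, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    adjacency <- Matrix::drop0(adjacency)
    if (!is.null(n) && n != nrow(adjacency))
      stop("n disagrees with adjacency dimension")
  }
  if (is.null(coords)) {
    coords <- matrix(numeric(), 0, 0)
  } else {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }
  new("DirectedGraph", adjacency = adjacency, coords = coords)
}

#' @rdname DirectedGraph
#' @param object,x a \code{DirectedGraph}.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname DirectedGraph
#' @export
setMethod("nVertices", "DirectedGraph", function(x) nrow(x@adjacency))

#' @rdname DirectedGraph
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname DirectedGraph
#' @export
setMethod("adjacencyMatrix", "DirectedGraph", function(x) x@adjacency)

#' @rdname DirectedGraph
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' @rdname DirectedGraph
#' @export
setMethod("vertexCoords", "DirectedGraph", function(x) {
  if (nrow(x@coords)) x@coords else NULL
})

#' @rdname DirectedGraph
#' @export
setGeneric("outDegrees", function(x) standardGeneric("outDegrees"))

#' @rdname DirectedGraph
#' @export
setMethod("outDegrees", "DirectedGraph",
          function(x) as.vector(Matrix::rowSums(x@adjacency)))

#' @rdname DirectedGraph
#' @export
setGeneric("inDegrees", function(x) standardGeneric("inDegrees"))

#' @rdname DirectedGraph
#' @export
setMethod("inDegrees", "DirectedGraph",
          function(x) as.vector(Matrix::colSums(x@adjacency)))

#' @rdname DirectedGraph
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Edge table of a graph
#'
#' @return data.frame with 1-based \code{source}, \code{target},
#'   \code{weight}, ordered by source then target.
#' @rdname DirectedGraph
#' @export
setMethod("edgeTable", "DirectedGraph", function(x) {
  s <- sparseTriplets(x@adjacency)
  out <- data.frame(source = s$i, target = s$j, weight = s$x)
  out[order(out$source, out$target), , drop = FALSE]
})

## 1-based (i, j, x) triplets of a sparse matrix
sparseTriplets <- function(A) {
  tm <- as(A, "TsparseMatrix")
  data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x)
}

setMethod("show", "DirectedGraph", function(object) {
  n <- nVertices(object)
  e <- length(object@adjacency@x)
  cat("DirectedGraph with", n, "vertices and", e, "edges\n")
  if (e) {
    w <- object@adjacency@x
    cat("  weights: [", format(min(w)), ",", format(max(w)), "]\n")
  }
  if (nrow(object@coords))
    cat("  coords:", ncol(object@coords), "dimensional\n")
  invisible(object)
})

#' Graph Laplacian L = D - A
#'
#' The degree matrix \code{D} is diagonal with the outdegree (row sum of
#' \code{A}) of vertex i as its i-th diagonal element, so every row of
#' \code{L} sums to zero exactly.
#'
#' @param x a \code{\linkS4class{DirectedGraph}} .
#' @return sparse \code{dgCMatrix} Laplacian.
#' @examples
#' g <- DirectedGraph(data.frame(source = 1, target = 2), n = 2)
#' laplacianMatrix(g)
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @rdname laplacianMatrix
#' @export
setMethod("laplacianMatrix", "DirectedGraph", function(x) {
  A <- x@adjacency
  as(Matrix::Diagonal(x = Matrix::rowSums(A)) - A, "CsparseMatrix")
})
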