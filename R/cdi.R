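## Communities of Dynamical Influence: leaders are vertices with no outward
## edge to a vertex farther from the origin of the eigenvector coordinate
## system; every other vertex joins a leader it can reach along a path of
## strictly increasing radius, ties resolved by the scalar product with the
## leaders' position vectors.

#' Vertex positions in eigenvector space
#'
#' Places vertex i at the point whose j-th coordinate is the i-th entry of
#' the j-th selected left eigenvector, and records each vertex's Euclidean
#' distance (radius) from the origin of this coordinate system.
#'
#' @param basis an \code{\linkS4class{EigenBasis}}.
#' @return an \code{\linkS4class{InfluenceCoordinates}}.
#' @examples
#' g <- generateErdosRenyi(30, 4, seed = 1)
#' ic <- influenceCoordinates(dominantLeftEigenvectors(g, m = 2))
#' head(radii(ic))
#' @export
influenceCoordinates <- function(basis) {
  stopifnot(is(basis, "EigenBasis"))
  V <- basis@vectors
  new("InfluenceCoordinates", coords = V, radii = sqrt(rowSums(V^2)))
}

#' @describeIn influenceCoordinates per-vertex distance from the origin.
#' @param ic an \code{InfluenceCoordinates}.
#' @export
radii <- function(ic) ic@radii

#' Community leaders
#'
#' A vertex leads when none of its out-neighbours lies strictly farther
#' from the origin of the eigenvector coordinate system — it does not
#' "follow" any vertex of greater influence. Leaders are returned in
#' descending order of their first-eigenvector entry (descending dynamical
#' influence), ties broken by vertex index.
#'
#' @param g a \code{\linkS4class{DirectedGraph}}.
#' @param ic \code{\linkS4class{InfluenceCoordinates}} over the same
#'   vertices.
#' @return integer vector of leader vertices.
#' @export
## "strictly farther from the origin", with a relative tolerance so that
## exact mathematical ties (e.g. the uniform first eigenvector of an
## undirected Laplacian) are not broken by eigen-solver noise
radiusTol <- 1e-9
fartherThan <- function(rj, ri) rj - ri > radiusTol * pmax(1, ri)

findLeaders <- function(g, ic) {
  n <- nVertices(g)
  stopifnot(length(ic@radii) == n)
  r <- ic@radii
  e <- sparseTriplets(adjacencyMatrix(g))
  follows <- unique(e$i[fartherThan(r[e$j], r[e$i])])
  leaders <- setdiff(seq_len(n), follows)
  vL1 <- ic@coords[, 1]
  leaders[order(-vL1[leaders], leaders)]
}

## reverse adjacency lists of the radius-increasing edge subgraph
increasingReverseAdj <- function(g, r) {
  e <- sparseTriplets(adjacencyMatrix(g))
  keep <- fartherThan(r[e$j], r[e$i])
  src <- e$i[keep]; tgt <- e$j[keep]
  split(src, factor(tgt, levels = seq_len(length(r))))
}

#' Assign vertices to leader communities
#'
#' A vertex belongs to a leader's community when a directed path runs from
#' the vertex to the leader with every step strictly increasing the radius
#' (distance from the eigenvector-space origin). A vertex that reaches
#' several leaders is kept in the community whose leader's position vector
#' is most aligned with its own, measured by the scalar product of the raw
#' coordinate rows; a residual tie goes to the leader with the larger
#' first-eigenvector entry. The result is a partition: communities are
#' numbered by descending leader influence and every leader anchors its own
#' community.
#'
#' @inheritParams findLeaders
#' @param leaders leader vertices from \code{\link{findLeaders}} on the
#'   same coordinates.
#' @return a \code{\linkS4class{CommunitySet}}.
#' @export
assignCommunities <- function(g, ic, leaders) {
  n <- nVertices(g)
  r <- ic@radii
  V <- ic@coords
  radj <- increasingReverseAdj(g, r)
  t <- length(leaders)
  ## reverse BFS from each leader over increasing edges
  reach <- matrix(FALSE, n, t)
  for (ci in seq_len(t)) {
    seen <- logical(n)
    queue <- leaders[ci]
    seen[queue] <- TRUE
    while (length(queue)) {
      nxt <- unique(unlist(radj[queue], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      queue <- nxt
    }
    reach[, ci] <- seen
  }
  if (any(rowSums(reach) == 0))
    stop("internal error: vertex reaches no leader")   # cannot happen
  score <- V %*% t(V[leaders, , drop = FALSE])   # scalar products
  membership <- integer(n)
  for (v in seq_len(n)) {
    cand <- which(reach[v, ])
    if (length(cand) == 1L) { membership[v] <- cand; next }
    s <- score[v, cand]
    best <- cand[s >= max(s) - 1e-12 * max(1, abs(max(s)))]
    ## ties: leaders are ordered by descending vL1, take the first
    membership[v] <- best[1L]
  }
  new("CommunitySet", leaders = as.integer(leaders),
      membership = membership,
      leaderScore = V[leaders, 1], radii = r,
      basis = new("EigenBasis"))
}

#' Detect Communities of Dynamical Influence
#'
#' Runs the full CDI pipeline: compute the \code{m} dominant left
#' eigenvectors of the chosen graph matrix, place the vertices in the
#' eigenvector coordinate system, identify the community leaders, and
#' assign every vertex to a leader community. Communities are ranked by
#' their leader's first-eigenvector entry; community 1 is the most
#' influential. Both the Laplacian (directed influence; default) and the
#' adjacency matrix (large undirected graphs) can drive the procedure.
#'
#' @param g a \code{\linkS4class{DirectedGraph}}.
#' @param m number of input eigenvectors (3 gives consistently good
#'   community division for consensus leadership).
#' @param kind \code{"laplacian"} or \code{"adjacency"}.
#' @param ... passed to \code{\link{dominantLeftEigenvectors}}.
#' @return a \code{\linkS4class{CommunitySet}} carrying the basis used.
#' @examples
#' g <- generateKNNR(100, 10, seed = 1)
#' cs <- detectCDI(g, m = 2)
#' nCommunities(cs)
#' @export
detectCDI <- function(g, m = 3, kind = c("laplacian", "adjacency"), ...) {
  kind <- match.arg(kind)
  basis <- dominantLeftEigenvectors(g, kind, m, ...)
  ic <- influenceCoordinates(basis)
  leaders <- findLeaders(g, ic)
  cs <- assignCommunities(g, ic, leaders)
  cs@basis <- basis
  validObject(cs)
  cs
}

#' @describeIn detectCDI number of communities (= number of leaders).
#' @param cs a \code{CommunitySet}.
#' @export
nCommunities <- function(cs) length(cs@leaders)

#' @describeIn detectCDI leader vertices by descending influence.
#' @export
communityLeaders <- function(cs) cs@leaders

#' @describeIn detectCDI per-vertex community id.
#' @export
communityMembership <- function(cs) cs@membership

#' @describeIn detectCDI community sizes in influence order.
#' @export
communitySizes <- function(cs)
  as.integer(table(factor(cs@membership, levels = seq_along(cs@leaders))))

setMethod("show", "CommunitySet", function(object) {
  t <- length(object@leaders)
  cat("CommunitySet:", t, "communities over",
      length(object@membership), "vertices\n")
  if (t) {
    sz <- communitySizes(object)
    cat("  leaders (by influence):",
        paste(utils::head(object@leaders, 8), collapse = ", "),
        if (t > 8) "...\n" else "\n")
    cat("  sizes:", paste(utils::head(sz, 8), collapse = ", "),
        if (t > 8) "...\n" else "\n")
  }
  invisible(object)
})
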