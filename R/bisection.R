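## Recursive spectral bisection baseline: three rounds of sign splits along
## the second dominant eigenvector of each sub-community's induced matrix,
## yielding 8 leaf communities.

## split a vertex subset by the sign of eigenvector column `col` of the
## induced submatrix basis; zero entries go to the nonnegative side
signSplit <- function(vec, vertices) {
  list(pos = vertices[vec >= 0], neg = vertices[vec < 0])
}

## second-and-later dominant eigenvectors on the induced subgraph
subBasis <- function(M, vertices, m, kind) {
  sub <- M[vertices, vertices, drop = FALSE]
  if (kind == "laplacian") {
    ## re-derive the Laplacian of the induced subgraph from its adjacency
    A <- -sub
    Matrix::diag(A) <- 0
    sub <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  }
  dominantLeftEigenvectors(sub, kind, m = min(m, length(vertices)),
                           sparse = FALSE)
}

#' Recursive spectral bisection into 8 communities
#'
#' Splits the graph by the sign of the entries of the second dominant
#' eigenvector, recomputes the second eigenvector on each resulting
#' sub-community, and repeats three times in total to create 8
#' communities. At the final level, if the second eigenvector of a
#' sub-community fails to produce two halves that each contain an
#' eigenvector entry above \code{matchThreshold} (the threshold later used
#' for community matching), later eigenvectors are tried in dominance
#' order until one succeeds. A sub-community with no splitting eigenvector
#' is duplicated into one populated and one empty leaf and flagged.
#'
#' @param g a \code{\linkS4class{DirectedGraph}}.
#' @param kind \code{"laplacian"} (Fiedler-style) or \code{"adjacency"}.
#' @param matchThreshold entry threshold for the final-level fallback.
#' @return a \code{\linkS4class{BisectionTree}}.
#' @examples
#' g <- generateKNNR(60, 6, seed = 1)
#' bt <- spectralBisect(g)
#' table(bt@membership)
#' @export
spectralBisect <- function(g, kind = c("laplacian", "adjacency"),
                           matchThreshold = 0.01) {
  kind <- match.arg(kind)
  M <- if (kind == "laplacian") laplacianMatrix(g) else adjacencyMatrix(g)
  n <- nVertices(g)
  membership <- integer(n)
  record <- data.frame(node = character(), level = integer(),
                       vector = integer(), sizePos = integer(),
                       sizeNeg = integer(), flagged = logical(),
                       stringsAsFactors = FALSE)
  leafId <- 0L

  recurse <- function(vertices, level, path) {
    if (level > 3L) {
      leafId <<- leafId + 1L
      membership[vertices] <<- leafId
      return(invisible())
    }
    final <- level == 3L
    splitFound <- FALSE; usedVec <- NA_integer_
    pos <- vertices; neg <- integer(0)
    if (length(vertices) >= 2L) {
      maxVec <- if (final) min(length(vertices), 6L) else 2L
      basis <- try(subBasis(M, vertices, maxVec, kind), silent = TRUE)
      if (!inherits(basis, "try-error")) {
        V <- basis@vectors
        for (col in 2:ncol(V)) {
          sp <- signSplit(V[, col], vertices)
          ok <- length(sp$pos) > 0 && length(sp$neg) > 0
          if (ok && final) {
            vp <- V[match(sp$pos, vertices), col]
            vn <- V[match(sp$neg, vertices), col]
            ok <- any(abs(vp) > matchThreshold) &&
                  any(abs(vn) > matchThreshold)
          }
          if (ok) {
            splitFound <- TRUE; usedVec <- col
            pos <- sp$pos; neg <- sp$neg
            break
          }
          if (!final) break   # earlier levels use the second vector only
        }
      }
    }
    record[nrow(record) + 1L, ] <<- list(path, level, usedVec,
                                         length(pos), length(neg),
                                         !splitFound)
    recurse(pos, level + 1L, paste0(path, "+"))
    recurse(neg, level + 1L, paste0(path, "-"))
  }
  recurse(seq_len(n), 1L, "r")
  new("BisectionTree", membership = membership, record = record)
}

setMethod("show", "BisectionTree", function(object) {
  cat("BisectionTree: 8 leaves over", length(object@membership),
      "vertices\n")
  sz <- as.integer(table(factor(object@membership, levels = 1:8)))
  cat("  leaf sizes:", paste(sz, collapse = ", "), "\n")
  if (any(object@record$flagged))
    cat("  flagged nodes:", sum(object@record$flagged), "\n")
  invisible(object)
})
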