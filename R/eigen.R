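## Dominant left eigenvector machinery.
##
## Left eigenvectors v of a matrix M satisfy v M = lambda v, i.e. they are
## (right) eigenvectors of t(M). Dominance order:
##   laplacian: ascending |Re(lambda)| from the zero eigenvalue (slowest
##              consensus modes),
##   adjacency: descending Re(lambda) from the spectral radius.
## Complex-conjugate pairs contribute one vector only (their real parts
## coincide); the twin is skipped and the next non-pair eigenvector taken.

## order eigenvalue indices by dominance for a given kind
dominanceOrder <- function(values, kind) {
  if (kind == "laplacian") {
    order(abs(Re(values)), -Im(values), abs(Im(values)))
  } else {
    order(-Re(values), -Im(values))
  }
}

## walk values in dominance order keeping at most one member per conjugate
## pair; returns list(keep = indices, skipped = indices)
selectNonConjugate <- function(values, ord, m, tol = 1e-10) {
  keep <- integer(0); skipped <- integer(0)
  for (idx in ord) {
    if (length(keep) >= m) break
    v <- values[idx]
    isTwin <- FALSE
    for (kv in keep) {
      if (abs(Im(v)) > tol && abs(values[kv] - Conj(v)) < tol *
            (1 + abs(v))) { isTwin <- TRUE; break }
    }
    if (isTwin) skipped <- c(skipped, idx) else keep <- c(keep, idx)
  }
  list(keep = keep, skipped = skipped)
}

## fix signs: column 1 entrywise nonnegative (flip if sum < 0; entries at
## numerical-noise level are snapped to exact zero so the Perron support
## is clean); later columns flipped so their largest-magnitude entry is
## positive
fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    col <- V[, j]
    nrm <- sqrt(sum(col^2))
    if (nrm > 0) col <- col / nrm
    if (j == 1L) {
      if (sum(col) < 0) col <- -col
      col[abs(col) < 1e-12 * max(abs(col))] <- 0
      nrm <- sqrt(sum(col^2))
      if (nrm > 0) col <- col / nrm
    } else {
      piv <- which.max(abs(col))
      if (length(piv) && col[piv] < 0) col <- -col
    }
    V[, j] <- col
  }
  V
}

denseLeftEigen <- function(M, kind, m, tol) {
  e <- eigen(t(as.matrix(M)))
  vals <- as.complex(e$values)
  ord <- dominanceOrder(vals, kind)
  sel <- selectNonConjugate(vals, ord, m, tol)
  if (length(sel$keep) < m)
    stop("fewer than m = ", m, " non-conjugate eigenvector directions ",
         "available (matrix size ", nrow(M), ", kind ", kind, ")")
  V <- fixSigns(Re(as.matrix(e$vectors[, sel$keep, drop = FALSE])))
  list(vectors = V, values = vals[sel$keep],
       skipped = vals[sel$skipped])
}

sparseLeftEigen <- function(M, kind, m, tol) {
  n <- nrow(M)
  Mt <- Matrix::t(M)
  nev <- min(n - 2L, m + 4L)
  repeat {
    if (kind == "laplacian") {
      ## shift-invert about 0: eigenvalues nearest the zero mode dominate
      sigma <- 1e-3
      fac <- Matrix::lu(Mt + Matrix::Diagonal(n, sigma))
      res <- arnoldiEig(function(x) as.vector(Matrix::solve(fac, x)),
                        n, nev, select = "LM")
      vals <- 1 / res$values - sigma
    } else {
      res <- arnoldiEig(function(x) as.vector(Mt %*% x), n, nev,
                        select = "LR", kmax = min(n, 16L * nev + 80L))
      vals <- res$values
    }
    if (max(res$residuals) > 1e-6)
      warning("eigen-solver residual ", format(max(res$residuals)),
              " above 1e-6 (matrix size ", n, ", kind ", kind, ")")
    ord <- dominanceOrder(vals, kind)
    sel <- selectNonConjugate(vals, ord, m, tol)
    if (length(sel$keep) >= m || nev >= n - 2L) {
      if (length(sel$keep) < m)
        stop("fewer than m = ", m, " non-conjugate eigenvector directions ",
             "available (matrix size ", n, ", kind ", kind, ")")
      V <- fixSigns(Re(as.matrix(res$vectors[, sel$keep, drop = FALSE])))
      return(list(vectors = V, values = vals[sel$keep],
                  skipped = vals[sel$skipped]))
    }
    nev <- min(n - 2L, nev + m + 4L)   # conjugate twins ate the window
  }
}

#' Dominant left eigenvectors of a graph matrix
#'
#' Computes the \code{m} most dominant left eigenvectors of the Laplacian
#' or adjacency matrix of a graph and returns them as an
#' \code{\linkS4class{EigenBasis}} — the coordinate system in which CDI
#' communities are detected. For the Laplacian, dominance runs from the
#' zero eigenvalue upward in \code{|Re(lambda)|} (the slow consensus
#' modes); for the adjacency matrix it runs down from the spectral radius.
#' If a dominant eigenvalue belongs to a complex-conjugate pair only one
#' member is used and the next non-pair eigenvector is taken instead.
#'
#' Below \code{sparseThreshold} vertices a dense full decomposition is
#' used; above it, ARPACK (shift-invert around zero for the Laplacian,
#' largest-real-part for the adjacency).
#'
#' @param x a \code{\linkS4class{DirectedGraph}} or a square matrix.
#' @param kind \code{"laplacian"} or \code{"adjacency"}; ignored when
#'   \code{x} is already the matrix to analyse and \code{asMatrix = TRUE}.
#' @param m number of eigenvectors to return.
#' @param sparse force the sparse (\code{TRUE}) or dense (\code{FALSE})
#'   path; default chooses by \code{sparseThreshold}.
#' @param sparseThreshold size above which the ARPACK path is used.
#' @param tol conjugate-pair detection tolerance.
#' @return an \code{\linkS4class{EigenBasis}}.
#' @examples
#' g <- generateErdosRenyi(30, 4, seed = 1)
#' b <- dominantLeftEigenvectors(g, "laplacian", m = 3)
#' basisValues(b)
#' @export
dominantLeftEigenvectors <- function(x, kind = c("laplacian", "adjacency"),
                                     m = 3, sparse = NULL,
                                     sparseThreshold = 500, tol = 1e-10) {
  kind <- match.arg(kind)
  if (m < 1) stop("m must be >= 1")
  if (is(x, "DirectedGraph")) {
    M <- if (kind == "laplacian") laplacianMatrix(x) else adjacencyMatrix(x)
  } else {
    M <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  n <- nrow(M)
  if (m > n) stop("m cannot exceed the number of vertices")
  useSparse <- if (is.null(sparse)) n > sparseThreshold else isTRUE(sparse)
  ans <- if (useSparse) sparseLeftEigen(M, kind, m, tol)
         else denseLeftEigen(M, kind, m, tol)
  nearZero <- sum(abs(Re(ans$values)) < 1e-8)
  if (kind == "laplacian" && nearZero > 1)
    message("near-zero Laplacian eigenvalue multiplicity ", nearZero,
            " (graph may be disconnected)")
  new("EigenBasis", matrixKind = kind, vectors = ans$vectors,
      values = as.complex(ans$values),
      skippedValues = as.complex(ans$skipped))
}

#' @describeIn dominantLeftEigenvectors eigenvector matrix accessor.
#' @param basis an \code{EigenBasis}.
#' @export
basisVectors <- function(basis) basis@vectors

#' @describeIn dominantLeftEigenvectors eigenvalue accessor.
#' @export
basisValues <- function(basis) basis@values

setMethod("show", "EigenBasis", function(object) {
  cat("EigenBasis (", object@matrixKind, "): ",
      ncol(object@vectors), " vectors over ", nrow(object@vectors),
      " vertices\n", sep = "")
  if (length(object@values))
    cat("  eigenvalues:", paste(format(object@values, digits = 4),
                                collapse = ", "), "\n")
  if (length(object@skippedValues))
    cat("  skipped conjugate twins:", length(object@skippedValues), "\n")
  invisible(object)
})
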