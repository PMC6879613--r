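## Compact Arnoldi eigensolver for the sparse paths.
##
## An (unrestarted, incrementally grown) Arnoldi factorisation
## op * V_k = V_k H_k + h_{k+1,k} v_{k+1} e_k'  is built with modified
## Gram-Schmidt plus one reorthogonalisation pass; Ritz pairs come from the
## dense eigendecomposition of the small Hessenberg matrix and the residual
## of a Ritz pair (theta, V_k y) is |h_{k+1,k}| |y_k|. The operators used
## here are shift-inverted (sparse LU solves), which spreads the wanted
## peripheral eigenvalues far apart, so modest Krylov dimensions reach
## machine-precision residuals. The basis is grown until every wanted pair
## converges or kmax is hit.

## deterministic, positive, non-constant start vector
arnoldiStart <- function(n) {
  v <- 0.7 + 0.3 * sin(seq_len(n))
  v / sqrt(sum(v^2))
}

## op: function(numeric) -> numeric; returns nwant Ritz pairs sorted by
## `select` ("LR" = descending real part, "LM" = descending modulus)
arnoldiEig <- function(op, n, nwant = 1L, select = c("LR", "LM"),
                       start = NULL, tol = 1e-10, kmax = NULL) {
  select <- match.arg(select)
  if (is.null(kmax)) kmax <- min(n, max(8L * nwant + 40L, 60L))
  kmax <- min(kmax, n)
  if (is.null(start)) start <- arnoldiStart(n)
  v <- start / sqrt(sum(start^2))
  V <- matrix(0, n, kmax + 1L)
  H <- matrix(0, kmax + 1L, kmax)
  V[, 1L] <- v
  j <- 0L
  checkAt <- min(max(2L * nwant + 6L, 12L), kmax)
  repeat {
    j <- j + 1L
    w <- op(V[, j])
    if (length(w) != n || anyNA(w) || any(!is.finite(w)))
      stop("eigen-solver operator returned an invalid vector (n = ", n, ")")
    ## modified Gram-Schmidt + one reorthogonalisation pass
    for (pass in 1:2) {
      for (i in seq_len(j)) {
        hij <- sum(V[, i] * w)
        w <- w - hij * V[, i]
        H[i, j] <- H[i, j] + hij
      }
    }
    beta <- sqrt(sum(w^2))
    H[j + 1L, j] <- beta
    if (beta < 1e-13) {
      ## invariant subspace: done if rich enough, else expand randomly-free
      e <- eigenRitz(H, V, j, nwant, select, beta = 0)
      if (nrow(e$table) >= nwant || j >= kmax) return(e)
      fresh <- arnoldiStart(n) * seq_len(n) %% 7  # deterministic new dir
      for (i in seq_len(j)) fresh <- fresh - sum(V[, i] * fresh) * V[, i]
      nf <- sqrt(sum(fresh^2))
      if (nf < 1e-13) stop("Arnoldi basis exhausted at k = ", j)
      V[, j + 1L] <- fresh / nf
      next
    }
    V[, j + 1L] <- w / beta
    if (j >= checkAt || j >= kmax) {
      e <- eigenRitz(H, V, j, nwant, select, beta)
      if (all(e$residuals <= tol * pmax(1, Mod(e$values))) || j >= kmax)
        return(e)
      checkAt <- min(kmax, j + max(6L, nwant))
    }
  }
}

eigenRitz <- function(H, V, j, nwant, select, beta) {
  hs <- H[seq_len(j), seq_len(j), drop = FALSE]
  e <- eigen(hs)
  vals <- as.complex(e$values)
  ord <- if (select == "LR") order(-Re(vals), -Im(vals))
         else order(-Mod(vals), -Im(vals))
  take <- ord[seq_len(min(nwant, length(ord)))]
  y <- e$vectors[, take, drop = FALSE]
  res <- beta * abs(y[j, ])
  vecs <- V[, seq_len(j), drop = FALSE] %*% y
  ## normalise Ritz vectors
  for (cc in seq_len(ncol(vecs)))
    vecs[, cc] <- vecs[, cc] / sqrt(sum(Mod(vecs[, cc])^2))
  list(values = vals[take], vectors = vecs, residuals = as.numeric(res),
       table = data.frame(value = vals[take], residual = as.numeric(res)))
}

## Leftmost (smallest real part) eigenvalue of a sparse matrix M whose
## spectrum lies in the closed right half plane and whose leftmost
## eigenvalue is real (Metzler -M). Shift-invert about -delta: the wanted
## eigenvalue maps to the unique largest-real-part eigenvalue of
## (M + delta I)^{-1}.
leftmostEigenvalue <- function(M, delta = 1e-3, start = NULL, tol = 1e-10) {
  n <- nrow(M)
  fac <- Matrix::lu(M + Matrix::Diagonal(n, delta))
  op <- function(x) as.vector(Matrix::solve(fac, x))
  e <- arnoldiEig(op, n, nwant = 1L, select = "LR", start = start,
                  tol = tol)
  theta <- Re(e$values[1])
  if (theta <= 0)
    stop("shift-invert Arnoldi failed to locate the leftmost eigenvalue")
  list(value = 1 / theta - delta, vector = Re(e$vectors[, 1]),
       residual = e$residuals[1])
}
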