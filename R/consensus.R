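## Perturbation-driven linear consensus: dx/dt = -L x + C (u - x) with
## C = diag(c), sum(c) = 1, c >= 0. After a change of coordinates the decay
## is governed by -(L + C); its rightmost eigenvalue sets the convergence
## rate. -(L + C) is a Metzler matrix (nonnegative off-diagonals), so the
## rightmost eigenvalue is real: it is s minus the Perron root of the
## nonnegative matrix s I - (L + C) for any s >= max(diag(L + C)).

asLaplacian <- function(x) {
  if (is(x, "DirectedGraph")) laplacianMatrix(x)
  else as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

asAllocation <- function(c, n) {
  c <- as.numeric(c)
  if (length(c) != n) stop("allocation length must equal vertex count")
  if (any(c < -1e-12)) stop("allocation entries must be nonnegative")
  pmax(c, 0)
}

#' Check a perturbation allocation lies on the simplex
#'
#' @param c numeric allocation vector.
#' @param tol tolerance on \code{sum(c) == 1} and nonnegativity.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isSimplexAllocation <- function(c, tol = 1e-10) {
  is.numeric(c) && all(is.finite(c)) && min(c) >= -tol &&
    abs(sum(c) - 1) <= tol
}

## Factory returning rate(c): |Re(rightmost eigenvalue of -(L + diag(c)))|.
## Dense full spectrum below sparseThreshold; ARPACK Perron solve above,
## reusing the previous eigenvector as the Arnoldi start vector.
rateEvaluator <- function(L, sparse = NULL, sparseThreshold = 500) {
  n <- nrow(L)
  useSparse <- if (is.null(sparse)) n > sparseThreshold else isTRUE(sparse)
  if (!useSparse) {
    Ld <- as.matrix(L)
    function(c) {
      ev <- eigen(-(Ld + diag(asAllocation(c, n), n)), only.values = TRUE)$values
      max(-max(Re(ev)), 0)
    }
  } else {
    env <- new.env()
    env$start <- NULL
    function(c) {
      c <- asAllocation(c, n)
      res <- leftmostEigenvalue(L + Matrix::Diagonal(n, c),
                                start = env$start)
      env$start <- res$vector   # warm start for the next evaluation
      max(res$value, 0)
    }
  }
}

#' Consensus convergence rate of a perturbed network
#'
#' Returns the magnitude of the real part of the rightmost (most dominant)
#' eigenvalue of \code{-(L + C)}, \code{C = diag(c)} — the exponential
#' rate at which perturbation-driven consensus converges on the target.
#' The rate is strictly positive exactly when every vertex is reachable,
#' along influence-flow edges, from the perturbed set; an unperturbed
#' connected network has rate 0 (the Laplacian's zero mode).
#'
#' @param x a \code{\linkS4class{DirectedGraph}} or a Laplacian matrix.
#' @param c perturbation allocation (length n, nonnegative; on the simplex
#'   for the globally bounded problem).
#' @param sparse force sparse/dense eigen path (default by size).
#' @param sparseThreshold size above which ARPACK is used.
#' @return nonnegative scalar rate.
#' @examples
#' g <- generateErdosRenyi(20, 4, seed = 1)
#' convergenceRate(g, rep(1 / 20, 20))
#' @export
convergenceRate <- function(x, c, sparse = NULL, sparseThreshold = 500) {
  L <- asLaplacian(x)
  rateEvaluator(L, sparse, sparseThreshold)(c)
}

#' Simulate perturbation-driven consensus
#'
#' Integrates \code{dx/dt = -L x + C (u 1 - x)} with an adaptive solver
#' (lsoda, relative tolerance 1e-8). When the convergence rate is positive
#' the worst-case deviation \code{max |x_i - u|} decays like
#' \code{exp(-rate t)}.
#'
#' @param g a \code{\linkS4class{DirectedGraph}} or Laplacian matrix.
#' @param c perturbation allocation.
#' @param u scalar consensus target.
#' @param x0 initial state vector (default 0).
#' @param horizon final time.
#' @param steps number of output samples.
#' @return data.frame with column \code{t} and one column \code{x_<i>}
#'   (0-based labels) per agent.
#' @examples
#' g <- generateErdosRenyi(10, 3, seed = 1)
#' tr <- simulateConsensus(g, rep(0.1, 10), u = 1, horizon = 20)
#' tail(tr, 1)
#' @export
simulateConsensus <- function(g, c, u = 1, x0 = NULL, horizon = 10,
                              steps = 200) {
  L <- asLaplacian(g)
  n <- nrow(L)
  c <- asAllocation(c, n)
  if (is.null(x0)) x0 <- rep(0, n)
  if (length(x0) != n) stop("x0 length must equal vertex count")
  if (horizon <= 0) stop("horizon must be positive")
  times <- seq(0, horizon, length.out = steps + 1)
  deriv <- function(t, y, parms)
    list(as.vector(-(L %*% y)) + c * (u - y))
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed; reduce the horizon or step count")
  out <- as.data.frame(sol)
  names(out) <- c("t", paste0("x_", seq_len(n) - 1L))
  out
}

#' Empirical decay rate of a simulated trajectory
#'
#' Least-squares slope of \code{log max_i |x_i - u|} over the late part of
#' a trajectory, for comparison with \code{\link{convergenceRate}}.
#'
#' @param trajectory output of \code{\link{simulateConsensus}}.
#' @param u consensus target used in the simulation.
#' @param window fraction of the trajectory tail to fit on.
#' @return positive decay-rate estimate.
#' @export
empiricalDecayRate <- function(trajectory, u = 1, window = 0.5) {
  t <- trajectory$t
  X <- as.matrix(trajectory[, -1, drop = FALSE])
  dev <- apply(abs(X - u), 1, max)
  keep <- t >= max(t) * (1 - window) & dev > 1e-13
  if (sum(keep) < 3) stop("trajectory too short or already converged")
  fit <- stats::lm(log(dev[keep]) ~ t[keep])
  -unname(stats::coef(fit)[2])
}

#' Consensus speed ratio
#'
#' Rate of a method relative to a reference (e.g. a direct numerical
#' optimiser); values above 1 mean the method converges faster.
#'
#' @param rateMethod rate achieved by the method under test.
#' @param rateReference strictly positive reference rate.
#' @return \code{rateMethod / rateReference}.
#' @export
consensusSpeedRatio <- function(rateMethod, rateReference) {
  if (rateReference <= 0) stop("reference rate must be strictly positive")
  rateMethod / rateReference
}
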