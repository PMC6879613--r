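## Flock responsiveness experiment: fix one prism point cloud, sweep the
## outdegree k, and track the optimised consensus rate lambda1. The rate
## falls with k roughly as a power law — low-outdegree flocks are the most
## responsive to their leading birds.

#' Outdegree sweep of the flock model
#'
#' Samples one set of bird positions in a rectangular prism (default 1200
#' birds, thickness 0.2), wires a k-NNR digraph for each requested
#' outdegree over the same positions, detects CDI with \code{m}
#' eigenvectors of the Laplacian, and runs the staged perturbation
#' optimiser. Returns the optimised dominant eigenvalue (convergence
#' rate) for each k.
#'
#' @param kValues outdegrees to sweep.
#' @param n number of birds.
#' @param thickness prism smallest:largest side ratio.
#' @param m number of CDI input eigenvectors.
#' @param seed integer seed for the bird positions.
#' @param control optimiser settings, see \code{\link{optimiserControl}}.
#' @param verbose print one line per k.
#' @return data.frame with columns \code{k}, \code{lambda1},
#'   \code{communities} (detected), \code{used} (retained by the
#'   optimiser).
#' @seealso \code{\link{fitPowerLaw}}
#' @export
flockResponseSweep <- function(kValues = c(5, 10, 15, 20, 25, 30, 40, 50),
                               n = 1200, thickness = 0.2, m = 3,
                               seed = NULL,
                               control = optimiserControl(),
                               verbose = FALSE) {
  pts <- flockPoints(n, thickness, seed)
  out <- data.frame(k = kValues, lambda1 = NA_real_,
                    communities = NA_integer_, used = NA_integer_)
  for (i in seq_along(kValues)) {
    g <- knnGraphFromPoints(pts, kValues[i])
    cs <- detectCDI(g, m = m, kind = "laplacian")
    res <- optimisePerturbation(g, cs, control = control)
    out$lambda1[i] <- res@rate
    out$communities[i] <- nCommunities(cs)
    out$used[i] <- length(res@communities)
    if (verbose)
      message(sprintf("k = %d: %d communities, rate %.3e",
                      kValues[i], nCommunities(cs), res@rate))
  }
  out
}

#' Least-squares power-law fit
#'
#' Fits \code{y = a * k^b} by ordinary least squares on the log-log
#' values and reports the prefactor, exponent, and coefficient of
#' determination of the log-log regression.
#'
#' @param k predictor values (positive).
#' @param y response values (positive).
#' @return list with \code{a}, \code{b}, \code{r2}.
#' @examples
#' fitPowerLaw(1:8, 2 * (1:8)^-0.5)
#' @export
fitPowerLaw <- function(k, y) {
  if (any(k <= 0) || any(y <= 0)) stop("power-law fit needs positive data")
  fit <- stats::lm(log(y) ~ log(k))
  list(a = unname(exp(stats::coef(fit)[1])),
       b = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}
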