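## Staged consensus-leadership perturbation optimisation.
##
## Stage A (leader preselection): optimise a simplex allocation supported
## on the community leaders only; discard communities whose leader ends up
## with (numerically) zero mass.
## Stage B (staged combination): build community input vectors omega_i
## (first-left-eigenvector entries masked to the community, zero
## elsewhere), power-optimise p_i = omega_i^eta_i / sum(omega_i^eta_i),
## and combine c = (sum_j p_j / r_j) / (sum_j 1 / r_j). Vectors are added
## greedily in influence order, each addition optimising only the new
## weighting variable; accepted additions trigger re-optimisation of all
## powers; a redundancy pass removes vectors whose removal improves the
## rate; a final joint optimisation polishes all eta and r.

#' Power optimisation of an input vector
#'
#' Raises a nonnegative input vector elementwise to the power \code{eta}
#' and renormalises to the simplex: \code{p = omega^eta / sum(omega^eta)}.
#' As \code{eta} shrinks to 0 the result approaches a uniform vector over
#' the support of \code{omega}; increasing \code{eta} concentrates mass on
#' the largest entries (the strongest leaders). Entries that are exactly
#' zero stay zero.
#'
#' @param omega nonnegative vector with positive sum.
#' @param eta positive power.
#' @return simplex vector with the support of \code{omega}.
#' @examples
#' powerOptimise(c(0.1, 0.2, 0.3), 1)
#' powerOptimise(c(0.1, 0.2, 0.3), 1e-9)  # ~ uniform
#' @export
powerOptimise <- function(omega, eta) {
  if (any(omega < 0)) stop("omega must be nonnegative")
  if (sum(omega) <= 0) stop("omega must have positive sum")
  if (eta <= 0) stop("eta must be positive")
  pos <- omega > 0
  w <- numeric(length(omega))
  w[pos] <- (omega[pos] / max(omega))^eta   # scale-invariant, no underflow of all entries
  w / sum(w)
}

#' Combine power-optimised vectors into one allocation
#'
#' \code{c = (sum_j p_j / r_j) / (sum_j 1 / r_j)}: a weighted mixture of
#' simplex vectors whose denominator guarantees \code{sum(c) = 1}. Smaller
#' \code{r_j} gives vector j a larger share.
#'
#' @param pList list of simplex vectors of equal length.
#' @param r positive weighting variables, one per vector.
#' @return simplex allocation vector.
#' @examples
#' combineInputVectors(list(c(1, 0), c(0, 1)), c(1, 1))  # mean
#' @export
combineInputVectors <- function(pList, r) {
  if (!length(pList)) stop("need at least one input vector")
  if (length(r) != length(pList)) stop("one weight per vector required")
  if (any(r <= 0)) stop("weights r must be positive")
  num <- Reduce(`+`, Map(function(p, rj) p / rj, pList, r))
  num / sum(1 / r)
}

#' Optimiser control settings
#'
#' Bounds and tolerances for the staged perturbation optimiser. The local
#' maximiser is \code{stats::optim(method = "L-BFGS-B")} over
#' log-transformed variables with box bounds (finite-difference
#' gradients), matching the smooth constrained local-maximiser contract.
#'
#' @param etaBounds bounds for the power variables.
#' @param rBounds bounds for the weighting variables.
#' @param improveTol relative rate gain required to accept a stage.
#' @param maxit iteration cap per optim call.
#' @param keepTol leader mass at or below which a community is discarded
#'   during preselection.
#' @param sparse,sparseThreshold eigen path selection as in
#'   \code{\link{convergenceRate}}.
#' @return list of settings.
#' @export
optimiserControl <- function(etaBounds = c(1e-3, 50),
                             rBounds = c(1e-6, 1e6),
                             improveTol = 1e-6, maxit = 200,
                             keepTol = 1e-6,
                             sparse = NULL, sparseThreshold = 500) {
  list(etaBounds = etaBounds, rBounds = rBounds, improveTol = improveTol,
       maxit = maxit, keepTol = keepTol, sparse = sparse,
       sparseThreshold = sparseThreshold)
}

## maximise fn over log-scale box [lo, hi]^d starting at x0 (natural scale);
## returns list(x, value); never returns something worse than x0
maximiseLogBox <- function(fn, x0, lo, hi, maxit) {
  f0 <- fn(x0)
  obj <- function(lx) {
    v <- try(fn(exp(lx)), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(-1e10)
    v
  }
  res <- try(stats::optim(log(pmin(pmax(x0, lo), hi)), obj,
                          method = "L-BFGS-B",
                          lower = log(lo), upper = log(hi),
                          control = list(fnscale = -1, maxit = maxit)),
             silent = TRUE)
  if (inherits(res, "try-error") || res$value <= f0)
    list(x = x0, value = f0)
  else list(x = exp(res$par), value = res$value)
}

## 1-D maximisation over [lo, hi] (log scale): coarse grid to escape flat
## or multimodal stretches, then local refinement from the best grid point
maximise1D <- function(fn, x0, lo, hi, maxit, npts = 11L) {
  grid <- unique(c(exp(seq(log(lo), log(hi), length.out = npts)), x0))
  vals <- vapply(grid, function(g) {
    v <- try(fn(g), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) -Inf else v
  }, numeric(1))
  best <- which.max(vals)
  maximiseLogBox(fn, grid[best], lo, hi, maxit)
}

## the perturbation target of each community: its highest-vL1 vertex
## (usually, but not always, the CDI leader); ties to the lowest index.
## A community lying entirely outside the support of vL1 carries no
## first-eigenvector information, so the influence geometry falls back to
## the eigenvector-space radius (the quantity CDI ranks leaders by).
influentialVertices <- function(communities, vL1) {
  vapply(seq_along(communities@leaders), function(ci) {
    members <- which(communities@membership == ci)
    if (max(vL1[members]) <= 0 && length(communities@radii))
      return(members[which.max(communities@radii[members])])
    members[which.max(vL1[members])]
  }, integer(1))
}

#' Preselect communities by influential-vertex perturbation optimisation
#'
#' Optimises a simplex-constrained perturbation applied only to the most
#' influential vertex of each community (the member with the highest
#' first-left-eigenvector entry), maximising the consensus convergence
#' rate. Communities whose vertex's optimised mass falls to (numerically)
#' zero are discarded: they add nothing that the retained communities do
#' not already provide.
#'
#' @param L Laplacian matrix or a \code{\linkS4class{DirectedGraph}}.
#' @param communities a \code{\linkS4class{CommunitySet}}.
#' @param vL1 first left Laplacian eigenvector; defaults to the basis
#'   stored in \code{communities}.
#' @param control see \code{\link{optimiserControl}}.
#' @return list with \code{kept} (retained community ids, influence
#'   order), \code{mass} (optimised masses), \code{vertices} (the
#'   perturbed vertices), and \code{rate}.
#' @export
leaderPreselect <- function(L, communities, vL1 = NULL,
                            control = optimiserControl()) {
  L <- asLaplacian(L)
  n <- nrow(L)
  if (is.null(vL1)) {
    if (!ncol(communities@basis@vectors))
      stop("communities carry no basis; supply vL1")
    vL1 <- communities@basis@vectors[, 1]
  }
  leaders <- influentialVertices(communities, vL1)
  t <- length(leaders)
  if (t == 0) stop("need at least one community")
  rate <- rateEvaluator(L, control$sparse, control$sparseThreshold)
  if (t == 1L) {
    c0 <- numeric(n); c0[leaders] <- 1
    return(list(kept = 1L, mass = 1, vertices = leaders,
                rate = rate(c0)))
  }
  evalMass <- function(y) {
    if (sum(y) < 1e-12) return(-Inf)
    c0 <- numeric(n)
    c0[leaders] <- y / sum(y)
    rate(c0)
  }
  res <- try(stats::optim(rep(1 / t, t), evalMass, method = "L-BFGS-B",
                          lower = rep(0, t), upper = rep(1, t),
                          control = list(fnscale = -1,
                                         maxit = control$maxit)),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    warning("leader preselection optimiser failed; keeping all communities")
    mass <- rep(1 / t, t)
  } else mass <- res$par / sum(res$par)
  kept <- which(mass > control$keepTol)
  if (!length(kept)) kept <- 1L
  c0 <- numeric(n); c0[leaders[kept]] <- mass[kept] / sum(mass[kept])
  list(kept = as.integer(kept), mass = mass[kept] / sum(mass[kept]),
       vertices = leaders[kept], rate = rate(c0))
}

## build community-masked vL1 input vectors for given community ids; a
## community on which vL1 is identically zero (outside the support of the
## influence distribution) falls back to its masked eigenvector-space
## radius profile — the influence measure CDI itself ranks vertices by —
## and to the uniform vector if even the radii vanish
communityInputVectors <- function(communities, vL1, ids) {
  lapply(ids, function(ci) {
    w <- numeric(length(vL1))
    inC <- communities@membership == ci
    w[inC] <- pmax(vL1[inC], 0)
    if (sum(w) <= 0 && length(communities@radii))
      w[inC] <- communities@radii[inC]
    if (sum(w) <= 0) w[inC] <- 1 / sum(inC)
    w
  })
}

#' Staged CDI perturbation optimisation
#'
#' Maximises the consensus convergence rate — the magnitude of the
#' rightmost eigenvalue of \code{-(L + diag(c))} — over globally bounded
#' perturbations \code{c} built from the CDI community structure.
#'
#' Procedure: (1) preselect communities by leader-only optimisation
#' (\code{\link{leaderPreselect}}); (2) power-optimise the most influential
#' retained community's input vector; (3) scan the remaining vectors in
#' influence order, adding each with its weighting variable optimised
#' alone and accepting only rate improvements, re-optimising all powers
#' after every acceptance; (4) redundancy pass removing any vector whose
#' removal improves the rate, starting from the first; (5) final joint
#' optimisation of all powers and weights. The accepted-stage rate trace
#' is non-decreasing and the result never falls below the best accepted
#' stage.
#'
#' @param x a \code{\linkS4class{DirectedGraph}} or Laplacian matrix.
#' @param communities a \code{\linkS4class{CommunitySet}} (typically from
#'   \code{\link{detectCDI}}).
#' @param vL1 first left Laplacian eigenvector; defaults to column 1 of
#'   the basis stored in \code{communities}.
#' @param control see \code{\link{optimiserControl}}.
#' @param preselect run the leader preselection stage (default) or keep
#'   all communities.
#' @return a \code{\linkS4class{PerturbationResult}}.
#' @examples
#' g <- generateKNNR(60, 6, seed = 1)
#' cs <- detectCDI(g, m = 3)
#' res <- optimisePerturbation(g, cs)
#' res@rate >= res@baselineRate
#' @export
optimisePerturbation <- function(x, communities, vL1 = NULL,
                                 control = optimiserControl(),
                                 preselect = TRUE) {
  L <- asLaplacian(x)
  n <- nrow(L)
  if (is.null(vL1)) {
    if (!ncol(communities@basis@vectors))
      stop("communities carry no basis; supply vL1")
    vL1 <- communities@basis@vectors[, 1]
  }
  rate <- rateEvaluator(L, control$sparse, control$sparseThreshold)
  baseline <- rate(pmax(vL1, 0) / sum(pmax(vL1, 0)))

  sel <- if (preselect) leaderPreselect(L, communities, vL1, control)
         else list(kept = seq_along(communities@leaders),
                   mass = rep(1 / length(communities@leaders),
                              length(communities@leaders)))
  ids <- sel$kept                      # influence order
  mass <- sel$mass
  omega <- communityInputVectors(communities, vL1, ids)
  nonzero <- vapply(omega, function(w) sum(w) > 0, logical(1))
  ids <- ids[nonzero]; omega <- omega[nonzero]; mass <- mass[nonzero]
  if (!length(ids)) stop("no community input vector has positive mass")

  stages <- data.frame(stage = character(), rate = numeric(),
                       stringsAsFactors = FALSE)
  note <- function(st, rt) stages <<- rbind(stages,
    data.frame(stage = st, rate = rt, stringsAsFactors = FALSE))

  evalSet <- function(active, eta, r) {
    p <- Map(powerOptimise, omega[active], eta)
    rate(combineInputVectors(p, r))
  }

  ## stage 1: single most influential vector, optimise its power
  active <- 1L
  eta <- 1; r <- 1
  best <- evalSet(active, eta, r)
  note("initial vL1 vector (eta = 1)", best)
  opt1 <- maximise1D(function(e) evalSet(active, e, r), eta,
                     control$etaBounds[1], control$etaBounds[2],
                     control$maxit)
  eta <- opt1$x; best <- opt1$value
  note("power-optimised first vector", best)

  ## stage 2: greedy addition, new weight optimised alone; all powers
  ## re-optimised after each acceptance
  for (j in seq_along(ids)[-1]) {
    cand <- c(active, j)
    optR <- maximise1D(
      function(rj) evalSet(cand, c(eta, 1), c(r, rj)), 1,
      control$rBounds[1], control$rBounds[2], control$maxit)
    if (optR$value > best * (1 + control$improveTol)) {
      active <- cand; eta <- c(eta, 1); r <- c(r, optR$x)
      best <- optR$value
      note(sprintf("added vector %d (weight optimised)", ids[j]), best)
      optE <- maximiseLogBox(function(e) evalSet(active, e, r), eta,
                             control$etaBounds[1], control$etaBounds[2],
                             min(control$maxit, 30))
      if (optE$value > best) {
        eta <- optE$x; best <- optE$value
        note("re-optimised all powers", best)
      }
    }
  }

  ## continuation of the leader-only preselection solution: large powers
  ## collapse each community vector onto its leader and weights 1/mass
  ## reproduce the preselected leader allocation, giving the joint
  ## optimisation a second, globally informed starting point
  if (length(mass) == length(ids) && length(ids) > length(active)) {
    etaC <- rep(control$etaBounds[2], length(ids))
    rC <- pmin(pmax(1 / pmax(mass, 1e-12), control$rBounds[1]),
               control$rBounds[2])
    rateC <- evalSet(seq_along(ids), etaC, rC)
    if (rateC > best * (1 + control$improveTol)) {
      active <- seq_along(ids); eta <- etaC; r <- rC
      best <- rateC
      note("leader-allocation continuation", best)
    }
  }

  ## stage 3: redundancy pruning, starting with the first input vector
  i <- 1L
  while (length(active) > 1L && i <= length(active)) {
    keep <- seq_along(active)[-i]
    rt <- evalSet(active[keep], eta[keep], r[keep])
    if (rt > best * (1 + control$improveTol)) {
      active <- active[keep]; eta <- eta[keep]; r <- r[keep]
      best <- rt
      note("pruned redundant vector", best)
    } else i <- i + 1L
  }

  ## stage 4: final joint optimisation of all powers and weights
  ## (r is scale-free: the first weight stays fixed)
  na <- length(active)
  if (na >= 1L) {
    pack <- function(th) {
      e <- th[seq_len(na)]
      rr <- if (na > 1L) c(r[1], th[na + seq_len(na - 1L)]) else r
      list(e = e, r = rr)
    }
    th0 <- c(eta, if (na > 1L) r[-1])
    lo <- c(rep(control$etaBounds[1], na),
            rep(control$rBounds[1], max(na - 1L, 0)))
    hi <- c(rep(control$etaBounds[2], na),
            rep(control$rBounds[2], max(na - 1L, 0)))
    optJ <- maximiseLogBox(function(th) {
      pr <- pack(th); evalSet(active, pr$e, pr$r)
    }, th0, lo, hi, control$maxit)
    if (optJ$value > best) {
      pr <- pack(optJ$x); eta <- pr$e; r <- pr$r
      best <- optJ$value
      note("final joint optimisation", best)
    }
  }

  p <- Map(powerOptimise, omega[active], eta)
  alloc <- combineInputVectors(p, r)
  new("PerturbationResult", allocation = as.numeric(alloc), rate = best,
      stages = stages, eta = as.numeric(eta), r = as.numeric(r),
      communities = as.integer(ids[active]), baselineRate = baseline)
}

setMethod("show", "PerturbationResult", function(object) {
  cat("PerturbationResult: rate", format(object@rate, digits = 6),
      "using", length(object@communities), "community vector(s)\n")
  cat("  baseline (plain vL1) rate:",
      format(object@baselineRate, digits = 6), "\n")
  cat("  stages accepted:", nrow(object@stages), "\n")
  invisible(object)
})
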