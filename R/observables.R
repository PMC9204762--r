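## Kinetic and thermodynamic observables of a soft-state Koopman model:
## state and ensemble averages, equilibrium frame weights, relaxation
## timescales, state lifetimes, transition rates, populations, and
## multi-model error statistics.

#' Soft state average of a per-frame observable
#'
#' The chi-weighted mean
#' \deqn{\langle A_i \rangle = \sum_t \chi_i(x_t) A(x_t) / \sum_t \chi_i(x_t).}
#' With hard assignments this is the arithmetic mean over the frames of
#' state i.
#'
#' @param A per-frame observable: numeric vector or frames x p matrix.
#' @param chi a [StateAssignment-class].
#' @param state state index, or `NULL` for all states.
#' @return numeric vector (or states x p matrix when `A` is a matrix and
#'   `state = NULL`).
#' @export
stateAverage <- function(A, chi, state = NULL) {
  stopifnot(is(chi, "StateAssignment"))
  X <- featureValues(chi)
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("observable contains non-finite values")
  if (nrow(A) != nrow(X)) stop("observable and assignment length mismatch")
  mass <- colSums(X)
  if (!is.null(state)) {
    if (mass[state] <= 1e-12) stop("state ", state, " has zero mass")
    out <- colSums(A * X[, state]) / mass[state]
    return(if (ncol(A) == 1) unname(out) else out)
  }
  if (any(mass <= 1e-12)) {
    stop("state(s) with zero mass: ", paste(which(mass <= 1e-12), collapse = ", "))
  }
  out <- crossprod(X, A) / mass
  if (ncol(A) == 1) drop(out) else out
}

#' Equilibrium frame weights from a soft assignment
#'
#' Reweights frames so that state populations match the model equilibrium
#' distribution: w_t proportional to sum_i pi_i chi_i(x_t) / N_i with
#' N_i = sum_t' chi_i(x_t'), normalized to sum 1. With hard assignments
#' and pi equal to the empirical state frequencies the weights are
#' exactly uniform.
#'
#' @param chi a [StateAssignment-class].
#' @param pi equilibrium distribution (length k) or a
#'   [KoopmanModel-class].
#' @return numeric per-frame weights summing to 1.
#' @export
frameWeights <- function(chi, pi) {
  stopifnot(is(chi, "StateAssignment"))
  if (is(pi, "KoopmanModel")) pi <- equilibriumDistribution(pi)
  X <- featureValues(chi)
  stopifnot(length(pi) == ncol(X))
  N <- colSums(X)
  if (any(N <= 1e-12)) {
    stop("state(s) with zero soft mass: ",
         paste(which(N <= 1e-12), collapse = ", "))
  }
  w <- drop(X %*% (pi / N))
  w / sum(w)
}

#' Weighted ensemble average
#'
#' @param A per-frame observable (vector or matrix).
#' @param weights normalized per-frame weights, e.g. from
#'   [frameWeights()].
#' @return scalar (or length-p vector for matrix `A`).
#' @export
ensembleAverage <- function(A, weights) {
  A <- as.matrix(A)
  if (nrow(A) != length(weights)) stop("observable/weights length mismatch")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  out <- colSums(A * weights)
  if (ncol(A) == 1) unname(out[1]) else out
}

#' Relaxation timescales of a Koopman model
#'
#' t_i = -tau / ln|lambda_i| for every non-unit eigenvalue of K, sorted
#' descending. Non-stationary modes with |lambda| >= 1 (beyond a 1e-10
#' tolerance) are reported as `Inf` with a warning. Complex eigenvalues
#' enter via their modulus.
#'
#' @param model a [KoopmanModel-class].
#' @return numeric timescales (ns), length k - 1.
#' @export
relaxationTimescales <- function(model) {
  stopifnot(is(model, "KoopmanModel"))
  ev <- eigen(model@K, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-12)) {
    message("complex eigenvalues: using moduli |lambda_i|")
  }
  mods <- sort(Mod(ev), decreasing = TRUE)[-1]
  out <- rep(Inf, length(mods))
  ok <- mods < 1 - 1e-10
  out[ok] <- -model@tau / log(mods[ok])
  if (any(!ok)) warning("non-stationary mode(s) with |lambda| >= 1: infinite timescale")
  sort(out, decreasing = TRUE)
}

#' State lifetimes from the Koopman diagonal
#'
#' Mean dwell times t_i = -tau / ln K_ii. A diagonal element of 1 gives an
#' infinite lifetime (flagged); non-positive diagonals are an error.
#'
#' @param model a [KoopmanModel-class].
#' @return numeric lifetimes (ns), one per state.
#' @export
stateLifetimes <- function(model) {
  stopifnot(is(model, "KoopmanModel"))
  d <- diag(model@K)
  if (any(d <= 0)) {
    stop("non-positive diagonal element(s): lifetime undefined for state(s) ",
         paste(which(d <= 0), collapse = ", "))
  }
  out <- rep(Inf, length(d))
  ok <- d < 1
  out[ok] <- -model@tau / log(d[ok])
  if (any(!ok)) warning("absorbing state(s) with K_ii = 1: infinite lifetime")
  out
}

#' Inter-state transition rates
#'
#' Default definition: rate_(i->j) = K_ij(tau) / tau for i != j, reported
#' in 1/microsecond. The alternative `"mfpt"` mode returns inverse mean
#' first-passage times computed from the embedded chain at the model lag.
#'
#' @param model a [KoopmanModel-class].
#' @param mode `"lag"` (default) or `"mfpt"`.
#' @return k x k rate matrix (1/us) with zero diagonal.
#' @export
transitionRates <- function(model, mode = c("lag", "mfpt")) {
  mode <- match.arg(mode)
  K <- model@K
  k <- nrow(K)
  tauUs <- model@tau / 1000
  if (mode == "lag") {
    R <- K / tauUs
    diag(R) <- 0
    return(R)
  }
  ## mean first-passage times of the discrete chain at lag tau
  R <- matrix(0, k, k)
  for (j in seq_len(k)) {
    idx <- setdiff(seq_len(k), j)
    M <- diag(length(idx)) - K[idx, idx, drop = FALSE]
    m <- solve(M, rep(1, length(idx)))     # in units of lag steps
    mfpt <- numeric(k)
    mfpt[idx] <- m * tauUs
    R[idx, j] <- 1 / mfpt[idx]
  }
  diag(R) <- 0
  R
}

#' Equilibrium state populations
#'
#' @param model a [KoopmanModel-class] (or a bare distribution vector).
#' @return numeric populations summing to 1.
#' @export
statePopulations <- function(model) {
  if (is(model, "KoopmanModel")) return(equilibriumDistribution(model))
  stopifnot(abs(sum(model) - 1) < 1e-6)
  model
}

#' Mean and uncertainty of an observable over trained models
#'
#' Averages an observable over the set of trained models and quantifies
#' the uncertainty from the bootstrap distribution of the mean (default
#' 1000 resamples): either its 95% percentile interval (default) or its
#' standard deviation.
#'
#' @param values numeric vector (one value per model) or models x p
#'   matrix.
#' @param mode `"percentile"` or `"sd"`.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return a [ModelEnsembleStat-class].
#' @export
modelEnsembleStats <- function(values, mode = c("percentile", "sd"),
                               nBoot = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  V <- as.matrix(values)
  if (nrow(V) < 2) stop("need at least 2 models")
  m <- colMeans(V)
  bootMeans <- withSeed(seed, {
    out <- matrix(0, nBoot, ncol(V))
    for (b in seq_len(nBoot)) {
      out[b, ] <- colMeans(V[sample.int(nrow(V), replace = TRUE), ,
                             drop = FALSE])
    }
    out
  })
  if (mode == "percentile") {
    lower <- apply(bootMeans, 2, quantile, probs = 0.025, names = FALSE)
    upper <- apply(bootMeans, 2, quantile, probs = 0.975, names = FALSE)
  } else {
    s <- apply(bootMeans, 2, stats::sd)
    lower <- m - s
    upper <- m + s
  }
  new("ModelEnsembleStat", mean = unname(m),
      lower = unname(pmin(lower, m)), upper = unname(pmax(upper, m)),
      nModels = nrow(V), mode = mode)
}
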