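## Koopman model estimation from soft state assignments, VAMP-2 scoring,
## frame splitting, unbound-frame filtering, and state alignment across
## independently trained models.

lagFrames <- function(x, tauNs) {
  lag <- as.integer(round(tauNs * 1000 / frameInterval(x)))
  if (lag < 1) stop("lag time ", tauNs, " ns is below the frame interval")
  lag
}

#' Estimate a Koopman model from a soft state assignment
#'
#' Soft transition counts C_ij = sum_t chi_i(x_t) chi_j(x_(t+tau)) over all
#' frame pairs separated by the lag within a trajectory; K is the
#' row-normalized count matrix and the equilibrium distribution pi its
#' leading left eigenvector (normalized to sum 1). With hard 0/1
#' assignments this reduces exactly to the classical count-based Markov
#' state model.
#'
#' @param chi a [StateAssignment-class].
#' @param tau lag time in ns.
#' @return a [KoopmanModel-class].
#' @export
estimateKoopman <- function(chi, tau) {
  stopifnot(is(chi, "StateAssignment"))
  lag <- lagFrames(chi, tau)
  pr <- lagPairs(trajIds(chi), lag)
  if (length(pr$t0) < 1) stop("no frame pairs available at lag ", tau, " ns")
  X <- featureValues(chi)[pr$t0, , drop = FALSE]
  Y <- featureValues(chi)[pr$t1, , drop = FALSE]
  C <- crossprod(X, Y)
  mass <- rowSums(C)
  if (any(mass <= 1e-12)) {
    stop("empty state(s): ", paste(which(mass <= 1e-12), collapse = ", "),
         " carry no probability mass at this lag")
  }
  K <- C / mass
  new("KoopmanModel", K = K, pi = stationaryDistribution(K), tau = tau,
      metadata = list(nPairs = length(pr$t0), lagFrames = lag))
}

## symmetric inverse square root with small-eigenvalue truncation
invSqrtPSD <- function(M, relTol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > relTol * max(e$values)
  if (!all(keep)) {
    message("rank-deficient correlation matrix: ", sum(!keep),
            " mode(s) truncated")
  }
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(e$values[keep]))
}

#' VAMP-2 score of a state assignment at a lag
#'
#' Sum of squared singular values of the normalized time-lagged
#' correlation operator C00^(-1/2) C01 C11^(-1/2) built from the raw
#' (uncentered) state-probability covariances. Bounded between 1 (only
#' the stationary process resolved) and the number of states. Rank
#' deficient covariances are handled by truncated pseudo-inversion, logged
#' via a message.
#'
#' @param chi a [StateAssignment-class] (or plain matrix with `traj`).
#' @param tau lag time (ns).
#' @return the scalar score.
#' @export
vamp2Score <- function(chi, tau) {
  stopifnot(is(chi, "StateAssignment"))
  lag <- lagFrames(chi, tau)
  pr <- lagPairs(trajIds(chi), lag)
  if (length(pr$t0) < 1) stop("no frame pairs available at lag ", tau, " ns")
  X <- featureValues(chi)[pr$t0, , drop = FALSE]
  Y <- featureValues(chi)[pr$t1, , drop = FALSE]
  vamp2FromChi(X, Y)
}

vamp2FromChi <- function(X, Y) {
  N <- nrow(X)
  C00 <- crossprod(X) / N
  C11 <- crossprod(Y) / N
  C01 <- crossprod(X, Y) / N
  M <- invSqrtPSD(C00) %*% C01 %*% invSqrtPSD(C11)
  sum(M^2)
}

#' Create test / train-validation split plans
#'
#' Holds out `testFraction` of the frames as a common test set, then
#' partitions the remainder into `nSplits` randomized train:validation
#' splits at ratio (1 - validationFraction) : validationFraction
#' (default 9:1).
#'
#' @param nFrames total number of frames.
#' @param testFraction fraction held out for testing (default 0.1).
#' @param nSplits number of train/validation partitions (default 20).
#' @param validationFraction validation share of the non-test frames.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return a [SplitPlan-class].
#' @export
makeSplits <- function(nFrames, testFraction = 0.1, nSplits = 20,
                       validationFraction = 0.1, seed = 1L) {
  if (nFrames < 20) stop("need at least 20 frames to split")
  withSeed(seed, {
    test <- sort(sample.int(nFrames, round(testFraction * nFrames)))
    rest <- setdiff(seq_len(nFrames), test)
    splits <- lapply(seq_len(nSplits), function(i) {
      val <- sort(sample(rest, round(validationFraction * length(rest))))
      list(train = setdiff(rest, val), validation = val)
    })
    new("SplitPlan", test = as.integer(test), splits = splits,
        nFrames = as.integer(nFrames), seed = as.integer(seed))
  })
}

#' Mask of frames where the ligand is bound
#'
#' TRUE where the minimum ligand-peptide distance over all residues is at
#' most the cutoff; frames beyond it are excluded from model training.
#'
#' @param distances a residue-level [DistanceSeries-class].
#' @param cutoff bound/unbound cutoff (nm), default 0.5.
#' @return logical per-frame mask.
#' @export
filterBoundFrames <- function(distances, cutoff = 0.5) {
  stopifnot(is(distances, "DistanceSeries"))
  apply(featureValues(distances), 1, min) <= cutoff
}

allPermutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in allPermutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Align state labels across independently trained models
#'
#' Each trained model labels its states in an arbitrary order. Given one
#' state-averaged contact map per model (a k x p matrix, one row per
#' state), finds for every model the state permutation minimizing the
#' total root-mean-square deviation to the reference model's maps. Ties
#' are broken in favour of the permutation keeping higher-population
#' states first.
#'
#' @param maps list (one per model) of k x p state-averaged contact map
#'   matrices.
#' @param populations optional list of per-model state populations used
#'   for tie-breaking.
#' @param reference index of the reference model (default 1).
#' @return list of integer permutations `perm` such that
#'   `maps[[m]][perm, ]` is aligned with the reference.
#' @export
alignStatesAcrossModels <- function(maps, populations = NULL, reference = 1L) {
  stopifnot(length(maps) >= 2)
  k <- nrow(maps[[reference]])
  perms <- allPermutations(k)
  ref <- maps[[reference]]
  lapply(seq_along(maps), function(m) {
    M <- maps[[m]]
    cost <- vapply(perms, function(p) {
      sqrt(mean((M[p, , drop = FALSE] - ref)^2))
    }, numeric(1))
    best <- which(cost <= min(cost) + 1e-12)
    if (length(best) > 1 && !is.null(populations)) {
      popOrder <- vapply(best, function(b) {
        ## prefer permutations listing higher-population states first
        sum(populations[[m]][perms[[b]]] * rev(seq_len(k)))
      }, numeric(1))
      best <- best[which.max(popOrder)]
    } else {
      best <- best[1]
    }
    as.integer(perms[[best]])
  })
}

#' Apply a state permutation to assignment and model
#'
#' @param chi a [StateAssignment-class].
#' @param model a [KoopmanModel-class].
#' @param perm integer permutation.
#' @return list with permuted `chi` and `model`.
#' @export
permuteStates <- function(chi, model, perm) {
  chi2 <- stateAssignment(featureValues(chi)[, perm, drop = FALSE],
                          trajIds(chi), frameInterval(chi))
  m2 <- new("KoopmanModel", K = model@K[perm, perm, drop = FALSE],
            pi = model@pi[perm], tau = model@tau, metadata = model@metadata)
  list(chi = chi2, model = m2)
}
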