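## Synthetic trajectory ensembles with analytically known kinetics.
##
## The global conformational process is a discrete-time Markov chain at the
## frame spacing dt; dihedral angles are emitted from state-dependent von
## Mises distributions; side-chain chi1 angles follow a rotamer-hopping jump
## process; ligand-residue contacts are two-state telegraph processes.
## Every quantity the downstream estimators recover (timescales, lifetimes,
## populations, contact kinetics) is therefore known in closed form.

#' Construct a ground-truth generator specification
#'
#' The defaults define the package's benchmark ensemble: a two-state global
#' process at 250 ps frame spacing with a slowest relaxation timescale of
#' about 33 ns and populations 1/3 : 2/3, five residues with well-separated
#' helical-like vs extended-like backbone dihedral emissions, state-dependent
#' chi1 rotamer hopping (fast in the expanded state, slow in the compact
#' one), and two transient ligand contacts with mean on-times of 20 ns.
#'
#' @param nStates number of global states.
#' @param transitionMatrix row-stochastic k x k matrix at step `dt`.
#' @param dt frame spacing (ps).
#' @param nTrajectories,nFrames ensemble size.
#' @param nResidues number of peptide residues.
#' @param phiMu,phiKappa,psiMu,psiKappa k x nResidues von Mises parameters
#'   (mean radians, concentration) for the backbone emissions.
#' @param chi1Rotamers rotamer centres (radians).
#' @param chi1HopRate k x nResidues rotamer hopping rates (1/ns).
#' @param contactRates data.frame(label, kOn, kOff) in 1/ns.
#' @param kOnByState,kOffByState optional n_contacts x k matrices making
#'   the telegraph rates depend on the global state.
#' @param seed master seed; per-trajectory seeds are derived from it.
#' @return a validated [GroundTruthSpec-class].
#' @export
groundTruthSpec <- function(nStates = 2L,
                            transitionMatrix = matrix(c(0.995, 0.005,
                                                        0.0025, 0.9975),
                                                      2, 2, byrow = TRUE),
                            dt = 250,
                            nTrajectories = 50L,
                            nFrames = 2000L,
                            nResidues = 5L,
                            phiMu = NULL, phiKappa = NULL,
                            psiMu = NULL, psiKappa = NULL,
                            chi1Rotamers = c(-pi / 3, pi / 3, pi),
                            chi1HopRate = NULL,
                            contactRates = data.frame(
                              label = c("Y10", "F19"),
                              kOn = c(0.0125, 0.05),
                              kOff = c(0.05, 0.05)),
                            kOnByState = NULL, kOffByState = NULL,
                            seed = 42L) {
  k <- as.integer(nStates)
  n <- as.integer(nResidues)
  fill <- function(x, default) {
    if (!is.null(x)) return(x)
    matrix(rep(default, each = n)[seq_len(k * n)], nrow = k, ncol = n,
           byrow = TRUE)
  }
  ## state 1: helical-like basin; state 2: extended-like basin
  if (is.null(phiMu)) phiMu <- matrix(rep(c(-1.2, -2.4), each = n)[seq_len(k * n)],
                                      k, n, byrow = TRUE)
  phiKappa <- fill(phiKappa, rep(8, k))
  if (is.null(psiMu)) psiMu <- matrix(rep(c(-0.8, 2.4), each = n)[seq_len(k * n)],
                                      k, n, byrow = TRUE)
  psiKappa <- fill(psiKappa, rep(8, k))
  chi1HopRate <- fill(chi1HopRate, c(0.2, 0.02))
  new("GroundTruthSpec",
      nStates = k, transitionMatrix = transitionMatrix, dt = dt,
      nTrajectories = as.integer(nTrajectories), nFrames = as.integer(nFrames),
      nResidues = n,
      phiMu = phiMu, phiKappa = phiKappa, psiMu = psiMu, psiKappa = psiKappa,
      chi1Rotamers = chi1Rotamers, chi1HopRate = chi1HopRate,
      contactRates = contactRates,
      kOnByState = kOnByState, kOffByState = kOffByState,
      seed = as.integer(seed))
}

#' Simulate the global state process
#'
#' Samples each trajectory independently from the discrete-time Markov
#' chain of the spec; initial states are drawn from the chain's stationary
#' distribution. Reproducible: trajectory i uses a seed derived from
#' `spec@seed` and i.
#'
#' @param spec a [GroundTruthSpec-class].
#' @return list of integer state-index vectors (1-based), one per trajectory.
#' @export
simulateStatePath <- function(spec) {
  stopifnot(is(spec, "GroundTruthSpec"))
  P <- spec@transitionMatrix
  assertRowStochastic(P, tol = 1e-12)
  k <- spec@nStates
  pi0 <- stationaryDistribution(P)
  cumP <- t(apply(P, 1, cumsum))
  lapply(seq_len(spec@nTrajectories), function(i) {
    withSeed(deriveSeed(spec@seed, i), {
      n <- spec@nFrames
      s <- integer(n)
      s[1] <- findInterval(runif(1), cumsum(pi0)) + 1L
      u <- runif(n - 1)
      for (t in 2:n) {
        s[t] <- findInterval(u[t - 1], cumP[s[t - 1], ]) + 1L
      }
      s
    })
  })
}

#' Simulate a two-state semi-Markov path with controllable dwell tails
#'
#' Alternating-renewal process over two states with dwell times drawn
#' either geometrically (the Markov control) or from a discretized Pareto
#' distribution with the same mean (heavy tails, hence non-Markovian
#' dynamics at the frame resolution). Used to probe the sensitivity of the
#' Chapman-Kolmogorov test.
#'
#' @param nTrajectories,nFrames ensemble size.
#' @param meanDwell length-2 mean dwell times in frames.
#' @param tail `"geometric"` or `"pareto"`.
#' @param alpha Pareto shape (> 1 so the mean exists); default 1.5 gives
#'   infinite dwell-time variance.
#' @param seed master seed.
#' @return list of integer state paths (1-based).
#' @export
simulateSemiMarkovPath <- function(nTrajectories, nFrames, meanDwell,
                                   tail = c("geometric", "pareto"),
                                   alpha = 1.5, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(length(meanDwell) == 2, all(meanDwell >= 1), alpha > 1)
  drawDwell <- function(m, n) {
    if (tail == "geometric") {
      stats::rgeom(n, prob = 1 / m) + 1
    } else {
      ## continuous Pareto mean alpha*xm/(alpha-1); match the target mean
      xm <- m * (alpha - 1) / alpha
      pmax(1, round(xm * runif(n)^(-1 / alpha)))
    }
  }
  lapply(seq_len(nTrajectories), function(i) {
    withSeed(deriveSeed(seed, i), {
      s0 <- sample.int(2L, 1)
      out <- integer(0)
      cur <- s0
      while (length(out) < nFrames) {
        d <- drawDwell(meanDwell[cur], 1)
        out <- c(out, rep.int(cur, d))
        cur <- 3L - cur
      }
      out[seq_len(nFrames)]
    })
  })
}

#' Emit dihedral angle series from a state path
#'
#' Backbone phi/psi angles are drawn per frame from the state's von Mises
#' distribution for each residue; chi1 angles follow a rotamer-hopping jump
#' process: hops occur with probability 1 - exp(-rate * dt) per frame (rate
#' taken from the current global state), and a hop resamples the rotamer
#' uniformly from the rotamer set. With rotamer centres equally spaced on
#' the circle the chi1 autocorrelation decays exactly as exp(-rate * lag).
#'
#' @param statePaths list of state-index vectors, e.g. from
#'   [simulateStatePath()].
#' @param spec the [GroundTruthSpec-class] holding the emission parameters.
#' @param seed seed for the emission noise (default derived from the spec).
#' @return a [FeatureSeries-class] with columns `phi_<r>`, `psi_<r>`,
#'   `chi1_<r>` in radians.
#' @export
emitDihedralSeries <- function(statePaths, spec, seed = NULL) {
  stopifnot(is(spec, "GroundTruthSpec"))
  if (is.null(seed)) seed <- deriveSeed(spec@seed, 1000003L)
  k <- spec@nStates
  maxState <- max(unlist(statePaths))
  if (maxState > k) {
    stop("state path contains state ", maxState,
         " but emissions are defined for ", k, " states")
  }
  nres <- spec@nResidues
  states <- unlist(statePaths)
  nT <- length(states)
  traj <- rep.int(seq_along(statePaths), lengths(statePaths))
  dtNs <- spec@dt / 1000

  phi <- matrix(NA_real_, nT, nres)
  psi <- matrix(NA_real_, nT, nres)
  chi1 <- matrix(NA_real_, nT, nres)
  withSeed(seed, {
    for (s in seq_len(k)) {
      idx <- which(states == s)
      if (!length(idx)) next
      for (r in seq_len(nres)) {
        phi[idx, r] <- rVonMises(length(idx), spec@phiMu[s, r], spec@phiKappa[s, r])
        psi[idx, r] <- rVonMises(length(idx), spec@psiMu[s, r], spec@psiKappa[s, r])
      }
    }
    rot <- spec@chi1Rotamers
    nrot <- length(rot)
    offset <- 0L
    for (p in statePaths) {
      n <- length(p)
      pHop <- 1 - exp(-spec@chi1HopRate[p, , drop = FALSE] * dtNs)
      for (r in seq_len(nres)) {
        hop <- runif(n) < pHop[, r]
        hop[1] <- TRUE                      # initial rotamer draw
        draws <- sample.int(nrot, sum(hop), replace = TRUE)
        idx <- cumsum(hop)                  # index of the last hop <= t
        chi1[offset + seq_len(n), r] <- rot[draws[idx]]
      }
      offset <- offset + n
    }
  })
  vals <- cbind(phi, psi, chi1)
  labs <- c(paste0("phi_", seq_len(nres)), paste0("psi_", seq_len(nres)),
            paste0("chi1_", seq_len(nres)))
  newFeatureSeries(vals, labs, traj, spec@dt)
}

## single telegraph trajectory sampled at dt, constant rates (1/ns), dt in ns
telegraphChain <- function(n, kOn, kOff, dtNs, init) {
  s <- kOn + kOff
  if (s == 0) return(rep(init, n))
  pOn <- kOn / s
  decay <- exp(-s * dtNs)
  p01 <- pOn * (1 - decay)        # off -> on
  p10 <- (1 - pOn) * (1 - decay)  # on -> off
  out <- logical(n)
  out[1] <- init
  u <- runif(n - 1)
  for (t in 2:n) {
    out[t] <- if (out[t - 1]) u[t - 1] >= p10 else u[t - 1] < p01
  }
  out
}

#' Emit telegraph-process contact series
#'
#' Each contact is an independent two-state continuous-time Markov
#' (telegraph) process with on-rate `kOn` and off-rate `kOff` (1/ns),
#' sampled at the frame spacing using the exact two-state propagator. The
#' stationary on-probability is kOn / (kOn + kOff) and the mean on-dwell
#' time is 1/kOff. Rates may be conditioned on a global state path.
#'
#' @param rates data.frame with columns `label`, `kOn`, `kOff` (1/ns).
#' @param nFrames frames per trajectory.
#' @param dt frame spacing (ps).
#' @param seed master seed.
#' @param nTrajectories number of independent trajectories.
#' @param init `"stationary"`, `"on"` or `"off"` initial condition.
#' @param statePaths optional list of global state paths; with
#'   `kOnByState`/`kOffByState` (n_contacts x k matrices) the rates follow
#'   the state.
#' @param kOnByState,kOffByState optional state-conditioned rate matrices.
#' @return a [ContactSeries-class].
#' @export
emitTelegraphContacts <- function(rates, nFrames, dt, seed = 1L,
                                  nTrajectories = 1L,
                                  init = c("stationary", "on", "off"),
                                  statePaths = NULL,
                                  kOnByState = NULL, kOffByState = NULL) {
  init <- match.arg(init)
  stopifnot(all(c("label", "kOn", "kOff") %in% names(rates)))
  if (any(rates$kOn < 0) || any(rates$kOff < 0)) {
    stop("contact rates must be non-negative")
  }
  dtNs <- dt / 1000
  nc <- nrow(rates)
  if (!is.null(statePaths)) nTrajectories <- length(statePaths)
  perTraj <- lapply(seq_len(nTrajectories), function(i) {
    withSeed(deriveSeed(seed, 7000L + i), {
      n <- if (is.null(statePaths)) nFrames else length(statePaths[[i]])
      on <- matrix(FALSE, n, nc)
      for (j in seq_len(nc)) {
        kOn <- rates$kOn[j]; kOff <- rates$kOff[j]
        p0 <- if (kOn + kOff > 0) kOn / (kOn + kOff) else 0
        startOn <- switch(init, stationary = runif(1) < p0, on = TRUE,
                          off = FALSE)
        if (is.null(statePaths) || (is.null(kOnByState) && is.null(kOffByState))) {
          on[, j] <- telegraphChain(n, kOn, kOff, dtNs, startOn)
        } else {
          sp <- statePaths[[i]]
          kon_t <- if (is.null(kOnByState)) rep(kOn, n) else kOnByState[j, sp]
          koff_t <- if (is.null(kOffByState)) rep(kOff, n) else kOffByState[j, sp]
          s_t <- kon_t + koff_t
          decay <- exp(-s_t * dtNs)
          p01 <- ifelse(s_t > 0, kon_t / s_t * (1 - decay), 0)
          p10 <- ifelse(s_t > 0, koff_t / s_t * (1 - decay), 0)
          x <- logical(n)
          x[1] <- startOn
          u <- runif(n - 1)
          for (t in 2:n) {
            x[t] <- if (x[t - 1]) u[t - 1] >= p10[t] else u[t - 1] < p01[t]
          }
          on[, j] <- x
        }
      }
      on
    })
  })
  on <- do.call(rbind, perTraj)
  traj <- rep.int(seq_len(nTrajectories), vapply(perTraj, nrow, integer(1)))
  contactSeries(on, labels = rates$label, traj = traj, frameInterval = dt)
}

#' Analytic kinetics of a ground-truth spec
#'
#' Relaxation timescales from the non-unit eigenvalues of the transition
#' matrix (-dt / ln |lambda|), state lifetimes from its diagonal
#' (-dt / ln P_ii), the stationary distribution, and mean contact on-times
#' (1 / kOff). All times in ns.
#'
#' @param spec a [GroundTruthSpec-class].
#' @return list with `timescales`, `lifetimes`, `populations`,
#'   `contactLifetimes`.
#' @export
analyticKinetics <- function(spec) {
  P <- spec@transitionMatrix
  dtNs <- spec@dt / 1000
  ev <- eigen(P, only.values = TRUE)$values
  mods <- Mod(ev)
  nonUnit <- sort(mods[abs(mods - 1) > 1e-12], decreasing = TRUE)
  list(
    timescales = -dtNs / log(nonUnit),
    lifetimes = -dtNs / log(diag(P)),
    populations = stationaryDistribution(P),
    contactLifetimes = stats::setNames(
      ifelse(spec@contactRates$kOff > 0, 1 / spec@contactRates$kOff, Inf),
      spec@contactRates$label)
  )
}

#' Generate the benchmark ensemble with known ground truth
#'
#' Runs the full generator: global state paths, dihedral emissions,
#' telegraph contacts, analytic ground truth, and (optionally) 3D
#' coordinates and on-disk artifacts (topology PDB, multi-model coordinate
#' PDBs, CSV feature/contact tables, ground-truth JSON).
#'
#' @param spec a [GroundTruthSpec-class]; default [groundTruthSpec()].
#' @param dir output directory; `NULL` (default) keeps everything in memory.
#' @param coordinates build 3D coordinates with
#'   [buildPeptideCoordinates()] (slow for large ensembles; default FALSE).
#' @return list with `features` ([FeatureSeries-class]), `contacts`
#'   ([ContactSeries-class]), `statePaths`, `groundTruth`
#'   ([GroundTruth-class]), and `ensemble` (a
#'   [TrajectoryEnsemble-class], when `coordinates = TRUE`).
#' @export
makeBenchmarkEnsemble <- function(spec = groundTruthSpec(), dir = NULL,
                                  coordinates = FALSE) {
  statePaths <- simulateStatePath(spec)
  features <- emitDihedralSeries(statePaths, spec)
  contacts <- if (nrow(spec@contactRates) > 0) {
    emitTelegraphContacts(spec@contactRates, spec@nFrames, spec@dt,
                          seed = spec@seed, statePaths = statePaths,
                          kOnByState = spec@kOnByState,
                          kOffByState = spec@kOffByState)
  } else NULL
  ak <- analyticKinetics(spec)
  gt <- new("GroundTruth", statePaths = statePaths,
            trueTimescales = ak$timescales, trueLifetimes = ak$lifetimes,
            truePopulations = ak$populations,
            trueContactLifetimes = ak$contactLifetimes)
  ensemble <- NULL
  if (coordinates) {
    ensemble <- buildPeptideCoordinates(features)
  }
  out <- list(features = features, contacts = contacts,
              statePaths = statePaths, groundTruth = gt, ensemble = ensemble)
  if (!is.null(dir)) {
    writeBenchmark(out, dir)
  }
  out
}

writeBenchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tryCatch({
    writeFeatureCSV(bench$features, file.path(dir, "features.csv"))
    if (!is.null(bench$contacts)) {
      writeFeatureCSV(bench$contacts, file.path(dir, "contacts.csv"))
    }
    gt <- bench$groundTruth
    jsonlite::write_json(list(
      trueTimescales = gt@trueTimescales,
      trueLifetimes = gt@trueLifetimes,
      truePopulations = gt@truePopulations,
      trueContactLifetimes = as.list(gt@trueContactLifetimes),
      statePaths = gt@statePaths
    ), file.path(dir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
    if (!is.null(bench$ensemble)) {
      writeTrajectoryPDB(bench$ensemble, dir)
    }
  }, error = function(e) {
    stop("failed writing benchmark to '", dir, "': ", conditionMessage(e))
  })
  invisible(dir)
}
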