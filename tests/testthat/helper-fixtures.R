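## Shared fixtures, generated in code at test time.

## small two-state benchmark spec; slowest timescale 33.2 ns at 250 ps steps
tinySpec <- function(nTrajectories = 10L, nFrames = 500L, seed = 1L, ...) {
  groundTruthSpec(nTrajectories = nTrajectories, nFrames = nFrames,
                  seed = seed, ...)
}

## hard state assignment from true state paths
hardAssignment <- function(statePaths, k = 2L, frameInterval = 250) {
  s <- unlist(statePaths)
  chi <- matrix(0, length(s), k)
  chi[cbind(seq_along(s), s)] <- 1
  stateAssignment(chi, rep.int(seq_along(statePaths), lengths(statePaths)),
                  frameInterval)
}

## random dihedral FeatureSeries for coordinate-construction tests
randomDihedrals <- function(nres, nframes, seed = 1L, withChi1 = TRUE) {
  withr::with_seed(seed, {
    p <- if (withChi1) 3L else 2L
    vals <- matrix(runif(nframes * nres * p, -pi, pi), nframes)
    labs <- c(paste0("phi_", seq_len(nres)), paste0("psi_", seq_len(nres)),
              if (withChi1) paste0("chi1_", seq_len(nres)))
    softmsm:::newFeatureSeries(vals, labs, rep(1L, nframes), 250)
  })
}

## brute-force transition-count MSM oracle (hard states, 1-based)
countMSM <- function(states, traj, lag) {
  k <- max(states)
  C <- matrix(0, k, k)
  t0 <- seq_len(length(states) - lag)
  keep <- traj[t0] == traj[t0 + lag]
  for (i in which(keep)) {
    C[states[i], states[i + lag]] <- C[states[i], states[i + lag]] + 1
  }
  C / rowSums(C)
}
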