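test_that("state path simulation matches the generating chain", {
  ## absorbing identity chain: every trajectory stays in its initial state
  specId <- tinySpec(nTrajectories = 4L, nFrames = 100L,
                     transitionMatrix = diag(2))
  paths <- simulateStatePath(specId)
  for (p in paths) expect_length(unique(p), 1L)

  ## empirical row-normalized transition counts within 3 SE of the matrix
  P <- matrix(c(0.99, 0.01, 0.02, 0.98), 2, 2, byrow = TRUE)
  spec <- tinySpec(nTrajectories = 200L, nFrames = 5000L,
                   transitionMatrix = P, seed = 11L)
  paths <- simulateStatePath(spec)
  s <- unlist(paths)
  traj <- rep.int(seq_along(paths), lengths(paths))
  Phat <- countMSM(s, traj, 1L)
  nRow <- c(sum(s == 1), sum(s == 2))
  for (i in 1:2) {
    se <- sqrt(P[i, 1] * (1 - P[i, 1]) / nRow[i])
    expect_lt(abs(Phat[i, 1] - P[i, 1]), 3 * se)
  }

  ## bitwise reproducibility under a fixed seed
  expect_identical(simulateStatePath(spec), paths)

  ## non-stochastic matrix rejected
  expect_error(groundTruthSpec(transitionMatrix = matrix(c(0.9, 0.2,
                                                           0.1, 0.9), 2)),
               "sum to 1")
})

test_that("dihedral emissions follow the state-conditional distributions", {
  ## infinite concentration collapses onto the state mean
  spec <- tinySpec(nTrajectories = 1L, nFrames = 200L,
                   transitionMatrix = diag(2),
                   phiKappa = matrix(Inf, 2, 5), psiKappa = matrix(Inf, 2, 5))
  paths <- list(rep(1L, 200L))
  d <- emitDihedralSeries(paths, spec)
  phi <- featureValues(d)[, "phi_1"]
  expect_equal(phi, rep(wrapAngle(spec@phiMu[1, 1]), 200))

  ## circular mean of a large von Mises sample within 3 SE of the parameter
  x <- withr::with_seed(5, rVonMises(1e5, 0.7, 5))
  cmean <- atan2(mean(sin(x)), mean(cos(x)))
  ## circular SE approx 1/sqrt(n * kappa * A(kappa)); bound loosely by
  ## sigma = 1/sqrt(n * kappa / 2)
  expect_lt(abs(cmean - 0.7), 3 / sqrt(1e5 * 5 / 2))
  expect_true(all(x >= -pi & x < pi))

  ## two disjoint states: nearest-mean classification error matches the
  ## overlap integral of the two densities (numeric oracle)
  mu <- c(-1.2, 1.2); kappa <- 4
  grid <- seq(-pi, pi, length.out = 20001)[-1]
  f1 <- dVonMises(grid, mu[1], kappa); f2 <- dVonMises(grid, mu[2], kappa)
  bayesErr <- 0.5 * sum(pmin(f1, f2)) * (grid[2] - grid[1])
  spec2 <- tinySpec(nTrajectories = 2L, nFrames = 5e4L,
                    transitionMatrix = diag(2), nResidues = 1L,
                    phiMu = matrix(mu, 2, 1), phiKappa = matrix(kappa, 2, 1),
                    seed = 7L)
  paths2 <- list(rep(1L, 5e4L), rep(2L, 5e4L))
  d2 <- emitDihedralSeries(paths2, spec2)
  ang <- featureValues(d2)[, "phi_1"]
  pred <- ifelse(dVonMises(ang, mu[1], kappa) >=
                   dVonMises(ang, mu[2], kappa), 1L, 2L)
  err <- mean(pred != rep(1:2, each = 5e4))
  se <- sqrt(bayesErr * (1 - bayesErr) / 1e5)
  expect_lt(abs(err - bayesErr), 3 * se)

  ## missing state parameters rejected
  expect_error(emitDihedralSeries(list(c(1L, 3L)), spec),
               "defined for")
})

test_that("telegraph contacts have the analytic stationary occupancy", {
  ## absorbing on-state
  cs <- emitTelegraphContacts(data.frame(label = "c", kOn = 0.1, kOff = 0),
                              200, 250, seed = 1, init = "on")
  expect_true(all(featureValues(cs)))

  ## symmetric rates: long-run occupancy 1/2 within 3 SE
  cs2 <- emitTelegraphContacts(data.frame(label = "c", kOn = 0.05,
                                          kOff = 0.05), 1e5, 250, seed = 2)
  ## effective variance of the mean of an OU-like indicator:
  ## var = 2 p(1-p) / (s * T_total)
  se2 <- sqrt(2 * 0.25 / (0.1 * 1e5 * 0.25))
  expect_lt(abs(mean(featureValues(cs2)) - 0.5), 3 * se2)

  ## asymmetric rates: kOn/(kOn+kOff) = 1/6
  cs3 <- emitTelegraphContacts(data.frame(label = "c", kOn = 0.01,
                                          kOff = 0.05), 1e5, 250, seed = 3)
  p <- 1 / 6
  se3 <- sqrt(2 * p * (1 - p) / (0.06 * 1e5 * 0.25))
  expect_lt(abs(mean(featureValues(cs3)) - p), 3 * se3)

  ## negative rates rejected
  expect_error(emitTelegraphContacts(data.frame(label = "c", kOn = -1,
                                                kOff = 1), 10, 250),
               "non-negative")
})

test_that("analytic ground truth matches closed forms and is seed-invariant", {
  spec <- tinySpec(seed = 3L)
  ak <- analyticKinetics(spec)
  lam2 <- eigen(spec@transitionMatrix)$values[2]
  expect_equal(ak$timescales, -0.25 / log(lam2))
  expect_equal(ak$lifetimes, -0.25 / log(diag(spec@transitionMatrix)))
  expect_equal(sum(ak$populations), 1)
  ## detailed-balanced 2-state chain: stationary distribution from rates
  p12 <- spec@transitionMatrix[1, 2]; p21 <- spec@transitionMatrix[2, 1]
  expect_equal(unname(ak$populations),
               c(p21, p12) / (p12 + p21))

  ## two specs differing only in seed: different paths, identical analytics
  b1 <- makeBenchmarkEnsemble(tinySpec(nTrajectories = 2L, nFrames = 200L,
                                       seed = 1L))
  b2 <- makeBenchmarkEnsemble(tinySpec(nTrajectories = 2L, nFrames = 200L,
                                       seed = 2L))
  expect_false(identical(b1$statePaths, b2$statePaths))
  expect_equal(b1$groundTruth@trueTimescales, b2$groundTruth@trueTimescales)
  expect_equal(b1$groundTruth@truePopulations, b2$groundTruth@truePopulations)
})

test_that("semi-Markov paths alternate with the requested mean dwell", {
  paths <- simulateSemiMarkovPath(20, 2000, c(50, 100), tail = "geometric",
                                  seed = 4)
  s <- unlist(paths)
  expect_true(all(s %in% 1:2))
  ## mean dwell of state 1 close to 50 frames
  runs <- rle(paths[[1]])
  d1 <- mean(runs$lengths[runs$values == 1])
  expect_gt(d1, 20); expect_lt(d1, 120)
  ## heavy-tailed variant produces occasional very long dwells
  hp <- simulateSemiMarkovPath(20, 2000, c(50, 100), tail = "pareto",
                               alpha = 1.5, seed = 4)
  maxRun <- max(unlist(lapply(hp, function(p) rle(p)$lengths)))
  expect_gt(maxRun, 500)
})

test_that("benchmark artifacts are written and readable by downstream stages", {
  d <- withr::local_tempdir()
  spec <- tinySpec(nTrajectories = 2L, nFrames = 30L, seed = 1L)
  bench <- makeBenchmarkEnsemble(spec, dir = d, coordinates = TRUE)
  expect_true(all(file.exists(file.path(d, c("features.csv", "contacts.csv",
                                             "ground_truth.json",
                                             "topology.pdb",
                                             "traj_001.pdb")))))
  feat <- readFeatureCSV(file.path(d, "features.csv"))
  expect_equal(featureValues(feat), featureValues(bench$features),
               tolerance = 1e-12, ignore_attr = TRUE)
  ens <- readTrajectoryEnsemble(file.path(d, "topology.pdb"),
                                file.path(d, sprintf("traj_%03d.pdb", 1:2)))
  ## PDB stores 3 decimals in Angstrom: 1e-4 nm round trip
  expect_equal(do.call(rbind, ens@coords),
               do.call(rbind, bench$ensemble@coords), tolerance = 1e-3,
               ignore_attr = TRUE)
  ## ground-truth JSON holds the eigenvalue timescale
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  lam2 <- eigen(spec@transitionMatrix)$values[2]
  expect_equal(gt$trueTimescales, -0.25 / log(lam2), tolerance = 1e-10)
})
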