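test_that("state averages follow the chi-weighted mean formula", {
  ## hard assignments reduce to the per-state arithmetic mean
  chi <- stateAssignment(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                         rep(1L, 4), 250)
  A <- c(2, 4, 6, 10)
  expect_equal(stateAverage(A, chi, 1), 3)
  expect_equal(stateAverage(A, chi, 2), 8)
  ## maximally ambiguous assignment: every state sees the global mean
  chiU <- stateAssignment(matrix(0.5, 4, 2), rep(1L, 4), 250)
  expect_equal(stateAverage(A, chiU, 1), mean(A))
  expect_equal(stateAverage(A, chiU, 2), mean(A))
  ## direct evaluation: A = (1,2), chi_1 = (1, 0.5) -> 4/3
  chiD <- stateAssignment(rbind(c(1, 0), c(0.5, 0.5)), rep(1L, 2), 250)
  expect_equal(stateAverage(c(1, 2), chiD, 1), 4 / 3)
  ## zero-mass state is an error
  chiZ <- stateAssignment(cbind(rep(1, 3), 0), rep(1L, 3), 250)
  expect_error(stateAverage(1:3, chiZ, 2), "zero mass")
})

test_that("frame weights reweight to the equilibrium distribution", {
  ## hard assignments with pi = empirical frequencies: exactly uniform
  chi <- hardAssignment(list(c(1L, 1L, 2L, 2L, 2L, 1L)))
  w <- frameWeights(chi, c(0.5, 0.5))
  expect_equal(w, rep(1 / 6, 6))
  ## single state: uniform
  chi1 <- stateAssignment(matrix(1, 5, 1), rep(1L, 5), 250)
  expect_equal(frameWeights(chi1, 1), rep(0.2, 5))
  ## hand-evaluated case: frames (1,1,2,2), pi = (0.75, 0.25)
  chi2 <- hardAssignment(list(c(1L, 1L, 2L, 2L)))
  expect_equal(frameWeights(chi2, c(0.75, 0.25)),
               c(0.375, 0.375, 0.125, 0.125))
  ## weights always normalized and non-negative (soft random cases)
  for (s in 1:5) {
    raw <- withr::with_seed(s, matrix(runif(60), 20, 3))
    chiR <- stateAssignment(raw / rowSums(raw), rep(1L, 20), 250)
    piR <- withr::with_seed(s + 10, {
      v <- runif(3); v / sum(v)
    })
    w <- frameWeights(chiR, piR)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    expect_true(all(w >= 0))
  }
})

test_that("ensemble averages combine weights and observables", {
  expect_equal(ensembleAverage(c(0, 4), c(0.25, 0.75)), 3)
  expect_equal(ensembleAverage(1:10, rep(0.1, 10)), mean(1:10))
  for (s in 1:3) {
    w <- withr::with_seed(s, {
      v <- runif(8); v / sum(v)
    })
    expect_equal(ensembleAverage(rep(2.5, 8), w), 2.5)
  }
  expect_error(ensembleAverage(1:3, c(0.5, 0.5)), "mismatch")
  expect_error(ensembleAverage(1:2, c(0.5, 0.4)), "normalized")
})

test_that("relaxation timescales and lifetimes follow the log-eigenvalue forms", {
  mk <- function(K) new("KoopmanModel", K = K,
                        pi = softmsm:::stationaryDistribution(K), tau = 5)
  ## eigenvalue e^-1 at tau = 5 ns: timescale exactly 5 ns
  e <- exp(-1)
  Ksym <- matrix(c((1 + e) / 2, (1 - e) / 2, (1 - e) / 2, (1 + e) / 2), 2)
  expect_equal(relaxationTimescales(mk(Ksym)), 5, tolerance = 1e-12)
  ## lambda2 = 0.5 -> -5 / ln 0.5
  K5 <- matrix(c(0.75, 0.25, 0.25, 0.75), 2)
  expect_equal(relaxationTimescales(mk(K5)), -5 / log(0.5), tolerance = 1e-12)
  ## identity: infinite timescales, flagged
  expect_warning(ts <- relaxationTimescales(mk(diag(2))), "non-stationary")
  expect_equal(ts, Inf)
  ## diagonal e^-1: lifetime exactly 5 ns
  Ke <- matrix(c(e, 1 - e, 1 - e, e), 2)
  expect_equal(stateLifetimes(mk(Ke)), c(5, 5), tolerance = 1e-12)
  ## K_ii = 0.9 -> -5 / ln 0.9 = 47.46 ns
  K9 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  expect_equal(stateLifetimes(mk(K9)), rep(-5 / log(0.9), 2),
               tolerance = 1e-12)
  expect_equal(stateLifetimes(mk(K9))[1], 47.4561, tolerance = 1e-4)
  ## absorbing diagonal flagged infinite
  expect_warning(lt <- stateLifetimes(mk(diag(2))), "infinite")
  expect_equal(lt, c(Inf, Inf))
})

test_that("two-state spectral identity links eigenvalue and trace", {
  ## for 2x2 row-stochastic K, lambda2 = K11 + K22 - 1 exactly, so the
  ## timescale from the spectrum equals the closed trace form
  for (s in 1:5) {
    ab <- withr::with_seed(s, runif(2, 0.02, 0.4))
    K <- matrix(c(1 - ab[1], ab[1], ab[2], 1 - ab[2]), 2, 2, byrow = TRUE)
    m <- new("KoopmanModel", K = K,
             pi = softmsm:::stationaryDistribution(K), tau = 5)
    expect_equal(relaxationTimescales(m), -5 / log(K[1, 1] + K[2, 2] - 1),
                 tolerance = 1e-8)
  }
})

test_that("estimated lifetimes track the analytic dwell times", {
  ## at the benchmark ensemble size (50 x 2000 frames, default seed)
  spec <- groundTruthSpec()
  chi <- hardAssignment(simulateStatePath(spec))
  m <- estimateKoopman(chi, 5)
  truth <- analyticKinetics(spec)$lifetimes
  est <- stateLifetimes(m)
  expect_lt(max(abs(est - truth) / truth), 0.10)
})

test_that("transition rates scale the off-diagonal Koopman entries", {
  mk <- function(K) new("KoopmanModel", K = K,
                        pi = softmsm:::stationaryDistribution(K), tau = 5)
  expect_equal(transitionRates(mk(diag(2))), matrix(0, 2, 2))
  K <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, 2, byrow = TRUE)
  R <- transitionRates(mk(K))
  ## K_12 = 0.05 at tau = 5 ns -> 10 events per microsecond
  expect_equal(R[1, 2], 10)
  expect_equal(R[2, 1], 4)
  expect_equal(diag(R), c(0, 0))
  ## symmetric K gives symmetric rates
  Ks <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  expect_equal(transitionRates(mk(Ks)), t(transitionRates(mk(Ks))))
  ## the MFPT variant is positive and finite for an ergodic chain
  Rm <- transitionRates(mk(K), mode = "mfpt")
  expect_true(all(Rm[row(Rm) != col(Rm)] > 0))
})

test_that("populations are the stationary distribution", {
  spec <- tinySpec(nTrajectories = 30L, nFrames = 2000L, seed = 23L)
  chi <- hardAssignment(simulateStatePath(spec))
  m <- estimateKoopman(chi, 5)
  pops <- statePopulations(m)
  expect_equal(sum(pops), 1, tolerance = 1e-10)
  truth <- analyticKinetics(spec)$populations
  ## 3 SE of the occupancy estimate; var ~ 2 p(1-p) t_corr / T for the
  ## correlated chain (t_corr = 133 frames, T = 60000 frames)
  se <- sqrt(2 * truth[1] * (1 - truth[1]) * 133 / 60000)
  expect_lt(abs(pops[1] - truth[1]), 3 * se)
})

test_that("observables are invariant under simultaneous state permutation", {
  spec <- tinySpec(nTrajectories = 5L, nFrames = 800L, seed = 29L)
  chi <- hardAssignment(simulateStatePath(spec))
  m <- estimateKoopman(chi, 5)
  sw <- permuteStates(chi, m, c(2L, 1L))
  A <- withr::with_seed(1, rnorm(nrow(featureValues(chi))))
  expect_equal(stateAverage(A, sw$chi, 2), stateAverage(A, chi, 1))
  expect_equal(frameWeights(sw$chi, sw$model), frameWeights(chi, m))
  expect_equal(stateLifetimes(sw$model), stateLifetimes(m)[c(2, 1)])
  expect_equal(relaxationTimescales(sw$model), relaxationTimescales(m))
})

test_that("model-ensemble statistics summarize multi-model spread", {
  ## identical values: degenerate interval
  s0 <- modelEnsembleStats(rep(3.2, 20))
  expect_equal(s0@mean, 3.2)
  expect_equal(s0@lower, 3.2)
  expect_equal(s0@upper, 3.2)
  ## interval contains the mean for arbitrary inputs
  for (s in 1:3) {
    v <- withr::with_seed(s, rnorm(20, 5, 2))
    st <- modelEnsembleStats(v, seed = s)
    expect_lte(st@lower, st@mean)
    expect_gte(st@upper, st@mean)
    expect_equal(st@nModels, 20L)
  }
  ## bootstrap SD of the mean close to sigma / sqrt(20)
  v <- withr::with_seed(9, rnorm(20, 0, 1))
  st <- modelEnsembleStats(v, mode = "sd", seed = 9)
  bootSD <- (st@upper - st@mean)
  expect_lt(abs(bootSD - 1 / sqrt(20)) / (1 / sqrt(20)), 0.30)
  expect_error(modelEnsembleStats(3), "at least 2")
})
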