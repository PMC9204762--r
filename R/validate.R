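## Model validation: implied-timescale curves over lag time, the
## Chapman-Kolmogorov test with bootstrap confidence bands, and timescale
## convergence against the number of trajectories.

#' Implied relaxation timescales over a grid of lag times
#'
#' For each lag a Koopman model is estimated from the assignment and the
#' relaxation timescales -tau / ln|lambda_i| of its non-unit eigenvalues
#' computed. Complex eigenvalues enter through their modulus (flagged via
#' a message). For an exactly Markovian process the curves are flat in
#' the lag.
#'
#' @param chi a [StateAssignment-class].
#' @param lagGrid lag times in ns (default brackets the 5 ns working lag:
#'   1.25, 2.5, 5, 10, 20).
#' @return data.frame with columns `lag`, `process`, `timescale` (ns).
#' @export
impliedTimescales <- function(chi, lagGrid = c(1.25, 2.5, 5, 10, 20)) {
  stopifnot(is(chi, "StateAssignment"))
  out <- lapply(lagGrid, function(tau) {
    m <- estimateKoopman(chi, tau)
    ts <- relaxationTimescales(m)
    data.frame(lag = tau, process = seq_along(ts), timescale = ts)
  })
  do.call(rbind, out)
}

#' Chapman-Kolmogorov test
#'
#' Compares n-fold application of the Koopman operator estimated at lag
#' tau, K(tau)^n, with the operator estimated directly at the longer lag,
#' K(n tau), for n = 1..n_max. An exactly Markovian process agrees up to
#' sampling error. The pass criterion is that every entry of the
#' prediction lies inside the 95% bootstrap band of the estimate obtained
#' by resampling trajectories with replacement.
#'
#' @param chi a [StateAssignment-class].
#' @param tau base lag (ns).
#' @param nMax largest lag multiple (default 5).
#' @param nBoot bootstrap resamples for the band (default 20).
#' @param seed bootstrap seed.
#' @return a [CKReport-class].
#' @export
chapmanKolmogorov <- function(chi, tau, nMax = 5L, nBoot = 20L, seed = 1L) {
  stopifnot(is(chi, "StateAssignment"))
  base <- estimateKoopman(chi, tau)
  trajs <- unique(trajIds(chi))
  vals <- featureValues(chi)
  ns <- seq_len(nMax)
  predicted <- list(); estimated <- list(); perEntry <- list()
  band <- list(); pass <- logical(nMax); maxDev <- numeric(nMax)
  Kpow <- diag(nrow(base@K))
  for (n in ns) {
    Kpow <- Kpow %*% base@K
    est <- tryCatch(estimateKoopman(chi, n * tau), error = function(e) {
      stop("insufficient frame pairs at n = ", n, " (lag ", n * tau,
           " ns): ", conditionMessage(e))
    })
    predicted[[n]] <- Kpow
    estimated[[n]] <- est@K
    perEntry[[n]] <- abs(Kpow - est@K)
    maxDev[n] <- max(perEntry[[n]])
    boots <- withSeed(deriveSeed(seed, 59L * n), {
      lapply(seq_len(nBoot), function(b) {
        pick <- sample(trajs, length(trajs), replace = TRUE)
        idx <- unlist(lapply(pick, function(tr) which(trajIds(chi) == tr)))
        newTraj <- rep.int(seq_along(pick),
                           vapply(pick, function(tr)
                             sum(trajIds(chi) == tr), integer(1)))
        bchi <- stateAssignment(vals[idx, , drop = FALSE], newTraj,
                                frameInterval(chi))
        tryCatch(estimateKoopman(bchi, n * tau)@K,
                 error = function(e) NULL)
      })
    })
    boots <- Filter(Negate(is.null), boots)
    arr <- simplify2array(boots)
    lower <- apply(arr, c(1, 2), quantile, probs = 0.025)
    upper <- apply(arr, c(1, 2), quantile, probs = 0.975)
    band[[n]] <- list(lower = lower, upper = upper)
    pass[n] <- all(Kpow >= lower - 1e-12 & Kpow <= upper + 1e-12)
  }
  new("CKReport", tau = tau, n = as.integer(ns), predicted = predicted,
      estimated = estimated, maxDeviation = maxDev, perEntry = perEntry,
      band = band, pass = pass)
}

#' Timescale convergence over the number of trajectories
#'
#' For each trajectory count, trajectories are resampled without
#' replacement `nResamples` times, the Koopman model re-estimated and the
#' slowest timescales summarized by mean and 95% percentile interval. At
#' the full count every subsample is the complete data set, so the point
#' equals the all-data estimate exactly.
#'
#' @param chi a [StateAssignment-class].
#' @param tau lag (ns).
#' @param counts trajectory counts to evaluate.
#' @param nResamples subsamples per count (default 10).
#' @param seed RNG seed.
#' @return data.frame with `count`, `mean`, `lower`, `upper` of the
#'   slowest timescale (ns).
#' @export
timescaleConvergence <- function(chi, tau, counts = NULL, nResamples = 10L,
                                 seed = 1L) {
  stopifnot(is(chi, "StateAssignment"))
  trajs <- unique(trajIds(chi))
  if (is.null(counts)) {
    counts <- unique(round(seq(2, length(trajs), length.out = 5)))
  }
  if (any(counts < 2)) stop("trajectory counts must be at least 2")
  if (any(counts > length(trajs))) {
    stop("count exceeds available trajectories (", length(trajs), ")")
  }
  vals <- featureValues(chi)
  out <- lapply(counts, function(cnt) {
    ts <- withSeed(deriveSeed(seed, 101L * cnt), {
      vapply(seq_len(nResamples), function(r) {
        pick <- sample(trajs, cnt, replace = FALSE)
        idx <- which(trajIds(chi) %in% pick)
        sub <- stateAssignment(vals[idx, , drop = FALSE],
                               trajIds(chi)[idx], frameInterval(chi))
        m <- tryCatch(estimateKoopman(sub, tau), error = function(e) NULL)
        if (is.null(m)) return(NA_real_)
        relaxationTimescales(m)[1]
      }, numeric(1))
    })
    ts <- ts[is.finite(ts)]
    data.frame(count = cnt, mean = mean(ts),
               lower = quantile(ts, 0.025, names = FALSE),
               upper = quantile(ts, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}
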