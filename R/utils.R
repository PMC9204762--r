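#' @import methods
#' @importFrom stats runif rnorm quantile setNames
NULL

#' Wrap angles to [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped into \eqn{[-\pi, \pi)}.
#' @export
wrapAngle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

## Deterministic per-stream seed derivation from a master seed.
## Keeps derived seeds inside the 32-bit integer range R requires.
deriveSeed <- function(seed, stream) {
  s <- (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629
  as.integer(s) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. For concentration below 1e-8 the
#' distribution is treated as circular-uniform; an infinite concentration
#' returns the mean angle exactly.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter (>= 0, may be `Inf`).
#' @return numeric vector of angles in \eqn{[-\pi, \pi)}.
#' @export
rVonMises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrapAngle(mu), n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0L) {
      u3 <- runif(nacc)
      out[(got + 1L):(got + nacc)] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + nacc
    }
  }
  wrapAngle(out + mu)
}

#' von Mises density
#'
#' @param x angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return density values.
#' @export
dVonMises <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0, expon.scaled = FALSE))
}

## index pairs (t, t + lag) that do not cross trajectory boundaries
lagPairs <- function(traj, lag) {
  stopifnot(lag >= 1)
  n <- length(traj)
  if (lag >= n) return(list(t0 = integer(0), t1 = integer(0)))
  t0 <- seq_len(n - lag)
  keep <- traj[t0] == traj[t0 + lag]
  list(t0 = t0[keep], t1 = t0[keep] + lag)
}

## stationary distribution (leading left eigenvector) of a row-stochastic matrix
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) v <- abs(v) / sum(abs(v))
  pmax(v, 0) / sum(pmax(v, 0))
}

assertRowStochastic <- function(P, tol = 1e-8, what = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop(what, " must be a square matrix")
  }
  if (any(P < -tol)) stop(what, " has negative entries")
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop(what, " rows must sum to 1 (max deviation ",
         format(max(abs(rowSums(P) - 1))), ")")
  }
  invisible(TRUE)
}
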