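## Contact kinetics: weighted contact probabilities, per-contact lifetimes
## via tiny two-state Markov models at a fixed lag, and conditional
## contact (e.g. ring-stacking) probabilities.

#' Weighted contact probabilities
#'
#' The (frame-weighted) fraction of frames in which each contact is
#' formed.
#'
#' @param series a [ContactSeries-class].
#' @param weights per-frame weights (normalized); `NULL` for raw counts.
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
contactProbability <- function(series, weights = NULL) {
  stopifnot(is(series, "ContactSeries"))
  on <- featureValues(series)
  if (is.null(weights)) weights <- rep(1 / nrow(on), nrow(on))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  setNames(drop(crossprod(on, weights)), featureLabels(series))
}

#' Per-contact lifetimes from two-state Markov models at a lag
#'
#' For each contact a 2 x 2 transition matrix is counted at the lag (hard
#' counts, pairs within trajectories only) and the on-state lifetime
#' computed from its diagonal as -tau / ln T_on,on. Contacts that are
#' never on, never observed leaving the on state at this lag, or whose
#' on-on self-transition count is zero (dwell below the lag resolution)
#' are flagged and get `NA` lifetimes.
#'
#' @param series a [ContactSeries-class].
#' @param lagNs lag time (ns), default 5.
#' @param nBoot optional trajectory-bootstrap resamples for a lifetime
#'   interval (0 = off).
#' @param seed bootstrap seed.
#' @return data.frame with `contact`, `probability`, `lifetime` (ns),
#'   `flag` (`"ok"`, `"never-on"`, `"absorbing-on"`,
#'   `"below-resolution"`), and bootstrap `lower`/`upper` when requested.
#' @export
contactLifetime <- function(series, lagNs = 5, nBoot = 0L, seed = 1L) {
  stopifnot(is(series, "ContactSeries"))
  lag <- lagFrames(series, lagNs)
  pr <- lagPairs(trajIds(series), lag)
  if (length(pr$t0) < 1) stop("no frame pairs at lag ", lagNs, " ns")
  on <- featureValues(series)
  prob <- colMeans(on)

  lifetimeOf <- function(x0, x1) {
    nOnOn <- sum(x0 & x1)
    nOnOff <- sum(x0 & !x1)
    if (nOnOn + nOnOff == 0) return(list(lt = NA_real_, flag = "never-on"))
    if (nOnOff == 0) return(list(lt = Inf, flag = "absorbing-on"))
    Tonon <- nOnOn / (nOnOn + nOnOff)
    if (Tonon == 0) return(list(lt = NA_real_, flag = "below-resolution"))
    list(lt = -lagNs / log(Tonon), flag = "ok")
  }

  out <- lapply(seq_len(ncol(on)), function(j) {
    r <- lifetimeOf(on[pr$t0, j], on[pr$t1, j])
    row <- data.frame(contact = featureLabels(series)[j],
                      probability = prob[j], lifetime = r$lt, flag = r$flag,
                      stringsAsFactors = FALSE)
    if (nBoot > 0) {
      trajs <- unique(trajIds(series))
      lts <- withSeed(deriveSeed(seed, 17L * j), {
        vapply(seq_len(nBoot), function(b) {
          pick <- sample(trajs, length(trajs), replace = TRUE)
          keep0 <- integer(0); keep1 <- integer(0)
          for (tr in pick) {
            sel <- which(trajIds(series)[pr$t0] == tr)
            keep0 <- c(keep0, pr$t0[sel]); keep1 <- c(keep1, pr$t1[sel])
          }
          rb <- lifetimeOf(on[keep0, j], on[keep1, j])
          if (identical(rb$flag, "ok")) rb$lt else NA_real_
        }, numeric(1))
      })
      lts <- lts[is.finite(lts)]
      row$lower <- if (length(lts)) quantile(lts, 0.025, names = FALSE) else NA_real_
      row$upper <- if (length(lts)) quantile(lts, 0.975, names = FALSE) else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "lagNs") <- lagNs
  res
}

#' Conditional contact probability
#'
#' P(target on | condition on) = P(both on) / P(condition on), with
#' optional frame weights. Used e.g. for the probability of one
#' ring-stacking interaction given another.
#'
#' @param series a [ContactSeries-class].
#' @param condition label or column index of the conditioning contact.
#' @param target label or column index of the target contact.
#' @param weights per-frame weights (normalized); `NULL` for raw counts.
#' @return scalar probability.
#' @export
conditionalContactProbability <- function(series, condition, target,
                                          weights = NULL) {
  stopifnot(is(series, "ContactSeries"))
  on <- featureValues(series)
  idx <- function(x) {
    if (is.character(x)) {
      j <- match(x, featureLabels(series))
      if (is.na(j)) stop("unknown contact label: ", x)
      j
    } else as.integer(x)
  }
  i <- idx(condition); j <- idx(target)
  if (is.null(weights)) weights <- rep(1 / nrow(on), nrow(on))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  pi_ <- sum(weights[on[, i]])
  if (pi_ <= 0) stop("conditioning contact '", featureLabels(series)[i],
                     "' never occurs")
  sum(weights[on[, i] & on[, j]]) / pi_
}
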