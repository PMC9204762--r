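## Local-dynamics metrics: per-residue Ramachandran entropy, state-
## assignment entropy, and circular autocorrelation of side-chain chi1
## dihedrals. Entropies are reported in nats.

#' Per-residue Ramachandran entropy
#'
#' Information entropy H = -sum p ln p of the weighted 2D histogram of
#' (phi, psi) over [-pi, pi)^2 per residue, with `nBins` bins per axis
#' (100 x 100 cells by default; set `binsPerAxis = FALSE` to interpret
#' `nBins` as the total cell count, 10 x 10 for 100). Residues with
#' all-missing angles are skipped with a message.
#'
#' @param dihedrals a [FeatureSeries-class] with `phi_<r>`/`psi_<r>`
#'   columns (radians), e.g. from [backboneDihedrals()].
#' @param weights per-frame weights (normalized); `NULL` for uniform.
#' @param nBins bins per axis (default 100).
#' @param binsPerAxis interpret `nBins` per axis (default) or in total.
#' @return list with `perResidue` (named nats vector), `total` (their
#'   sum), `nBins`.
#' @export
ramachandranEntropy <- function(dihedrals, weights = NULL, nBins = 100L,
                                binsPerAxis = TRUE) {
  labs <- featureLabels(dihedrals)
  vals <- featureValues(dihedrals)
  if (!binsPerAxis) nBins <- max(1L, floor(sqrt(nBins)))
  residues <- sort(as.integer(sub("^phi_", "", grep("^phi_", labs, value = TRUE))))
  if (is.null(weights)) weights <- rep(1 / nrow(vals), nrow(vals))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  breaks <- seq(-pi, pi, length.out = nBins + 1L)
  H <- setNames(rep(NA_real_, length(residues)), paste0("res_", residues))
  for (i in seq_along(residues)) {
    r <- residues[i]
    phi <- vals[, match(paste0("phi_", r), labs)]
    psi <- vals[, match(paste0("psi_", r), labs)]
    ok <- is.finite(phi) & is.finite(psi)
    if (!any(ok)) {
      message("residue ", r, ": no defined phi/psi pair, skipped")
      next
    }
    bx <- findInterval(phi[ok], breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    by <- findInterval(psi[ok], breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    w <- weights[ok]
    w <- w / sum(w)
    cell <- (bx - 1L) * nBins + by
    p <- vapply(split(w, cell), sum, numeric(1))
    p <- p[p > 0]
    H[i] <- -sum(p * log(p))
  }
  keep <- !is.na(H)
  list(perResidue = H[keep], total = sum(H[keep]), nBins = nBins)
}

#' Population-weighted state-assignment entropy
#'
#' The weighted mean over frames of the information entropy of the soft
#' state assignment, sum_t w_t H(chi(x_t)) with
#' H(chi) = -sum_i chi_i ln chi_i. Zero for hard assignments, ln k for a
#' uniformly ambiguous assignment.
#'
#' @param chi a [StateAssignment-class].
#' @param weights per-frame weights (normalized); `NULL` for uniform.
#' @return scalar entropy (nats).
#' @export
stateEntropy <- function(chi, weights = NULL) {
  stopifnot(is(chi, "StateAssignment"))
  X <- featureValues(chi)
  if (is.null(weights)) weights <- rep(1 / nrow(X), nrow(X))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  Xl <- ifelse(X > 0, X * log(X), 0)
  sum(weights * (-rowSums(Xl)))
}

#' Circular autocorrelation of an angle series at a fixed lag
#'
#' Embeds each angle as the unit vector u = (cos theta, sin theta) and
#' computes
#' \deqn{\rho(\tau) = (\langle u_t u_{t+\tau}\rangle - |\langle u\rangle|^2)
#'   / (1 - |\langle u\rangle|^2),}
#' with lagged pairs restricted to single trajectories. A constant series
#' has rho = 1 by convention (flagged via a message). A plain linear
#' autocorrelation on the raw angle values is available with
#' `method = "linear"`.
#'
#' @param series a [FeatureSeries-class] of angles (radians), or a
#'   numeric vector/matrix (single trajectory).
#' @param lagNs lag time (ns), default 5.
#' @param method `"circular"` (default) or `"linear"`.
#' @return named numeric vector, one value per column.
#' @export
circularAutocorrelation <- function(series, lagNs = 5,
                                    method = c("circular", "linear")) {
  method <- match.arg(method)
  if (!is(series, "FrameSeries")) {
    series <- newFeatureSeries(as.matrix(series),
                               paste0("theta", seq_len(ncol(as.matrix(series)))),
                               rep(1L, nrow(as.matrix(series))), 250)
  }
  lag <- lagFrames(series, lagNs)
  pr <- lagPairs(trajIds(series), lag)
  if (length(pr$t0) < 1) stop("series shorter than the lag")
  vals <- featureValues(series)
  out <- setNames(numeric(ncol(vals)), featureLabels(series))
  for (j in seq_len(ncol(vals))) {
    th <- vals[, j]
    if (method == "linear") {
      x0 <- th[pr$t0]; x1 <- th[pr$t1]
      v <- stats::var(th)
      if (v < 1e-15) {
        message(featureLabels(series)[j], ": constant series, rho = 1")
        out[j] <- 1
        next
      }
      out[j] <- mean((x0 - mean(th)) * (x1 - mean(th))) / v
    } else {
      u <- cbind(cos(th), sin(th))
      mbar <- colMeans(u)
      m2 <- sum(mbar^2)
      if (m2 > 1 - 1e-12) {
        message(featureLabels(series)[j], ": constant angle, rho = 1")
        out[j] <- 1
        next
      }
      dot <- rowSums(u[pr$t0, , drop = FALSE] * u[pr$t1, , drop = FALSE])
      out[j] <- (mean(dot) - m2) / (1 - m2)
    }
  }
  out
}
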