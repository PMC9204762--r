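## Feed-forward soft state-assignment network trained on the VAMP-2
## objective: SELU hidden units with LeCun-normal initialization, inverted
## (alpha-style) dropout, softmax output, Adam updates with an analytic
## gradient of the VAMP-2 score through the batch covariances.

#' Trained soft state-assignment network
#'
#' Maps standardized input features through SELU hidden layers and a
#' softmax output to a k-state probability vector per frame.
#'
#' @slot weights list of weight matrices and bias vectors per layer.
#' @slot k number of output states.
#' @slot center,scale feature standardization applied before the network.
#' @slot hyper hyperparameter list used for training.
#' @slot metadata training provenance: seed, trial scores, collapse flag.
#' @exportClass SoftAssignmentModel
setClass("SoftAssignmentModel", representation(
  weights = "list", k = "integer", center = "numeric", scale = "numeric",
  hyper = "list", metadata = "list"
))

setMethod("show", "SoftAssignmentModel", function(object) {
  widths <- vapply(object@weights$W, ncol, integer(1))
  cat(sprintf("SoftAssignmentModel: %d features -> [%s] -> %d states\n",
              length(object@center),
              paste(widths[-length(widths)], collapse = ", "), object@k))
  if (!is.null(object@metadata$testScore)) {
    cat(sprintf("  VAMP-2 (test): %.4f\n", object@metadata$testScore))
  }
  if (isTRUE(object@metadata$collapsed)) {
    cat("  WARNING: degenerate state collapse detected\n")
  }
})

#' Hyperparameter presets for the assignment network
#'
#' `"desk"` is a small configuration for laptop-scale synthetic data;
#' `"paper"` is the published protocol scale: 2 x 512 SELU layers, L2
#' 1e-7, dropout 0.05, Adam with learning rate 0.05, beta2 0.99, epsilon
#' 1e-4, 10,000 frame pairs per batch, and early stopping on a minimum
#' validation-score improvement of 1e-3 over the last five epochs.
#'
#' @param preset `"desk"` or `"paper"`.
#' @return named list of hyperparameters.
#' @export
presetHyperparams <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  base <- list(
    lagNs = 5, depth = 2L, l2 = 1e-7, beta1 = 0.9, beta2 = 0.99,
    epsilon = 1e-4, batchPairs = 10000L, minImprove = 1e-3, patience = 5L,
    nTrials = 3L, covRidge = 1e-6, constrainedLrFactor = 0.02
  )
  if (preset == "desk") {
    c(base, list(width = 64L, dropout = 0, lr = 0.02, maxEpochs = 40L))
  } else {
    c(base, list(width = 512L, dropout = 0.05, lr = 0.05, maxEpochs = 100L))
  }
}

.seluLambda <- 1.0507009873554805
.seluAlpha <- 1.6732632423543772

selu <- function(x) {
  .seluLambda * ifelse(x > 0, x, .seluAlpha * (exp(x) - 1))
}

seluGrad <- function(x) {
  .seluLambda * ifelse(x > 0, 1, .seluAlpha * exp(x))
}

initNetwork <- function(d, width, depth, k) {
  sizes <- c(d, rep(width, depth), k)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

netForward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  a <- X
  cache <- list(A = vector("list", L), Z = vector("list", L),
                mask = vector("list", L))
  for (l in seq_len(L)) {
    cache$A[[l]] <- a
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    cache$Z[[l]] <- z
    if (l < L) {
      a <- selu(z)
      if (training && dropout > 0) {
        mask <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * mask / (1 - dropout)
        cache$mask[[l]] <- mask
      }
    } else {
      ## softmax with max-shift for stability
      z <- z - apply(z, 1, max)
      e <- exp(z)
      a <- e / rowSums(e)
    }
  }
  list(chi = a, cache = cache)
}

## gradient of the (ridge-regularized) VAMP-2 score w.r.t. chi0 and chi1
vamp2Grad <- function(chi0, chi1, ridge) {
  N <- nrow(chi0)
  k <- ncol(chi0)
  C00 <- crossprod(chi0) / N + ridge * diag(k)
  C11 <- crossprod(chi1) / N + ridge * diag(k)
  C01 <- crossprod(chi0, chi1) / N
  A <- solve(C00)
  Ci <- solve(C11)
  ABCi <- A %*% C01 %*% Ci
  score <- sum(diag(ABCi %*% t(C01)))
  dB <- 2 * ABCi
  dC00 <- -A %*% C01 %*% Ci %*% t(C01) %*% A
  dC11 <- -Ci %*% t(C01) %*% A %*% C01 %*% Ci
  G0 <- (chi1 %*% t(dB) + 2 * chi0 %*% dC00) / N
  G1 <- (chi0 %*% dB + 2 * chi1 %*% dC11) / N
  list(score = score, G0 = G0, G1 = G1)
}

netBackward <- function(net, fwd, Gchi, dropout) {
  L <- length(net$W)
  chi <- fwd$chi
  ## through softmax
  delta <- chi * (Gchi - rowSums(Gchi * chi))
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$cache$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      da <- delta %*% t(net$W[[l]])
      if (!is.null(fwd$cache$mask[[l - 1]])) {
        da <- da * fwd$cache$mask[[l - 1]] / (1 - dropout)
      }
      delta <- da * seluGrad(fwd$cache$Z[[l - 1]])
    }
  }
  list(W = gW, b = gb)
}

adamInit <- function(net) {
  zero <- function(x) lapply(x, function(v) v * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b),
       vb = zero(net$b), t = 0)
}

adamStep <- function(net, grad, state, hp) {
  state$t <- state$t + 1
  corr1 <- 1 - hp$beta1^state$t
  corr2 <- 1 - hp$beta2^state$t
  for (l in seq_along(net$W)) {
    gW <- grad$W[[l]] + hp$l2 * 2 * net$W[[l]]
    state$mW[[l]] <- hp$beta1 * state$mW[[l]] + (1 - hp$beta1) * gW
    state$vW[[l]] <- hp$beta2 * state$vW[[l]] + (1 - hp$beta2) * gW^2
    net$W[[l]] <- net$W[[l]] - hp$lr * (state$mW[[l]] / corr1) /
      (sqrt(state$vW[[l]] / corr2) + hp$epsilon)
    gb <- grad$b[[l]]
    state$mb[[l]] <- hp$beta1 * state$mb[[l]] + (1 - hp$beta1) * gb
    state$vb[[l]] <- hp$beta2 * state$vb[[l]] + (1 - hp$beta2) * gb^2
    net$b[[l]] <- net$b[[l]] - hp$lr * (state$mb[[l]] / corr1) /
      (sqrt(state$vb[[l]] / corr2) + hp$epsilon)
  }
  list(net = net, state = state)
}

trainOneTrial <- function(Xs, pr, trainPairIdx, valPairIdx, k, hp, seed) {
  withSeed(seed, {
    net <- initNetwork(ncol(Xs), hp$width, hp$depth, k)
    opt <- adamInit(net)
    evalScore <- function(idx) {
      chi0 <- netForward(net, Xs[pr$t0[idx], , drop = FALSE])$chi
      chi1 <- netForward(net, Xs[pr$t1[idx], , drop = FALSE])$chi
      vamp2Grad(chi0, chi1, hp$covRidge)$score
    }
    valHistory <- numeric(0)
    bestNet <- net
    bestVal <- -Inf
    for (epoch in seq_len(hp$maxEpochs)) {
      order <- sample(trainPairIdx)
      nb <- max(1L, ceiling(length(order) / hp$batchPairs))
      for (bi in seq_len(nb)) {
        idx <- order[seq.int((bi - 1) * hp$batchPairs + 1,
                             min(bi * hp$batchPairs, length(order)))]
        f0 <- netForward(net, Xs[pr$t0[idx], , drop = FALSE],
                         dropout = hp$dropout, training = TRUE)
        f1 <- netForward(net, Xs[pr$t1[idx], , drop = FALSE],
                         dropout = hp$dropout, training = TRUE)
        g <- vamp2Grad(f0$chi, f1$chi, hp$covRidge)
        ## maximize the score: descend on its negative
        g0 <- netBackward(net, f0, -g$G0, hp$dropout)
        g1 <- netBackward(net, f1, -g$G1, hp$dropout)
        grad <- list(
          W = Map(`+`, g0$W, g1$W),
          b = Map(`+`, g0$b, g1$b)
        )
        upd <- adamStep(net, grad, opt, hp)
        net <- upd$net
        opt <- upd$state
      }
      val <- evalScore(valPairIdx)
      valHistory <- c(valHistory, val)
      if (val > bestVal) {
        bestVal <- val
        bestNet <- net
      }
      if (length(valHistory) > hp$patience) {
        recent <- valHistory[(length(valHistory) - hp$patience):
                               length(valHistory)]
        if (max(recent) - recent[1] < hp$minImprove) break
      }
    }
    list(net = bestNet, valScore = bestVal, epochs = length(valHistory))
  })
}

#' Train a soft state-assignment model
#'
#' Trains a softmax-output SELU network to maximize the VAMP-2 score at
#' the configured lag on the training frames of one split; `nTrials`
#' independently initialized trials are run and the one with the best
#' VAMP-2 score on the held-out test frames is kept, with early stopping
#' on the validation score. A frame pair (t, t + lag) is attributed to the
#' partition of its first frame.
#'
#' @param features a [FeatureSeries-class] (use [expandCircular()] first
#'   for angle features) or numeric matrix.
#' @param k number of output states (default 2).
#' @param hyperparams list from [presetHyperparams()]; individual entries
#'   may be overridden.
#' @param split one element of a [SplitPlan-class]'s partitions plus the
#'   plan's test indices: a list with `train`, `validation`, `test` frame
#'   indices. `NULL` trains on a fresh 10/90 split of all frames.
#' @param seed RNG seed controlling initialization, dropout and batch
#'   order for all trials.
#' @return list with `model` ([SoftAssignmentModel-class]), `assignment`
#'   (the [StateAssignment-class] over all frames), `koopman`
#'   ([KoopmanModel-class] at the training lag), and `scores` per trial.
#' @export
trainAssignmentModel <- function(features, k = 2L, hyperparams = list(),
                                 split = NULL, seed = 1L) {
  hp <- utils::modifyList(presetHyperparams("desk"), hyperparams)
  X <- featureValues(features)
  if (any(!is.finite(X))) stop("features contain non-finite values")
  traj <- trajIds(features)
  lag <- lagFrames(features, hp$lagNs)
  pr <- lagPairs(traj, lag)
  if (length(pr$t0) < 10) stop("too few frame pairs at lag ", hp$lagNs, " ns")
  n <- nrow(X)
  if (is.null(split)) {
    plan <- makeSplits(n, nSplits = 1, seed = seed)
    split <- c(plan@splits[[1]], list(test = plan@test))
  }
  inTrain <- pr$t0 %in% split$train
  inVal <- pr$t0 %in% split$validation
  inTest <- pr$t0 %in% split$test
  center <- colMeans(X[split$train, , drop = FALSE])
  scale <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  trials <- lapply(seq_len(hp$nTrials), function(tr) {
    fit <- trainOneTrial(Xs, pr, which(inTrain), which(inVal), k, hp,
                         deriveSeed(seed, 31L * tr))
    chi0 <- netForward(fit$net, Xs[pr$t0[inTest], , drop = FALSE])$chi
    chi1 <- netForward(fit$net, Xs[pr$t1[inTest], , drop = FALSE])$chi
    fit$testScore <- vamp2Grad(chi0, chi1, hp$covRidge)$score
    fit
  })
  scores <- vapply(trials, `[[`, numeric(1), "testScore")
  best <- trials[[which.max(scores)]]

  chiAll <- netForward(best$net, Xs)$chi
  collapsed <- any(colSums(chiAll) < 0.005 * n)
  if (collapsed) {
    warning("degenerate state collapse: at least one state is almost empty")
  }
  model <- new("SoftAssignmentModel", weights = best$net, k = as.integer(k),
               center = center, scale = scale, hyper = hp,
               metadata = list(seed = seed, trialScores = scores,
                               testScore = max(scores),
                               epochs = best$epochs, collapsed = collapsed))
  assignment <- stateAssignment(chiAll, traj, frameInterval(features))
  koopman <- estimateKoopman(assignment, hp$lagNs)
  list(model = model, assignment = assignment, koopman = koopman,
       scores = scores)
}

#' Apply a trained assignment model to features
#'
#' @param model a [SoftAssignmentModel-class].
#' @param features a [FeatureSeries-class] with the training feature
#'   layout.
#' @return a [StateAssignment-class].
#' @export
assignStates <- function(model, features) {
  X <- featureValues(features)
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  chi <- netForward(model@weights, Xs)$chi
  stateAssignment(chi, trajIds(features), frameInterval(features))
}

#' Expand angle features into cosine/sine pairs
#'
#' Dihedral angles are circular; feeding them to the network as raw values
#' puts a discontinuity at +-pi. This helper replaces every angle column
#' (labels `phi_*`, `psi_*`, `chi1_*`) by its cosine and sine.
#'
#' @param features a [FeatureSeries-class].
#' @return a [FeatureSeries-class] with `cos_*`/`sin_*` columns.
#' @export
expandCircular <- function(features) {
  labs <- featureLabels(features)
  vals <- featureValues(features)
  ang <- angleColumn(labs)
  newVals <- cbind(vals[, !ang, drop = FALSE],
                   cos(vals[, ang, drop = FALSE]),
                   sin(vals[, ang, drop = FALSE]))
  newLabs <- c(labs[!ang], paste0("cos_", labs[ang]), paste0("sin_", labs[ang]))
  newFeatureSeries(newVals, newLabs, trajIds(features),
                   frameInterval(features))
}
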