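## Central S4 containers. All per-frame containers derive from the virtual
## FrameSeries class: a frames x p matrix, per-frame trajectory ids (so lagged
## frame pairs never cross trajectory boundaries), and the frame interval in ps.

#' Virtual parent for per-frame series containers
#'
#' @slot values frames x p numeric (or logical) matrix.
#' @slot labels length-p character vector of column labels.
#' @slot traj integer per-frame trajectory id, non-decreasing.
#' @slot frameInterval frame spacing in picoseconds.
#' @exportClass FrameSeries
setClass("FrameSeries", representation("VIRTUAL",
  values = "matrix",
  labels = "character",
  traj = "integer",
  frameInterval = "numeric"
))

validFrameSeries <- function(object) {
  msg <- character(0)
  if (ncol(object@values) != length(object@labels))
    msg <- c(msg, "ncol(values) must equal length(labels)")
  if (nrow(object@values) != length(object@traj))
    msg <- c(msg, "nrow(values) must equal length(traj)")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number (ps)")
  if (is.unsorted(object@traj))
    msg <- c(msg, "traj ids must be non-decreasing")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (length(msg)) msg else TRUE
}

#' General per-frame feature matrix (distances in nm, angles in radians)
#'
#' @exportClass FeatureSeries
setClass("FeatureSeries", contains = "FrameSeries", validity = function(object) {
  validFrameSeries(object)
})

#' Per-frame minimum-distance matrix (nm), one column per residue or ligand atom
#'
#' @slot level `"residue"` or `"atom"`: the contact entities in the columns.
#' @exportClass DistanceSeries
setClass("DistanceSeries", contains = "FrameSeries",
  representation(level = "character"),
  prototype(level = "residue"),
  validity = function(object) {
    msg <- validFrameSeries(object)
    msg <- if (isTRUE(msg)) character(0) else msg
    if (any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "distances must be non-negative")
    if (!object@level %in% c("residue", "atom"))
      msg <- c(msg, "level must be 'residue' or 'atom'")
    if (length(msg)) msg else TRUE
  })

#' Per-frame boolean on/off contact series
#'
#' @slot cutoff distance cutoff (nm) used to define the contacts, or `NA`
#'   when the series was generated directly (e.g. a telegraph process).
#' @exportClass ContactSeries
setClass("ContactSeries", contains = "FrameSeries",
  representation(cutoff = "numeric"),
  prototype(cutoff = NA_real_),
  validity = function(object) {
    msg <- validFrameSeries(object)
    msg <- if (isTRUE(msg)) character(0) else msg
    if (!is.logical(object@values))
      msg <- c(msg, "contact values must be logical")
    if (length(msg)) msg else TRUE
  })

#' Soft per-frame state assignment
#'
#' Rows are probability vectors over k metastable states.
#'
#' @slot values frames x k matrix of state probabilities.
#' @exportClass StateAssignment
setClass("StateAssignment", contains = "FrameSeries", validity = function(object) {
  msg <- validFrameSeries(object)
  msg <- if (isTRUE(msg)) character(0) else msg
  if (any(object@values < -1e-9))
    msg <- c(msg, "state probabilities must be non-negative")
  if (nrow(object@values) > 0 &&
      max(abs(rowSums(object@values) - 1)) > 1e-6)
    msg <- c(msg, "state probability rows must sum to 1 (tol 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Koopman (soft transition) model at a fixed lag time
#'
#' @slot K k x k row-stochastic operator at lag `tau`.
#' @slot pi length-k equilibrium distribution (sums to 1, satisfies pi K = pi).
#' @slot tau lag time in nanoseconds.
#' @slot metadata list of provenance (seed, split, scores, flags).
#' @exportClass KoopmanModel
setClass("KoopmanModel", representation(
  K = "matrix", pi = "numeric", tau = "numeric", metadata = "list"
), prototype(metadata = list()), validity = function(object) {
  msg <- character(0)
  K <- object@K
  if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
  if (any(K < -1e-10)) msg <- c(msg, "K entries must be non-negative")
  if (any(abs(rowSums(K) - 1) > 1e-8)) msg <- c(msg, "K rows must sum to 1 (tol 1e-8)")
  if (length(object@pi) != nrow(K)) msg <- c(msg, "pi length must match K")
  if (abs(sum(object@pi) - 1) > 1e-6) msg <- c(msg, "pi must sum to 1")
  if (max(abs(drop(object@pi %*% K) - object@pi)) > 1e-6)
    msg <- c(msg, "pi must be stationary under K (tol 1e-6)")
  if (length(object@tau) != 1 || object@tau <= 0)
    msg <- c(msg, "tau must be a single positive lag time (ns)")
  if (length(msg)) msg else TRUE
})

#' Train/validation/test split plan
#'
#' A held-out test fraction plus repeated train/validation partitions of
#' the remaining frames.
#'
#' @exportClass SplitPlan
setClass("SplitPlan", representation(
  test = "integer", splits = "list", nFrames = "integer", seed = "integer"
), validity = function(object) {
  msg <- character(0)
  rest <- setdiff(seq_len(object@nFrames), object@test)
  for (i in seq_along(object@splits)) {
    s <- object@splits[[i]]
    if (!setequal(c(s$train, s$validation), rest) ||
        length(intersect(s$train, s$validation)) > 0) {
      msg <- c(msg, sprintf("split %d does not partition the non-test frames", i))
      break
    }
  }
  if (length(intersect(object@test, unlist(lapply(object@splits, `[[`, "train")))) > 0)
    msg <- c(msg, "test frames leak into training")
  if (length(msg)) msg else TRUE
})

#' Chapman-Kolmogorov test report
#'
#' @slot tau base lag (ns); @slot n integer lag multiples tested.
#' @slot predicted list of K(tau)^n; @slot estimated list of K(n tau).
#' @slot maxDeviation per-n max-norm deviation; @slot perEntry list of
#'   per-entry absolute deviation matrices.
#' @slot band list (per n) of lower/upper bootstrap band matrices.
#' @slot pass logical per n: predicted within the bootstrap band.
#' @exportClass CKReport
setClass("CKReport", representation(
  tau = "numeric", n = "integer", predicted = "list", estimated = "list",
  maxDeviation = "numeric", perEntry = "list", band = "list", pass = "logical"
), validity = function(object) {
  msg <- character(0)
  for (M in c(object@predicted, object@estimated)) {
    if (any(abs(rowSums(M) - 1) > 1e-8)) {
      msg <- c(msg, "predicted/estimated matrices must be row-stochastic (tol 1e-8)")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Mean and percentile interval of an observable over trained models
#'
#' @exportClass ModelEnsembleStat
setClass("ModelEnsembleStat", representation(
  mean = "numeric", lower = "numeric", upper = "numeric",
  nModels = "integer", mode = "character"
), validity = function(object) {
  if (any(object@lower > object@mean + 1e-12) ||
      any(object@upper < object@mean - 1e-12)) {
    "interval must contain the mean"
  } else TRUE
})

#' Trajectory ensemble: topology plus per-trajectory coordinates
#'
#' Coordinates follow the bio3d layout (one matrix per trajectory, rows =
#' frames, columns = x1,y1,z1,x2,...), in nanometres.
#'
#' @slot topology data.frame with columns `eleno`, `elety`, `resid`,
#'   `resno`, `element`, `segment` (`"PEP"` or `"LIG"`).
#' @slot coords list of frames x (3 * n_atoms) matrices (nm).
#' @slot frameInterval frame spacing (ps).
#' @slot box per-trajectory orthorhombic box lengths (nm) or NULL.
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble", representation(
  topology = "data.frame", coords = "list", frameInterval = "numeric",
  box = "ANY"
), prototype(box = NULL), validity = function(object) {
  msg <- character(0)
  need <- c("eleno", "elety", "resid", "resno", "element", "segment")
  if (!all(need %in% names(object@topology)))
    msg <- c(msg, paste("topology must have columns:", paste(need, collapse = ", ")))
  natom <- nrow(object@topology)
  for (x in object@coords) {
    if (ncol(x) != 3 * natom) {
      msg <- c(msg, "each coordinate matrix must have 3 * n_atoms columns")
      break
    }
  }
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive (ps)")
  if (length(msg)) msg else TRUE
})

#' Ground-truth generator specification
#'
#' Defines a discrete-time global state process at frame spacing `dt`,
#' state-dependent circular dihedral emissions, side-chain rotamer hopping,
#' and ligand-contact telegraph processes.
#'
#' @slot transitionMatrix k x k row-stochastic matrix at time step `dt`.
#' @slot dt frame spacing (ps).
#' @slot phiMu,phiKappa,psiMu,psiKappa k x n_residues matrices of von Mises
#'   mean (radians) and concentration per state and residue.
#' @slot chi1Rotamers rotamer centres (radians), shared across residues.
#' @slot chi1HopRate k x n_residues matrix of rotamer hopping rates (1/ns).
#' @slot contactRates data.frame with columns `label`, `kOn`, `kOff` (1/ns);
#'   optional `kOnByState`/`kOffByState` matrices condition rates on the
#'   global state.
#' @exportClass GroundTruthSpec
setClass("GroundTruthSpec", representation(
  nStates = "integer", transitionMatrix = "matrix", dt = "numeric",
  nTrajectories = "integer", nFrames = "integer", nResidues = "integer",
  phiMu = "matrix", phiKappa = "matrix", psiMu = "matrix", psiKappa = "matrix",
  chi1Rotamers = "numeric", chi1HopRate = "matrix",
  contactRates = "data.frame",
  kOnByState = "ANY", kOffByState = "ANY",
  seed = "integer"
), prototype(kOnByState = NULL, kOffByState = NULL),
validity = function(object) {
  msg <- character(0)
  k <- object@nStates
  P <- object@transitionMatrix
  if (nrow(P) != k || ncol(P) != k)
    msg <- c(msg, "transitionMatrix must be nStates x nStates")
  if (any(P < 0)) msg <- c(msg, "transitionMatrix entries must be >= 0")
  if (nrow(P) == k && any(abs(rowSums(P) - 1) > 1e-12))
    msg <- c(msg, "transitionMatrix rows must sum to 1 (tol 1e-12)")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive (ps)")
  if (object@nTrajectories < 1 || object@nFrames < 2)
    msg <- c(msg, "need at least 1 trajectory of at least 2 frames")
  for (nm in c("phiMu", "phiKappa", "psiMu", "psiKappa", "chi1HopRate")) {
    M <- slot(object, nm)
    if (nrow(M) != k || ncol(M) != object@nResidues)
      msg <- c(msg, sprintf("%s must be nStates x nResidues", nm))
  }
  if (any(object@phiKappa < 0) || any(object@psiKappa < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (any(object@chi1HopRate < 0)) msg <- c(msg, "hop rates must be >= 0")
  if (nrow(object@contactRates) > 0) {
    if (!all(c("label", "kOn", "kOff") %in% names(object@contactRates)))
      msg <- c(msg, "contactRates needs columns label, kOn, kOff")
    else if (any(object@contactRates$kOn < 0) || any(object@contactRates$kOff < 0))
      msg <- c(msg, "contact rates must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Analytic ground truth of a generated benchmark ensemble
#'
#' @slot statePaths list of per-trajectory true state index vectors (1-based).
#' @slot trueTimescales relaxation timescales (ns) from the spec matrix
#'   eigenvalues.
#' @slot trueLifetimes per-state mean dwell times (ns) from the diagonal.
#' @slot truePopulations stationary distribution of the spec matrix.
#' @slot trueContactLifetimes mean contact on-times 1/kOff (ns).
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  statePaths = "list", trueTimescales = "numeric", trueLifetimes = "numeric",
  truePopulations = "numeric", trueContactLifetimes = "numeric"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("%s: %d frames x %d columns, %d trajectories, dt = %g ps\n",
              class(object), nrow(object@values), ncol(object@values),
              length(unique(object@traj)), object@frameInterval))
  if (length(object@labels) > 0) {
    shown <- utils::head(object@labels, 5)
    cat("  columns:", paste(shown, collapse = ", "),
        if (length(object@labels) > 5) "..." else "", "\n")
  }
})

setMethod("show", "KoopmanModel", function(object) {
  cat(sprintf("KoopmanModel: %d states, tau = %g ns\n", nrow(object@K), object@tau))
  cat("  pi:", paste(signif(object@pi, 4), collapse = ", "), "\n")
  cat("  diag(K):", paste(signif(diag(object@K), 4), collapse = ", "), "\n")
})

setMethod("show", "CKReport", function(object) {
  cat(sprintf("Chapman-Kolmogorov report at tau = %g ns\n", object@tau))
  for (i in seq_along(object@n)) {
    cat(sprintf("  n = %d: max |K(tau)^n - K(n tau)| = %.4g  [%s]\n",
                object@n[i], object@maxDeviation[i],
                if (object@pass[i]) "within band" else "outside band"))
  }
})

setMethod("show", "ModelEnsembleStat", function(object) {
  cat(sprintf("ModelEnsembleStat over %d models (%s):\n", object@nModels, object@mode))
  print(data.frame(mean = object@mean, lower = object@lower, upper = object@upper))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  nf <- vapply(object@coords, nrow, integer(1))
  cat(sprintf("TrajectoryEnsemble: %d trajectories, %s frames each, %d atoms, dt = %g ps\n",
              length(object@coords),
              if (length(unique(nf)) == 1) as.character(nf[1]) else
                paste0(min(nf), "-", max(nf)),
              nrow(object@topology), object@frameInterval))
})

setMethod("show", "GroundTruthSpec", function(object) {
  cat(sprintf(
    "GroundTruthSpec: %d states, %d trajectories x %d frames, dt = %g ps, %d residues, %d contacts, seed = %d\n",
    object@nStates, object@nTrajectories, object@nFrames, object@dt,
    object@nResidues, nrow(object@contactRates), object@seed))
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("trajIds", function(x) standardGeneric("trajIds"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("koopmanMatrix", function(x) standardGeneric("koopmanMatrix"))
#' @rdname accessors
#' @export
setGeneric("equilibriumDistribution", function(x) standardGeneric("equilibriumDistribution"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(x) standardGeneric("lagTime"))

#' Accessors for softmsm containers
#'
#' `featureValues` returns the frames x p matrix, `featureLabels` the column
#' labels, `trajIds` the per-frame trajectory ids, `frameInterval` the frame
#' spacing (ps), `nStates` the number of states, `koopmanMatrix` /
#' `equilibriumDistribution` / `lagTime` the Koopman model components.
#'
#' @param x a softmsm S4 object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("featureValues", "FrameSeries", function(x) x@values)
#' @rdname accessors
setMethod("featureLabels", "FrameSeries", function(x) x@labels)
#' @rdname accessors
setMethod("trajIds", "FrameSeries", function(x) x@traj)
#' @rdname accessors
setMethod("frameInterval", "FrameSeries", function(x) x@frameInterval)
#' @rdname accessors
setMethod("nStates", "StateAssignment", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nStates", "KoopmanModel", function(x) nrow(x@K))
#' @rdname accessors
setMethod("koopmanMatrix", "KoopmanModel", function(x) x@K)
#' @rdname accessors
setMethod("equilibriumDistribution", "KoopmanModel", function(x) x@pi)
#' @rdname accessors
setMethod("lagTime", "KoopmanModel", function(x) x@tau)

## internal constructors used throughout
newFeatureSeries <- function(values, labels, traj, frameInterval,
                             class = "FeatureSeries", ...) {
  colnames(values) <- as.character(labels)
  new(class, values = values, labels = as.character(labels),
      traj = as.integer(traj), frameInterval = frameInterval, ...)
}

#' Construct a StateAssignment
#'
#' @param chi frames x k matrix of state probabilities (rows sum to 1).
#' @param traj per-frame trajectory id.
#' @param frameInterval frame spacing (ps).
#' @return a [StateAssignment-class] object.
#' @export
stateAssignment <- function(chi, traj = rep(1L, nrow(chi)), frameInterval = 250) {
  chi <- as.matrix(chi)
  labs <- colnames(chi)
  if (is.null(labs)) labs <- paste0("state", seq_len(ncol(chi)))
  newFeatureSeries(chi, labs, traj, frameInterval, class = "StateAssignment")
}

#' Construct a ContactSeries
#'
#' @param on frames x contacts logical matrix.
#' @param labels contact labels.
#' @param traj per-frame trajectory id.
#' @param frameInterval frame spacing (ps).
#' @param cutoff cutoff (nm) used, or NA.
#' @return a [ContactSeries-class] object.
#' @export
contactSeries <- function(on, labels = colnames(on),
                          traj = rep(1L, nrow(on)),
                          frameInterval = 250, cutoff = NA_real_) {
  on <- as.matrix(on)
  storage.mode(on) <- "logical"
  if (is.null(labels)) labels <- paste0("contact", seq_len(ncol(on)))
  newFeatureSeries(on, labels, traj, frameInterval,
                   class = "ContactSeries", cutoff = cutoff)
}
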