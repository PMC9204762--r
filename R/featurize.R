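## Featurization of trajectory ensembles: nearest-neighbour inter-residue
## heavy-atom distances (the soft-MSM network input), backbone and chi1
## dihedrals, ligand minimum distances, and aromatic ring-stacking
## indicators. All distances in nm, all angles in radians.

## concatenated coordinate matrix (frames x 3N) + per-frame trajectory ids
flatCoords <- function(ensemble) {
  list(xyz = do.call(rbind, ensemble@coords),
       traj = rep.int(seq_along(ensemble@coords),
                      vapply(ensemble@coords, nrow, integer(1))))
}

atomXYZ <- function(xyz, atom) {
  xyz[, c(3 * atom - 2, 3 * atom - 1, 3 * atom), drop = FALSE]
}

## per-frame distance between two atoms; minimum-image for orthorhombic
## boxes when box lengths are supplied
atomPairDist2 <- function(xyz, a, b, box = NULL) {
  d2 <- 0
  for (dim in 1:3) {
    dx <- xyz[, 3 * a - 3 + dim] - xyz[, 3 * b - 3 + dim]
    if (!is.null(box)) dx <- dx - box[dim] * round(dx / box[dim])
    d2 <- d2 + dx * dx
  }
  d2
}

## minimum distance between two atom groups, per frame
groupMinDist <- function(xyz, atomsA, atomsB, box = NULL) {
  best <- rep(Inf, nrow(xyz))
  for (a in atomsA) {
    for (b in atomsB) {
      best <- pmin(best, atomPairDist2(xyz, a, b, box))
    }
  }
  sqrt(best)
}

heavyAtoms <- function(top) which(top$element != "H")

peptideResidues <- function(top) {
  sort(unique(top$resno[top$segment == "PEP"]))
}

#' Nearest-neighbour inter-residue heavy-atom distance features
#'
#' One feature per unordered residue pair (i, j) with j - i >=
#' `minSeqSep`; the value is the minimum over all heavy-atom pairs of the
#' Euclidean (minimum-image, if a box is present) distance. Pairs are
#' ordered row-major: (1,1+s), (1,2+s), ..., (2,2+s), ... For a chain of n
#' residues this yields (n-s)(n-s+1)/2 features; 780 for n = 42, s = 3.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param minSeqSep minimum sequence separation between paired residues
#'   (default 3).
#' @return a [FeatureSeries-class] with labels `d_<i>_<j>`.
#' @export
nnDistanceFeatures <- function(ensemble, minSeqSep = 3L) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"), minSeqSep >= 1)
  top <- ensemble@topology
  res <- peptideResidues(top)
  n <- length(res)
  heavy <- heavyAtoms(top)
  resAtoms <- lapply(res, function(r) {
    intersect(which(top$resno == r & top$segment == "PEP"), heavy)
  })
  if (any(lengths(resAtoms) == 0)) {
    stop("residue(s) with no heavy atoms in selection: ",
         paste(res[lengths(resAtoms) == 0], collapse = ", "))
  }
  pairs <- nnPairIndex(n, minSeqSep)
  fc <- flatCoords(ensemble)
  if (nrow(pairs) == 0) {
    warning("fewer than minSeqSep + 1 residues: no distance features")
    return(newFeatureSeries(matrix(0, nrow(fc$xyz), 0), character(0),
                            fc$traj, ensemble@frameInterval))
  }
  vals <- matrix(NA_real_, nrow(fc$xyz), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    vals[, p] <- groupMinDist(fc$xyz, resAtoms[[pairs[p, 1]]],
                              resAtoms[[pairs[p, 2]]])
  }
  labs <- sprintf("d_%d_%d", res[pairs[, 1]], res[pairs[, 2]])
  newFeatureSeries(vals, labs, fc$traj, ensemble@frameInterval)
}

#' Residue-pair index of the nearest-neighbour distance featurizer
#'
#' @param n number of residues.
#' @param minSeqSep minimum sequence separation.
#' @return two-column integer matrix of (i, j) residue positions, row-major.
#' @export
nnPairIndex <- function(n, minSeqSep = 3L) {
  out <- matrix(0L, 0, 2)
  if (n > minSeqSep) {
    ii <- unlist(lapply(seq_len(n - minSeqSep),
                        function(i) rep.int(i, n - i - minSeqSep + 1L)))
    jj <- unlist(lapply(seq_len(n - minSeqSep),
                        function(i) seq.int(i + minSeqSep, n)))
    out <- cbind(as.integer(ii), as.integer(jj))
  }
  out
}

## vectorized torsion over frames: P* are frames x 3 matrices
vTorsion <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  vcross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- vcross(n1, b2n)
  wrapAngle(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

findAtom <- function(top, resno, elety) {
  which(top$resno == resno & top$elety == elety & top$segment == "PEP")[1]
}

#' Backbone phi/psi dihedral angles
#'
#' IUPAC convention: phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1). The first
#' residue's phi and the last residue's psi are undefined and reported as
#' `NA`. Residues with missing backbone atoms get `NA` with a message.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @return a [FeatureSeries-class] with columns `phi_<r>`, `psi_<r>`
#'   (radians).
#' @export
backboneDihedrals <- function(ensemble) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  top <- ensemble@topology
  res <- peptideResidues(ensemble@topology)
  n <- length(res)
  fc <- flatCoords(ensemble)
  xyz <- fc$xyz
  nF <- nrow(xyz)
  phi <- matrix(NA_real_, nF, n)
  psi <- matrix(NA_real_, nF, n)
  N <- vapply(res, findAtom, integer(1), top = top, elety = "N")
  CA <- vapply(res, findAtom, integer(1), top = top, elety = "CA")
  C <- vapply(res, findAtom, integer(1), top = top, elety = "C")
  for (i in seq_len(n)) {
    if (anyNA(c(N[i], CA[i], C[i]))) {
      message("residue ", res[i], ": missing backbone atom, dihedrals set NA")
      next
    }
    if (i > 1 && !is.na(C[i - 1])) {
      phi[, i] <- vTorsion(atomXYZ(xyz, C[i - 1]), atomXYZ(xyz, N[i]),
                           atomXYZ(xyz, CA[i]), atomXYZ(xyz, C[i]))
    }
    if (i < n && !is.na(N[i + 1])) {
      psi[, i] <- vTorsion(atomXYZ(xyz, N[i]), atomXYZ(xyz, CA[i]),
                           atomXYZ(xyz, C[i]), atomXYZ(xyz, N[i + 1]))
    }
  }
  labs <- c(paste0("phi_", seq_len(n)), paste0("psi_", seq_len(n)))
  newFeatureSeries(cbind(phi, psi), labs, fc$traj, ensemble@frameInterval)
}

#' Side-chain chi1 dihedral angles
#'
#' chi1 = N-CA-CB-CG for every residue that defines one (Gly and Ala do
#' not). Residues with missing side-chain atoms are skipped with a message;
#' if no residue has a chi1 the result has zero columns, with a warning.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @return a [FeatureSeries-class] with columns `chi1_<r>` (radians).
#' @export
chi1Dihedrals <- function(ensemble) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  top <- ensemble@topology
  res <- peptideResidues(top)
  fc <- flatCoords(ensemble)
  cols <- list()
  labs <- character(0)
  for (i in seq_along(res)) {
    r <- res[i]
    resName <- top$resid[top$resno == r & top$segment == "PEP"][1]
    if (resName %in% .noChi1) next
    at <- c(findAtom(top, r, "N"), findAtom(top, r, "CA"),
            findAtom(top, r, "CB"), findAtom(top, r, "CG"))
    if (anyNA(at)) {
      message("residue ", r, " (", resName,
              "): missing side-chain atoms, chi1 skipped")
      next
    }
    cols[[length(cols) + 1L]] <-
      vTorsion(atomXYZ(fc$xyz, at[1]), atomXYZ(fc$xyz, at[2]),
               atomXYZ(fc$xyz, at[3]), atomXYZ(fc$xyz, at[4]))
    labs <- c(labs, paste0("chi1_", i))
  }
  if (length(cols) == 0) {
    warning("no residue with a defined chi1 dihedral")
    return(newFeatureSeries(matrix(0, nrow(fc$xyz), 0), character(0),
                            fc$traj, ensemble@frameInterval))
  }
  newFeatureSeries(do.call(cbind, cols), labs, fc$traj,
                   ensemble@frameInterval)
}

#' Ligand-peptide minimum distances
#'
#' At `level = "residue"`, the per-frame minimum heavy-atom distance
#' between the ligand and each peptide residue; at `level = "atom"`, per
#' ligand atom the minimum distance to any peptide heavy atom. Uses the
#' minimum-image convention when the ensemble carries box vectors.
#'
#' @param ensemble a [TrajectoryEnsemble-class] containing ligand atoms
#'   (segment `"LIG"`).
#' @param level `"residue"` or `"atom"`.
#' @return a [DistanceSeries-class] (nm).
#' @export
ligandMinDistances <- function(ensemble, level = c("residue", "atom")) {
  level <- match.arg(level)
  top <- ensemble@topology
  lig <- intersect(which(top$segment == "LIG"), heavyAtoms(top))
  if (length(lig) == 0) stop("empty ligand selection (segment 'LIG')")
  fc <- flatCoords(ensemble)
  box <- NULL
  if (!is.null(ensemble@box)) box <- ensemble@box
  if (level == "residue") {
    res <- peptideResidues(top)
    vals <- matrix(NA_real_, nrow(fc$xyz), length(res))
    for (i in seq_along(res)) {
      ra <- intersect(which(top$resno == res[i] & top$segment == "PEP"),
                      heavyAtoms(top))
      vals[, i] <- groupMinDist(fc$xyz, lig, ra, box)
    }
    labs <- paste0("res_", res)
  } else {
    pep <- intersect(which(top$segment == "PEP"), heavyAtoms(top))
    vals <- matrix(NA_real_, nrow(fc$xyz), length(lig))
    for (i in seq_along(lig)) {
      vals[, i] <- groupMinDist(fc$xyz, lig[i], pep, box)
    }
    labs <- paste0("atom_", top$elety[lig])
  }
  newFeatureSeries(vals, labs, fc$traj, ensemble@frameInterval,
                   class = "DistanceSeries", level = level)
}

ringCentroid <- function(xyz, atoms) {
  out <- matrix(0, nrow(xyz), 3)
  for (a in atoms) out <- out + atomXYZ(xyz, a)
  out / length(atoms)
}

ringNormal <- function(xyz, atoms) {
  c1 <- ringCentroid(xyz, atoms)
  v1 <- atomXYZ(xyz, atoms[1]) - c1
  v2 <- atomXYZ(xyz, atoms[3]) - c1
  n <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
             v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
             v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Detect aromatic ring-stacking contacts
#'
#' A (ligand-ring, residue-ring) pair is "stacked" in a frame when the
#' ring-centroid distance is at most `centroidCutoff` (default 0.55 nm).
#' An optional planarity filter additionally requires the angle between
#' ring normals to be at most `maxPlaneAngle` degrees; it is off by
#' default because a distance-only criterion is the minimal reproducible
#' choice.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param ligandRings named list of atom-index vectors (>= 5 atoms each).
#' @param residueRings named list of atom-index vectors (>= 5 atoms each).
#' @param centroidCutoff centroid distance cutoff (nm).
#' @param planarityFilter apply the normal-angle filter.
#' @param maxPlaneAngle maximum angle between ring planes (degrees).
#' @return a [ContactSeries-class], one column per ring pair.
#' @export
detectPiStacks <- function(ensemble, ligandRings, residueRings,
                           centroidCutoff = 0.55, planarityFilter = FALSE,
                           maxPlaneAngle = 45) {
  allRings <- c(ligandRings, residueRings)
  if (any(lengths(allRings) < 5)) {
    stop("aromatic rings need at least 5 atoms: ",
         paste(names(allRings)[lengths(allRings) < 5], collapse = ", "))
  }
  fc <- flatCoords(ensemble)
  cl <- lapply(ligandRings, ringCentroid, xyz = fc$xyz)
  cr <- lapply(residueRings, ringCentroid, xyz = fc$xyz)
  on <- matrix(FALSE, nrow(fc$xyz),
               length(ligandRings) * length(residueRings))
  labs <- character(ncol(on))
  p <- 0L
  for (i in seq_along(ligandRings)) {
    for (j in seq_along(residueRings)) {
      p <- p + 1L
      d <- sqrt(rowSums((cl[[i]] - cr[[j]])^2))
      hit <- d <= centroidCutoff
      if (planarityFilter) {
        nl <- ringNormal(fc$xyz, ligandRings[[i]])
        nr <- ringNormal(fc$xyz, residueRings[[j]])
        ang <- acos(pmin(1, abs(rowSums(nl * nr)))) * 180 / pi
        hit <- hit & (ang <= maxPlaneAngle)
      }
      on[, p] <- hit
      labs[p] <- paste0(names(ligandRings)[i], ":", names(residueRings)[j])
    }
  }
  contactSeries(on, labels = labs, traj = fc$traj,
                frameInterval = ensemble@frameInterval,
                cutoff = centroidCutoff)
}

#' Threshold a distance series into contacts
#'
#' @param distances a [DistanceSeries-class].
#' @param cutoff contact cutoff (nm), default 0.45.
#' @return a [ContactSeries-class].
#' @export
distancesToContacts <- function(distances, cutoff = 0.45) {
  stopifnot(is(distances, "DistanceSeries"))
  contactSeries(featureValues(distances) <= cutoff,
                labels = featureLabels(distances),
                traj = trajIds(distances),
                frameInterval = frameInterval(distances), cutoff = cutoff)
}
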