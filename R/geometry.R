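## Internal-coordinate chain construction and dihedral measurement.
## All lengths in nm, all angles in radians.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Place atom D given reference atoms A, B, C, the bond length |C-D|, the
## bond angle B-C-D and the torsion A-B-C-D (NeRF construction).
nerfPlace <- function(A, B, C, bond, angle, dihedral) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         -bond * sin(angle) * sin(dihedral))
  C + d[1] * bc + d[2] * m + d[3] * n
}

## Signed torsion angle of four points, IUPAC convention, in [-pi, pi).
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  wrapAngle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

## Ideal backbone geometry (nm / radians), CHARMM-like values.
.geom <- list(
  b_N_CA  = 0.1458, b_CA_C = 0.1525, b_C_N = 0.1329,
  b_CA_CB = 0.1530, b_CB_CG = 0.1520,
  a_N_CA_C = 111.2 * pi / 180, a_CA_C_N = 116.2 * pi / 180,
  a_C_N_CA = 121.7 * pi / 180,
  a_N_CA_CB = 110.5 * pi / 180, a_CA_CB_CG = 114.0 * pi / 180,
  d_CB = 122.5 * pi / 180,   # torsion C-N-CA-CB fixing the CB branch
  omega = pi
)

## residues with no chi1 torsion
.noChi1 <- c("GLY", "ALA")

## Atom layout for one residue of the synthetic peptide model:
## backbone N, CA, C for all residues; CB unless Gly; a pseudo gamma atom
## CG (placed by chi1) unless Gly/Ala.
residueAtomNames <- function(resid) {
  if (resid == "GLY") return(c("N", "CA", "C"))
  if (resid == "ALA") return(c("N", "CA", "C", "CB"))
  c("N", "CA", "C", "CB", "CG")
}

#' Build 3D peptide coordinates from backbone and side-chain dihedrals
#'
#' Constructs an ideal-geometry polypeptide (N, CA, C backbone plus a CB
#' atom and a pseudo gamma atom per residue) frame by frame with the NeRF
#' internal-coordinate algorithm: phi and psi set the backbone torsions
#' (omega fixed trans) and chi1 places the gamma atom. The first residue's
#' phi and the last residue's psi are undefined and ignored.
#'
#' @param dihedrals a [FeatureSeries-class] with columns named
#'   `phi_<i>`, `psi_<i>` and optionally `chi1_<i>` (radians, residue index
#'   i = 1..n), e.g. from [emitDihedralSeries()].
#' @param sequence character vector of 3-letter residue codes; default all
#'   `"LEU"` (chi1-capable). `"GLY"`/`"ALA"` get no gamma atom.
#' @param ligand optional function `frame_index -> 3-column matrix` of
#'   ligand atom positions (nm), used to script a rigid ligand; `NULL` for
#'   apo ensembles.
#' @param ligandAtoms number of ligand atoms when `ligand` is given.
#' @return a [TrajectoryEnsemble-class].
#' @export
buildPeptideCoordinates <- function(dihedrals, sequence = NULL,
                                    ligand = NULL, ligandAtoms = 0L) {
  stopifnot(is(dihedrals, "FrameSeries"))
  labs <- featureLabels(dihedrals)
  phiIdx <- grep("^phi_", labs)
  nres <- length(phiIdx)
  if (nres < 3) stop("need at least 3 residues to define backbone dihedrals")
  if (is.null(sequence)) sequence <- rep("LEU", nres)
  stopifnot(length(sequence) == nres)
  vals <- featureValues(dihedrals)
  colOf <- function(prefix, i) match(paste0(prefix, "_", i), labs)

  perRes <- lapply(sequence, residueAtomNames)
  natomPep <- sum(lengths(perRes))
  topology <- data.frame(
    eleno = seq_len(natomPep + ligandAtoms),
    elety = c(unlist(perRes), if (ligandAtoms > 0) paste0("L", seq_len(ligandAtoms))),
    resid = c(rep(sequence, lengths(perRes)), rep("LIG", ligandAtoms)),
    resno = c(rep(seq_len(nres), lengths(perRes)),
              rep(nres + 1L, ligandAtoms)),
    element = "C",
    segment = c(rep("PEP", natomPep), rep("LIG", ligandAtoms)),
    stringsAsFactors = FALSE
  )
  topology$element[topology$elety == "N"] <- "N"

  g <- .geom
  trajSplit <- split(seq_along(trajIds(dihedrals)), trajIds(dihedrals))
  coords <- lapply(trajSplit, function(frames) {
    xyz <- matrix(NA_real_, nrow = length(frames),
                  ncol = 3 * (natomPep + ligandAtoms))
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      pos <- matrix(NA_real_, nrow = natomPep, ncol = 3)
      a <- 0L
      Nprev <- CAprev <- Cprev <- NULL
      psiPrev <- NA_real_
      for (i in seq_len(nres)) {
        getv <- function(prefix) {
          j <- colOf(prefix, i)
          if (is.na(j)) NA_real_ else vals[f, j]
        }
        phi <- getv("phi"); psi <- getv("psi"); chi1 <- getv("chi1")
        if (i == 1L) {
          Ni <- c(0, 0, 0)
          CAi <- c(g$b_N_CA, 0, 0)
          Ci <- CAi + g$b_CA_C * c(-cos(g$a_N_CA_C), sin(g$a_N_CA_C), 0)
        } else {
          ## torsions: psi(i-1) = N-CA-C-N', omega = CA-C-N'-CA',
          ## phi(i) = C-N'-CA'-C'
          Ni <- nerfPlace(Nprev, CAprev, Cprev, g$b_C_N, g$a_CA_C_N,
                          if (is.na(psiPrev)) 0 else psiPrev)
          CAi <- nerfPlace(CAprev, Cprev, Ni, g$b_N_CA, g$a_C_N_CA, g$omega)
          Ci <- nerfPlace(Cprev, Ni, CAi, g$b_CA_C, g$a_N_CA_C,
                          if (is.na(phi)) -pi / 2 else phi)
        }
        atoms <- perRes[[i]]
        pos[a + 1L, ] <- Ni
        pos[a + 2L, ] <- CAi
        pos[a + 3L, ] <- Ci
        if ("CB" %in% atoms) {
          CBi <- nerfPlace(Ci, Ni, CAi, g$b_CA_CB, g$a_N_CA_CB, g$d_CB)
          pos[a + 4L, ] <- CBi
          if ("CG" %in% atoms) {
            pos[a + 5L, ] <- nerfPlace(Ni, CAi, CBi, g$b_CB_CG, g$a_CA_CB_CG,
                                       if (is.na(chi1)) pi else chi1)
          }
        }
        a <- a + length(atoms)
        Nprev <- Ni; CAprev <- CAi; Cprev <- Ci
        psiPrev <- psi
      }
      if (ligandAtoms > 0) {
        lig <- ligand(f)
        stopifnot(nrow(lig) == ligandAtoms)
        pos <- rbind(pos, lig)
      }
      xyz[fi, ] <- as.vector(t(pos))
    }
    xyz
  })
  names(coords) <- NULL
  new("TrajectoryEnsemble", topology = topology, coords = coords,
      frameInterval = frameInterval(dihedrals), box = NULL)
}
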