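## Readers and writers: CSV feature tables (with a JSON label sidecar),
## PDB topology, multi-model PDB coordinates, DCD input via bio3d.
## Internal units are nm and radians; CSV exports use degrees for angle
## columns and PDB files use Angstrom, converted on the way in and out.

angleColumn <- function(labels) grepl("^(phi|psi|chi1)_", labels)

#' Write a per-frame series to CSV
#'
#' Columns: `trajectory_id`, `frame`, then one column per feature. Angle
#' columns (labels `phi_*`, `psi_*`, `chi1_*`) are exported in degrees;
#' logical contact columns as 0/1. A sidecar `<file>.labels.json` records
#' the label order, frame interval and cutoff.
#'
#' @param x a [FrameSeries-class] object.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeFeatureCSV <- function(x, file) {
  stopifnot(is(x, "FrameSeries"))
  vals <- featureValues(x)
  labs <- featureLabels(x)
  out <- as.data.frame(vals)
  names(out) <- labs
  if (is.logical(vals)) {
    out[] <- lapply(out, as.integer)
  } else {
    deg <- angleColumn(labs)
    out[deg] <- lapply(out[deg], function(v) v * 180 / pi)
  }
  frame <- unlist(lapply(split(seq_along(trajIds(x)), trajIds(x)), seq_along),
                  use.names = FALSE)
  out <- cbind(trajectory_id = trajIds(x), frame = frame, out)
  utils::write.csv(out, file, row.names = FALSE)
  meta <- list(labels = labs, frame_interval_ps = frameInterval(x),
               class = class(x)[1])
  if (is(x, "ContactSeries") && !is.na(x@cutoff)) meta$cutoff_nm <- x@cutoff
  if (is(x, "DistanceSeries")) meta$level <- x@level
  jsonlite::write_json(meta, paste0(file, ".labels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a per-frame series written by [writeFeatureCSV()]
#'
#' @param file CSV path (the `.labels.json` sidecar must sit next to it).
#' @return the reconstructed [FrameSeries-class] object.
#' @export
readFeatureCSV <- function(file) {
  sidecar <- paste0(file, ".labels.json")
  if (!file.exists(file)) stop("no such file: ", file)
  if (!file.exists(sidecar)) stop("missing label sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- utils::read.csv(file, check.names = FALSE)
  labs <- meta$labels
  vals <- as.matrix(d[, labs, drop = FALSE])
  cls <- meta$class
  if (identical(cls, "ContactSeries")) {
    storage.mode(vals) <- "logical"
    return(contactSeries(vals, labels = labs, traj = d$trajectory_id,
                         frameInterval = meta$frame_interval_ps,
                         cutoff = if (is.null(meta$cutoff_nm)) NA_real_ else
                           as.numeric(meta$cutoff_nm)))
  }
  deg <- angleColumn(labs)
  vals[, deg] <- vals[, deg] * pi / 180
  if (identical(cls, "DistanceSeries")) {
    return(newFeatureSeries(vals, labs, d$trajectory_id,
                            meta$frame_interval_ps, class = "DistanceSeries",
                            level = meta$level))
  }
  newFeatureSeries(vals, labs, d$trajectory_id, meta$frame_interval_ps)
}

pdbAtomLine <- function(i, elety, resid, resno, xyzA, segment) {
  sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s",
          i %% 100000, substr(elety, 1, 4), substr(resid, 1, 4),
          resno %% 100000, xyzA[1], xyzA[2], xyzA[3], segment)
}

#' Write a trajectory ensemble as PDB files
#'
#' Writes `topology.pdb` (first frame) plus one multi-model coordinate PDB
#' per trajectory (`traj_<i>.pdb`); coordinates are converted from nm to
#' Angstrom.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeTrajectoryPDB <- function(ensemble, dir) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  top <- ensemble@topology
  frameLines <- function(xyzRow) {
    m <- matrix(xyzRow, ncol = 3, byrow = TRUE) * 10
    vapply(seq_len(nrow(top)), function(a) {
      pdbAtomLine(top$eleno[a], top$elety[a], top$resid[a], top$resno[a],
                  m[a, ], top$segment[a])
    }, character(1))
  }
  writeLines(c(frameLines(ensemble@coords[[1]][1, ]), "END"),
             file.path(dir, "topology.pdb"))
  for (i in seq_along(ensemble@coords)) {
    xyz <- ensemble@coords[[i]]
    con <- file(file.path(dir, sprintf("traj_%03d.pdb", i)), "w")
    for (f in seq_len(nrow(xyz))) {
      writeLines(c(sprintf("MODEL     %4d", f), frameLines(xyz[f, ]),
                   "ENDMDL"), con)
    }
    writeLines("END", con)
    close(con)
  }
  invisible(dir)
}

topologyFromPDB <- function(pdb, ligandResid = "LIG") {
  a <- pdb$atom
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("^[0-9]", "", a$elety), 1, 1)
  }
  data.frame(
    eleno = seq_len(nrow(a)),
    elety = a$elety,
    resid = a$resid,
    resno = a$resno,
    element = toupper(element),
    segment = ifelse(a$resid == ligandResid, "LIG", "PEP"),
    stringsAsFactors = FALSE
  )
}

#' Read a trajectory ensemble from PDB/DCD files
#'
#' The topology comes from a PDB file; coordinates either from multi-model
#' PDBs (as written by [writeTrajectoryPDB()]) or from binary DCD files.
#' Coordinates are converted to nm.
#'
#' @param topology path to a PDB file.
#' @param trajFiles character vector of coordinate files (`.pdb` or `.dcd`).
#' @param frameInterval frame spacing (ps).
#' @param ligandResid residue name identifying the ligand atoms.
#' @return a [TrajectoryEnsemble-class].
#' @export
readTrajectoryEnsemble <- function(topology, trajFiles, frameInterval = 250,
                                   ligandResid = "LIG") {
  pdb <- bio3d::read.pdb(topology)
  top <- topologyFromPDB(pdb, ligandResid)
  coords <- lapply(trajFiles, function(f) {
    if (!file.exists(f)) stop("no such trajectory file: ", f)
    if (grepl("\\.dcd$", f, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(f, verbose = FALSE)
    } else {
      mm <- bio3d::read.pdb(f, multi = TRUE)
      xyz <- mm$xyz
    }
    if (ncol(xyz) != 3 * nrow(top)) {
      stop("atom count mismatch between topology and ", f)
    }
    unclass(xyz) / 10
  })
  new("TrajectoryEnsemble", topology = top, coords = coords,
      frameInterval = frameInterval, box = NULL)
}
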