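test_that("nearest-neighbour distance featurizer has the documented dimension", {
  ## (n - s)(n - s + 1)/2 by enumeration up to n = 50
  for (n in c(4, 7, 20, 42, 50)) {
    for (s in c(1L, 3L, 5L)) {
      expect_equal(nrow(nnPairIndex(n, s)), max(0, (n - s) * (n - s + 1) / 2))
    }
  }
  ## a 42-residue chain with the default separation yields 780 features
  d42 <- randomDihedrals(42, 1, seed = 9)
  ens <- buildPeptideCoordinates(d42)
  feats <- nnDistanceFeatures(ens)
  expect_length(featureLabels(feats), 780)
  ## 3 residues cannot form a pair at separation 3
  ens3 <- buildPeptideCoordinates(randomDihedrals(3, 1, seed = 1))
  expect_warning(f3 <- nnDistanceFeatures(ens3), "no distance features")
  expect_length(featureLabels(f3), 0)
})

test_that("distance features equal the brute-force atom-pair minimum", {
  ens <- buildPeptideCoordinates(randomDihedrals(5, 3, seed = 2))
  feats <- nnDistanceFeatures(ens, minSeqSep = 3)
  expect_identical(featureLabels(feats), c("d_1_4", "d_1_5", "d_2_5"))
  top <- ens@topology
  xyz <- ens@coords[[1]]
  pairs <- list(c(1, 4), c(1, 5), c(2, 5))
  for (f in seq_len(nrow(xyz))) {
    p <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    for (k in seq_along(pairs)) {
      ai <- which(top$resno == pairs[[k]][1])
      aj <- which(top$resno == pairs[[k]][2])
      brute <- min(as.matrix(dist(rbind(p[ai, ], p[aj, ])))[
        seq_along(ai), length(ai) + seq_along(aj)])
      expect_equal(unname(featureValues(feats)[f, k]), brute,
                   tolerance = 1e-12)
    }
  }
})

test_that("distance features are invariant under rigid-body motion", {
  ens <- buildPeptideCoordinates(randomDihedrals(6, 2, seed = 3))
  f0 <- featureValues(nnDistanceFeatures(ens))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens
  moved@coords <- lapply(ens@coords, function(xyz) {
    t(apply(xyz, 1, function(row) {
      p <- matrix(row, ncol = 3, byrow = TRUE) %*% R
      as.vector(t(sweep(p, 2, c(1.5, -2, 0.3), "+")))
    }))
  })
  f1 <- featureValues(nnDistanceFeatures(moved))
  expect_equal(f1, f0, tolerance = 1e-10)
})

test_that("backbone dihedral extraction inverts coordinate construction", {
  nres <- 8; nf <- 5
  dih <- randomDihedrals(nres, nf, seed = 4)
  ens <- buildPeptideCoordinates(dih)
  bb <- backboneDihedrals(ens)
  vals <- featureValues(bb)
  truth <- featureValues(dih)
  ## terminal angles undefined
  expect_true(all(is.na(vals[, "phi_1"])))
  expect_true(all(is.na(vals[, paste0("psi_", nres)])))
  expect_equal(sum(!is.na(vals[1, grep("^phi", featureLabels(bb))])), nres - 1)
  expect_equal(sum(!is.na(vals[1, grep("^psi", featureLabels(bb))])), nres - 1)
  for (r in 2:nres) {
    expect_equal(wrapAngle(vals[, paste0("phi_", r)] -
                             truth[, paste0("phi_", r)]),
                 rep(0, nf), tolerance = 1e-6)
  }
  for (r in 1:(nres - 1)) {
    expect_equal(wrapAngle(vals[, paste0("psi_", r)] -
                             truth[, paste0("psi_", r)]),
                 rep(0, nf), tolerance = 1e-6)
  }
  ## ideal backbone bond lengths reproduced exactly
  p <- matrix(ens@coords[[1]][1, ], ncol = 3, byrow = TRUE)
  top <- ens@topology
  iN <- which(top$elety == "N")[1]; iCA <- which(top$elety == "CA")[1]
  expect_equal(sqrt(sum((p[iCA, ] - p[iN, ])^2)), 0.1458, tolerance = 1e-6)
  ## atom count: 5 atoms per chi1-capable residue
  expect_equal(nrow(top), nres * 5)
})

test_that("chi1 extraction handles rotamers and chi1-less residues", {
  nres <- 4; nf <- 3
  dih <- randomDihedrals(nres, nf, seed = 6)
  ens <- buildPeptideCoordinates(dih)
  c1 <- chi1Dihedrals(ens)
  expect_equal(wrapAngle(featureValues(c1) -
                           featureValues(dih)[, paste0("chi1_", 1:nres)]),
               matrix(0, nf, nres), tolerance = 1e-6, ignore_attr = TRUE)
  ## staggered rotamer geometry recovered exactly
  vals <- featureValues(dih)
  vals[, paste0("chi1_", 1:nres)] <- rep_len(c(-pi / 3, pi / 3, pi),
                                             nf * nres)
  dih2 <- softmsm:::newFeatureSeries(vals, featureLabels(dih),
                                     trajIds(dih), 250)
  c2 <- chi1Dihedrals(buildPeptideCoordinates(dih2))
  expect_equal(wrapAngle(featureValues(c2) -
                           vals[, paste0("chi1_", 1:nres)]),
               matrix(0, nf, nres), tolerance = 1e-6, ignore_attr = TRUE)
  ## Gly/Ala-only peptide: no chi1 anywhere
  ensGA <- buildPeptideCoordinates(randomDihedrals(4, 2, seed = 7,
                                                   withChi1 = FALSE),
                                   sequence = c("GLY", "ALA", "ALA", "GLY"))
  expect_warning(cGA <- chi1Dihedrals(ensGA), "no residue")
  expect_length(featureLabels(cGA), 0)
})

test_that("ligand minimum distances match exhaustive enumeration", {
  nres <- 5; nf <- 4
  lig <- withr::with_seed(8, {
    offsets <- matrix(rnorm(10 * 3, sd = 0.3), 10, 3)
    function(f) sweep(offsets, 2, c(0.5 + 0.1 * f, 0.2, -0.1), "+")
  })
  ens <- buildPeptideCoordinates(randomDihedrals(nres, nf, seed = 8),
                                 ligand = lig, ligandAtoms = 10L)
  dres <- ligandMinDistances(ens, level = "residue")
  datm <- ligandMinDistances(ens, level = "atom")
  top <- ens@topology
  ligIdx <- which(top$segment == "LIG")
  for (f in seq_len(nf)) {
    p <- matrix(ens@coords[[1]][f, ], ncol = 3, byrow = TRUE)
    for (r in seq_len(nres)) {
      ri <- which(top$resno == r & top$segment == "PEP")
      brute <- min(sqrt(outer(rowSums(p[ligIdx, ]^2), rowSums(p[ri, ]^2), "+") -
                          2 * p[ligIdx, ] %*% t(p[ri, ])))
      expect_equal(unname(featureValues(dres)[f, r]), brute,
                   tolerance = 1e-10)
    }
    pep <- which(top$segment == "PEP")
    for (a in seq_along(ligIdx)) {
      brute <- min(sqrt(colSums((t(p[pep, ]) - p[ligIdx[a], ])^2)))
      expect_equal(unname(featureValues(datm)[f, a]), brute,
                   tolerance = 1e-10)
    }
  }
  ## degenerate single-atom groups: plain Euclidean distance
  expect_error(ligandMinDistances(buildPeptideCoordinates(
    randomDihedrals(4, 1, seed = 1))), "empty ligand")
})

test_that("distances honour the minimum-image convention across the box", {
  ## two atoms 0.2 nm apart through the boundary of a 2 nm box
  top <- data.frame(eleno = 1:2, elety = c("CA", "L1"),
                    resid = c("LEU", "LIG"), resno = 1:2,
                    element = "C", segment = c("PEP", "LIG"))
  xyz <- matrix(c(0.1, 0.5, 0.5, 1.9, 0.5, 0.5), 1)
  ens <- new("TrajectoryEnsemble", topology = top, coords = list(xyz),
             frameInterval = 250, box = c(2, 2, 2))
  d <- ligandMinDistances(ens, level = "residue")
  expect_equal(unname(featureValues(d)[1, 1]), 0.2, tolerance = 1e-12)
  ## without the box the raw distance is 1.8 nm
  ens@box <- NULL
  expect_equal(unname(featureValues(ligandMinDistances(ens))[1, 1]), 1.8,
               tolerance = 1e-12)
})

test_that("ring stacking follows thresholded centroid distances", {
  ## scripted centroids: ligand ring fixed, residue ring walks away
  mkRing <- function(center, r = 0.14) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(center[1] + r * cos(th), center[2] + r * sin(th), center[3])
  }
  sep <- c(0.35, 0.45, 0.6, 2.0)
  frames <- lapply(sep, function(s) rbind(mkRing(c(0, 0, 0)),
                                          mkRing(c(0, 0, s))))
  top <- data.frame(eleno = 1:12, elety = paste0("C", 1:12),
                    resid = rep(c("LIG", "PHE"), each = 6),
                    resno = rep(1:2, each = 6), element = "C",
                    segment = rep(c("LIG", "PEP"), each = 6))
  xyz <- do.call(rbind, lapply(frames, function(p) as.vector(t(p))))
  ens <- new("TrajectoryEnsemble", topology = top, coords = list(xyz),
             frameInterval = 250, box = NULL)
  cs <- detectPiStacks(ens, ligandRings = list(L1 = 1:6),
                       residueRings = list(F1 = 7:12))
  expect_equal(unname(featureValues(cs)[, 1]), sep <= 0.55)
  ## independent centroid computation
  cent <- vapply(frames, function(p) {
    sqrt(sum((colMeans(p[1:6, ]) - colMeans(p[7:12, ]))^2))
  }, numeric(1))
  expect_equal(unname(featureValues(cs)[, 1]), cent <= 0.55)
  ## undersized rings rejected
  expect_error(detectPiStacks(ens, list(L1 = 1:4), list(F1 = 7:12)),
               "at least 5")
})
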