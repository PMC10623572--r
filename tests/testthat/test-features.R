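# Distance and dihedral feature extraction.

test_that("Calpha distance features honor the mean-distance filter", {
  st <- toyStructure(nRes = 3, ligand = FALSE)
  # residues 1-2 fixed 3 A apart; residue 3 placed 15 A from residue 1
  base <- st@coords
  base[3, ] <- c(16, 0, 0)
  frames <- list(base, base, base)
  traj <- toyTrajectory(st, frames)
  fm <- caDistanceFeatures(traj, 1:3, maxMeanDistance = 12)
  desc <- featureDescriptors(fm)
  expect_true(any(desc$resA == 1 & desc$resB == 2))
  expect_false(any(desc$resA == 1 & desc$resB == 3))
  vals <- featureValues(fm)
  expect_equal(unname(vals[, which(desc$resA == 1 & desc$resB == 2)]),
               rep(3, 3))
})

test_that("a pair with mean distance just above the cutoff is dropped", {
  st <- toyStructure(nRes = 2, ligand = FALSE)
  mk <- function(d) { m <- st@coords; m[2, ] <- m[1, ] + c(d, 0, 0); m }
  traj <- toyTrajectory(st, list(mk(10), mk(11), mk(16)))  # mean 12.33
  fm <- caDistanceFeatures(traj, 1:2, maxMeanDistance = 12)
  expect_equal(nrow(fm), 0L)
  traj2 <- toyTrajectory(st, list(mk(10), mk(11), mk(15)))  # mean 12.0
  expect_equal(nrow(caDistanceFeatures(traj2, 1:2, maxMeanDistance = 12)), 1L)
})

test_that("Calpha features match a brute-force all-pairs scan", {
  set.seed(11)
  nRes <- 8; nF <- 20
  st <- toyStructure(nRes = nRes, ligand = FALSE)
  frames <- lapply(seq_len(nF), function(f)
    st@coords + matrix(rnorm(nRes * 3, 0, 4), ncol = 3))
  traj <- toyTrajectory(st, frames)
  fm <- caDistanceFeatures(traj, seq_len(nRes), maxMeanDistance = 12)
  desc <- featureDescriptors(fm)
  vals <- featureValues(fm)
  # oracle: direct enumeration
  co <- coordArray(traj)
  got <- 0L
  for (i in seq_len(nRes - 1)) {
    for (j in seq.int(i + 1, nRes)) {
      d <- sapply(seq_len(nF), function(f) sqrt(sum((co[i, , f] - co[j, , f])^2)))
      inFm <- which(desc$resA == i & desc$resB == j)
      if (mean(d) <= 12) {
        got <- got + 1L
        expect_length(inFm, 1L)
        expect_equal(unname(vals[, inFm]), d, tolerance = 1e-12)
      } else {
        expect_length(inFm, 0L)
      }
    }
  }
  expect_equal(nrow(fm), got)
  # properties: symmetry of the pair definition and non-negativity
  expect_true(all(desc$resA < desc$resB))
  expect_true(all(vals >= 0))
})

test_that("pocket membership follows the 50% prevalence rule", {
  st <- toyStructure(nRes = 2, withCB = TRUE)
  manifest <- LigandManifest("LIG",
    data.frame(role = "head_oxygen",
               atomId = atomTable(st)$id[atomTable(st)$name == "O1"]))
  oIdx <- which(atomTable(st)$name == "O1")
  mk <- function(d1) {
    m <- st@coords
    # residue 1's closest heavy atom (CA) at distance d1 from the polar atom
    m[1, ] <- m[oIdx, ] + c(d1, 0, 0)
    m[2, ] <- m[oIdx, ] + c(d1 + 2, 2, 0)  # CB of residue 1, farther out
    m
  }
  # residue 1 within 6 A in 4 of 10 frames (40%) -> absent
  frames <- lapply(c(3, 3, 3, 3, 8, 8, 8, 8, 8, 8), mk)
  traj <- toyTrajectory(st, frames)
  fm <- ligandPocketDistances(traj, manifest)
  expect_false(1 %in% featureDescriptors(fm)$resA[
    featureDescriptors(fm)$kind == "ligand_polar_distance" &
      featureDescriptors(fm)$resA == 1 &
      featureDescriptors(fm)$atomRef == atomTable(st)$id[oIdx]])
  # 60% within -> present, values equal the per-frame minimum heavy distance
  frames2 <- lapply(c(3, 3, 3, 3, 3, 3, 8, 8, 8, 8), mk)
  traj2 <- toyTrajectory(st, frames2)
  fm2 <- ligandPocketDistances(traj2, manifest)
  d2 <- featureDescriptors(fm2)
  hit <- which(d2$resA == 1 & d2$atomRef == atomTable(st)$id[oIdx])
  expect_length(hit, 1L)
  # oracle: frame-by-frame brute-force min over residue heavy atoms
  co <- coordArray(traj2)
  resIdx <- which(atomTable(st)$resno == 1 & atomTable(st)$chain == "R")
  oracle <- sapply(seq_len(10), function(f)
    min(sapply(resIdx, function(i) sqrt(sum((co[i, , f] - co[oIdx, , f])^2)))))
  expect_equal(unname(featureValues(fm2)[, hit]), oracle, tolerance = 1e-12)
})

test_that("dihedral angles follow the IUPAC convention and stay in range", {
  st <- toyStructure(nRes = 4, ligand = FALSE)
  mk <- function(y4) {
    m <- st@coords
    m[1, ] <- c(0, 1, 0); m[2, ] <- c(0, 0, 0)
    m[3, ] <- c(1.5, 0, 0); m[4, ] <- c(1.5, y4, 0)
    m
  }
  traj <- toyTrajectory(st, list(mk(1), mk(-1)))
  ids <- atomTable(st)$id[1:4]
  ang <- dihedralSeries(traj, ids)
  expect_equal(ang[1], 0)     # cis / eclipsed
  expect_equal(abs(ang[2]), 180)  # trans
  expect_true(all(ang > -180 & ang <= 180))
})

test_that("dihedrals match an independent implementation on random quadruples", {
  set.seed(99)
  st <- toyStructure(nRes = 4, ligand = FALSE)
  frames <- lapply(1:25, function(f) matrix(rnorm(nrow(st@coords) * 3, 0, 3),
                                            ncol = 3))
  traj <- toyTrajectory(st, frames)
  ids <- atomTable(st)$id[1:4]
  got <- dihedralSeries(traj, ids)
  oracle <- sapply(1:25, function(f)
    bio3d::torsion.xyz(as.vector(t(coordArray(traj)[1:4, , f]))))
  expect_equal(got, unname(oracle), tolerance = 1e-6)
})

test_that("interface features pair receptor with G-alpha residues only", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 10L, noiseSigma = 0, seed = 1L)
  traj <- generateTrajectory(rec$structure, p, manifest = rec$manifest)$trajectory
  fm <- interfaceDistances(traj)
  desc <- featureDescriptors(fm)
  expect_gt(nrow(fm), 0L)
  expect_true(all(desc$chainA == "R" & desc$chainB == "G"))
  expect_true(all(colMeans(featureValues(fm)) <= 12))
  # brute-force check on a handful of retained pairs
  co <- coordArray(traj)
  a <- atomTable(traj)
  for (k in head(seq_len(nrow(desc)), 3)) {
    iA <- which(a$chain == "R" & a$resno == desc$resA[k] & a$name == "CA")
    iB <- which(a$chain == "G" & a$resno == desc$resB[k] & a$name == "CA")
    d <- sqrt(colSums((co[iA, , ] - co[iB, , ])^2))
    expect_equal(unname(featureValues(fm)[, k]), unname(d), tolerance = 1e-12)
  }
})

test_that("motif chi1 features resolve through BW codes and error when absent", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 5L, noiseSigma = 0, seed = 1L)
  traj <- generateTrajectory(rec$structure, p, manifest = rec$manifest)$trajectory
  fm <- motifDihedrals(traj, rec$residueMap)
  expect_equal(nrow(fm), 15L)  # CWxP + DRY + PIF + NPxxY
  expect_true(all(featureDescriptors(fm)$units == "degree"))
  badMap <- rec$residueMap[rec$residueMap$bw != "6.48", ]
  expect_error(motifDihedrals(traj, badMap), "6.48")
})

test_that("feature extraction is deterministic", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 8L, noiseSigma = 0.2, seed = 4L)
  traj <- generateTrajectory(rec$structure, p, manifest = rec$manifest)$trajectory
  f1 <- ligandPocketDistances(traj, rec$manifest)
  f2 <- ligandPocketDistances(traj, rec$manifest)
  expect_identical(featureValues(f1), featureValues(f2))
})
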