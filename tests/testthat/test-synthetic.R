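# Synthetic generator: determinism, plant recovery, conflict detection.

test_that("receptor generation is deterministic and fully annotated", {
  rec <- sharedReceptor()
  sch <- cb1rScheme()
  a <- atomTable(rec$structure)
  # every subsegment populated
  for (nm in subsegmentNames(sch)) {
    expect_true(any(a$resno[a$chain == "R"] %in% subsegmentResidues(sch, nm)),
                label = nm)
  }
  # manifest: 6 polar atoms, two 4-atom dihedrals
  expect_equal(nrow(rec$manifest@polarAtoms), 6L)
  expect_equal(lengths(lapply(rec$manifest@dihedrals, `[[`, "quad")),
               c(chi1 = 4L, chi2 = 4L))
  # residue map covers every receptor residue exactly once
  rmR <- rec$residueMap[rec$residueMap$chain == "R", ]
  expect_setequal(rmR$resnum, unique(a$resno[a$chain == "R"]))
  expect_false(anyDuplicated(rmR$resnum) > 0)
  # same seed -> byte-identical PDB
  p1 <- tmpfile("r1.pdb"); p2 <- tmpfile("r2.pdb")
  writeStructure(generateReceptor(seed = 9L)$structure, p1)
  writeStructure(generateReceptor(seed = 9L)$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero noise and no plants reproduce the base coordinates", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 4L, noiseSigma = 0, seed = 2L)
  g <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
  for (f in 1:4) {
    expect_equal(coordArray(g$trajectory)[, , f], rec$structure@coords)
  }
})

test_that("generator output is bit-reproducible under a fixed seed", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 12L, noiseSigma = 0.3, seed = 77L,
    dihedralPlant = list(name = "chi1", modes = c(80, 160),
                         occupancies = c(0.5, 0.5), switchRate = 0.5),
    contactPlants = list(list(resno = 194L, freq = 0.5)))
  g1 <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
  g2 <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
  expect_identical(coordArray(g1$trajectory), coordArray(g2$trajectory))
  expect_identical(g1$groundTruth$contacts[[1]]$schedule,
                   g2$groundTruth$contacts[[1]]$schedule)
})

test_that("planted correlations materialise at the target r", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 2000L, noiseSigma = 0.3, seed = 7L,
    correlationPlants = list(list(r = 0.95, amplitude = 2, members = list(
      list(kind = "ca", residues = c(165L, 172L)),
      list(kind = "ca", residues = c(195L, 199L))))))
  g <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
  rr <- g$groundTruth$correlations[[1]]$realizedR[1, 2]
  expect_equal(rr, 0.95, tolerance = 0.05)
  # the realized value is recomputable from the emitted frames
  m <- g$groundTruth$correlations[[1]]$members
  s1 <- MDAllostery:::memberSeries(g$trajectory, m[[1]])
  s2 <- MDAllostery:::memberSeries(g$trajectory, m[[2]])
  expect_equal(cor(s1, s2), rr)
})

test_that("contact schedules are recovered exactly by contactFrequency", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 400L, noiseSigma = 0.3, seed = 8L,
                       contactPlants = list(list(resno = 194L, freq = 0.6)))
  g <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
  ct <- contactFrequency(g$trajectory, "LIG", residues = 194L)
  expect_equal(ct$frequency, g$groundTruth$contacts[[1]]$realizedFreq)
  expect_equal(g$groundTruth$contacts[[1]]$realizedFreq,
               mean(g$groundTruth$contacts[[1]]$schedule))
})

test_that("conflicting plants on one residue are rejected", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 10L, noiseSigma = 0.3, seed = 1L,
    shiftPlants = list(list(name = "TM2e", magnitude = 0.8,
                            direction = "inward")),
    contactPlants = list(list(resno = 178L, freq = 0.5)))  # 178 is in TM2e
  expect_error(generateTrajectory(rec$structure, p, manifest = rec$manifest),
               "conflicting plants")
})

test_that("planted conformational states are recovered across seeds", {
  rec <- sharedReceptor()
  sch <- cb1rScheme()
  sel <- tmBackboneIndices(rec$structure, sch)
  hits <- 0L
  for (s in 1:10) {
    p <- generatorParams(nFrames = 150L, noiseSigma = 0.3,
                         seed = 1000L + s,
                         clusterPlant = list(k = 2L,
                                             segments = c("TM6e", "TM6m", "TM6i"),
                                             magnitude = 2.5,
                                             weights = c(0.65, 0.35)))
    g <- generateTrajectory(rec$structure, p, manifest = rec$manifest)
    rmsd <- pairwiseRmsd(g$trajectory, sel)
    emb <- mdsEmbed(rmsd)
    ids <- sampleFrames(g$trajectory, 800L, seed = s)
    pts <- emb[match(ids, frameIds(g$trajectory)), , drop = FALSE]
    gap <- gapStatistic(pts, kMax = 3L, B = 8L, seed = s, nInit = 5L)
    k <- suppressWarnings(as.integer(selectK(gap)))
    if (k == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the default condition pair carries its planted contrasts", {
  pair <- smallPair()
  expect_equal(conditionLabel(pair$trajectoryA), "MDMB-like")
  # contact plant: 100% vs 46% target
  expect_equal(pair$truthA$contacts[[1]]$targetFreq, 1.0)
  expect_equal(pair$truthB$contacts[[1]]$targetFreq, 0.46)
  # shift plant: TM2e at 0.8 A inward
  shifts <- vapply(pair$truthA$shifts, function(s) s$magnitude, numeric(1))
  expect_true(0.8 %in% shifts)
  expect_length(pair$truthB$shifts, 0L)
  # chi1: unimodal A, bimodal B
  expect_equal(length(unique(pair$truthA$dihedral$states)), 1L)
  expect_equal(sort(unique(pair$truthB$dihedral$states)), 1:2)
})
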