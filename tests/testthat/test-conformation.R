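# Subsegment centers of mass, COM displacements/distances and mode analysis.

test_that("the center of mass is the mass-weighted atom average", {
  # one-atom and two-equal-mass checks, then an unequal-mass oracle
  atoms <- data.frame(id = 1:3, name = c("CA", "CB", "O1"),
                      element = c("C", "C", "O"), resno = c(176L, 176L, 177L),
                      resname = "ALA", chain = "R")
  co <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  st <- Structure(atoms, co)
  traj <- toyTrajectory(st, list(co))
  sch <- cb1rScheme()
  com <- subsegmentCom(traj, sch, "TM2e")
  m <- atomTable(st)$mass
  oracle <- colSums(co * m) / sum(m)
  expect_equal(unname(com[1, ]), unname(oracle))
  # restrict to residue 176's two equal-mass carbons: midpoint
  atoms2 <- atoms[1:2, ]
  st2 <- Structure(atoms2, co[1:2, ])
  com2 <- subsegmentCom(toyTrajectory(st2, list(co[1:2, ])), sch, "TM2e")
  expect_equal(unname(com2[1, ]), c(1, 0, 0))
})

test_that("COM displacement report recovers a constructed rigid shift", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 6L, noiseSigma = 0, seed = 1L)
  traj <- generateTrajectory(rec$structure, p,
                             manifest = rec$manifest)$trajectory
  sch <- cb1rScheme()
  comsA <- allSubsegmentComs(traj, sch)
  # shift TM2e atoms by +1 A in x in every frame
  a <- atomTable(traj)
  idx <- which(a$chain == "R" & a$resno %in% subsegmentResidues(sch, "TM2e"))
  co <- coordArray(traj)
  co[idx, 1, ] <- co[idx, 1, ] + 1
  trajShift <- Trajectory(traj@structure, co, condition = "shifted")
  comsB <- allSubsegmentComs(trajShift, sch)
  d <- deltaComReport(comsB, comsA)
  expect_equal(d$magnitude[d$subsegment == "TM2e"], 1, tolerance = 1e-9)
  expect_equal(d$dx[d$subsegment == "TM2e"], 1, tolerance = 1e-9)
  expect_true(all(d$magnitude[d$subsegment != "TM2e"] < 1e-9))
  # identical conditions give zero; the report is antisymmetric
  d0 <- deltaComReport(comsA, comsA)
  expect_true(all(d0$magnitude == 0))
  dBA <- deltaComReport(comsA, comsB)
  expect_equal(dBA$dx, -d$dx)
  expect_equal(dBA$dy, -d$dy)
})

test_that("COM distances are invariant under a rigid motion of all frames", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 4L, noiseSigma = 0.3, seed = 6L)
  traj <- generateTrajectory(rec$structure, p,
                             manifest = rec$manifest)$trajectory
  sch <- cb1rScheme()
  d0 <- comDistanceSeries(traj, sch)
  motion <- randomRigidMotion(9)
  co <- coordArray(traj)
  for (f in seq_len(nFrames(traj))) {
    co[, , f] <- applyRigid(co[, , f], motion)
  }
  trajR <- Trajectory(traj@structure, co, condition = "moved")
  expect_equal(comDistanceSeries(trajR, sch), d0, tolerance = 1e-9)
})

test_that("COM distance series handle degenerate and static fixtures", {
  atoms <- data.frame(id = 1:2, name = "CA", element = "C",
                      resno = c(113L, 186L), resname = "GLY", chain = "R")
  co <- rbind(c(1, 2, 3), c(1, 2, 3))  # coincident subsegments
  st <- Structure(atoms, co)
  traj <- toyTrajectory(st, list(co, co, co))
  d <- comDistanceSeries(traj, cb1rScheme(), pairs = list(c("TM1e", "TM3e")))
  expect_equal(d[["TM1e-TM3e"]], rep(0, 3))
  co2 <- rbind(c(0, 0, 0), c(5, 0, 0))
  st2 <- Structure(atoms, co2)
  d2 <- comDistanceSeries(toyTrajectory(st2, list(co2, co2)), cb1rScheme(),
                          pairs = list(c("TM1e", "TM3e")))
  expect_equal(d2[["TM1e-TM3e"]], rep(5, 2))
})

test_that("mode detection resolves unimodal, bimodal and constant series", {
  set.seed(15)
  uni <- wrapAngle(rnorm(2000, 90, 10))
  m1 <- detectModes(uni)
  expect_equal(nrow(m1), 1L)
  expect_lt(circularDiff(m1$location, 90), 8)
  expect_equal(m1$occupancy, 1)
  # planted 60/40 two-state at 80/160 degrees
  states <- sample(1:2, 2000, replace = TRUE, prob = c(0.6, 0.4))
  bim <- wrapAngle(c(80, 160)[states] + rnorm(2000, 0, 9))
  m2 <- detectModes(bim)
  expect_equal(nrow(m2), 2L)
  expect_lt(circularDiff(m2$location[1], 80), 10)
  expect_lt(circularDiff(m2$location[2], 160), 10)
  expect_equal(m2$occupancy, tabulate(states) / 2000, tolerance = 0.05)
  cst <- detectModes(rep(42.4, 100))
  expect_equal(nrow(cst), 1L)
  expect_equal(cst$location, 42.4)
  expect_equal(cst$supportLo, cst$supportHi)
  expect_error(detectModes(uni[1:10]), "too short")
})

test_that("the 2D dihedral map is a normalised occupancy grid", {
  expect_error(dihedral2dMap(1:5, 1:4), "length mismatch")
  g1 <- dihedral2dMap(rep(80, 50), rep(-120, 50))
  expect_equal(sum(g1), 1)
  expect_equal(max(g1), 1)  # single occupied bin
  set.seed(4)
  states <- sample(1:2, 1000, replace = TRUE, prob = c(0.7, 0.3))
  chi1 <- wrapAngle(c(80, 160)[states] + rnorm(1000, 0, 6))
  chi2 <- wrapAngle(-60 + rnorm(1000, 0, 6))
  g2 <- dihedral2dMap(chi1, chi2)
  expect_equal(sum(g2), 1)
  # marginal chi1 modes agree with detectModes
  marg <- rowSums(g2)
  mids <- as.numeric(rownames(g2))
  peaks <- detectModes(chi1)
  expect_equal(nrow(peaks), 2L)
  for (loc in peaks$location) {
    expect_gt(marg[which.min(abs(mids - loc))], 0.01)
  }
})
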