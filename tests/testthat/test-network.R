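# Correlation network: assembly, Pearson pairs and the three filters,
# bootstrap consensus, TM involvement and edge export.

# Minimal FeatureMatrix straight from a values matrix + descriptor fields.
mkFm <- function(vals, kind, resA, resB, units = "angstrom", region = "tm",
                 chainA = "R", chainB = "R") {
  n <- ncol(vals)
  desc <- data.frame(kind = kind, chainA = chainA, resA = resA,
                     chainB = chainB, resB = resB, atomRef = NA_integer_,
                     quad = NA_character_, units = units, region = region,
                     label = paste0("f", seq_len(n)),
                     stringsAsFactors = FALSE)
  MDAllostery:::makeFeatureMatrix(vals, desc, seq_len(nrow(vals)) - 1L, "toy")
}

test_that("assembled features are the union of the per-region extractors", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 60L, noiseSigma = 0.3, seed = 2L)
  traj <- generateTrajectory(rec$structure, p,
                             manifest = rec$manifest)$trajectory
  sch <- cb1rScheme()
  fm <- assembleFeatures(traj, frameIds(traj), rec$manifest, rec$residueMap,
                         sch)
  desc <- featureDescriptors(fm)
  expect_setequal(unique(desc$region), c("pocket", "tm", "interface"))
  tmRes <- intersect(unlist(Map(seq.int, schemeTable(sch)$start,
                                schemeTable(sch)$end)),
                     atomTable(traj)$resno[atomTable(traj)$chain == "R"])
  nPocket <- nrow(ligandPocketDistances(traj, rec$manifest)) +
    nrow(ligandHeadDihedrals(traj, rec$manifest))
  nTm <- nrow(caDistanceFeatures(traj, tmRes)) +
    nrow(motifDihedrals(traj, rec$residueMap))
  nIface <- nrow(interfaceDistances(traj))
  expect_equal(nrow(fm), nPocket + nTm + nIface)
  expect_equal(sum(desc$region == "pocket"), nPocket)
  expect_equal(sum(desc$region == "interface"), nIface)
})

test_that("Pearson pairs match the textbook formula, with constant flags", {
  set.seed(10)
  x <- rnorm(10)
  vals <- cbind(x, x, -x, rnorm(10), rep(2, 10))
  vals10 <- vals + 20  # keep distances positive
  fm <- mkFm(vals10, "ca_distance", resA = 1:5 * 10L, resB = 1:5 * 10L + 5L)
  pp <- pearsonPairs(fm)
  getR <- function(i, j) pp$r[pp$i == i & pp$j == j]
  expect_equal(getR(1, 2), 1)
  expect_equal(getR(1, 3), -1)
  # direct covariance formula oracle
  ora <- function(a, b) {
    n <- length(a)
    (sum(a * b) - n * mean(a) * mean(b)) /
      sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  }
  expect_equal(getR(1, 4), ora(vals10[, 1], vals10[, 4]), tolerance = 1e-12)
  # constant column: r = 0 and flagged, never NaN
  expect_equal(getR(1, 5), 0)
  expect_true(all(pp$constant[pp$i == 5 | pp$j == 5]))
  expect_false(any(is.na(pp$r)))
  expect_error(pearsonPairs(fm[1, ]), "at least 2")
})

test_that("angular features correlate through their sin/cos embedding", {
  set.seed(12)
  u <- rnorm(200, 0, 0.2)
  ang <- wrapAngle(170 + 40 * u)  # wraps across the boundary
  dist <- 10 + u
  vals <- cbind(dist, ang)
  desc <- data.frame(kind = c("ca_distance", "ligand_dihedral"),
                     chainA = c("R", NA), resA = c(10L, NA),
                     chainB = c("R", NA), resB = c(20L, NA),
                     atomRef = NA_integer_, quad = NA_character_,
                     units = c("angstrom", "degree"),
                     region = c("tm", "pocket"), label = c("d", "chi"),
                     stringsAsFactors = FALSE)
  fm <- MDAllostery:::makeFeatureMatrix(vals, desc, 0:199, "toy")
  pp <- pearsonPairs(fm)
  expect_true(pp$circular[1])
  expect_gt(abs(pp$r[1]), 0.9)  # naive Pearson on wrapped angles would fail
  expect_lt(abs(cor(dist, ang)), 0.6)
})

test_that("the r threshold filter is inclusive at the printed boundary", {
  pairs <- data.frame(i = 1:4, j = 5:8, r = c(0.85, 0.8499, -0.99, 0.99),
                      circular = FALSE, constant = FALSE)
  kept <- filterThreshold(pairs, 0.85)
  expect_equal(kept$r, c(0.85, 0.99))  # signed rule drops r = -0.99
  keptAbs <- filterThreshold(pairs, 0.85, absR = TRUE)
  expect_equal(keptAbs$r, c(0.85, -0.99, 0.99))
  set.seed(30)
  rnd <- data.frame(i = 1:50, j = 51:100, r = runif(50, -1, 1),
                    circular = FALSE, constant = FALSE)
  expect_equal(filterThreshold(rnd, 0.5)$r, rnd$r[rnd$r >= 0.5])
})

test_that("the separation filter keeps pairs with an 8+ residue gap", {
  vals <- matrix(rnorm(40) + 30, nrow = 10)
  fm <- mkFm(vals, "ca_distance", resA = c(100L, 100L, 100L, 120L),
             resB = c(110L, 111L, 110L, 130L))
  desc <- featureDescriptors(fm)
  pairs <- data.frame(i = c(1L, 1L), j = c(2L, 4L), r = 0.9,
                      circular = FALSE, constant = FALSE)
  kept <- filterSeparation(pairs, desc, 8L)
  # d_i=(100,110) vs d_j=(100,111): gaps 0 and 1 -> dropped
  # d_i=(100,110) vs d_j=(120,130): gaps 20 and 20 -> kept
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$j, 4L)
})

test_that("separation filter matches brute force and spares dihedral pairs", {
  set.seed(44)
  n <- 20
  resA <- sample(100:140, n, replace = TRUE)
  resB <- resA + sample(3:30, n, replace = TRUE)
  kind <- sample(c("ca_distance", "motif_dihedral"), n, replace = TRUE,
                 prob = c(0.8, 0.2))
  vals <- matrix(rnorm(10 * n) + 50, nrow = 10)
  desc <- data.frame(kind = kind, chainA = "R", resA = resA, chainB = "R",
                     resB = resB, atomRef = NA_integer_, quad = NA_character_,
                     units = ifelse(kind == "ca_distance", "angstrom",
                                    "degree"),
                     region = "tm", label = paste0("f", 1:n),
                     stringsAsFactors = FALSE)
  cmb <- utils::combn(n, 2)
  pairs <- data.frame(i = cmb[1, ], j = cmb[2, ], r = 0.9, circular = FALSE,
                      constant = FALSE)
  kept <- filterSeparation(pairs, desc, 8L)
  oracle <- apply(cmb, 2, function(p) {
    if (kind[p[1]] != "ca_distance" || kind[p[2]] != "ca_distance") return(TRUE)
    abs(resA[p[1]] - resA[p[2]]) >= 8 || abs(resB[p[1]] - resB[p[2]]) >= 8
  })
  expect_equal(nrow(kept), sum(oracle))
  expect_equal(paste(kept$i, kept$j),
               paste(cmb[1, oracle], cmb[2, oracle]))
})

test_that("the redundancy filter keeps the maximum-gap pair with tie-break", {
  vals <- matrix(rnorm(40) + 30, nrow = 10)
  fm <- mkFm(vals, "ca_distance",
             resA = c(151L, 175L, 175L, 175L),
             resB = c(160L, 176L, 178L, 179L))
  desc <- featureDescriptors(fm)
  # partners all in (TM2e, TM2e); gaps to anchor (151,160):
  # (175,176): max(24,16)=24; (175,178): max(24,18)=24; (175,179): max(24,19)=24
  # all tie at 24 -> lexicographically smallest partner (175,176) survives
  pairs <- data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L), r = 0.9,
                      circular = FALSE, constant = FALSE)
  kept <- filterRedundancy(pairs, desc, cb1rScheme())
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$j, 2L)
  # no shared-anchor groups: output equals input
  lone <- data.frame(i = 1L, j = 3L, r = 0.9, circular = FALSE,
                     constant = FALSE)
  expect_equal(filterRedundancy(lone, desc, cb1rScheme()), lone)
})

test_that("the redundancy filter matches a brute-force group-and-argmax oracle", {
  set.seed(55)
  sch <- cb1rScheme()
  n <- 25
  resA <- sample(c(113:144, 151:179, 186:220), n)
  resB <- pmin(resA + sample(2:12, n, replace = TRUE), 400L)
  ok <- resA < resB
  resA <- resA[ok]; resB <- resB[ok]; n <- length(resA)
  vals <- matrix(rnorm(8 * n) + 40, nrow = 8)
  fm <- mkFm(vals, "ca_distance", resA = resA, resB = resB)
  desc <- featureDescriptors(fm)
  cmb <- utils::combn(n, 2)
  keepIdx <- sample(ncol(cmb), 40)
  pairs <- data.frame(i = cmb[1, keepIdx], j = cmb[2, keepIdx], r = 0.9,
                      circular = FALSE, constant = FALSE)
  kept <- filterRedundancy(pairs, desc, sch)
  # oracle: independent implementation of the grouping rule
  seg <- function(r) assignSubsegment(sch, r)
  drop <- rep(FALSE, nrow(pairs))
  for (anchor in sort(unique(c(pairs$i, pairs$j)))) {
    rows <- which(!drop & (pairs$i == anchor | pairs$j == anchor))
    partners <- ifelse(pairs$i[rows] == anchor, pairs$j[rows], pairs$i[rows])
    if (length(rows) < 2) next
    grp <- paste(seg(desc$resA[partners]), seg(desc$resB[partners]))
    for (g in unique(grp)) {
      sel <- which(grp == g)
      if (length(sel) < 2) next
      gaps <- pmax(abs(desc$resA[anchor] - desc$resA[partners[sel]]),
                   abs(desc$resB[anchor] - desc$resB[partners[sel]]))
      win <- sel[gaps == max(gaps)]
      if (length(win) > 1) {
        o <- order(desc$resA[partners[win]], desc$resB[partners[win]])
        win <- win[o[1]]
      }
      drop[rows[sel[!sel %in% win]]] <- TRUE
    }
  }
  expect_equal(paste(kept$i, kept$j),
               paste(pairs$i[!drop], pairs$j[!drop]))
})

test_that("a single-replicate consensus equals that replicate's network", {
  rec <- sharedReceptor()
  p <- generatorParams(nFrames = 150L, noiseSigma = 0.3, seed = 14L,
    correlationPlants = list(list(r = 0.95, amplitude = 2, members = list(
      list(kind = "ca", residues = c(165L, 172L)),
      list(kind = "ca", residues = c(195L, 199L))))))
  traj <- generateTrajectory(rec$structure, p, manifest = rec$manifest)$trajectory
  params1 <- networkParams(nBoot = 1L, framesPerBoot = 300L, seed = 31L,
                           kMax = 2L, B = 4L, nInit = 3L)
  net1 <- bootstrapConsensus(traj, rec$manifest, rec$residueMap, cb1rScheme(),
                             params = params1)
  expect_true(all(!is.na(networkPairs(net1)$r_rep1)))
  expect_equal(networkPairs(net1)$meanR, networkPairs(net1)$r_rep1)
  # consensus is monotone in the number of replicates (shared child seeds)
  params3 <- networkParams(nBoot = 3L, framesPerBoot = 300L, seed = 31L,
                           kMax = 2L, B = 4L, nInit = 3L)
  net3 <- bootstrapConsensus(traj, rec$manifest, rec$residueMap, cb1rScheme(),
                             params = params3)
  expect_true(all(networkPairs(net3)$key %in% networkPairs(net1)$key))
})

test_that("TM involvement percentages follow the scheme residue counts", {
  sch <- cb1rScheme()
  empty <- methods::new("ConsensusNetwork", condition = "x",
                        pairs = data.frame(), nBoot = 1L, seeds = 1L,
                        params = list())
  inv0 <- tmInvolvement(empty, sch)
  expect_true(all(inv0$percent == 0))
  pairs <- data.frame(
    kindI = "ca_distance", chainAI = "R", resAI = 151L, chainBI = "R",
    resBI = 160L, labelI = "a", regionI = "tm",
    kindJ = "ca_distance", chainAJ = "R", resAJ = 164L, chainBJ = "R",
    resBJ = 310L, labelJ = "b", regionJ = "tm",
    key = "k", r_rep1 = 0.9, meanR = 0.9, stringsAsFactors = FALSE)
  net <- methods::new("ConsensusNetwork", condition = "x", pairs = pairs,
                      nBoot = 1L, seeds = 1L, params = list())
  inv <- tmInvolvement(net, sch)
  # TM2 has 29 residues (151..179); residues 151, 160, 164 participate
  expect_equal(inv$percent[inv$tm == 2], 100 * 3 / 29)
  expect_equal(inv$nInvolved[inv$tm == 5], 1L)  # residue 310
  expect_equal(inv$percent[inv$tm == 1], 0)
})

test_that("network export writes a deterministic roundtrippable edge list", {
  rec <- sharedReceptor()
  empty <- methods::new("ConsensusNetwork", condition = "x",
                        pairs = data.frame(), nBoot = 1L, seeds = 1L,
                        params = list())
  path <- tmpfile("net.tsv")
  exportNetwork(empty, path)
  e0 <- readNetworkEdges(path)
  expect_equal(nrow(e0), 0L)
  expect_true("meanR" %in% names(e0))
})
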