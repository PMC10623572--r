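# Pairwise RMSD, k-means, gap statistic and representative frames.

test_that("superposition RMSD is zero for identical and rigidly moved frames", {
  st <- toyStructure(nRes = 4, ligand = FALSE)
  set.seed(2)
  base <- st@coords + matrix(rnorm(12, 0, 2), ncol = 3)
  motion <- randomRigidMotion(5)
  frames <- list(base, sweep(base, 2, c(3, -2, 7), "+"),
                 applyRigid(base, motion))
  traj <- toyTrajectory(st, frames)
  m <- pairwiseRmsd(traj, selection = 1:4)
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  expect_lt(m[1, 2], 1e-6)   # translation removed
  expect_lt(m[1, 3], 1e-6)   # rotation+translation removed
  expect_equal(m, t(m), tolerance = 1e-6)
})

test_that("a known symmetric 4-atom displacement gives the closed-form RMSD", {
  st <- toyStructure(nRes = 4, ligand = FALSE)
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  # push opposite corners out along x by 1 A: centered, no net
  # rotation/translation, so RMSD = sqrt(mean(1, 0, 1, 0)) = sqrt(1/2)
  sq2 <- sq + rbind(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0), c(0, 0, 0))
  traj <- toyTrajectory(st, list(sq, sq2))
  m <- pairwiseRmsd(traj, 1:4)
  expect_lte(m[1, 2], sqrt(0.5) + 1e-9)  # optimal fit can only reduce it
  expect_equal(m[1, 2], hornRmsd(sq, sq2), tolerance = 1e-6)
})

test_that("pairwise RMSD agrees with a quaternion superposition oracle", {
  st <- toyStructure(nRes = 6, ligand = FALSE)
  set.seed(31)
  frames <- lapply(1:6, function(f) matrix(rnorm(18, 0, 3), ncol = 3))
  traj <- toyTrajectory(st, frames)
  m <- pairwiseRmsd(traj, 1:6)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], hornRmsd(frames[[i]], frames[[j]]),
                 tolerance = 1e-6)
  }
})

test_that("k-means W_k hits its closed-form extremes", {
  set.seed(8)
  x <- matrix(rnorm(24), ncol = 2)
  expect_equal(withinSS(kmeansCluster(x, nrow(x), seed = 1L)), 0)
  cl1 <- kmeansCluster(x, 1L, seed = 1L)
  expect_equal(withinSS(cl1), sum(scale(x, scale = FALSE)^2))
  expect_error(kmeansCluster(x, 13L, seed = 1L), "exceeds")
})

test_that("k-means recovers planted blobs, matching exhaustive search", {
  set.seed(21)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  x <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(rnorm(6, 0, 0.5), ncol = 2), 2, centers[b, ], "+")))
  cl <- kmeansCluster(x, 3L, seed = 2L)
  # exhaustive assignment search over all 3^9 labelings
  wOf <- function(lab) {
    sum(sapply(unique(lab), function(g) {
      m <- x[lab == g, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }))
  }
  labs <- as.matrix(expand.grid(rep(list(1:3), 9)))
  best <- min(apply(labs, 1, wOf))
  expect_equal(withinSS(cl), best, tolerance = 1e-9)
  truth <- rep(1:3, each = 3)
  expect_equal(length(unique(paste(truth, clusterLabels(cl)))), 3L)
})

test_that("W_k is non-increasing in k with best-of-restarts", {
  set.seed(77)
  x <- matrix(rnorm(60), ncol = 2)
  w <- sapply(1:6, function(k) withinSS(kmeansCluster(x, k, seed = 3L,
                                                      nInit = 10L)))
  expect_true(all(diff(w) <= 1e-9))
})

test_that("the gap decomposition holds exactly and degenerate data error", {
  set.seed(5)
  x <- matrix(rnorm(80), ncol = 2)
  g <- gapStatistic(x, kMax = 4L, B = 10L, seed = 9L)
  expect_equal(g@gap, g@eLogW - g@logW)
  expect_equal(g@sk, g@sdk * sqrt(1 + 1 / 10))
  expect_error(gapStatistic(matrix(1, 20, 2), kMax = 3L, B = 5L, seed = 1L),
               "degenerate")
})

test_that("well-separated Gaussian blobs select k = 3", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(2, 0), c(0, 2))  # separation 20 sigma
  x <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(rnorm(60, 0, 0.1), ncol = 2), 2, centers[b, ], "+")))
  g <- gapStatistic(x, kMax = 5L, B = 20L, seed = 17L)
  expect_equal(as.integer(selectK(g)), 3L)
})

test_that("gap agrees with the independent clusGap reference on one fixture", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             sweep(matrix(rnorm(40, 0, 0.2), ncol = 2), 2, c(4, 4), "+"))
  g <- gapStatistic(x, kMax = 4L, B = 60L, seed = 3L)
  ref <- cluster::clusGap(x, FUN = function(x, k) stats::kmeans(x, k,
                            nstart = 10), K.max = 4, B = 60,
                          spaceH0 = "original", d.power = 2,
                          verbose = FALSE)
  expect_equal(g@gap, unname(ref$Tab[, "gap"]), tolerance = 0.05)
})

test_that("the selection rule fires at the smallest qualifying k", {
  mk <- function(gap, sk) methods::new("GapResult", k = seq_along(gap),
    logW = rep(0, length(gap)), eLogW = gap, gap = gap,
    sdk = sk, sk = sk, B = 10L, seed = 1L)
  # huge s: rule fires immediately
  expect_equal(as.integer(selectK(mk(c(0, 1, 2), rep(10, 3)))), 1L)
  # strictly increasing gap, zero s: never fires -> kMax with a warning
  expect_warning(k <- selectK(mk(c(0, 1, 2), rep(0, 3))), "never fired")
  expect_equal(as.integer(k), 3L)
  expect_true(attr(k, "exhausted"))
})

test_that("representative frames back-map the largest cluster, deduplicated", {
  cl <- methods::new("ClusterResult", k = 2L,
                     labels = c(1L, 2L, 1L, 1L, 2L, 1L),
                     wk = 1, sizes = c(4L, 2L), centers = matrix(0, 2, 1))
  sample <- c(10L, 20L, 11L, 10L, 21L, 12L)
  expect_equal(representativeFrames(cl, sample), c(10L, 11L, 12L))
  one <- methods::new("ClusterResult", k = 1L, labels = rep(1L, 4),
                      wk = 1, sizes = 4L, centers = matrix(0, 1, 1))
  expect_equal(representativeFrames(one, c(5L, 5L, 3L, 9L)), c(3L, 5L, 9L))
  expect_error(representativeFrames(one, 1:3), "length mismatch")
})
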