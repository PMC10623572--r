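# RMSD-based clustering of trajectory frames with gap-statistic selection of
# the cluster number: pairwise backbone RMSD after optimal superposition,
# classical MDS embedding, k-means (k-means++ seeding, best of restarts),
# the gap statistic against a uniform bounding-box reference, and
# back-mapping of the representative cluster to original frames.

#' @useDynLib MDAllostery, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Atom indices of the TM-domain backbone
#'
#' Convenience selection for RMSD clustering: the Calpha atoms of every
#' residue covered by the subsegment scheme.
#'
#' @param structure a [Structure].
#' @param scheme a [SubsegmentScheme].
#' @param chain receptor chain id.
#' @param atomNames backbone atom names to select.
#' @return integer atom row indices.
#' @export
tmBackboneIndices <- function(structure, scheme = cb1rScheme(), chain = "R",
                              atomNames = "CA") {
  t <- schemeTable(scheme)
  res <- unlist(Map(seq.int, t$start, t$end))
  atomIndices(structure, chain = chain, resno = res, names = atomNames)
}

#' Pairwise RMSD matrix after optimal superposition
#'
#' Each entry is the minimal root-mean-square deviation of the selected
#' atoms over rigid-body superposition (rotation + translation) of one frame
#' onto the other.
#'
#' @param trajectory a [Trajectory].
#' @param selection integer atom row indices (e.g. [tmBackboneIndices()]).
#' @param frames frame ids (default all).
#' @return symmetric numeric matrix (Angstrom) with frame ids as dimnames.
#' @export
pairwiseRmsd <- function(trajectory, selection, frames = NULL) {
  stopIf(length(selection) == 0L, "selection resolves to zero atoms")
  fr <- frameIndex(trajectory, frames)
  stopIf(length(fr) < 2L, "need at least 2 frames")
  cube <- coordArray(trajectory)[selection, , fr, drop = FALSE]
  m <- pairwise_rmsd_cpp(cube)
  ids <- frameIds(trajectory)[fr]
  dimnames(m) <- list(ids, ids)
  m
}

#' Classical MDS embedding of an RMSD matrix
#'
#' Embeds frames in a Euclidean space that preserves the RMSD geometry.
#' Components are retained up to `varianceExplained` of the
#' positive-eigenvalue variance, but never beyond `maxDim` axes nor past
#' the point where an eigenvalue falls below `relEig` of the leading one:
#' an RMSD matrix dominated by isotropic fluctuations spreads its variance
#' over very many near-equal noise axes, and retaining them would drown the
#' conformational signal the clustering stage looks for.
#'
#' @param rmsd symmetric RMSD matrix.
#' @param varianceExplained fraction of variance to retain.
#' @param maxDim maximum embedding dimension.
#' @param relEig relative eigenvalue floor for retained axes.
#' @return numeric matrix, frames x dims.
#' @export
mdsEmbed <- function(rmsd, varianceExplained = 0.95, maxDim = 20L,
                     relEig = 0.05) {
  n <- nrow(rmsd)
  k <- min(n - 1L, maxDim)
  fit <- cmdscale(rmsd, k = k, eig = TRUE)
  ev <- pmax(fit$eig, 0)
  tot <- sum(ev)
  if (tot <= 0) return(matrix(0, nrow = n, ncol = 1L))
  p95 <- which(cumsum(ev[seq_len(k)]) / tot >= varianceExplained)
  p95 <- if (length(p95)) min(p95[1], ncol(fit$points)) else ncol(fit$points)
  floorOk <- which(ev[seq_len(k)] >= relEig * ev[1])
  pFloor <- if (length(floorOk)) max(floorOk) else 1L
  p <- max(min(p95, pFloor), 1L)
  pts <- fit$points[, seq_len(p), drop = FALSE]
  rownames(pts) <- rownames(rmsd)
  pts
}

# k-means++ seeding: first centre uniform, then D^2-weighted draws.
# Uses the current RNG stream.
kppInit <- function(data, k) {
  n <- nrow(data)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(data))
  i <- sample.int(n, 1L)
  centers[1L, ] <- data[i, ]
  if (k > 1L) {
    d2 <- colSums((t(data) - centers[1L, ])^2)
    for (c in seq.int(2L, k)) {
      if (all(d2 <= 0)) {
        stop("k exceeds the number of distinct points", call. = FALSE)
      }
      i <- sample.int(n, 1L, prob = d2)
      centers[c, ] <- data[i, ]
      d2 <- pmin(d2, colSums((t(data) - centers[c, ])^2))
    }
  }
  centers
}

#' K-means clustering with k-means++ seeding and restarts
#'
#' Lloyd/Hartigan-Wong iterations via [stats::kmeans()] from k-means++
#' initial centres; the best of `nInit` restarts by lowest within-cluster
#' sum of squares `W_k` is returned. Reproducible for a fixed seed.
#'
#' @param data numeric matrix, points x dims.
#' @param k number of clusters (`1 <= k <= nrow(data)`).
#' @param seed RNG seed.
#' @param nInit number of restarts.
#' @return a [ClusterResult].
#' @export
kmeansCluster <- function(data, k, seed = 1L, nInit = 10L) {
  data <- as.matrix(data)
  stopIf(k < 1L, "k must be >= 1")
  stopIf(k > nrow(data), "k exceeds the number of points")
  if (k == nrow(data)) {
    stopIf(anyDuplicated(data) > 0, "k exceeds the number of distinct points")
    return(new("ClusterResult", k = as.integer(k),
               labels = seq_len(nrow(data)), wk = 0,
               sizes = rep(1L, nrow(data)), centers = unname(data)))
  }
  fit <- withSeed(seed, {
    best <- NULL
    for (r in seq_len(nInit)) {
      centers <- kppInit(data, k)
      f <- suppressWarnings(
        stats::kmeans(data, centers = centers, iter.max = 100L))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  new("ClusterResult", k = as.integer(k), labels = as.integer(fit$cluster),
      wk = fit$tot.withinss, sizes = as.integer(fit$size),
      centers = unname(fit$centers))
}

logWk <- function(data, k, nInit) {
  if (k == 1L) {
    w <- sum(scale(data, scale = FALSE)^2)
  } else {
    best <- Inf
    for (r in seq_len(nInit)) {
      centers <- kppInit(data, k)
      f <- suppressWarnings(
        stats::kmeans(data, centers = centers, iter.max = 100L))
      best <- min(best, f$tot.withinss)
    }
    w <- best
  }
  stopIf(w <= 0, "degenerate data: W_k is zero, log W_k undefined")
  log(w)
}

#' Gap statistic for cluster-number estimation
#'
#' Compares the observed `log W_k` against its expectation under `B`
#' Monte-Carlo reference data sets drawn uniformly over the data's
#' per-dimension bounding box:
#' `Gap(k) = E*[log W_k] - log W_k`, with simulation error
#' `s_k = sd_k * sqrt(1 + 1/B)`.
#'
#' @param data numeric matrix, points x dims.
#' @param kMax largest candidate cluster number (`>= 2`).
#' @param B number of reference replicates (`>= 2`).
#' @param seed RNG seed.
#' @param nInit k-means restarts per fit.
#' @return a [GapResult].
#' @export
gapStatistic <- function(data, kMax = 10L, B = 50L, seed = 1L, nInit = 10L) {
  data <- as.matrix(data)
  stopIf(kMax < 2L, "kMax must be >= 2")
  stopIf(B < 2L, "B must be >= 2")
  stopIf(all(apply(data, 2, function(c) diff(range(c)) == 0)),
         "degenerate data: all points identical, W_k undefined in log")
  ks <- seq_len(kMax)
  lo <- apply(data, 2, min); hi <- apply(data, 2, max)
  res <- withSeed(seed, {
    obs <- vapply(ks, function(k) logWk(data, k, nInit), numeric(1))
    ref <- matrix(NA_real_, nrow = kMax, ncol = B)
    for (b in seq_len(B)) {
      refData <- vapply(seq_along(lo),
                        function(j) runif(nrow(data), lo[j], hi[j]),
                        numeric(nrow(data)))
      ref[, b] <- vapply(ks, function(k) logWk(refData, k, nInit), numeric(1))
    }
    list(obs = obs, ref = ref)
  })
  eLogW <- rowMeans(res$ref)
  sdk <- sqrt(rowMeans((res$ref - eLogW)^2))
  sk <- sdk * sqrt(1 + 1 / B)
  new("GapResult", k = ks, logW = res$obs, eLogW = eLogW,
      gap = eLogW - res$obs, sdk = sdk, sk = sk, B = as.integer(B),
      seed = as.integer(seed))
}

#' Select the cluster number from a gap result
#'
#' The smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}`. If no `k` satisfies
#' the rule, returns `kMax` with a warning and attribute
#' `exhausted = TRUE`.
#'
#' @param gapResult a [GapResult].
#' @return integer `k` (with attribute `exhausted` when the rule never
#'   fired).
#' @export
selectK <- function(gapResult) {
  g <- gapResult@gap; s <- gapResult@sk
  kMax <- max(gapResult@k)
  stopIf(kMax < 2L, "gap result must cover k up to at least 2")
  for (k in seq_len(kMax - 1L)) {
    if (g[k] >= g[k + 1L] - s[k + 1L]) {
      out <- as.integer(k)
      attr(out, "exhausted") <- FALSE
      return(out)
    }
  }
  warning("gap selection rule never fired; returning kMax = ", kMax,
          call. = FALSE)
  out <- as.integer(kMax)
  attr(out, "exhausted") <- TRUE
  out
}

#' Original frames of the representative (largest) cluster
#'
#' Maps the bootstrap sample positions assigned to the most populated
#' cluster back to original frame ids, deduplicated and sorted. These
#' frames feed every downstream per-condition analysis.
#'
#' @param clusterResult a [ClusterResult] fitted on the sampled frames.
#' @param sample the frame-id vector the clustering was run on (one id per
#'   clustered point, as produced by [sampleFrames()]).
#' @return sorted unique integer frame ids.
#' @export
representativeFrames <- function(clusterResult, sample) {
  labels <- clusterLabels(clusterResult)
  stopIf(length(labels) != length(sample),
         "label/sample length mismatch: ", length(labels), " vs ",
         length(sample))
  sizes <- clusterResult@sizes
  chosen <- which(sizes == max(sizes))[1]
  sort(unique(sample[labels == chosen]))
}
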