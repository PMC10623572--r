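# Correlation-based allosteric network analysis: feature assembly over the
# three regions (ligand pocket, TM domain, receptor/G-alpha interface),
# Pearson correlation over all feature pairs, the three filtering criteria
# (r threshold, sequence separation, subsegment redundancy), and bootstrap
# consensus across repeated clustering + network runs.

#' Network analysis parameters
#'
#' Defaults are the analysis constants of the pipeline: `r >= 0.85`
#' threshold, 12 Angstrom mean-distance pre-filter, sequence separation 8,
#' 10 bootstrap replicates of 10,000 resampled frames.
#'
#' @param rMin Pearson threshold (signed unless `absR`).
#' @param absR apply the threshold to `abs(r)` instead of signed `r`.
#' @param maxMeanDistance Angstrom pre-filter for distance features.
#' @param minSep minimum residue-number separation (filter 2).
#' @param nBoot bootstrap replicates.
#' @param framesPerBoot frames resampled per replicate.
#' @param seed master seed; child seeds are derived per replicate.
#' @param kMax,B,nInit gap-statistic / k-means settings per replicate.
#' @param varianceExplained,maxDim MDS embedding settings.
#' @param contactCutoff,contactPrevalence pocket feature membership rule.
#' @return a named list of class `networkParams`.
#' @export
networkParams <- function(rMin = 0.85, absR = FALSE, maxMeanDistance = 12,
                          minSep = 8L, nBoot = 10L, framesPerBoot = 10000L,
                          seed = 1L, kMax = 10L, B = 50L, nInit = 10L,
                          varianceExplained = 0.95, maxDim = 20L,
                          contactCutoff = 6, contactPrevalence = 0.5) {
  stopIf(rMin <= 0 || rMin > 1, "rMin must be in (0, 1]")
  stopIf(minSep < 0, "minSep must be >= 0")
  stopIf(nBoot < 1, "nBoot must be >= 1")
  structure(list(rMin = rMin, absR = absR, maxMeanDistance = maxMeanDistance,
                 minSep = as.integer(minSep), nBoot = as.integer(nBoot),
                 framesPerBoot = as.integer(framesPerBoot),
                 seed = as.integer(seed), kMax = as.integer(kMax),
                 B = as.integer(B), nInit = as.integer(nInit),
                 varianceExplained = varianceExplained,
                 maxDim = as.integer(maxDim), contactCutoff = contactCutoff,
                 contactPrevalence = contactPrevalence),
            class = "networkParams")
}

#' Assemble the three-region feature matrix
#'
#' Concatenates pocket features (ligand polar-atom distances plus ligand
#' head dihedrals), TM features (Calpha-Calpha distances plus conserved
#' motif chi1 dihedrals) and interface features (receptor/G-alpha Calpha
#' distances), each tagged by region. Empty regions warn; an entirely empty
#' assembly errors.
#'
#' @param trajectory a [Trajectory].
#' @param frames representative frame ids from the clustering stage.
#' @param manifest a [LigandManifest].
#' @param residueMap residue map data.frame.
#' @param scheme a [SubsegmentScheme].
#' @param receptorChain,gChain chain ids.
#' @param params a [networkParams()] list.
#' @return a [FeatureMatrix].
#' @export
assembleFeatures <- function(trajectory, frames, manifest, residueMap,
                             scheme, receptorChain = "R", gChain = "G",
                             params = networkParams()) {
  tmRes <- intersect(
    unlist(Map(seq.int, schemeTable(scheme)$start, schemeTable(scheme)$end)),
    atomTable(trajectory)$resno[atomTable(trajectory)$chain == receptorChain])
  pocket <- combineFeatures(
    ligandPocketDistances(trajectory, manifest, frames = frames,
                          cutoff = params$contactCutoff,
                          prevalence = params$contactPrevalence,
                          receptorChain = receptorChain),
    ligandHeadDihedrals(trajectory, manifest, frames = frames))
  tm <- combineFeatures(
    caDistanceFeatures(trajectory, tmRes, chain = receptorChain,
                       frames = frames,
                       maxMeanDistance = params$maxMeanDistance),
    motifDihedrals(trajectory, residueMap, frames = frames,
                   receptorChain = receptorChain))
  iface <- suppressWarnings(
    interfaceDistances(trajectory, receptorChain, gChain, frames = frames,
                       maxMeanDistance = params$maxMeanDistance))
  counts <- c(pocket = nrow(pocket), tm = nrow(tm), interface = nrow(iface))
  for (nm in names(counts)) {
    if (counts[nm] == 0L) warning("empty feature region: ", nm, call. = FALSE)
  }
  stopIf(sum(counts) == 0L, "all feature regions are empty")
  combineFeatures(pocket, tm, iface)
}

# Feature-level correlation matrix from transformed-column correlations:
# distance/distance pairs use plain Pearson r; pairs involving an angular
# feature take the component (sin or cos) with the largest absolute r,
# keeping its sign and a circular-derived flag. Fully vectorised: the
# sin/cos alternative reduces to an elementwise max-|r| pick between two
# candidate submatrices.
featureCor <- function(fm) {
  desc <- featureDescriptors(fm)
  vals <- featureValues(fm)
  p <- nrow(desc)
  ang <- desc$units == "degree"
  # candidate column set 1: linear values, sin for angles
  # candidate column set 2: linear values, cos for angles
  m1 <- vals; m2 <- vals
  if (any(ang)) {
    r <- vals[, ang, drop = FALSE] * pi / 180
    m1[, ang] <- sin(r); m2[, ang] <- cos(r)
  }
  n <- nrow(m1)
  standardize <- function(m) {
    mu <- colMeans(m)
    mc <- sweep(m, 2, mu)
    s <- sqrt(colSums(mc^2) / (n - 1))
    const <- s == 0 | !is.finite(s)
    s[const] <- 1
    list(z = sweep(mc, 2, s * sqrt(n - 1), "/"), const = const)
  }
  z1 <- standardize(m1)
  r <- crossprod(z1$z)  # Pearson r via BLAS
  if (any(ang)) {
    z2 <- standardize(m2)
    # cosine-channel candidates only matter for pairs involving an angular
    # feature; restrict the second crossprod to those columns
    r22 <- crossprod(z2$z, z2$z[, ang, drop = FALSE])  # p x n_ang
    rA <- r[, ang, drop = FALSE]
    pick <- abs(r22) > abs(rA)
    rA[pick] <- r22[pick]
    r[, ang] <- rA
    r[ang, ] <- t(rA)
    circ <- outer(ang, ang, "|")
    constFeat <- ifelse(ang, z1$const & z2$const, z1$const)
  } else {
    circ <- matrix(FALSE, p, p)
    constFeat <- z1$const
  }
  r[constFeat, ] <- 0; r[, constFeat] <- 0
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  list(r = r, circular = circ, constant = constFeat)
}

#' Pearson correlation over all feature pairs
#'
#' Standard Pearson r for every unordered feature pair `i < j`. Angular
#' features are correlated on their sine/cosine embedding, taking the
#' component with the maximum `abs(r)` (flagged `circular`). Constant
#' features yield `r = 0` with a flag rather than `NaN`.
#'
#' @param fm a [FeatureMatrix] with at least 2 features and 3 frames.
#' @return data.frame with columns `i`, `j` (feature row indices), `r`,
#'   `circular`, `constant`.
#' @export
pearsonPairs <- function(fm) {
  stopIf(nrow(fm) < 2L, "need at least 2 features")
  stopIf(ncol(fm) < 3L, "need at least 3 frames")
  fc <- featureCor(fm)
  p <- nrow(fm)
  idx <- which(upper.tri(fc$r), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], r = fc$r[idx],
             circular = fc$circular[idx],
             constant = fc$constant[idx[, 1]] | fc$constant[idx[, 2]])
}

# Threshold directly on the feature correlation matrix and materialise only
# the surviving pairs (equivalent to pearsonPairs + filterThreshold, without
# allocating the all-pairs list).
thresholdedPairs <- function(fm, rMin = 0.85, absR = FALSE) {
  fc <- featureCor(fm)
  keep <- if (absR) abs(fc$r) >= rMin else fc$r >= rMin
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], r = fc$r[idx],
             circular = fc$circular[idx],
             constant = fc$constant[idx[, 1]] | fc$constant[idx[, 2]])
}

#' Network filter 1: correlation threshold
#'
#' Keeps pairs with signed `r >= rMin` (or `abs(r) >= rMin` when `absR`);
#' the boundary is inclusive.
#'
#' @param pairs data.frame from [pearsonPairs()].
#' @param rMin threshold.
#' @param absR threshold the absolute value instead.
#' @return the surviving pairs.
#' @export
filterThreshold <- function(pairs, rMin = 0.85, absR = FALSE) {
  keep <- if (absR) abs(pairs$r) >= rMin else pairs$r >= rMin
  pairs[keep, , drop = FALSE]
}

# Residues of a distance feature as (X, Y) with chain roles; X < Y holds
# within one numbering space (ca features); interface features keep the
# receptor residue as X and the G-alpha residue as Y.
isDistanceKind <- function(kind) {
  kind %in% c("ca_distance", "interface_distance")
}

#' Network filter 2: sequence separation
#'
#' Applies to distance-distance pairs only (pairs involving a dihedral or a
#' ligand polar-atom distance pass unfiltered): a pair of distances
#' `d_i = X_i - Y_i`, `d_j = X_j - Y_j` is kept iff
#' `|X_i - X_j| >= minSep` or `|Y_i - Y_j| >= minSep`, comparing residues
#' within the same chain role only (receptor with receptor, G-alpha with
#' G-alpha); a pair with no comparable residue slot passes.
#'
#' @param pairs data.frame from [filterThreshold()].
#' @param descriptors feature descriptors ([featureDescriptors()]).
#' @param minSep minimum separation.
#' @return the surviving pairs.
#' @export
filterSeparation <- function(pairs, descriptors, minSep = 8L) {
  if (nrow(pairs) == 0L) return(pairs)
  d <- descriptors
  keep <- vapply(seq_len(nrow(pairs)), function(t) {
    i <- pairs$i[t]; j <- pairs$j[t]
    if (!isDistanceKind(d$kind[i]) || !isDistanceKind(d$kind[j])) return(TRUE)
    cmp <- logical(0)
    if (identical(d$chainA[i], d$chainA[j])) {
      cmp <- c(cmp, abs(d$resA[i] - d$resA[j]) >= minSep)
    }
    if (identical(d$chainB[i], d$chainB[j])) {
      cmp <- c(cmp, abs(d$resB[i] - d$resB[j]) >= minSep)
    }
    if (!length(cmp)) return(TRUE)
    any(cmp)
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

# Subsegment of each residue slot of a distance feature; receptor residues
# through the scheme (loop pseudo-segment outside every range), G-alpha
# residues through the gSegments block table (single "Galpha" block by
# default).
slotSegment <- function(desc, scheme, gSegments = NULL, gChain = "G") {
  segFor <- function(chain, res) {
    out <- rep(NA_character_, length(res))
    isG <- !is.na(chain) & chain == gChain
    out[isG & !is.na(res)] <- if (is.null(gSegments)) "Galpha" else {
      vapply(res[isG & !is.na(res)], function(r) {
        hit <- gSegments$name[r >= gSegments$start & r <= gSegments$end]
        if (length(hit)) hit[1] else "Galpha"
      }, character(1))
    }
    isR <- !is.na(chain) & chain != gChain & !is.na(res)
    out[isR] <- assignSubsegment(scheme, res[isR])
    out
  }
  list(segA = segFor(desc$chainA, desc$resA),
       segB = segFor(desc$chainB, desc$resB))
}

#' Network filter 3: subsegment redundancy
#'
#' Among surviving distance-distance pairs that share one common feature
#' `d_i` and whose partners `d_j` are formed by residues from the same
#' ordered pair of TM subsegments, only the pair with the maximum residue
#' number difference `max(|X_i - X_j|, |Y_i - Y_j|)` is kept; ties break to
#' the lexicographically smallest partner `(X_j, Y_j)`. Pairs involving a
#' dihedral or pocket feature pass unfiltered. Residues outside every
#' subsegment are grouped under a `"loop"` pseudo-segment; G-alpha residues
#' under configurable blocks (one `"Galpha"` block by default).
#'
#' @param pairs data.frame of surviving pairs.
#' @param descriptors feature descriptors.
#' @param scheme a [SubsegmentScheme].
#' @param gSegments optional data.frame (`name`, `start`, `end`) of G-alpha
#'   blocks.
#' @param gChain G-alpha chain id.
#' @return the surviving pairs.
#' @export
filterRedundancy <- function(pairs, descriptors, scheme, gSegments = NULL,
                             gChain = "G") {
  if (nrow(pairs) == 0L) return(pairs)
  d <- descriptors
  seg <- slotSegment(d, scheme, gSegments, gChain)
  isDist <- isDistanceKind(d$kind)
  drop <- rep(FALSE, nrow(pairs))
  gapOf <- function(a, b) {  # max comparable residue gap between features
    g <- -Inf
    if (identical(d$chainA[a], d$chainA[b])) {
      g <- max(g, abs(d$resA[a] - d$resA[b]))
    }
    if (identical(d$chainB[a], d$chainB[b])) {
      g <- max(g, abs(d$resB[a] - d$resB[b]))
    }
    g
  }
  features <- sort(unique(c(pairs$i, pairs$j)))
  for (anchor in features) {
    if (!isDist[anchor]) next
    rows <- which(!drop & (pairs$i == anchor | pairs$j == anchor))
    if (length(rows) < 2L) next
    partners <- ifelse(pairs$i[rows] == anchor, pairs$j[rows], pairs$i[rows])
    ok <- isDist[partners]
    rows <- rows[ok]; partners <- partners[ok]
    if (length(rows) < 2L) next
    key <- paste(seg$segA[partners], seg$segB[partners], sep = "|")
    for (grp in split(seq_along(rows), key)) {
      if (length(grp) < 2L) next
      gaps <- vapply(partners[grp], function(p) gapOf(anchor, p), numeric(1))
      best <- grp[gaps == max(gaps)]
      if (length(best) > 1L) {
        ordKey <- order(d$resA[partners[best]], d$resB[partners[best]])
        best <- best[ordKey[1]]
      }
      drop[rows[setdiff(grp, best)]] <- TRUE
    }
  }
  pairs[!drop, , drop = FALSE]
}

# Stable signature of a feature descriptor, used to match features across
# bootstrap replicates.
featureKey <- function(desc) {
  paste(desc$kind, desc$chainA, desc$resA, desc$chainB, desc$resB,
        desc$atomRef, desc$quad, sep = "|")
}

pairKeys <- function(pairs, desc) {
  k <- featureKey(desc)
  paste(k[pairs$i], k[pairs$j], sep = " ~ ")
}

#' Bootstrap-consensus correlation network for one condition
#'
#' Repeats the full per-condition pipeline `nBoot` times with derived child
#' seeds -- resample frames with replacement, cluster in the MDS embedding
#' of the TM-backbone RMSD matrix with gap-statistic k selection, take the
#' representative (largest) cluster's original frames, assemble the
#' three-region features, correlate and apply filters 1-3 -- and intersects
#' the surviving pairs across all replicates.
#'
#' The RMSD matrix and its MDS embedding are computed once on the
#' trajectory's frames; each replicate indexes its resampled frame ids into
#' that embedding.
#'
#' @param trajectory a [Trajectory].
#' @param manifest a [LigandManifest].
#' @param residueMap residue map data.frame.
#' @param scheme a [SubsegmentScheme].
#' @param receptorChain,gChain chain ids.
#' @param params a [networkParams()] list.
#' @param selection RMSD atom selection (default TM backbone Calpha).
#' @param gSegments optional G-alpha block table for filter 3.
#' @param rmsd,embedding optional precomputed RMSD matrix / MDS embedding
#'   over all trajectory frames (recomputed when `NULL`).
#' @return a [ConsensusNetwork].
#' @export
bootstrapConsensus <- function(trajectory, manifest, residueMap, scheme,
                               receptorChain = "R", gChain = "G",
                               params = networkParams(), selection = NULL,
                               gSegments = NULL, rmsd = NULL,
                               embedding = NULL) {
  if (is.null(selection)) {
    selection <- tmBackboneIndices(trajectory@structure, scheme,
                                   chain = receptorChain)
  }
  if (is.null(rmsd) && is.null(embedding)) {
    rmsd <- pairwiseRmsd(trajectory, selection)
  }
  emb <- if (is.null(embedding)) {
    mdsEmbed(rmsd, params$varianceExplained, params$maxDim)
  } else embedding
  ids <- frameIds(trajectory)
  seeds <- vapply(seq_len(params$nBoot), function(b)
    deriveSeed(params$seed, b), integer(1))
  repKeys <- list(); repR <- list(); repDesc <- list(); repPairs <- list()
  for (b in seq_len(params$nBoot)) {
    sampleIds <- sampleFrames(trajectory, n = params$framesPerBoot,
                              seed = seeds[b])
    pts <- emb[match(sampleIds, ids), , drop = FALSE]
    gap <- gapStatistic(pts, kMax = params$kMax, B = params$B,
                        seed = deriveSeed(seeds[b], 1L),
                        nInit = params$nInit)
    k <- suppressWarnings(selectK(gap))
    cl <- kmeansCluster(pts, k, seed = deriveSeed(seeds[b], 2L),
                        nInit = params$nInit)
    repFrames <- representativeFrames(cl, sampleIds)
    fm <- assembleFeatures(trajectory, repFrames, manifest, residueMap,
                           scheme, receptorChain, gChain, params)
    stopIf(nrow(fm) == 0L, "replicate ", b, " produced an empty feature matrix")
    desc <- featureDescriptors(fm)
    pairs <- thresholdedPairs(fm, params$rMin, params$absR)
    pairs <- filterSeparation(pairs, desc, params$minSep)
    pairs <- filterRedundancy(pairs, desc, scheme, gSegments, gChain)
    keys <- pairKeys(pairs, desc)
    repKeys[[b]] <- keys
    repR[[b]] <- setNames(pairs$r, keys)
    repDesc[[b]] <- desc
    repPairs[[b]] <- pairs
  }
  consensus <- Reduce(intersect, repKeys)
  consensus <- sort(consensus)
  if (length(consensus)) {
    d1 <- repDesc[[1]]
    p1 <- repPairs[[1]][match(consensus, repKeys[[1]]), ]
    base <- data.frame(
      kindI = d1$kind[p1$i], chainAI = d1$chainA[p1$i], resAI = d1$resA[p1$i],
      chainBI = d1$chainB[p1$i], resBI = d1$resB[p1$i],
      labelI = d1$label[p1$i], regionI = d1$region[p1$i],
      kindJ = d1$kind[p1$j], chainAJ = d1$chainA[p1$j], resAJ = d1$resA[p1$j],
      chainBJ = d1$chainB[p1$j], resBJ = d1$resB[p1$j],
      labelJ = d1$label[p1$j], regionJ = d1$region[p1$j],
      key = consensus, stringsAsFactors = FALSE)
    rmat <- vapply(seq_len(params$nBoot),
                   function(b) unname(repR[[b]][consensus]),
                   numeric(length(consensus)))
    rmat <- matrix(rmat, nrow = length(consensus))
    colnames(rmat) <- paste0("r_rep", seq_len(params$nBoot))
    base <- cbind(base, rmat)
    base$meanR <- rowMeans(rmat)
  } else {
    base <- data.frame()
  }
  new("ConsensusNetwork", condition = conditionLabel(trajectory),
      pairs = base, nBoot = params$nBoot, seeds = seeds,
      params = unclass(params))
}

#' Per-TM involvement in the consensus network
#'
#' For each transmembrane helix, the percentage of its residues (per the
#' scheme) participating in at least one consensus pair.
#'
#' @param network a [ConsensusNetwork].
#' @param scheme a [SubsegmentScheme].
#' @param gChain G-alpha chain id (its residues are never counted).
#' @return data.frame with columns `tm`, `nResidues`, `nInvolved`,
#'   `percent`.
#' @export
tmInvolvement <- function(network, scheme, gChain = "G") {
  p <- networkPairs(network)
  involved <- integer(0)
  if (nrow(p) > 0) {
    pick <- function(chain, res)
      res[!is.na(res) & !is.na(chain) & chain != gChain]
    involved <- unique(c(pick(p$chainAI, p$resAI), pick(p$chainBI, p$resBI),
                         pick(p$chainAJ, p$resAJ), pick(p$chainBJ, p$resBJ)))
  }
  t <- schemeTable(scheme)
  tms <- sort(unique(t$tm))
  out <- data.frame(tm = tms, nResidues = NA_integer_,
                    nInvolved = NA_integer_, percent = NA_real_)
  for (i in seq_along(tms)) {
    res <- tmResidues(scheme, tms[i])
    out$nResidues[i] <- length(res)
    out$nInvolved[i] <- length(intersect(res, involved))
    out$percent[i] <- 100 * out$nInvolved[i] / out$nResidues[i]
  }
  out
}

#' Export / read a consensus network edge list
#'
#' Tab-separated edge list with stable column order and deterministic row
#' order (sorted by pair key).
#'
#' @param network a [ConsensusNetwork].
#' @param path output TSV path.
#' @return `path` invisibly (`exportNetwork`); the edge data.frame
#'   (`readNetworkEdges`).
#' @export
exportNetwork <- function(network, path) {
  p <- networkPairs(network)
  if (nrow(p) == 0L) {
    p <- data.frame(kindI = character(), chainAI = character(),
                    resAI = integer(), chainBI = character(),
                    resBI = integer(), labelI = character(),
                    regionI = character(), kindJ = character(),
                    chainAJ = character(), resAJ = integer(),
                    chainBJ = character(), resBJ = integer(),
                    labelJ = character(), regionJ = character(),
                    key = character(), meanR = numeric())
  } else {
    p <- p[order(p$key), , drop = FALSE]
  }
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportNetwork
#' @export
readNetworkEdges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
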