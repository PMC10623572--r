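# Per-frame quantitative features: Calpha-Calpha distances, ligand-pocket
# polar-atom distances, receptor/G-alpha interface distances, and side-chain
# / ligand dihedral angles. All extractors return a FeatureMatrix.

emptyDescriptors <- function() {
  data.frame(kind = character(), chainA = character(), resA = integer(),
             chainB = character(), resB = integer(), atomRef = integer(),
             quad = character(), units = character(), region = character(),
             label = character(), stringsAsFactors = FALSE)
}

# Build a FeatureMatrix from a frames x features value matrix and a
# descriptor data.frame.
makeFeatureMatrix <- function(values, descriptors, frameIds, condition) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    rowData = S4Vectors::DataFrame(descriptors),
    colData = S4Vectors::DataFrame(frameId = as.integer(frameIds)))
  S4Vectors::metadata(se)$condition <- condition
  new("FeatureMatrix", se)
}

#' Combine feature matrices over the same frames
#'
#' @param ... [FeatureMatrix] objects sharing identical frame ids.
#' @return a [FeatureMatrix] with the features stacked.
#' @export
combineFeatures <- function(...) {
  fms <- list(...)
  fms <- fms[!vapply(fms, is.null, logical(1))]
  stopIf(length(fms) == 0L, "no feature matrices to combine")
  out <- do.call(rbind, lapply(fms, function(x) as(x, "SummarizedExperiment")))
  out <- new("FeatureMatrix", out)
  S4Vectors::metadata(out)$condition <- conditionLabel(fms[[1]])
  out
}

# Resolve frames argument: NULL means all frames; otherwise frame ids.
frameIndex <- function(trajectory, frames) {
  if (is.null(frames)) return(seq_len(nFrames(trajectory)))
  idx <- match(frames, frameIds(trajectory))
  stopIf(anyNA(idx), "unknown frame id(s): ",
         paste(head(frames[is.na(idx)], 5), collapse = ", "))
  idx
}

# Atom row indices for (chain, resno) with optional atom-name filter.
atomIndices <- function(structure, chain = NULL, resno = NULL, names = NULL,
                        heavyOnly = FALSE) {
  a <- atomTable(structure)
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(names)) sel <- sel & a$name %in% names
  if (heavyOnly) sel <- sel & toupper(a$element) != "H"
  which(sel)
}

caIndexFor <- function(structure, chain, resno) {
  idx <- vapply(resno, function(r) {
    i <- atomIndices(structure, chain = chain, resno = r, names = "CA")
    if (length(i) != 1L) {
      stop("residue ", r, " (chain ", chain, ") has no unique CA atom",
           call. = FALSE)
    }
    i
  }, integer(1))
  idx
}

# Per-frame Euclidean distance between two atoms (vectorised over frames).
atomDistSeries <- function(coords, i, j, frames) {
  d <- coords[i, , frames, drop = FALSE] - coords[j, , frames, drop = FALSE]
  sqrt(colSums(matrix(d, nrow = 3L)^2))
}

# Per-frame minimum distance between an atom set and a single atom.
minDistSeries <- function(coords, idxSet, j, frames) {
  out <- NULL
  for (i in idxSet) {
    d <- atomDistSeries(coords, i, j, frames)
    out <- if (is.null(out)) d else pmin(out, d)
  }
  out
}

#' Dihedral angle series for an atom quadruple
#'
#' IUPAC sign convention, degrees in (-180, 180]: 0 for cis (eclipsed),
#' 180 for trans.
#'
#' @param trajectory a [Trajectory].
#' @param quad integer vector of 4 atom ids.
#' @param frames frame ids (default all).
#' @return numeric vector, one angle per frame.
#' @export
dihedralSeries <- function(trajectory, quad, frames = NULL) {
  stopIf(length(quad) != 4L || anyDuplicated(quad) > 0,
         "dihedral needs 4 distinct atoms")
  idx <- match(quad, atomTable(trajectory)$id)
  stopIf(anyNA(idx), "unknown atom id(s): ", paste(quad[is.na(idx)], collapse = ", "))
  fr <- frameIndex(trajectory, frames)
  co <- coordArray(trajectory)
  p <- lapply(idx, function(i) matrix(co[i, , fr], nrow = 3L))
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  cross <- function(a, b) {
    rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
          a[3, ] * b[1, ] - a[1, ] * b[3, ],
          a[1, ] * b[2, ] - a[2, ] * b[1, ])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- sqrt(colSums(b2^2))
  x <- colSums(n1 * n2)
  y <- colSums(cross(n1, n2) * b2) / b2n
  wrapAngle(atan2(y, x) * 180 / pi)
}

#' Calpha-Calpha distance features within a residue set
#'
#' One feature per unordered residue pair (canonically ordered `resA < resB`)
#' whose mean Calpha-Calpha distance over the analysed frames does not exceed
#' `maxMeanDistance` (12 Angstrom by default, the network pre-filter).
#'
#' @param trajectory a [Trajectory].
#' @param residues integer residue numbers (all must have a CA atom).
#' @param chain chain id holding the residues.
#' @param frames frame ids to analyse (default all).
#' @param maxMeanDistance Angstrom cutoff on the mean distance.
#' @param region region tag recorded in the descriptors.
#' @return a [FeatureMatrix] of distances in Angstrom.
#' @export
caDistanceFeatures <- function(trajectory, residues, chain = "R",
                               frames = NULL, maxMeanDistance = 12,
                               region = "tm") {
  residues <- sort(unique(as.integer(residues)))
  ca <- caIndexFor(trajectory@structure, chain, residues)
  fr <- frameIndex(trajectory, frames)
  cube <- coordArray(trajectory)[ca, , fr, drop = FALSE]
  n <- length(residues)
  if (n >= 2L) {
    pi_ <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pj_ <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)))
  } else {
    pi_ <- integer(0); pj_ <- integer(0)
  }
  res <- pair_distance_filter_cpp(cube, cube, pi_ - 1L, pj_ - 1L,
                                  maxMeanDistance)
  keepA <- residues[pi_[res$kept]]
  keepB <- residues[pj_[res$kept]]
  vals <- if (res$nKept > 0) {
    res$values[, seq_len(res$nKept), drop = FALSE]
  } else matrix(0, nrow = length(fr), ncol = 0)
  desc <- if (length(keepA) == 0L) emptyDescriptors() else data.frame(
    kind = rep("ca_distance", length(keepA)), chainA = chain, resA = keepA,
    chainB = chain, resB = keepB, atomRef = NA_integer_, quad = NA_character_,
    units = "angstrom", region = region,
    label = sprintf("dCA(%d,%d)", keepA, keepB), stringsAsFactors = FALSE)
  makeFeatureMatrix(vals, if (nrow(desc)) desc else emptyDescriptors(),
                    frameIds(trajectory)[fr], conditionLabel(trajectory))
}

#' Ligand-pocket polar-atom distance features
#'
#' For each polar atom of the ligand manifest, residues whose closest heavy
#' atom lies within `cutoff` (6 Angstrom) in at least `prevalence` (50%) of
#' the analysed frames contribute one feature: the per-frame minimum
#' heavy-atom distance between that residue and the polar atom.
#'
#' @param trajectory a [Trajectory].
#' @param manifest a [LigandManifest].
#' @param frames frame ids (default all).
#' @param cutoff contact cutoff, Angstrom.
#' @param prevalence minimum fraction of frames within the cutoff.
#' @param receptorChain chain id of the receptor.
#' @return a [FeatureMatrix] (region `"pocket"`).
#' @export
ligandPocketDistances <- function(trajectory, manifest, frames = NULL,
                                  cutoff = 6, prevalence = 0.5,
                                  receptorChain = "R") {
  stopIf(nrow(manifest@polarAtoms) == 0L, "manifest has no polar atoms")
  st <- trajectory@structure
  a <- atomTable(st)
  fr <- frameIndex(trajectory, frames)
  co <- coordArray(trajectory)
  resnos <- sort(unique(a$resno[a$chain == receptorChain]))
  heavy <- atomIndices(st, chain = receptorChain, heavyOnly = TRUE)
  heavyRes <- a$resno[heavy]
  hx <- matrix(co[heavy, 1, fr], nrow = length(heavy))
  hy <- matrix(co[heavy, 2, fr], nrow = length(heavy))
  hz <- matrix(co[heavy, 3, fr], nrow = length(heavy))
  keepVals <- list(); keepRes <- integer(); keepAtom <- integer()
  keepRole <- character()
  for (p in seq_len(nrow(manifest@polarAtoms))) {
    pid <- manifest@polarAtoms$atomId[p]
    pIdx <- match(pid, a$id)
    stopIf(is.na(pIdx), "polar atom id not in structure: ", pid)
    px <- co[pIdx, 1, fr]; py <- co[pIdx, 2, fr]; pz <- co[pIdx, 3, fr]
    dAll <- sqrt(sweep(hx, 2, px)^2 + sweep(hy, 2, py)^2 +
                   sweep(hz, 2, pz)^2)
    for (r0 in resnos) {
      rows <- which(heavyRes == r0)
      d <- dAll[rows[1], ]
      for (rr in rows[-1]) d <- pmin(d, dAll[rr, ])
      if (mean(d <= cutoff) >= prevalence) {
        keepVals[[length(keepVals) + 1L]] <- d
        keepRes <- c(keepRes, r0); keepAtom <- c(keepAtom, pid)
        keepRole <- c(keepRole, manifest@polarAtoms$role[p])
      }
    }
  }
  desc <- if (length(keepRes) == 0L) emptyDescriptors() else data.frame(
    kind = rep("ligand_polar_distance", length(keepRes)),
    chainA = receptorChain, resA = keepRes, chainB = NA_character_,
    resB = NA_integer_, atomRef = keepAtom, quad = NA_character_,
    units = "angstrom", region = "pocket",
    label = sprintf("dPolar(%d,%s:%d)", keepRes, keepRole, keepAtom),
    stringsAsFactors = FALSE)
  vals <- if (length(keepVals)) do.call(cbind, keepVals) else
    matrix(0, nrow = length(fr), ncol = 0)
  makeFeatureMatrix(vals, if (nrow(desc)) desc else emptyDescriptors(),
                    frameIds(trajectory)[fr], conditionLabel(trajectory))
}

#' Side-chain chi1 dihedrals of the conserved activation motifs
#'
#' Resolves the CWxP, DRY, PIF and NPxxY motif residues through the residue
#' map's Ballesteros-Weinstein codes and returns the chi1 (N-CA-CB-CG class)
#' side-chain dihedral for every motif residue possessing one.
#'
#' @param trajectory a [Trajectory].
#' @param residueMap residue map data.frame (`chain`, `resnum`, `bw`,
#'   `segment`).
#' @param frames frame ids (default all).
#' @param motifBw BW codes to resolve (defaults to the built-in motif list).
#' @param receptorChain receptor chain id.
#' @return a [FeatureMatrix] of angles in degrees (region `"tm"`).
#' @export
motifDihedrals <- function(trajectory, residueMap, frames = NULL,
                           motifBw = GPCR_MOTIF_BW, receptorChain = "R") {
  resnos <- resnoFromBw(residueMap[residueMap$chain == receptorChain, ],
                        motifBw)
  sidechainChi1(trajectory, resnos, chain = receptorChain, frames = frames,
                kind = "motif_dihedral", region = "tm")
}

#' Chi1 side-chain dihedral features for chosen residues
#'
#' @param trajectory a [Trajectory].
#' @param residues residue numbers.
#' @param chain chain id.
#' @param frames frame ids (default all).
#' @param kind descriptor kind recorded.
#' @param region region tag.
#' @return a [FeatureMatrix] of chi1 angles (degrees). Residues lacking the
#'   N/CA/CB/CG atom set are skipped.
#' @export
sidechainChi1 <- function(trajectory, residues, chain = "R", frames = NULL,
                          kind = "sidechain_chi1", region = "tm") {
  st <- trajectory@structure
  a <- atomTable(st)
  fr <- frameIndex(trajectory, frames)
  keepVals <- list(); keepRes <- integer(); keepQuad <- character()
  for (r in unique(as.integer(residues))) {
    ids <- vapply(c("N", "CA", "CB", "CG"), function(nm) {
      i <- atomIndices(st, chain = chain, resno = r, names = nm)
      if (length(i) == 1L) a$id[i] else NA_integer_
    }, integer(1))
    if (anyNA(ids)) next
    keepVals[[length(keepVals) + 1L]] <-
      dihedralSeries(trajectory, ids, frames = frames)
    keepRes <- c(keepRes, r)
    keepQuad <- c(keepQuad, paste(ids, collapse = ","))
  }
  desc <- if (length(keepRes) == 0L) emptyDescriptors() else data.frame(
    kind = rep(kind, length(keepRes)), chainA = chain, resA = keepRes,
    chainB = NA_character_, resB = NA_integer_, atomRef = NA_integer_,
    quad = keepQuad, units = "degree", region = region,
    label = sprintf("chi1(%d)", keepRes), stringsAsFactors = FALSE)
  vals <- if (length(keepVals)) do.call(cbind, keepVals) else
    matrix(0, nrow = length(fr), ncol = 0)
  makeFeatureMatrix(vals, if (nrow(desc)) desc else emptyDescriptors(),
                    frameIds(trajectory)[fr], conditionLabel(trajectory))
}

#' Ligand head-moiety dihedral features (chi1, chi2)
#'
#' Uses the manifest's named atom quadruples.
#'
#' @param trajectory a [Trajectory].
#' @param manifest a [LigandManifest] with dihedral definitions.
#' @param frames frame ids (default all).
#' @return a [FeatureMatrix] of angles (degrees, region `"pocket"`).
#' @export
ligandHeadDihedrals <- function(trajectory, manifest, frames = NULL) {
  stopIf(length(manifest@dihedrals) == 0L, "manifest defines no dihedrals")
  fr <- frameIndex(trajectory, frames)
  vals <- list(); quads <- character(); labs <- character()
  for (nm in names(manifest@dihedrals)) {
    q <- manifest@dihedrals[[nm]]$quad
    vals[[nm]] <- dihedralSeries(trajectory, q, frames = frames)
    quads <- c(quads, paste(q, collapse = ","))
    labs <- c(labs, paste0("ligand_", nm))
  }
  desc <- data.frame(
    kind = rep("ligand_dihedral", length(vals)), chainA = NA_character_,
    resA = NA_integer_, chainB = NA_character_, resB = NA_integer_,
    atomRef = NA_integer_, quad = quads, units = "degree", region = "pocket",
    label = labs, stringsAsFactors = FALSE)
  makeFeatureMatrix(do.call(cbind, vals), desc,
                    frameIds(trajectory)[fr], conditionLabel(trajectory))
}

#' Receptor--G-alpha interface Calpha distance features
#'
#' One feature per receptor/G-alpha residue pair whose mean Calpha-Calpha
#' distance over the analysed frames is within `maxMeanDistance`; `resA`
#' carries the receptor residue and `resB` the G-alpha residue (separate
#' numbering spaces).
#'
#' @param trajectory a [Trajectory].
#' @param receptorChain receptor chain id.
#' @param gChain G-alpha chain id.
#' @param frames frame ids (default all).
#' @param maxMeanDistance Angstrom cutoff on the mean distance.
#' @return a [FeatureMatrix] (region `"interface"`); empty with a warning if
#'   no pair passes the filter.
#' @export
interfaceDistances <- function(trajectory, receptorChain = "R", gChain = "G",
                               frames = NULL, maxMeanDistance = 12) {
  a <- atomTable(trajectory)
  stopIf(!receptorChain %in% a$chain, "chain absent: ", receptorChain)
  stopIf(!gChain %in% a$chain, "chain absent: ", gChain)
  rRes <- sort(unique(a$resno[a$chain == receptorChain]))
  gRes <- sort(unique(a$resno[a$chain == gChain]))
  rCa <- caIndexFor(trajectory@structure, receptorChain, rRes)
  gCa <- caIndexFor(trajectory@structure, gChain, gRes)
  fr <- frameIndex(trajectory, frames)
  co <- coordArray(trajectory)
  rc <- co[rCa, , fr, drop = FALSE]
  gc <- co[gCa, , fr, drop = FALSE]
  pi_ <- rep(seq_along(rRes), each = length(gRes))
  pj_ <- rep(seq_along(gRes), times = length(rRes))
  res <- pair_distance_filter_cpp(rc, gc, pi_ - 1L, pj_ - 1L,
                                  maxMeanDistance)
  keepA <- rRes[pi_[res$kept]]
  keepB <- gRes[pj_[res$kept]]
  if (res$nKept == 0L) {
    warning("no interface residue pair within ", maxMeanDistance,
            " Angstrom mean distance", call. = FALSE)
  }
  vals <- if (res$nKept > 0) {
    res$values[, seq_len(res$nKept), drop = FALSE]
  } else matrix(0, nrow = length(fr), ncol = 0)
  desc <- if (length(keepA) == 0L) emptyDescriptors() else data.frame(
    kind = rep("interface_distance", length(keepA)), chainA = receptorChain,
    resA = keepA, chainB = gChain, resB = keepB, atomRef = NA_integer_,
    quad = NA_character_, units = "angstrom", region = "interface",
    label = sprintf("dIface(%d,G%d)", keepA, keepB), stringsAsFactors = FALSE)
  makeFeatureMatrix(vals, if (nrow(desc)) desc else emptyDescriptors(),
                    frameIds(trajectory)[fr], conditionLabel(trajectory))
}
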