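# PIA-GPCR style conformational analysis: subsegment centers of mass,
# between-condition COM displacement, COM-distance series, and 1D/2D
# dihedral mode analysis.

#' Per-frame center of mass of a subsegment
#'
#' Mass-weighted center of mass of the subsegment's residues, per frame.
#' Heavy atoms by default; a Calpha-only mode is selectable.
#'
#' @param trajectory a [Trajectory].
#' @param scheme a [SubsegmentScheme].
#' @param name subsegment name (e.g. `"TM2e"`).
#' @param frames frame ids (default all).
#' @param chain receptor chain id.
#' @param atoms `"heavy"` (default) or `"ca"`.
#' @return numeric matrix frames x 3 (Angstrom) with attributes
#'   `subsegment` and `condition`.
#' @export
subsegmentCom <- function(trajectory, scheme, name, frames = NULL,
                          chain = "R", atoms = c("heavy", "ca")) {
  atoms <- match.arg(atoms)
  res <- subsegmentResidues(scheme, name)
  st <- trajectory@structure
  idx <- if (atoms == "ca") {
    atomIndices(st, chain = chain, resno = res, names = "CA")
  } else {
    atomIndices(st, chain = chain, resno = res, heavyOnly = TRUE)
  }
  stopIf(length(idx) == 0L, "no atoms found for subsegment ", name)
  fr <- frameIndex(trajectory, frames)
  co <- coordArray(trajectory)
  m <- atomTable(st)$mass[idx]
  w <- m / sum(m)
  out <- matrix(NA_real_, nrow = length(fr), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (d in 1:3) {
    out[, d] <- colSums(matrix(co[idx, d, fr], nrow = length(idx)) * w)
  }
  attr(out, "subsegment") <- name
  attr(out, "condition") <- conditionLabel(trajectory)
  out
}

#' COM series for every subsegment of a scheme
#'
#' @rdname subsegmentCom
#' @return for `allSubsegmentComs`: a named list of COM matrices.
#' @export
allSubsegmentComs <- function(trajectory, scheme, frames = NULL, chain = "R",
                              atoms = "heavy") {
  nms <- subsegmentNames(scheme)
  setNames(lapply(nms, function(n)
    subsegmentCom(trajectory, scheme, n, frames = frames, chain = chain,
                  atoms = atoms)), nms)
}

#' Between-condition subsegment COM displacement report
#'
#' For each subsegment, the displacement of the time-averaged center of mass
#' between two conditions, `Delta = mean COM(A) - mean COM(B)`, with its
#' magnitude and (when a pocket center is supplied) its signed projection
#' onto the unit vector pointing from the subsegment toward the
#' binding-pocket center -- positive values mean condition A sits farther
#' inward (toward the pocket) than condition B.
#'
#' @param comsA,comsB named lists of COM matrices ([allSubsegmentComs()])
#'   covering the same subsegments.
#' @param pocketCenter optional 3-vector (Angstrom), e.g. the mean ligand
#'   heavy-atom position.
#' @return data.frame with columns `subsegment`, `dx`, `dy`, `dz`,
#'   `magnitude` and (optionally) `inward`.
#' @export
deltaComReport <- function(comsA, comsB, pocketCenter = NULL) {
  stopIf(!setequal(names(comsA), names(comsB)),
         "conditions cover different subsegment sets")
  nms <- names(comsA)
  out <- data.frame(subsegment = nms, dx = NA_real_, dy = NA_real_,
                    dz = NA_real_, magnitude = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(pocketCenter)) out$inward <- NA_real_
  for (i in seq_along(nms)) {
    mA <- colMeans(comsA[[nms[i]]])
    mB <- colMeans(comsB[[nms[i]]])
    d <- mA - mB
    out[i, c("dx", "dy", "dz")] <- d
    out$magnitude[i] <- sqrt(sum(d^2))
    if (!is.null(pocketCenter)) {
      mid <- (mA + mB) / 2
      u <- pocketCenter - mid
      nu <- sqrt(sum(u^2))
      out$inward[i] <- if (nu > 0) sum(d * u) / nu else 0
    }
  }
  out
}

#' Per-frame COM distances between subsegment pairs
#'
#' Euclidean distance between subsegment centers of mass per frame; the
#' default pairs probe the extracellular pocket geometry (TM1e-TM3e and
#' TM2e-TM7e).
#'
#' @param trajectory a [Trajectory].
#' @param scheme a [SubsegmentScheme].
#' @param pairs list of length-2 character vectors of subsegment names.
#' @param frames frame ids (default all).
#' @param chain receptor chain id.
#' @return data.frame with one column per pair (named `"TM1e-TM3e"` etc.),
#'   distances in Angstrom.
#' @export
comDistanceSeries <- function(trajectory, scheme,
                              pairs = list(c("TM1e", "TM3e"),
                                           c("TM2e", "TM7e")),
                              frames = NULL, chain = "R") {
  out <- list()
  for (p in pairs) {
    a <- subsegmentCom(trajectory, scheme, p[1], frames = frames,
                       chain = chain)
    b <- subsegmentCom(trajectory, scheme, p[2], frames = frames,
                       chain = chain)
    out[[paste(p, collapse = "-")]] <- sqrt(rowSums((a - b)^2))
  }
  as.data.frame(out, check.names = FALSE)
}

# Circular topographic prominence of local maxima of a density on a closed
# grid; returns peak indices and prominences.
circularPeaks <- function(dens) {
  n <- length(dens)
  nxt <- c(seq_len(n)[-1], 1L); prv <- c(n, seq_len(n)[-n])
  isMax <- dens > dens[prv] & dens >= dens[nxt]
  peaks <- which(isMax)
  if (!length(peaks)) return(list(peaks = integer(), prom = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- dens[p]
    walk <- function(step) {
      i <- p; lo <- h
      for (s in seq_len(n)) {
        i <- if (step > 0) (i %% n) + 1L else ((i - 2L) %% n) + 1L
        if (dens[i] > h) return(lo)
        lo <- min(lo, dens[i])
      }
      lo
    }
    saddle <- max(walk(1L), walk(-1L))
    if (h == max(dens)) saddle <- min(dens)
    h - saddle
  }, numeric(1))
  list(peaks = peaks, prom = prom)
}

#' Detect modes of an angular or distance series
#'
#' Histograms the series (circularly for angles), smooths the density with a
#' Gaussian kernel, and reports local maxima whose topographic prominence
#' reaches `minProminence` of the peak density, with supports at
#' half-prominence and occupancies assigned by splitting samples at the
#' density minima between adjacent modes.
#'
#' @param x numeric series (degrees for angles; length >= 50).
#' @param circular treat the series as angular in (-180, 180].
#' @param binWidth histogram bin width (degrees or same units as `x`).
#' @param smoothSigma Gaussian smoothing bandwidth (same units).
#' @param minProminence minimum prominence as a fraction of the maximum
#'   density.
#' @param minLength minimum series length.
#' @return data.frame with columns `mode`, `location`, `supportLo`,
#'   `supportHi`, `occupancy` (occupancies sum to 1).
#' @export
detectModes <- function(x, circular = TRUE, binWidth = 5, smoothSigma = 10,
                        minProminence = 0.05, minLength = 50L) {
  stopIf(length(x) < minLength, "series too short: ", length(x), " < ",
         minLength)
  if (diff(range(x)) == 0) {
    return(data.frame(mode = 1L, location = x[1], supportLo = x[1],
                      supportHi = x[1], occupancy = 1))
  }
  if (circular) {
    x <- wrapAngle(x)
    breaks <- seq(-180, 180, by = binWidth)
  } else {
    pad <- 3 * smoothSigma
    breaks <- seq(min(x) - pad, max(x) + pad + binWidth, by = binWidth)
  }
  mids <- breaks[-1] - binWidth / 2
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(mids))
  n <- length(mids)
  halfw <- ceiling(3 * smoothSigma / binWidth)
  kern <- exp(-0.5 * ((-halfw:halfw) * binWidth / smoothSigma)^2)
  kern <- kern / sum(kern)
  dens <- numeric(n)
  for (o in -halfw:halfw) {
    idx <- if (circular) ((seq_len(n) - 1L + o) %% n) + 1L else
      pmin(pmax(seq_len(n) + o, 1L), n)
    dens <- dens + kern[o + halfw + 1L] * counts[idx]
  }
  pk <- if (circular) circularPeaks(dens) else {
    # linear case: pad with zeros conceptually; reuse circular machinery on
    # a zero-extended vector so ends cannot wrap
    tmp <- circularPeaks(c(0, dens, 0))
    keep <- tmp$peaks > 1 & tmp$peaks <= n + 1
    list(peaks = tmp$peaks[keep] - 1L, prom = tmp$prom[keep])
  }
  keep <- pk$prom >= minProminence * max(dens)
  peaks <- pk$peaks[keep]; prom <- pk$prom[keep]
  if (!length(peaks)) {
    peaks <- which.max(dens); prom <- max(dens) - min(dens)
  }
  ord <- order(mids[peaks])
  peaks <- peaks[ord]; prom <- prom[ord]
  m <- length(peaks)
  # support at half-prominence
  supLo <- numeric(m); supHi <- numeric(m)
  for (i in seq_len(m)) {
    thr <- dens[peaks[i]] - prom[i] / 2
    lo <- peaks[i]; hi <- peaks[i]
    for (s in seq_len(n)) {
      nl <- if (circular) ((lo - 2L) %% n) + 1L else max(lo - 1L, 1L)
      if (dens[nl] < thr || nl == lo) break
      lo <- nl
      if (lo == peaks[i]) break
    }
    for (s in seq_len(n)) {
      nh <- if (circular) (hi %% n) + 1L else min(hi + 1L, n)
      if (dens[nh] < thr || nh == hi) break
      hi <- nh
      if (hi == peaks[i]) break
    }
    supLo[i] <- mids[lo]; supHi[i] <- mids[hi]
  }
  # occupancy: split at the density minimum between adjacent peaks
  if (m == 1L) {
    occ <- 1
  } else {
    bounds <- numeric(m)  # boundary after peak i (circularly)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      seg <- if (circular && i == m) c(seq(peaks[i], n), seq_len(peaks[j])) else
        seq(peaks[i], peaks[j])
      bounds[i] <- mids[seg[which.min(dens[seg])]]
    }
    assignMode <- function(v) {
      for (i in seq_len(m)) {
        lo <- if (i == 1L) bounds[m] else bounds[i - 1L]
        hi <- bounds[i]
        inSeg <- if (circular && lo > hi) (v > lo | v <= hi) else
          (v > lo & v <= hi)
        if (inSeg) return(i)
      }
      which.min(abs(v - mids[peaks]))
    }
    occ <- tabulate(vapply(x, assignMode, integer(1)), nbins = m) / length(x)
  }
  data.frame(mode = seq_len(m), location = mids[peaks], supportLo = supLo,
             supportHi = supHi, occupancy = occ)
}

#' 2D occupancy map of two dihedral series
#'
#' Normalised 2D histogram over (-180, 180] x (-180, 180]; the grid sums
#' to 1.
#'
#' @param chi1,chi2 angle series of equal length (degrees).
#' @param binWidth bin width, degrees.
#' @return numeric matrix with bin-center dimnames; `sum(map) == 1`.
#' @export
dihedral2dMap <- function(chi1, chi2, binWidth = 5) {
  stopIf(length(chi1) != length(chi2), "series length mismatch: ",
         length(chi1), " vs ", length(chi2))
  breaks <- seq(-180, 180, by = binWidth)
  mids <- breaks[-1] - binWidth / 2
  i <- findInterval(wrapAngle(chi1), breaks, rightmost.closed = TRUE)
  j <- findInterval(wrapAngle(chi2), breaks, rightmost.closed = TRUE)
  g <- matrix(0, nrow = length(mids), ncol = length(mids),
              dimnames = list(mids, mids))
  for (t in seq_along(i)) g[i[t], j[t]] <- g[i[t], j[t]] + 1
  g / length(i)
}
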