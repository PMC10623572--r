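# Ligand-residue contact frequencies, cross-condition reporting and
# highlighting rules, and side-chain rotamer comparison.

#' Default binding-site residue set
#'
#' All receptor residues with any heavy atom within `radius` (10 Angstrom)
#' of any ligand heavy atom in the first analysed frame: a superset that
#' cannot drop true contacts.
#'
#' @param trajectory a [Trajectory].
#' @param ligandResname ligand residue name.
#' @param receptorChain receptor chain id.
#' @param radius Angstrom.
#' @return integer residue numbers.
#' @export
bindingSiteResidues <- function(trajectory, ligandResname,
                                receptorChain = "R", radius = 10) {
  a <- atomTable(trajectory)
  st <- trajectory@structure
  lig <- which(a$resname == ligandResname & toupper(a$element) != "H")
  stopIf(length(lig) == 0L, "no ligand heavy atoms for resname ", ligandResname)
  co <- coordArray(trajectory)
  resnos <- sort(unique(a$resno[a$chain == receptorChain]))
  keep <- vapply(resnos, function(r) {
    idx <- atomIndices(st, chain = receptorChain, resno = r, heavyOnly = TRUE)
    m <- Inf
    for (i in idx) {
      d <- sqrt(colSums((co[lig, , 1, drop = TRUE] -
                           matrix(co[i, , 1], nrow = length(lig),
                                  ncol = 3, byrow = TRUE))^2))
      m <- min(m, min(d))
    }
    m <= radius
  }, logical(1))
  resnos[keep]
}

#' Ligand-residue contact frequency
#'
#' Fraction of frames in which any heavy atom of the residue lies within
#' `cutoff` (6 Angstrom) of any ligand heavy atom.
#'
#' @param trajectory a [Trajectory].
#' @param ligandResname ligand residue name (its heavy atoms are used).
#' @param residues binding-site residue numbers; defaults to
#'   [bindingSiteResidues()].
#' @param frames frame ids (default all).
#' @param cutoff contact cutoff, Angstrom.
#' @param receptorChain receptor chain id.
#' @return data.frame with columns `condition`, `resno`, `frequency`
#'   (fraction in `[0, 1]`).
#' @export
contactFrequency <- function(trajectory, ligandResname, residues = NULL,
                             frames = NULL, cutoff = 6,
                             receptorChain = "R") {
  a <- atomTable(trajectory)
  st <- trajectory@structure
  lig <- which(a$resname == ligandResname & toupper(a$element) != "H")
  stopIf(length(lig) == 0L, "no ligand heavy atoms for resname ", ligandResname)
  fr <- frameIndex(trajectory, frames)
  stopIf(length(fr) == 0L, "no frames to analyse")
  if (is.null(residues)) {
    residues <- bindingSiteResidues(trajectory, ligandResname, receptorChain)
  }
  co <- coordArray(trajectory)
  freq <- vapply(residues, function(r) {
    idx <- atomIndices(st, chain = receptorChain, resno = r, heavyOnly = TRUE)
    contact <- rep(FALSE, length(fr))
    for (i in idx) {
      for (l in lig) {
        contact <- contact | (atomDistSeries(co, i, l, fr) <= cutoff)
      }
    }
    mean(contact)
  }, numeric(1))
  data.frame(condition = conditionLabel(trajectory),
             resno = as.integer(residues), frequency = freq,
             stringsAsFactors = FALSE)
}

#' Residues reportable across conditions
#'
#' The union over conditions of residues whose contact frequency reaches
#' `threshold` (50%) in at least one condition; contact tables are then
#' tabulated for those residues in every condition.
#'
#' @param tables list of contact tables from [contactFrequency()].
#' @param threshold minimum frequency (fraction).
#' @return sorted integer residue numbers.
#' @export
reportableResidues <- function(tables, threshold = 0.50) {
  stopIf(length(tables) < 1L, "need at least one contact table")
  res <- lapply(tables, function(t) t$resno[t$frequency >= threshold])
  sort(unique(unlist(res)))
}

#' Cross-condition contact differences with highlighting
#'
#' Pairwise differences of contact frequency between conditions over a
#' common residue set; absolute differences of `minDiff` (25%) or more are
#' flagged.
#'
#' @param tables list of >= 2 contact tables from [contactFrequency()].
#' @param minDiff highlight threshold (fraction).
#' @param residues residues to tabulate; defaults to
#'   [reportableResidues()] of the tables.
#' @return data.frame with columns `resno`, `conditionA`, `conditionB`,
#'   `freqA`, `freqB`, `diff` and logical `highlighted`
#'   (`abs(diff) >= minDiff`).
#' @export
highlightDifferences <- function(tables, minDiff = 0.25, residues = NULL) {
  stopIf(length(tables) < 2L, "need at least two contact tables")
  if (is.null(residues)) residues <- reportableResidues(tables)
  common <- Reduce(union, lapply(tables, function(t) t$resno))
  stopIf(length(common) == 0L, "contact tables share no residues")
  conds <- vapply(tables, function(t) t$condition[1], character(1))
  out <- list()
  for (i in seq_len(length(tables) - 1L)) {
    for (j in seq.int(i + 1L, length(tables))) {
      fa <- tables[[i]]$frequency[match(residues, tables[[i]]$resno)]
      fb <- tables[[j]]$frequency[match(residues, tables[[j]]$resno)]
      fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
      d <- fa - fb
      out[[length(out) + 1L]] <- data.frame(
        resno = residues, conditionA = conds[i], conditionB = conds[j],
        freqA = fa, freqB = fb, diff = d,
        highlighted = abs(d) >= minDiff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Side-chain rotamer shift between conditions
#'
#' Circular means of two chi1 series (vector averaging, never naive
#' arithmetic means on angles) and their minimal angular difference; shifts
#' exceeding `threshold` (70 degrees) are flagged.
#'
#' @param chiA,chiB numeric chi1 angle series (degrees).
#' @param threshold flag threshold, degrees.
#' @return list with `meanA`, `meanB`, `diff` (degrees, in `[0, 180]`) and
#'   logical `flagged`.
#' @export
rotamerShift <- function(chiA, chiB, threshold = 70) {
  stopIf(length(chiA) == 0L || length(chiB) == 0L, "empty angle series")
  mA <- circularMean(chiA)
  mB <- circularMean(chiB)
  d <- circularDiff(mA, mB)
  list(meanA = mA, meanB = mB, diff = d, flagged = d > threshold)
}
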