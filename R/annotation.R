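# Residue annotation: transmembrane subsegment scheme, Ballesteros-Weinstein
# numbering, residue map and ligand manifest I/O.

#' Built-in human CB1R transmembrane subsegment scheme
#'
#' The 21 subsegments (extracellular/middle/intracellular thirds of each of
#' the seven transmembrane helices) with their author residue-number ranges,
#' as used for PIA-GPCR style coarse conformational analysis of CB1R.
#'
#' @return a [SubsegmentScheme].
#' @examples
#' sch <- cb1rScheme()
#' subsegmentRange(sch, "TM2e")  # 175..179
#' @export
cb1rScheme <- function() {
  t <- data.frame(
    name = c("TM1e", "TM1m", "TM1i", "TM2e", "TM2m", "TM2i", "TM3e", "TM3m",
             "TM3i", "TM4e", "TM4m", "TM4i", "TM5e", "TM5m", "TM5i", "TM6e",
             "TM6m", "TM6i", "TM7e", "TM7m", "TM7i"),
    start = c(113L, 121L, 130L, 175L, 165L, 151L, 186L, 196L, 203L, 247L,
              241L, 229L, 272L, 281L, 289L, 363L, 355L, 335L, 374L, 383L,
              391L),
    end = c(120L, 129L, 144L, 179L, 174L, 164L, 195L, 202L, 220L, 253L,
            246L, 240L, 280L, 288L, 311L, 368L, 362L, 354L, 382L, 390L,
            400L),
    stringsAsFactors = FALSE)
  t$tm <- as.integer(substr(t$name, 3, 3))
  t$part <- substr(t$name, 4, 4)
  new("SubsegmentScheme", table = t[, c("name", "tm", "part", "start", "end")])
}

# Ballesteros-Weinstein offsets for the built-in CB1R numbering:
# bw position = resno - offset[tm] within each helix.
CB1R_BW_OFFSETS <- c(`1` = 84L, `2` = 113L, `3` = 164L, `4` = 191L,
                     `5` = 236L, `6` = 308L, `7` = 344L)

#' Residue-number range of a named subsegment
#'
#' @param scheme a [SubsegmentScheme].
#' @param name subsegment name, e.g. `"TM2e"`.
#' @return integer `c(start, end)` (inclusive).
#' @export
subsegmentRange <- function(scheme, name) {
  t <- schemeTable(scheme)
  i <- match(name, t$name)
  stopIf(is.na(i), "unknown subsegment: ", name)
  c(t$start[i], t$end[i])
}

#' @rdname subsegmentRange
#' @export
subsegmentNames <- function(scheme) schemeTable(scheme)$name

#' Residues of a subsegment or a whole TM helix
#' @param tm helix number 1..7.
#' @rdname subsegmentRange
#' @export
tmResidues <- function(scheme, tm) {
  t <- schemeTable(scheme)
  sub <- t[t$tm == tm, ]
  stopIf(nrow(sub) == 0L, "unknown TM: ", tm)
  sort(unique(unlist(Map(seq.int, sub$start, sub$end))))
}

#' @rdname subsegmentRange
#' @export
subsegmentResidues <- function(scheme, name) {
  r <- subsegmentRange(scheme, name)
  seq.int(r[1], r[2])
}

#' Assign residues to subsegments
#'
#' Residues outside every subsegment range are assigned the `"loop"`
#' pseudo-segment.
#'
#' @param scheme a [SubsegmentScheme].
#' @param resno integer residue numbers.
#' @return character vector of subsegment names.
#' @export
assignSubsegment <- function(scheme, resno) {
  t <- schemeTable(scheme)
  out <- rep("loop", length(resno))
  for (i in seq_len(nrow(t))) {
    hit <- resno >= t$start[i] & resno <= t$end[i]
    out[hit] <- t$name[i]
  }
  out
}

#' Ballesteros-Weinstein code for built-in CB1R numbering
#'
#' @param resno author residue numbers.
#' @param scheme a [SubsegmentScheme] (the built-in CB1R scheme).
#' @return character BW codes like `"2.65"`, `""` for residues outside the
#'   TM bundle.
#' @export
bwFromResno <- function(resno, scheme = cb1rScheme()) {
  seg <- assignSubsegment(scheme, resno)
  tm <- ifelse(seg == "loop", NA_integer_,
               as.integer(substr(seg, 3, 3)))
  out <- rep("", length(resno))
  ok <- !is.na(tm)
  out[ok] <- paste0(tm[ok], ".", resno[ok] - CB1R_BW_OFFSETS[as.character(tm[ok])])
  out
}

#' Resolve a BW code through a residue map
#'
#' @param residueMap data.frame with columns `chain`, `resnum`, `bw`,
#'   `segment`.
#' @param bw character BW codes (e.g. `"3.50"`).
#' @return integer residue numbers; error listing any unresolvable codes.
#' @export
resnoFromBw <- function(residueMap, bw) {
  i <- match(bw, residueMap$bw)
  if (anyNA(i)) {
    stop("unresolvable BW code(s): ", paste(bw[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  residueMap$resnum[i]
}

#' Validate a residue map
#'
#' Checks (chain, resnum) uniqueness and that non-empty BW codes parse as
#' `helix.position`.
#'
#' @param residueMap data.frame with columns `chain`, `resnum`, `bw`,
#'   `segment`.
#' @return the map, invisibly; errors on violation.
#' @export
validateResidueMap <- function(residueMap) {
  need <- c("chain", "resnum", "bw", "segment")
  stopIf(!all(need %in% names(residueMap)),
         "residue map must have columns: ", paste(need, collapse = ", "))
  key <- paste(residueMap$chain, residueMap$resnum)
  stopIf(anyDuplicated(key) > 0, "(chain, resnum) entries must be unique")
  bw <- residueMap$bw[!is.na(residueMap$bw) & residueMap$bw != ""]
  bad <- !grepl("^[0-9]+\\.[0-9]+$", bw)
  stopIf(any(bad), "malformed BW code(s): ", paste(bw[bad], collapse = ", "))
  invisible(residueMap)
}

#' Read / write a residue map as TSV
#'
#' Tab-separated with header `chain`, `resnum`, `bw`, `segment`.
#'
#' @param path file path.
#' @return the residue map data.frame.
#' @export
readResidueMap <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chain = "character", bw = "character",
                                 segment = "character"))
  m$bw[is.na(m$bw)] <- ""
  validateResidueMap(m)
  m
}

#' @rdname readResidueMap
#' @param residueMap the map to write.
#' @export
writeResidueMap <- function(residueMap, path) {
  write.table(residueMap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a ligand manifest
#'
#' @param resname ligand residue name.
#' @param polarAtoms data.frame with columns `role`, `atomId`.
#' @param dihedrals named list of `list(quad = <4 atom ids>, rotating = ...)`.
#' @return a [LigandManifest].
#' @export
LigandManifest <- function(resname, polarAtoms, dihedrals = list()) {
  new("LigandManifest", resname = resname,
      polarAtoms = as.data.frame(polarAtoms), dihedrals = dihedrals)
}

#' Read / write a ligand manifest as TSV
#'
#' Tab-separated with header `role`, `atom_id`. Polar-atom roles appear one
#' row per atom; dihedral definitions appear as four ordered rows sharing the
#' role (`chi1`, `chi2`), with optional `<name>_rotating` rows listing the
#' atoms driven when the generator rotates that dihedral. The ligand residue
#' name is carried in a `resname` role row (atom_id gives the name).
#'
#' @param path file path.
#' @return a [LigandManifest].
#' @export
readLigandManifest <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(role = "character"))
  stopIf(!all(c("role", "atom_id") %in% names(t)),
         "manifest must have columns role, atom_id")
  resname <- t$atom_id[t$role == "resname"]
  stopIf(length(resname) != 1L, "manifest must name the ligand residue once")
  dihRoles <- unique(t$role[grepl("^chi[0-9]+$", t$role)])
  dihedrals <- list()
  for (r in dihRoles) {
    dihedrals[[r]] <- list(quad = as.integer(t$atom_id[t$role == r]))
    rot <- t$atom_id[t$role == paste0(r, "_rotating")]
    if (length(rot)) dihedrals[[r]]$rotating <- as.integer(rot)
  }
  polar <- t[!grepl("^chi[0-9]+(_rotating)?$", t$role) & t$role != "resname", ]
  LigandManifest(resname = resname,
                 polarAtoms = data.frame(role = polar$role,
                                         atomId = as.integer(polar$atom_id),
                                         stringsAsFactors = FALSE),
                 dihedrals = dihedrals)
}

#' @rdname readLigandManifest
#' @param manifest the [LigandManifest] to write.
#' @export
writeLigandManifest <- function(manifest, path) {
  rows <- data.frame(role = "resname", atom_id = manifest@resname,
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(role = manifest@polarAtoms$role,
                                 atom_id = as.character(manifest@polarAtoms$atomId)))
  for (nm in names(manifest@dihedrals)) {
    d <- manifest@dihedrals[[nm]]
    rows <- rbind(rows, data.frame(role = nm, atom_id = as.character(d$quad)))
    if (!is.null(d$rotating)) {
      rows <- rbind(rows, data.frame(role = paste0(nm, "_rotating"),
                                     atom_id = as.character(d$rotating)))
    }
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a manifest against a structure
#'
#' Checks that every referenced atom exists and that each dihedral has four
#' distinct atoms.
#'
#' @param manifest a [LigandManifest].
#' @param structure the parent [Structure].
#' @return the manifest, invisibly; errors on violation.
#' @export
validateManifest <- function(manifest, structure) {
  ids <- atomTable(structure)$id
  ref <- c(manifest@polarAtoms$atomId,
           unlist(lapply(manifest@dihedrals, `[[`, "quad")))
  missing <- setdiff(ref, ids)
  stopIf(length(missing) > 0,
         "manifest references missing atom(s): ", paste(missing, collapse = ", "))
  validObject(manifest)
  invisible(manifest)
}

# BW codes of the conserved class-A activation motifs used for motif
# dihedral features: CWxP (6.47-6.50), DRY (3.49-3.51), PIF (5.50, 3.40,
# 6.44) and NPxxY (7.49-7.53).
GPCR_MOTIF_BW <- c("6.47", "6.48", "6.49", "6.50",
                   "3.49", "3.50", "3.51",
                   "5.50", "3.40", "6.44",
                   "7.49", "7.50", "7.51", "7.52", "7.53")
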