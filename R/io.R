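# Structure / trajectory I/O. Multi-model PDB parsing and writing are
# delegated to bio3d; the compact binary frame format documented below is
# read/written directly.

# Standard atomic masses (Da). Unknown elements fall back to the mass of
# carbon with a warning; this only affects mass-weighted centers of mass.
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, FE = 55.845,
  ZN = 65.38, MN = 54.938, SE = 78.971
)
DEFAULT_MASS <- 12.011

elementMass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- ELEMENT_MASSES[key]
  unknown <- is.na(m) | key == ""
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; assigning default mass ", DEFAULT_MASS, " Da", call. = FALSE)
    m[unknown] <- DEFAULT_MASS
  }
  unname(m)
}

# Derive an element symbol from a PDB atom name when the element column is
# blank ("CA1" -> "C"; two-letter halogens respected via leading characters).
guessElement <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG"), two, substr(nm, 1, 1))
  out
}

#' Construct a Structure
#'
#' @param atoms data.frame with columns `id`, `name`, `element`, `resno`,
#'   `resname`, `chain` and optionally `mass` (derived from `element` when
#'   absent).
#' @param coords numeric atoms x 3 matrix, Angstrom.
#' @return a [Structure] object.
#' @export
Structure <- function(atoms, coords) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$mass)) atoms$mass <- elementMass(atoms$element)
  atoms$id <- as.integer(atoms$id)
  atoms$resno <- as.integer(atoms$resno)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("Structure", atoms = atoms, coords = coords)
}

#' Construct a Trajectory
#'
#' @param structure a [Structure].
#' @param coords array atoms x 3 x frames (Angstrom), or a list of
#'   atoms x 3 matrices.
#' @param frameIds integer frame ids; defaults to `0:(n-1)`.
#' @param condition condition label (e.g. ligand name).
#' @return a [Trajectory] object.
#' @export
Trajectory <- function(structure, coords, frameIds = NULL,
                       condition = "unlabelled") {
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  if (length(dim(coords)) != 3L) stop("coords must be atoms x 3 x frames")
  if (is.null(frameIds)) frameIds <- seq_len(dim(coords)[3]) - 1L
  new("Trajectory", structure = structure, coords = coords,
      frameIds = as.integer(frameIds), condition = condition)
}

#' Read a structure from a (multi-model) PDB file
#'
#' Model 1 defines the structure. Masses are derived from the element column
#' (or, when blank, from the atom name); unknown elements receive a default
#' mass of 12.011 Da with a warning.
#'
#' @param path path to a PDB file.
#' @return a [Structure].
#' @export
readStructure <- function(path) {
  stopIf(!file.exists(path), "file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  a <- pdb$atom
  stopIf(nrow(a) == 0L, "no atoms parsed from ", path)
  if (anyDuplicated(a$eleno)) {
    dup <- a$eleno[duplicated(a$eleno)][1]
    stop("parse error: duplicate atom id ", dup, " (atom '",
         a$elety[a$eleno == dup][2], "' residue ",
         a$resno[a$eleno == dup][2], ")", call. = FALSE)
  }
  ele <- a$elesy
  blank <- is.na(ele) | trimws(ele) == ""
  ele[blank] <- guessElement(a$elety[blank])
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  Structure(
    atoms = data.frame(id = a$eleno, name = trimws(a$elety), element = trimws(ele),
                       resno = a$resno, resname = trimws(a$resid),
                       chain = a$chain, stringsAsFactors = FALSE),
    coords = xyz)
}

#' Write a structure (or trajectory) to a multi-model PDB file
#'
#' @param object a [Structure] or [Trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(object, path) {
  a <- atomTable(object)
  if (is(object, "Trajectory")) {
    xyz <- t(apply(object@coords, 3, function(m) as.vector(t(m))))
  } else {
    xyz <- matrix(as.vector(t(object@coords)), nrow = 1)
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   eleno = a$id, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' @rdname writeStructure
#' @export
writeTrajectory <- function(object, path, format = c("pdb", "bin")) {
  format <- match.arg(format)
  if (format == "pdb") return(writeStructure(object, path))
  writeTrajectoryBin(object, path)
}

# Binary frame format: magic "MDTF", int32 atom count, int32 frame count,
# then per frame 3*natoms float32 (x,y,z per atom), little-endian.
writeTrajectoryBin <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MDTF", con, nchars = 4, eos = NULL)
  d <- dim(trajectory@coords)
  writeBin(as.integer(c(d[1], d[3])), con, size = 4L, endian = "little")
  writeBin(as.integer(trajectory@frameIds), con, size = 4L, endian = "little")
  for (f in seq_len(d[3])) {
    writeBin(as.numeric(t(trajectory@coords[, , f])), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

readTrajectoryBin <- function(path, structure, condition) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = 4, useBytes = TRUE)
  stopIf(!identical(magic, "MDTF"), "not a binary trajectory file: ", path)
  hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  natoms <- hdr[1]; nframes <- hdr[2]
  stopIf(natoms != nrow(structure@atoms),
         "atom count mismatch: file has ", natoms, ", structure has ",
         nrow(structure@atoms))
  ids <- readBin(con, "integer", n = nframes, size = 4L, endian = "little")
  coords <- array(NA_real_, dim = c(natoms, 3L, nframes))
  for (f in seq_len(nframes)) {
    v <- readBin(con, "numeric", n = 3L * natoms, size = 4L, endian = "little")
    stopIf(length(v) != 3L * natoms, "truncated frame ", f - 1L, " in ", path)
    coords[, , f] <- matrix(v, ncol = 3L, byrow = TRUE)
  }
  Trajectory(structure, coords, frameIds = ids, condition = condition)
}

# Pre-validate a multi-model PDB: every MODEL must contain the structure's
# atom count, so a dropped atom is reported with its frame index.
checkModelAtomCounts <- function(path, natoms) {
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM|HETATM)", lines)
  isModel <- grepl("^MODEL", lines)
  if (!any(isModel)) {
    stopIf(sum(isAtom) != natoms,
           "atom count mismatch at frame 0: expected ", natoms,
           ", found ", sum(isAtom))
    return(invisible(1L))
  }
  bounds <- c(which(isModel), length(lines) + 1L)
  for (m in seq_len(length(bounds) - 1L)) {
    cnt <- sum(isAtom[bounds[m]:(bounds[m + 1L] - 1L)])
    stopIf(cnt != natoms,
           "atom count mismatch at frame ", m - 1L, ": expected ", natoms,
           ", found ", cnt)
  }
  invisible(length(bounds) - 1L)
}

#' Read a coordinate trajectory
#'
#' Accepts a multi-model PDB or the package's binary frame format (header:
#' magic `"MDTF"`, atom count, frame count as little-endian int32, the frame
#' ids, then float32 coordinate blocks). Frames are returned in storage
#' order with ids `0..n-1` unless the source names them.
#'
#' @param path input file.
#' @param structure the topology [Structure] the frames must match.
#' @param condition condition label attached to the trajectory.
#' @return a [Trajectory].
#' @export
readTrajectory <- function(path, structure, condition = "unlabelled") {
  stopIf(!file.exists(path), "file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), "MDTF")) {
    return(readTrajectoryBin(path, structure, condition))
  }
  checkModelAtomCounts(path, nrow(structure@atoms))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(nrow(structure@atoms), 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  Trajectory(structure, coords, condition = condition)
}

#' Sample frame ids with replacement
#'
#' Uniform bootstrap sampling of frames, reproducible for a fixed seed.
#' The default draw of 10,000 frames matches the pipeline's bootstrap
#' convention; because sampling is with replacement any `n >= 1` is valid
#' for any trajectory size.
#'
#' @param trajectory a [Trajectory].
#' @param n number of frame ids to draw.
#' @param seed RNG seed.
#' @return integer vector of `n` frame ids.
#' @export
sampleFrames <- function(trajectory, n = 10000L, seed = 1L) {
  stopIf(nFrames(trajectory) == 0L, "trajectory has no frames")
  stopIf(n < 1L, "n must be >= 1")
  ids <- frameIds(trajectory)
  withSeed(seed, ids[sample.int(length(ids), size = n, replace = TRUE)])
}
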