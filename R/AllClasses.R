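#' @import methods
NULL

#' Molecular structure with per-atom annotation
#'
#' Holds one conformation of an annotated atom set: the receptor, the bound
#' ligand and (optionally) a G-alpha chain of a receptor--G protein complex.
#' Atom metadata live in the `atoms` data.frame (columns `id`, `name`,
#' `element`, `mass`, `resno`, `resname`, `chain`); coordinates (in Angstrom)
#' in the `coords` matrix, one row per atom.
#'
#' Residue numbers follow author (PDB) numbering and are never renumbered.
#'
#' @slot atoms data.frame of per-atom annotation.
#' @slot coords numeric matrix, atoms x 3, Angstrom.
#' @aliases Structure-class
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix"))

setValidity("Structure", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("id", "name", "element", "mass", "resno", "resname", "chain")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) msg <- c(msg, "structure has zero atoms")
  if (anyDuplicated(a$id)) msg <- c(msg, "atom ids must be unique")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    msg <- c(msg, "every atom must have positive mass")
  if (nrow(object@coords) != nrow(a) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an atoms x 3 matrix")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(r)) {
      msg <- c(msg, sprintf("residue numbers in chain '%s' must be non-decreasing", ch))
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      "chains:", paste(unique(a$chain), collapse = ", "), "\n")
})

#' Coordinate trajectory over a fixed structure
#'
#' Ordered coordinate frames (Angstrom) for the atom set of a [Structure],
#' labelled with the simulated condition (typically the ligand name).
#'
#' @slot structure the topology [Structure].
#' @slot coords numeric array, atoms x 3 x frames.
#' @slot frameIds integer frame identifiers, unique and strictly increasing.
#' @slot condition single string condition label.
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(structure = "Structure", coords = "array",
                 frameIds = "integer", condition = "character"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an atoms x 3 x frames array")
  if (d[1] != nrow(object@structure@atoms))
    msg <- c(msg, "every frame must have exactly the structure's atom count")
  if (length(object@frameIds) != d[3])
    msg <- c(msg, "frameIds length must equal frame count")
  if (anyDuplicated(object@frameIds) || is.unsorted(object@frameIds, strictly = TRUE))
    msg <- c(msg, "frame ids must be unique and strictly increasing")
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single string")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@coords)[3], "frames x",
      dim(object@coords)[1], "atoms, condition:", object@condition, "\n")
})

#' Transmembrane subsegment scheme
#'
#' Maps named subsegments (e.g. `"TM2e"`: extracellular third of TM2) to
#' inclusive author residue-number ranges. The built-in human CB1R scheme is
#' returned by [cb1rScheme()].
#'
#' @slot table data.frame with columns `name`, `tm`, `part`, `start`, `end`.
#' @aliases SubsegmentScheme-class
#' @exportClass SubsegmentScheme
setClass("SubsegmentScheme", representation(table = "data.frame"))

setValidity("SubsegmentScheme", function(object) {
  t <- object@table
  need <- c("name", "tm", "part", "start", "end")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(t$name)) msg <- c(msg, "subsegment names must be unique")
  if (any(t$end < t$start)) msg <- c(msg, "every range must be non-empty")
  for (tm in unique(t$tm)) {
    sub <- t[t$tm == tm, ]
    res <- unlist(Map(seq.int, sub$start, sub$end))
    if (anyDuplicated(res))
      msg <- c(msg, sprintf("ranges within TM%s overlap", tm))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "SubsegmentScheme", function(object) {
  cat("SubsegmentScheme:", nrow(object@table), "subsegments over",
      length(unique(object@table$tm)), "TMs\n")
})

#' Ligand atom manifest
#'
#' Identifies the ligand's polar atoms by pharmacophore role (head oxygens,
#' linker/core nitrogens, tail fluorine) and the atom quadruples defining the
#' head-moiety dihedral angles chi1/chi2. Entries reference atom ids of the
#' parent [Structure].
#'
#' @slot resname ligand residue name.
#' @slot polarAtoms data.frame with columns `role`, `atomId`.
#' @slot dihedrals named list; each element a list with `quad` (4 atom ids,
#'   ordered) and optionally `rotating` (atom ids moved when the dihedral is
#'   driven by the synthetic generator).
#' @aliases LigandManifest-class
#' @exportClass LigandManifest
setClass("LigandManifest",
  representation(resname = "character", polarAtoms = "data.frame",
                 dihedrals = "list"))

setValidity("LigandManifest", function(object) {
  msg <- character()
  if (!all(c("role", "atomId") %in% names(object@polarAtoms)))
    return("polarAtoms must have columns role, atomId")
  for (nm in names(object@dihedrals)) {
    q <- object@dihedrals[[nm]]$quad
    if (length(q) != 4L || anyDuplicated(q))
      msg <- c(msg, sprintf("dihedral '%s' must have 4 distinct atoms", nm))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-frame feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features as rows and
#' trajectory frames as columns. `rowData` carries the feature descriptors:
#' `kind` (one of `ca_distance`, `ligand_polar_distance`, `interface_distance`,
#' `motif_dihedral`, `ligand_dihedral`, `sidechain_chi1`), the participating
#' residues (`resA` < `resB` for distances) and chains, the polar-atom
#' reference for pocket distances, the atom quadruple for dihedrals, `units`
#' (`"angstrom"` or `"degree"`) and the `region` tag (`pocket`, `tm`,
#' `interface`). The single assay `"values"` holds the per-frame values.
#'
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
#' @import SummarizedExperiment
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  msg <- character()
  need <- c("kind", "chainA", "resA", "chainB", "resB", "atomRef", "quad",
            "units", "region", "label")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns:", paste(need, collapse = ", ")))
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("assay 'values' is required")
  v <- SummarizedExperiment::assay(object, "values")
  if (nrow(v) > 0 && ncol(v) > 0) {
    isDist <- rd$units == "angstrom"
    if (any(isDist) && any(v[isDist, , drop = FALSE] < 0))
      msg <- c(msg, "distances must be non-negative")
    isAng <- rd$units == "degree"
    if (any(isAng)) {
      a <- v[isAng, , drop = FALSE]
      if (any(a <= -180 - 1e-9) || any(a > 180 + 1e-9))
        msg <- c(msg, "dihedrals must lie in (-180, 180]")
    }
  }
  if (!"frameId" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry frameId")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' K-means clustering result
#'
#' Partition of frames (or points) into `k` clusters with the within-cluster
#' sum of squared distances to centroids, `W_k`.
#'
#' @slot k number of clusters.
#' @slot labels integer cluster label per point, in `1..k`.
#' @slot wk within-cluster sum of squares `W_k`.
#' @slot sizes cluster sizes.
#' @slot centers centroid matrix, k x dims.
#' @aliases ClusterResult-class
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(k = "integer", labels = "integer", wk = "numeric",
                 sizes = "integer", centers = "matrix"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(object@sizes) != object@k || any(object@sizes == 0L))
    msg <- c(msg, "every cluster must be non-empty")
  if (object@wk < 0) msg <- c(msg, "W_k must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, " W_k =", format(object@wk),
      " sizes:", paste(object@sizes, collapse = "/"), "\n")
})

#' Gap-statistic result
#'
#' Per candidate cluster number `k`: the observed `log W_k`, the Monte-Carlo
#' estimate of its expectation under a uniform reference distribution over the
#' data's bounding box, the gap `Gap(k) = E*[log W_k] - log W_k`, the
#' reference standard deviation `sd_k` and the simulation error
#' `s_k = sd_k * sqrt(1 + 1/B)`.
#'
#' @slot k integer vector of candidate cluster numbers, `1..kMax`.
#' @slot logW observed `log W_k`.
#' @slot eLogW mean of the `B` reference `log W_k` values.
#' @slot gap `eLogW - logW`.
#' @slot sdk reference standard deviation per k.
#' @slot sk simulation error per k.
#' @slot B number of reference replicates.
#' @slot seed RNG seed used.
#' @aliases GapResult-class
#' @exportClass GapResult
setClass("GapResult",
  representation(k = "integer", logW = "numeric", eLogW = "numeric",
                 gap = "numeric", sdk = "numeric", sk = "numeric",
                 B = "integer", seed = "integer"))

setValidity("GapResult", function(object) {
  n <- length(object@k)
  msg <- character()
  if (!all(lengths(list(object@logW, object@eLogW, object@gap,
                        object@sdk, object@sk)) == n))
    msg <- c(msg, "per-k vectors must have equal length")
  if (any(object@sk < 0)) msg <- c(msg, "s_k must be >= 0")
  if (any(abs(object@gap - (object@eLogW - object@logW)) > 1e-12))
    msg <- c(msg, "Gap(k) must equal E*[log W_k] - log W_k exactly")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "GapResult", function(object) {
  cat("GapResult: k = 1..", max(object@k), ", B = ", object@B, "\n", sep = "")
  print(data.frame(k = object@k, logW = object@logW, gap = object@gap,
                   sk = object@sk))
})

#' Bootstrap-consensus correlation network
#'
#' Correlated feature pairs surviving the threshold, sequence-separation and
#' redundancy filters in every bootstrap replicate of the
#' sample -> cluster -> correlate -> filter pipeline, for one condition.
#'
#' @slot condition condition label.
#' @slot pairs data.frame: descriptor columns for both features, per-replicate
#'   Pearson r columns (`r_rep1`, ...) and `meanR`.
#' @slot nBoot number of bootstrap replicates.
#' @slot seeds integer child seeds used per replicate.
#' @slot params the [networkParams()] list used.
#' @aliases ConsensusNetwork-class
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
  representation(condition = "character", pairs = "data.frame",
                 nBoot = "integer", seeds = "integer", params = "list"))

setValidity("ConsensusNetwork", function(object) {
  msg <- character()
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  rcols <- grep("^r_rep", names(object@pairs))
  if (nrow(object@pairs) > 0 && length(rcols) != object@nBoot)
    msg <- c(msg, "pairs must carry one r column per replicate")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork (", object@condition, "): ", nrow(object@pairs),
      " consensus pairs over ", object@nBoot, " bootstrap replicates\n",
      sep = "")
})
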