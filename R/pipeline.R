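# Config-driven orchestration of the full two-condition comparison:
# per-condition clustering with gap-selected k, representative frames,
# contact / conformational / network analyses, cross-condition contrasts,
# and a Markdown + JSON report with full provenance.

#' Read and validate a run configuration
#'
#' YAML with blocks `paths` (structure, trajectoryA, trajectoryB,
#' residueMap, manifest), `conditions` (labels `A`, `B`), `chains`
#' (receptor, ligand, galpha), optional `params` (any [networkParams()]
#' argument), and `outDir`.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  stopIf(!file.exists(path), "config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
validateRunConfig <- function(config) {
  need <- c("paths", "outDir")
  stopIf(!all(need %in% names(config)),
         "config must define: ", paste(need, collapse = ", "))
  pneed <- c("structure", "trajectoryA", "trajectoryB", "residueMap",
             "manifest")
  stopIf(!all(pneed %in% names(config$paths)),
         "config paths must define: ", paste(pneed, collapse = ", "))
  for (p in pneed) {
    stopIf(!file.exists(config$paths[[p]]),
           "configured file missing (", p, "): ", config$paths[[p]])
  }
  config$conditions <- config$conditions %||% list(A = "conditionA",
                                                   B = "conditionB")
  config$chains <- config$chains %||% list(receptor = "R", ligand = "L",
                                           galpha = "G")
  config$params <- config$params %||% list()
  invisible(config)
}

roundDf <- function(df, digits) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], digits)
  df
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Per-condition clustering stage: sample, embed, gap-select k, cluster,
# back-map the representative cluster.
clusterStage <- function(trajectory, scheme, params, receptorChain,
                         seedOffset, rmsd = NULL, embedding = NULL) {
  st <- trajectory@structure
  selection <- tmBackboneIndices(st, scheme, chain = receptorChain)
  if (is.null(rmsd)) rmsd <- pairwiseRmsd(trajectory, selection)
  if (is.null(embedding)) {
    embedding <- mdsEmbed(rmsd, params$varianceExplained, params$maxDim)
  }
  sampleIds <- sampleFrames(trajectory, n = params$framesPerBoot,
                            seed = deriveSeed(params$seed, seedOffset))
  pts <- embedding[match(sampleIds, frameIds(trajectory)), , drop = FALSE]
  gap <- gapStatistic(pts, kMax = params$kMax, B = params$B,
                      seed = deriveSeed(params$seed, seedOffset + 1L),
                      nInit = params$nInit)
  k <- suppressWarnings(selectK(gap))
  cl <- kmeansCluster(pts, k, seed = deriveSeed(params$seed, seedOffset + 2L),
                      nInit = params$nInit)
  list(rmsd = rmsd, embedding = embedding, sampleIds = sampleIds, gap = gap,
       k = as.integer(k), cluster = cl,
       representative = representativeFrames(cl, sampleIds),
       occupancy = as.numeric(cl@sizes) / length(sampleIds))
}

#' Run the full two-condition comparison
#'
#' Executes, per condition: bootstrap frame sampling, RMSD/MDS clustering
#' with gap-statistic selection of k, representative-cluster back-mapping;
#' then contact frequencies with difference highlighting, subsegment COM
#' displacement and COM-distance distributions, ligand head dihedral mode
#' detection and 2D maps, motif rotamer shifts, and the bootstrap-consensus
#' correlation networks with per-TM involvement. Writes tables, a Markdown
#' report and a JSON twin under `config$outDir`.
#'
#' @param config a validated config list ([readRunConfig()]), or the list
#'   returned by [makeConditionPair()] via [runCompareOnPair()].
#' @return the report list, invisibly.
#' @export
runCompare <- function(config) {
  config <- validateRunConfig(config)
  chains <- config$chains
  structure <- readStructure(config$paths$structure)
  residueMap <- readResidueMap(config$paths$residueMap)
  manifest <- readLigandManifest(config$paths$manifest)
  scheme <- cb1rScheme()
  trajA <- readTrajectory(config$paths$trajectoryA, structure,
                          condition = config$conditions$A)
  trajB <- readTrajectory(config$paths$trajectoryB, structure,
                          condition = config$conditions$B)
  runCompareImpl(structure, residueMap, manifest, scheme, trajA, trajB,
                 chains, config$params, config$outDir)
}

#' @rdname runCompare
#' @param pair list from [makeConditionPair()].
#' @param params list of [networkParams()] overrides.
#' @param outDir output directory.
#' @export
runCompareOnPair <- function(pair, params = list(), outDir) {
  runCompareImpl(pair$structure, pair$residueMap, pair$manifest,
                 cb1rScheme(), pair$trajectoryA, pair$trajectoryB,
                 list(receptor = "R", ligand = "L", galpha = "G"),
                 params, outDir)
}

runCompareImpl <- function(structure, residueMap, manifest, scheme,
                           trajA, trajB, chains, paramOverrides, outDir) {
  params <- do.call(networkParams, paramOverrides)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(outDir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  condA <- conditionLabel(trajA); condB <- conditionLabel(trajB)
  report <- list(provenance = list(
    package = "MDAllostery",
    version = as.character(packageVersion("MDAllostery")),
    seed = params$seed, params = unclass(params),
    conditions = c(condA, condB),
    nFrames = c(nFrames(trajA), nFrames(trajB))))

  ## clustering
  stageA <- clusterStage(trajA, scheme, params, chains$receptor, 11L)
  stageB <- clusterStage(trajB, scheme, params, chains$receptor, 21L)
  report$clustering <- list(
    A = list(selectedK = stageA$k, occupancy = stageA$occupancy,
             nRepresentative = length(stageA$representative),
             gap = gapTable(stageA$gap)),
    B = list(selectedK = stageB$k, occupancy = stageB$occupancy,
             nRepresentative = length(stageB$representative),
             gap = gapTable(stageB$gap)))
  writeTsv(roundDf(gapTable(stageA$gap), 4),
           file.path(tdir, "gap_statistic_A.tsv"))
  writeTsv(roundDf(gapTable(stageB$gap), 4),
           file.path(tdir, "gap_statistic_B.tsv"))

  ## contacts
  ligName <- atomTable(structure)$resname[
    atomTable(structure)$chain == chains$ligand][1]
  ctA <- contactFrequency(trajA, ligName, frames = stageA$representative,
                          cutoff = params$contactCutoff,
                          receptorChain = chains$receptor)
  ctB <- contactFrequency(trajB, ligName, frames = stageB$representative,
                          cutoff = params$contactCutoff,
                          receptorChain = chains$receptor)
  diffs <- highlightDifferences(list(ctA, ctB))
  report$contacts <- list(tableA = ctA, tableB = ctB, differences = diffs)
  writeTsv(roundDf(rbind(ctA, ctB), 4), file.path(tdir, "contact_frequencies.tsv"))
  writeTsv(roundDf(diffs, 4), file.path(tdir, "contact_differences.tsv"))

  ## conformation
  comsA <- allSubsegmentComs(trajA, scheme, frames = stageA$representative,
                             chain = chains$receptor)
  comsB <- allSubsegmentComs(trajB, scheme, frames = stageB$representative,
                             chain = chains$receptor)
  a <- atomTable(structure)
  lig <- which(a$chain == chains$ligand & toupper(a$element) != "H")
  pocketCenter <- colMeans(structure@coords[lig, , drop = FALSE])
  dcom <- deltaComReport(comsA, comsB, pocketCenter = pocketCenter)
  comDistA <- comDistanceSeries(trajA, scheme, frames = stageA$representative,
                                chain = chains$receptor)
  comDistB <- comDistanceSeries(trajB, scheme, frames = stageB$representative,
                                chain = chains$receptor)
  dihA <- featureValues(ligandHeadDihedrals(trajA, manifest,
                                            frames = stageA$representative))
  dihB <- featureValues(ligandHeadDihedrals(trajB, manifest,
                                            frames = stageB$representative))
  modesA <- detectModes(dihA[, 1])
  modesB <- detectModes(dihB[, 1])
  map2dA <- dihedral2dMap(dihA[, 1], dihA[, 2])
  map2dB <- dihedral2dMap(dihB[, 1], dihB[, 2])
  report$conformation <- list(
    deltaCom = dcom, chi1ModesA = modesA, chi1ModesB = modesB,
    comDistanceMeansA = colMeans(comDistA),
    comDistanceMeansB = colMeans(comDistB))
  writeTsv(roundDf(dcom, 2), file.path(tdir, "delta_com.tsv"))
  writeTsv(roundDf(modesA, 1), file.path(tdir, "chi1_modes_A.tsv"))
  writeTsv(roundDf(modesB, 1), file.path(tdir, "chi1_modes_B.tsv"))

  ## rotamer shifts of the conserved motif residues
  motifRes <- resnoFromBw(residueMap[residueMap$chain == chains$receptor, ],
                          GPCR_MOTIF_BW)
  rot <- list()
  fmChiA <- sidechainChi1(trajA, motifRes, chain = chains$receptor,
                          frames = stageA$representative)
  fmChiB <- sidechainChi1(trajB, motifRes, chain = chains$receptor,
                          frames = stageB$representative)
  chiA <- featureValues(fmChiA)
  chiB <- featureValues(fmChiB)
  descA <- featureDescriptors(fmChiA)
  for (i in seq_len(ncol(chiA))) {
    s <- rotamerShift(chiA[, i], chiB[, i])
    rot[[i]] <- data.frame(resno = descA$resA[i], meanA = s$meanA,
                           meanB = s$meanB, diff = s$diff,
                           flagged = s$flagged)
  }
  rot <- do.call(rbind, rot)
  report$rotamers <- rot
  writeTsv(roundDf(rot, 1), file.path(tdir, "rotamer_shifts.tsv"))

  ## networks
  netA <- bootstrapConsensus(trajA, manifest, residueMap, scheme,
                             chains$receptor, chains$galpha, params,
                             embedding = stageA$embedding)
  netB <- bootstrapConsensus(trajB, manifest, residueMap, scheme,
                             chains$receptor, chains$galpha, params,
                             embedding = stageB$embedding)
  invA <- tmInvolvement(netA, scheme, gChain = chains$galpha)
  invB <- tmInvolvement(netB, scheme, gChain = chains$galpha)
  report$network <- list(
    nPairsA = nrow(networkPairs(netA)), nPairsB = nrow(networkPairs(netB)),
    involvementA = invA, involvementB = invB)
  exportNetwork(netA, file.path(tdir, "network_A_edges.tsv"))
  exportNetwork(netB, file.path(tdir, "network_B_edges.tsv"))
  writeTsv(roundDf(invA, 1), file.path(tdir, "tm_involvement_A.tsv"))
  writeTsv(roundDf(invB, 1), file.path(tdir, "tm_involvement_B.tsv"))

  writeReport(report, outDir)
  invisible(report)
}

# Markdown + JSON twin of the comparison report; content is deterministic
# for a fixed seed (no timestamps, no absolute paths).
writeReport <- function(report, outDir) {
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  fmt1 <- function(x) sprintf("%.1f", x)
  md <- c(
    "# Two-condition MD comparison report", "",
    paste0("Conditions: ", paste(report$provenance$conditions, collapse = " vs ")),
    paste0("Seed: ", report$provenance$seed,
           "; frames: ", paste(report$provenance$nFrames, collapse = "/")),
    "",
    "## Clustering",
    paste0("- Selected k (A): ", report$clustering$A$selectedK,
           "; cluster occupancy: ",
           paste(fmt1(100 * report$clustering$A$occupancy), collapse = "/"), "%"),
    paste0("- Selected k (B): ", report$clustering$B$selectedK,
           "; cluster occupancy: ",
           paste(fmt1(100 * report$clustering$B$occupancy), collapse = "/"), "%"),
    "",
    "## Contacts (reportable residues, % of frames)")
  d <- report$contacts$differences
  for (i in seq_len(nrow(d))) {
    md <- c(md, sprintf("- residue %d: %s%% vs %s%% (diff %s%%)%s",
                        d$resno[i], fmt1(100 * d$freqA[i]),
                        fmt1(100 * d$freqB[i]), fmt1(100 * d$diff[i]),
                        if (d$highlighted[i]) "  ** highlighted" else ""))
  }
  md <- c(md, "", "## Subsegment COM displacement (A - B, Angstrom)")
  dc <- report$conformation$deltaCom
  top <- dc[order(-dc$magnitude), ][seq_len(min(5, nrow(dc))), ]
  for (i in seq_len(nrow(top))) {
    md <- c(md, sprintf("- %s: |Delta| = %.2f, inward = %.2f",
                        top$subsegment[i], top$magnitude[i], top$inward[i]))
  }
  md <- c(md, "", "## Ligand head chi1 modes",
          sprintf("- A: %d mode(s) at %s deg", nrow(report$conformation$chi1ModesA),
                  paste(fmt1(report$conformation$chi1ModesA$location),
                        collapse = ", ")),
          sprintf("- B: %d mode(s) at %s deg (occupancy %s)",
                  nrow(report$conformation$chi1ModesB),
                  paste(fmt1(report$conformation$chi1ModesB$location),
                        collapse = ", "),
                  paste(sprintf("%.2f", report$conformation$chi1ModesB$occupancy),
                        collapse = "/")),
          "", "## Consensus networks",
          sprintf("- A: %d pairs; B: %d pairs", report$network$nPairsA,
                  report$network$nPairsB),
          "- TM involvement (%, A vs B):")
  invA <- report$network$involvementA; invB <- report$network$involvementB
  for (i in seq_len(nrow(invA))) {
    md <- c(md, sprintf("  - TM%d: %s vs %s", invA$tm[i],
                        fmt1(invA$percent[i]), fmt1(invB$percent[i])))
  }
  writeLines(md, file.path(outDir, "report.md"))
  invisible(NULL)
}
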