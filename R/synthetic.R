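# Synthetic receptor / trajectory generator with planted ground truth.
# Emulates the statistical structures the analysis assumes -- multi-state
# receptor conformations, feature pairs co-varying at a chosen Pearson r,
# a one- or two-state ligand head dihedral process, residue-ligand contact
# schedules with chosen frequencies, and rigid inward subsegment shifts --
# on a coarse 7-helix bundle with ligand and G-alpha pseudo-chain.

# ---- geometry helpers -------------------------------------------------

rodrigues <- function(points, axisPoint, axisDir, angleDeg) {
  k <- axisDir / sqrt(sum(axisDir^2))
  a <- angleDeg * pi / 180
  v <- sweep(points, 2, axisPoint)
  kv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  kdv <- as.vector(v %*% k)
  out <- v * cos(a) + kv * sin(a) + outer(kdv * (1 - cos(a)), k)
  sweep(out, 2, axisPoint, "+")
}

unitVec <- function(v) v / sqrt(sum(v^2))

# ---- receptor construction --------------------------------------------

#' Generate a coarse synthetic receptor--ligand--G-alpha complex
#'
#' Builds a 7-helix-bundle-like geometry populating every subsegment of the
#' scheme (5 heavy atoms per residue: N, CA, C, CB, CG), a 20-atom ligand
#' with three head oxygens, linker/core nitrogens and a tail fluorine plus
#' two defined head dihedrals, and a 30-residue G-alpha pseudo-helix docked
#' under the intracellular face. Deterministic for a fixed seed.
#'
#' @param scheme a [SubsegmentScheme] (default the built-in CB1R scheme).
#' @param gResidues number of G-alpha residues.
#' @param seed RNG seed (construction is deterministic; the seed is part of
#'   the contract so generated artifacts are reproducible byte for byte).
#' @return list with elements `structure` ([Structure]), `residueMap`
#'   (data.frame) and `manifest` ([LigandManifest]).
#' @export
generateReceptor <- function(scheme = cb1rScheme(), gResidues = 30L,
                             seed = 1L) {
  t <- schemeTable(scheme)
  atoms <- list(); coords <- list()
  nextId <- 1L
  addAtom <- function(name, element, resno, resname, chain, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      id = nextId, name = name, element = element, resno = resno,
      resname = resname, chain = chain, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    nextId <<- nextId + 1L
  }
  zBot <- -16; zTop <- 16
  rBot <- 14.5; rTop <- 10.5
  for (h in sort(unique(t$tm))) {
    res <- tmResidues(scheme, h)
    # orient: the extracellular subsegment end sits at the top (z = zTop)
    eStart <- t$start[t$tm == h & t$part == "e"]
    iStart <- t$start[t$tm == h & t$part == "i"]
    up <- eStart > iStart  # residue number increases toward extracellular
    n <- length(res)
    theta <- 2 * pi * (h - 1) / 7
    for (idx in seq_len(n)) {
      rank <- if (up) idx else n + 1L - idx
      tt <- (rank - 1) / max(n - 1, 1)
      z <- zBot + (zTop - zBot) * tt
      rad <- rBot + (rTop - rBot) * tt
      axis <- c(rad * cos(theta), rad * sin(theta), z)
      e1 <- c(cos(theta), sin(theta), 0)     # radial outward (bundle)
      e2 <- c(-sin(theta), cos(theta), 0)    # tangent
      phi <- (100 * (rank - 1)) * pi / 180   # helical twist
      vhat <- cos(phi) * e1 + sin(phi) * e2  # side-chain direction
      ca <- axis + 2.3 * vhat
      aDir <- unitVec(c((rTop - rBot) / (zTop - zBot) * cos(theta),
                        (rTop - rBot) / (zTop - zBot) * sin(theta), 1))
      r0 <- res[idx]
      addAtom("N", "N", r0, "GLY", "R", ca - 1.2 * aDir + 0.5 * e2)
      addAtom("CA", "C", r0, "GLY", "R", ca)
      addAtom("C", "C", r0, "GLY", "R", ca + 1.2 * aDir - 0.5 * e2)
      vrot <- cos(phi + 35 * pi / 180) * e1 + sin(phi + 35 * pi / 180) * e2
      addAtom("CB", "C", r0, "GLY", "R", ca + 1.5 * vhat + 0.3 * aDir)
      addAtom("CG", "C", r0, "GLY", "R",
              ca + 1.5 * vhat + 1.4 * vrot + 0.7 * aDir)
    }
  }
  # ligand: tail (F) - core ring (N2) - linker (N1) - head (C3 with O1-O3)
  lig <- rbind(
    F1  = c(-3.2,  0.5, 9.5), Ct1 = c(-2.0, 0.3, 9.2), Ct2 = c(-0.8, 0.2, 9.0),
    N2  = c( 0.4,  0.0, 9.0),
    Cr1 = c( 1.4,  0.9, 9.2), Cr2 = c( 2.6,  0.6, 9.6), Cr3 = c( 3.0, -0.7, 9.7),
    Cr4 = c( 2.1, -1.6, 9.3), Cr5 = c( 0.9, -1.3, 9.0), Cr6 = c( 3.9,  1.5, 9.9),
    Cl1 = c( 4.2, -1.2, 10.0),
    N1  = c( 4.4, -3.6, 10.2), C1 = c( 6.4, -2.0, 10.4), C2 = c( 7.8, -4.0, 10.7),
    C3  = c(10.2, -3.4, 10.8), O1 = c(11.4, -2.2, 10.6), O2 = c(11.2, -4.9, 11.1),
    C4  = c( 7.5, -5.2, 9.7),  O3 = c( 8.1, -6.3, 9.6),  C5 = c( 6.1, -5.4, 9.4))
  ligNames <- rownames(lig)
  ligIds <- integer(length(ligNames))
  for (i in seq_along(ligNames)) {
    el <- substr(ligNames[i], 1, 1)
    ligIds[i] <- nextId
    addAtom(ligNames[i], el, 501L, "LIG", "L", lig[i, ])
  }
  names(ligIds) <- ligNames
  # G-alpha pseudo-helix under the TM6/TM7 intracellular face
  g0 <- c(-6, -12, -19); g1 <- c(8, -10, -19.5)
  gDir <- unitVec(g1 - g0)
  gPerp1 <- unitVec(c(-gDir[2], gDir[1], 0))
  gPerp2 <- c(0, 0, 1)
  for (gr in seq_len(gResidues)) {
    tt <- (gr - 1) / max(gResidues - 1, 1)
    base <- g0 + tt * (g1 - g0)
    phi <- 100 * (gr - 1) * pi / 180
    ca <- base + 1.5 * (cos(phi) * gPerp1 + sin(phi) * gPerp2)
    addAtom("N", "N", gr, "GLY", "G", ca - 1.0 * gDir)
    addAtom("CA", "C", gr, "GLY", "G", ca)
    addAtom("C", "C", gr, "GLY", "G", ca + 1.0 * gDir)
  }
  st <- Structure(do.call(rbind, atoms), do.call(rbind, coords))
  a <- atomTable(st)
  recRes <- sort(unique(a$resno[a$chain == "R"]))
  residueMap <- rbind(
    data.frame(chain = "R", resnum = recRes, bw = bwFromResno(recRes, scheme),
               segment = assignSubsegment(scheme, recRes),
               stringsAsFactors = FALSE),
    data.frame(chain = "L", resnum = 501L, bw = "", segment = "ligand"),
    data.frame(chain = "G", resnum = seq_len(gResidues), bw = "",
               segment = "Galpha"))
  manifest <- LigandManifest(
    resname = "LIG",
    polarAtoms = data.frame(
      role = c("head_oxygen", "head_oxygen", "head_oxygen",
               "linker_nitrogen", "core_nitrogen", "tail_fluorine"),
      atomId = unname(ligIds[c("O1", "O2", "O3", "N1", "N2", "F1")]),
      stringsAsFactors = FALSE),
    dihedrals = list(
      chi1 = list(quad = unname(ligIds[c("N1", "C1", "C2", "C3")]),
                  rotating = unname(ligIds[c("C3", "O1", "O2", "C4",
                                             "O3", "C5")])),
      chi2 = list(quad = unname(ligIds[c("C1", "C2", "C3", "O1")]),
                  rotating = unname(ligIds[c("O1", "O2")]))))
  validateManifest(manifest, st)
  validateResidueMap(residueMap)
  list(structure = st, residueMap = residueMap, manifest = manifest)
}

# ---- generator parameters ---------------------------------------------

#' Synthetic trajectory generator parameters
#'
#' Describes the planted ground truth of one simulated condition.
#'
#' @param nFrames number of frames.
#' @param noiseSigma isotropic per-atom Gaussian noise (Angstrom).
#' @param seed RNG seed.
#' @param condition condition label.
#' @param clusterPlant `NULL` or `list(k, segments, magnitude, weights)`:
#'   frames occupy `k` conformational states; states `2..k` rigidly offset
#'   the atoms of the named subsegments by `magnitude` Angstrom in
#'   state-specific directions; `weights` are the state probabilities.
#' @param correlationPlants list of groups
#'   `list(members, r, amplitude)`; each member is
#'   `list(kind = "ca"|"interface"|"pocket", residues, gResidue, polarAtom,
#'   targetDist)` and displaces its second (or G-alpha, or pocket) residue
#'   along the feature axis so member feature pairs attain Pearson `r`
#'   (noise-attenuation compensated); single-member groups plant
#'   uncorrelated (null) features.
#' @param dihedralPlant `NULL` or `list(name, modes, occupancies,
#'   switchRate, angleNoise)`: drives the named ligand dihedral through a
#'   Markov jump process over the mode angles.
#' @param contactPlants list of `list(resno, freq, contactDist, apartDist)`:
#'   per-frame Bernoulli(`freq`) schedule placing the residue's closest
#'   heavy atom at `contactDist` (in contact) or `apartDist` Angstrom from
#'   the ligand.
#' @param shiftPlants list of `list(name, magnitude, direction)`: constant
#'   rigid displacement of a subsegment; `direction = "inward"` points from
#'   the subsegment's center of mass toward the ligand pocket center, or
#'   give an explicit 3-vector.
#' @return a named list of class `generatorParams`.
#' @export
generatorParams <- function(nFrames = 2000L, noiseSigma = 0.3, seed = 1L,
                            condition = "synthetic", clusterPlant = NULL,
                            correlationPlants = list(),
                            dihedralPlant = NULL, contactPlants = list(),
                            shiftPlants = list()) {
  stopIf(nFrames < 1L, "nFrames must be >= 1")
  stopIf(noiseSigma < 0, "noiseSigma must be >= 0")
  if (!is.null(dihedralPlant)) {
    occ <- dihedralPlant$occupancies %||% 1
    stopIf(abs(sum(occ) - 1) > 1e-9, "dihedral occupancies must sum to 1")
  }
  for (g in correlationPlants) {
    stopIf(!is.null(g$r) && (g$r < -1 || g$r > 1), "target r must be in [-1, 1]")
  }
  structure(list(nFrames = as.integer(nFrames), noiseSigma = noiseSigma,
                 seed = as.integer(seed), condition = condition,
                 clusterPlant = clusterPlant,
                 correlationPlants = correlationPlants,
                 dihedralPlant = dihedralPlant,
                 contactPlants = contactPlants, shiftPlants = shiftPlants),
            class = "generatorParams")
}

# atom row indices moved by each positional plant (conflict detection)
plantAtomSets <- function(structure, params, scheme, manifest) {
  a <- atomTable(structure)
  sets <- list()
  addSet <- function(label, idx) {
    sets[[length(sets) + 1L]] <<- list(label = label, idx = idx)
  }
  if (!is.null(params$clusterPlant)) {
    res <- unlist(lapply(params$clusterPlant$segments,
                         function(s) subsegmentResidues(scheme, s)))
    addSet("clusterPlant", which(a$chain == "R" & a$resno %in% res))
  }
  for (gi in seq_along(params$correlationPlants)) {
    g <- params$correlationPlants[[gi]]
    for (mi in seq_along(g$members)) {
      m <- g$members[[mi]]
      idx <- switch(m$kind,
        ca = which(a$chain == "R" & a$resno == m$residues[2]),
        interface = which(a$chain == "G" & a$resno == m$gResidue),
        pocket = which(a$chain == "R" & a$resno == m$residues[1] &
                         !a$name %in% c("N", "CA", "C")),
        stop("unknown correlation member kind: ", m$kind))
      addSet(sprintf("correlationPlant[%d].member[%d]", gi, mi), idx)
    }
  }
  if (!is.null(params$dihedralPlant)) {
    rot <- manifest@dihedrals[[params$dihedralPlant$name]]$rotating
    stopIf(is.null(rot), "manifest lacks rotating atoms for dihedral ",
           params$dihedralPlant$name)
    addSet("dihedralPlant", match(rot, a$id))
  }
  for (ci in seq_along(params$contactPlants)) {
    cp <- params$contactPlants[[ci]]
    addSet(sprintf("contactPlant[%d]", ci),
           which(a$chain == "R" & a$resno == cp$resno &
                   !a$name %in% c("N", "CA", "C")))
  }
  for (si in seq_along(params$shiftPlants)) {
    sp <- params$shiftPlants[[si]]
    res <- subsegmentResidues(scheme, sp$name)
    addSet(sprintf("shiftPlant[%d]", si),
           which(a$chain == "R" & a$resno %in% res))
  }
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      common <- intersect(sets[[i]]$idx, sets[[j]]$idx)
      stopIf(length(common) > 0, "conflicting plants: ", sets[[j]]$label,
             " and ", sets[[i]]$label, " both move atom(s) ",
             paste(head(a$id[common], 3), collapse = ", "))
    }
  }
  invisible(sets)
}

# Markov jump process over mode indices with stationary distribution
# proportional to the occupancies; switchRate c sets transition
# probabilities p(i -> j) = c * pi_j for j != i.
markovStates <- function(n, occupancies, switchRate) {
  k <- length(occupancies)
  if (k == 1L) return(rep(1L, n))
  s <- integer(n)
  s[1] <- sample.int(k, 1L, prob = occupancies)
  for (t in seq.int(2L, n)) {
    p <- switchRate * occupancies
    p[s[t - 1L]] <- 1 - sum(p[-s[t - 1L]])
    s[t] <- sample.int(k, 1L, prob = p)
  }
  s
}

closestHeavyPair <- function(structure, residueIdx, targetIdx) {
  co <- structure@coords
  best <- c(NA_integer_, NA_integer_); bestD <- Inf
  for (i in residueIdx) {
    d <- sqrt(rowSums((co[targetIdx, , drop = FALSE] -
                         matrix(co[i, ], nrow = length(targetIdx),
                                ncol = 3, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] < bestD) { bestD <- d[j]; best <- c(i, targetIdx[j]) }
  }
  list(residueAtom = best[1], targetAtom = best[2], dist = bestD)
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Frames are the base coordinates plus, in order: conformational-state
#' offsets (cluster plant), latent-variable-coupled displacements
#' (correlation plants, with mixing weights compensated for the coordinate
#' noise so realized Pearson r matches the target), the dihedral jump
#' process, the contact on/off displacement schedule, constant subsegment
#' shifts, and isotropic Gaussian noise. Returns the trajectory together
#' with the realized ground truth (state labels, schedules, empirical r).
#'
#' @param structure a [Structure] from [generateReceptor()].
#' @param params a [generatorParams()] list.
#' @param scheme the [SubsegmentScheme] the plants refer to.
#' @param manifest the [LigandManifest] (needed for dihedral/pocket/contact
#'   plants).
#' @return list with elements `trajectory` ([Trajectory]) and `groundTruth`
#'   (list).
#' @export
generateTrajectory <- function(structure, params, scheme = cb1rScheme(),
                               manifest = NULL) {
  a <- atomTable(structure)
  base <- structure@coords
  nf <- params$nFrames
  plantAtomSets(structure, params, scheme, manifest)
  ligHeavy <- which(a$resname == "LIG" & toupper(a$element) != "H")
  pocketCenter <- if (length(ligHeavy)) colMeans(base[ligHeavy, , drop = FALSE])
    else c(0, 0, 0)
  truth <- list(condition = params$condition, seed = params$seed)
  coords <- array(rep(base, nf), dim = c(nrow(base), 3L, nf))
  withSeed(params$seed, {
    # 1. conformational states
    if (!is.null(params$clusterPlant)) {
      cp <- params$clusterPlant
      w <- cp$weights %||% rep(1 / cp$k, cp$k)
      states <- sample.int(cp$k, nf, replace = TRUE, prob = w)
      res <- unlist(lapply(cp$segments,
                           function(s) subsegmentResidues(scheme, s)))
      idx <- which(a$chain == "R" & a$resno %in% res)
      dirs <- lapply(seq_len(cp$k), function(s) {
        if (s == 1L) c(0, 0, 0) else {
          ang <- 2 * pi * (s - 1) / cp$k + 0.7
          cp$magnitude * unitVec(c(cos(ang), sin(ang), 0.3))
        }
      })
      for (f in seq_len(nf)) {
        off <- dirs[[states[f]]]
        if (any(off != 0)) {
          coords[idx, , f] <- sweep(coords[idx, , f, drop = TRUE], 2, off, "+")
        }
      }
      truth$clusterStates <- states
      truth$clusterK <- cp$k
    }
    # 2. correlation plants
    corTruth <- list()
    for (gi in seq_along(params$correlationPlants)) {
      g <- params$correlationPlants[[gi]]
      amp <- g$amplitude %||% 2
      nm <- length(g$members)
      if (nm > 1L) {
        s2 <- amp^2
        rho2 <- (g$r %||% 0.95) * (s2 + 2 * params$noiseSigma^2) / s2
        stopIf(rho2 > 1, "correlation plant ", gi,
               ": amplitude too small for target r under this noise")
        rho <- sqrt(rho2)
      } else rho <- 1
      z <- rnorm(nf)
      members <- list()
      for (mi in seq_len(nm)) {
        m <- g$members[[mi]]
        u <- if (nm > 1L) rho * z + sqrt(1 - rho^2) * rnorm(nf) else rnorm(nf)
        if (m$kind == "ca") {
          iA <- which(a$chain == "R" & a$resno == m$residues[1] & a$name == "CA")
          iB <- which(a$chain == "R" & a$resno == m$residues[2] & a$name == "CA")
          u3 <- unitVec(base[iB, ] - base[iA, ])
          idx <- which(a$chain == "R" & a$resno == m$residues[2])
          disp <- amp * u
        } else if (m$kind == "interface") {
          iA <- which(a$chain == "R" & a$resno == m$residues[1] & a$name == "CA")
          iB <- which(a$chain == "G" & a$resno == m$gResidue & a$name == "CA")
          u3 <- unitVec(base[iB, ] - base[iA, ])
          idx <- which(a$chain == "G" & a$resno == m$gResidue)
          disp <- amp * u
        } else {  # pocket: side-chain displacement, backbone untouched
          resIdx <- which(a$chain == "R" & a$resno == m$residues[1] &
                            toupper(a$element) != "H" &
                            !a$name %in% c("N", "CA", "C"))
          pAtom <- match(m$polarAtom, a$id)
          cp <- closestHeavyPair(structure, resIdx, pAtom)
          u3 <- unitVec(base[cp$targetAtom, ] - base[cp$residueAtom, ])
          idx <- resIdx
          target <- m$targetDist %||% 4
          disp <- cp$dist - (target + amp * u)  # toward polar atom
        }
        for (f in seq_len(nf)) {
          coords[idx, , f] <- sweep(coords[idx, , f, drop = TRUE], 2,
                                    disp[f] * u3, "+")
        }
        members[[mi]] <- m
      }
      corTruth[[gi]] <- list(members = members, targetR = g$r %||% NA_real_,
                             amplitude = amp)
    }
    # 3. dihedral jump process
    if (!is.null(params$dihedralPlant)) {
      dp <- params$dihedralPlant
      stopIf(is.null(manifest), "dihedral plant requires a manifest")
      dh <- manifest@dihedrals[[dp$name]]
      quadIdx <- match(dh$quad, a$id)
      rotIdx <- match(dh$rotating, a$id)
      occ <- dp$occupancies %||% rep(1 / length(dp$modes), length(dp$modes))
      st <- markovStates(nf, occ, dp$switchRate %||% 0.5)
      noise <- rnorm(nf, 0, dp$angleNoise %||% 7)
      # base dihedral of the unmodified geometry
      p <- base[quadIdx, ]
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
              n1[1] * n2[2] - n1[2] * n2[1])
      baseAngle <- atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
      targets <- wrapAngle(dp$modes[st] + noise)
      for (f in seq_len(nf)) {
        delta <- targets[f] - baseAngle
        coords[rotIdx, , f] <- rodrigues(coords[rotIdx, , f, drop = TRUE],
                                         coords[quadIdx[2], , f],
                                         coords[quadIdx[3], , f] -
                                           coords[quadIdx[2], , f], delta)
      }
      truth$dihedral <- list(name = dp$name, states = st,
                             modes = dp$modes,
                             targetAngles = targets,
                             realizedOccupancy = tabulate(st, length(occ)) / nf)
    }
    # 4. contact schedules
    contactTruth <- list()
    for (ci in seq_along(params$contactPlants)) {
      cp <- params$contactPlants[[ci]]
      resIdx <- which(a$chain == "R" & a$resno == cp$resno &
                        toupper(a$element) != "H" &
                        !a$name %in% c("N", "CA", "C"))
      pr <- closestHeavyPair(structure, resIdx, ligHeavy)
      u3 <- unitVec(base[pr$targetAtom, ] - base[pr$residueAtom, ])
      sched <- runif(nf) < cp$freq
      targetD <- ifelse(sched, cp$contactDist %||% 3.5, cp$apartDist %||% 9)
      disp <- pr$dist - targetD
      idx <- resIdx
      for (f in seq_len(nf)) {
        coords[idx, , f] <- sweep(coords[idx, , f, drop = TRUE], 2,
                                  disp[f] * u3, "+")
      }
      contactTruth[[ci]] <- list(resno = cp$resno, targetFreq = cp$freq,
                                 schedule = sched,
                                 realizedFreq = mean(sched))
    }
    # 5. subsegment shifts
    shiftTruth <- list()
    for (si in seq_along(params$shiftPlants)) {
      sp <- params$shiftPlants[[si]]
      res <- subsegmentResidues(scheme, sp$name)
      idx <- which(a$chain == "R" & a$resno %in% res)
      vec <- if (is.numeric(sp$direction %||% "inward")) {
        sp$magnitude * unitVec(sp$direction)
      } else {
        com <- colMeans(base[idx, , drop = FALSE])
        sp$magnitude * unitVec(pocketCenter - com)
      }
      coords[idx, , ] <- coords[idx, , , drop = FALSE] +
        rep(rep(vec, each = length(idx)), nf)
      shiftTruth[[si]] <- list(name = sp$name, vector = vec,
                               magnitude = sp$magnitude)
    }
    # 6. isotropic noise
    if (params$noiseSigma > 0) {
      coords <- coords + array(rnorm(length(coords), 0, params$noiseSigma),
                               dim = dim(coords))
    }
    truth$correlations <- corTruth
    truth$contacts <- contactTruth
    truth$shifts <- shiftTruth
  })
  traj <- Trajectory(structure, coords, condition = params$condition)
  # realized r, recomputed from the emitted frames
  for (gi in seq_along(truth$correlations)) {
    g <- truth$correlations[[gi]]
    series <- lapply(g$members, function(m) memberSeries(traj, m, manifest))
    if (length(series) > 1L) {
      truth$correlations[[gi]]$realizedR <- cor(do.call(cbind, series))
    }
  }
  list(trajectory = traj, groundTruth = truth)
}

# Feature series of a correlation-plant member, measured from a trajectory.
memberSeries <- function(trajectory, m, manifest = NULL) {
  a <- atomTable(trajectory)
  co <- coordArray(trajectory)
  fr <- seq_len(nFrames(trajectory))
  if (m$kind == "ca") {
    iA <- which(a$chain == "R" & a$resno == m$residues[1] & a$name == "CA")
    iB <- which(a$chain == "R" & a$resno == m$residues[2] & a$name == "CA")
    atomDistSeries(co, iA, iB, fr)
  } else if (m$kind == "interface") {
    iA <- which(a$chain == "R" & a$resno == m$residues[1] & a$name == "CA")
    iB <- which(a$chain == "G" & a$resno == m$gResidue & a$name == "CA")
    atomDistSeries(co, iA, iB, fr)
  } else {
    resIdx <- which(a$chain == "R" & a$resno == m$residues[1] &
                      toupper(a$element) != "H")
    pIdx <- match(m$polarAtom, a$id)
    minDistSeries(co, resIdx, pIdx, fr)
  }
}

#' Generate a matched condition pair with contrasting plants
#'
#' Emulates the two-ligand comparison the pipeline is built for. Condition A
#' ("MDMB-like"): unimodal ligand head chi1, rigid inward shifts of TM1e
#' (0.5 Angstrom) and TM2e (0.8 Angstrom), a pocket contact planted at 100%
#' frequency, and a correlated pathway (pocket distance - TM2 Calpha
#' distance - TM7/G-alpha interface distance sharing one latent). Condition
#' B ("MMB-like"): bimodal chi1 (modes 80/160 degrees, 60/40 occupancy), no
#' shift, the same pocket contact planted at 46%, and a TM3-internal
#' correlated pair only. Both share a two-state conformational plant on TM6.
#'
#' @param scheme a [SubsegmentScheme].
#' @param seed master seed (conditions derive child seeds).
#' @param nFrames frames per condition.
#' @param noiseSigma per-atom noise (Angstrom).
#' @param paramsA,paramsB optional full [generatorParams()] overrides.
#' @return list with `structure`, `residueMap`, `manifest`, `trajectoryA`,
#'   `trajectoryB`, `truthA`, `truthB`.
#' @export
makeConditionPair <- function(scheme = cb1rScheme(), seed = 1L,
                              nFrames = 2000L, noiseSigma = 0.3,
                              paramsA = NULL, paramsB = NULL) {
  rec <- generateReceptor(scheme, seed = seed)
  clusterPlant <- list(k = 2L, segments = c("TM6e", "TM6m", "TM6i"),
                       magnitude = 2.5, weights = c(0.65, 0.35))
  if (is.null(paramsA)) {
    paramsA <- generatorParams(
      nFrames = nFrames, noiseSigma = noiseSigma,
      seed = deriveSeed(seed, 101L), condition = "MDMB-like",
      clusterPlant = clusterPlant,
      dihedralPlant = list(name = "chi1", modes = 80, occupancies = 1,
                           switchRate = 0.5, angleNoise = 7),
      shiftPlants = list(list(name = "TM1e", magnitude = 0.5,
                              direction = "inward"),
                         list(name = "TM2e", magnitude = 0.8,
                              direction = "inward")),
      contactPlants = list(list(resno = 194L, freq = 1.0)),
      correlationPlants = list(list(
        r = 0.92, amplitude = 2,
        members = list(
          list(kind = "pocket", residues = 187L,
               polarAtom = rec$manifest@polarAtoms$atomId[1], targetDist = 4),
          list(kind = "ca", residues = c(165L, 172L)),
          list(kind = "interface", residues = 398L, gResidue = 10L)))))
  }
  if (is.null(paramsB)) {
    paramsB <- generatorParams(
      nFrames = nFrames, noiseSigma = noiseSigma,
      seed = deriveSeed(seed, 202L), condition = "MMB-like",
      clusterPlant = clusterPlant,
      dihedralPlant = list(name = "chi1", modes = c(80, 160),
                           occupancies = c(0.6, 0.4), switchRate = 0.5,
                           angleNoise = 7),
      contactPlants = list(list(resno = 194L, freq = 0.46)),
      correlationPlants = list(list(
        r = 0.92, amplitude = 2,
        members = list(list(kind = "ca", residues = c(186L, 193L)),
                       list(kind = "ca", residues = c(203L, 210L)))))
  )}
  genA <- generateTrajectory(rec$structure, paramsA, scheme, rec$manifest)
  genB <- generateTrajectory(rec$structure, paramsB, scheme, rec$manifest)
  list(structure = rec$structure, residueMap = rec$residueMap,
       manifest = rec$manifest, trajectoryA = genA$trajectory,
       trajectoryB = genB$trajectory, truthA = genA$groundTruth,
       truthB = genB$groundTruth)
}
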