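# Shared fixtures, built in code and memoised across test files.

.fixtureCache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Full synthetic receptor complex (CB1R scheme geometry).
sharedReceptor <- function() memo("receptor", generateReceptor())

# Small two-condition pair for pipeline-level tests.
smallPair <- function() memo("smallPair", makeConditionPair(nFrames = 250L,
                                                            seed = 3L))

smallPipelineParams <- function(seed = 5L) {
  list(nBoot = 2L, framesPerBoot = 600L, seed = seed, kMax = 3L, B = 8L,
       nInit = 5L)
}

# Hand-built toy structure: nRes residues on chain "R", each with CA (+ an
# optional CB heavy atom), plus a 2-atom "LIG" residue on chain "L".
toyStructure <- function(nRes = 4, withCB = FALSE, ligand = TRUE) {
  atoms <- list(); coords <- list(); id <- 1L
  add <- function(name, element, resno, resname, chain, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      id = id, name = name, element = element, resno = resno,
      resname = resname, chain = chain, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    id <<- id + 1L
  }
  for (r in seq_len(nRes)) {
    base <- c(3 * r, 0, 0)
    add("CA", "C", r, "ALA", "R", base)
    if (withCB) add("CB", "C", r, "ALA", "R", base + c(0.5, 1.2, 0))
  }
  if (ligand) {
    add("C1", "C", 501L, "LIG", "L", c(0, 5, 0))
    add("O1", "O", 501L, "LIG", "L", c(1, 5.5, 0))
  }
  Structure(do.call(rbind, atoms), do.call(rbind, coords))
}

# Trajectory over a toy structure from an explicit list of frame matrices.
toyTrajectory <- function(structure, frames, condition = "toy") {
  Trajectory(structure, frames, condition = condition)
}

# Random rigid motion (rotation + translation) applied to an atoms x 3
# coordinate matrix.
randomRigidMotion <- function(seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -5, 5))
}

applyRigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, "+")
}

# Independent quaternion (Horn) superposition RMSD oracle.
hornRmsd <- function(X, Y) {
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lmax) / nrow(X)
  sqrt(max(msd, 0))
}

tmpfile <- function(name) file.path(tempdir(), paste0(sample.int(1e6, 1), name))

# md5 of a set of files, order-stable.
filesDigest <- function(paths) {
  unname(tools::md5sum(sort(paths)))
}
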