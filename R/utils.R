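# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats kmeans cor sd runif rnorm cmdscale setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed derivation (Lehmer step, keeps values < 2^31).
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 1103 * as.numeric(i)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular angle utilities
#'
#' `wrapAngle` maps angles (degrees) into `(-180, 180]`; `circularMean` is
#' the vector-averaged mean direction; `circularDiff` the minimal absolute
#' angular distance in `[0, 180]`.
#'
#' @param x,a,b angles in degrees.
#' @return numeric, degrees.
#' @export
wrapAngle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' @rdname wrapAngle
#' @export
circularMean <- function(x) {
  r <- x * pi / 180
  wrapAngle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' @rdname wrapAngle
#' @export
circularDiff <- function(a, b) {
  abs(wrapAngle(a - b))
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
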