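# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Wrap angles to (-pi, pi].
wrapAngle <- function(theta) {
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

# Absolute angular difference wrapped to [0, pi]. Differences below 1e-12
# rad are below the angular resolution of any representable displacement
# (they arise from floating-point accumulation of positions along an exact
# straight line) and are treated as no turn at all.
angleDiff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  d[!is.na(d) & d < 1e-12] <- 0
  d
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

assertScalarNum <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single numeric >= %s", name, min),
         call. = FALSE)
  invisible(x)
}
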