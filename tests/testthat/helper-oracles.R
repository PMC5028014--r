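# Independent oracles used to cross-check the implementation.

# Exact Euclidean distance transform by exhaustive search over all
# foreground/background pixel pairs. O(N^2); only for small images.
bruteDistanceTransform <- function(binary) {
  H <- nrow(binary); W <- ncol(binary)
  out <- matrix(0, H, W)
  bg <- which(binary == 0, arr.ind = TRUE)
  fg <- which(binary != 0, arr.ind = TRUE)
  if (!nrow(fg)) return(out)
  if (!nrow(bg)) { out[] <- Inf; out[binary == 0] <- 0; return(out) }
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  }
  out
}

# Full-graph CGP interpreter: computes EVERY node value in forward column
# order (no decoding / reachability analysis), with its own copy of the
# protected semantics. One input vector at a time.
bruteEvaluateCGP <- function(genome, x) {
  B <- 1e100
  clamp <- function(v) min(max(v, -B), B)
  fs <- cgpFunctionSet()
  ni <- genome@nInputs
  vals <- c(as.numeric(x), rep(0, genome@nColumns))
  for (k in seq_len(genome@nColumns)) {
    f <- fs$name[genome@funcGene[k]]
    a <- vals[genome@connGene[1, k] + 1]
    b <- vals[genome@connGene[2, k] + 1]
    v <- switch(f,
      "+" = a + b, "-" = a - b, "*" = a * b,
      "/" = if (b == 0) 1 else a / b,
      "SQR" = a^2, "SQRT" = sqrt(abs(a)), "CUBE" = a^3,
      "CONST0" = 0, "CONST1" = 1,
      "AND" = if (a > 0 && b > 0) 1 else 0,
      "OR" = if (a > 0 || b > 0) 1 else 0,
      "NAND" = if (a > 0 && b > 0) 0 else 1,
      "NOR" = if (a > 0 || b > 0) 0 else 1,
      "NOT" = if (a > 0) 0 else 1)
    vals[ni + k] <- clamp(v)
  }
  vals[genome@outputGene + 1]
}

# Backward reachability over the full graph by fixed-point iteration
# (independent of the stack-based decoder).
bruteActiveNodes <- function(genome) {
  fs <- cgpFunctionSet()
  ni <- genome@nInputs
  needed <- rep(FALSE, ni + genome@nColumns)
  needed[genome@outputGene + 1] <- TRUE
  repeat {
    before <- needed
    for (k in seq_len(genome@nColumns)) {
      if (!needed[ni + k]) next
      ar <- fs$arity[genome@funcGene[k]]
      if (ar >= 1) needed[genome@connGene[1, k] + 1] <- TRUE
      if (ar >= 2) needed[genome@connGene[2, k] + 1] <- TRUE
    }
    if (identical(before, needed)) break
  }
  which(needed[-seq_len(ni)]) - 1L
}

# Textbook sums-of-squares one-way ANOVA.
ssAnova <- function(groups) {
  vals <- unlist(groups)
  grand <- mean(vals)
  k <- length(groups); N <- length(vals)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, p = pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Hand-built genome: nodes is a list of c(funcName, conn1, conn2) with
# 0-based addresses; remaining columns are filled with inert CONST0 nodes.
makeGenome <- function(nodes, output, nInputs = 10L, nColumns = 70L) {
  fs <- cgpFunctionSet()
  funcGene <- rep(which(fs$name == "CONST0"), nColumns)
  connGene <- matrix(0L, 2L, nColumns)
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    funcGene[k] <- which(fs$name == nd[[1]])
    connGene[1, k] <- as.integer(nd[[2]])
    connGene[2, k] <- as.integer(nd[[3]])
  }
  new("CGPGenome", nInputs = as.integer(nInputs),
      nColumns = as.integer(nColumns), levelsBack = as.integer(nColumns),
      funcGene = as.integer(funcGene), connGene = connGene,
      outputGene = as.integer(output), functionSet = fs$name)
}

# Table of printed per-video average migration speeds (control, 10 uM ATP,
# 50 uM ATP) used for the ANOVA checks.
speedGroups <- function() {
  list(control = c(3.52, 3.75, 3.45, 3.56),
       atp10 = c(3.04, 3.09, 3.08, 3.01),
       atp50 = c(2.00, 2.22, 2.06, 1.83))
}

# Two-class feature-table configuration with class means following the
# observed control vs 50 uM ATP trends (speed 3.57 vs 2.03 px/frame,
# angular velocity 1.35 vs 1.79 rad/frame).
trendTableConfig <- function(sd = 0, nPerClass = 12, seed = 1) {
  mA <- c(3.57, 3.20, 2.50, 1.35, 1.30, 1.25, 0.50, 5.0, 4.0, 3.0)
  mB <- c(2.03, 1.80, 1.40, 1.79, 1.85, 1.90, 0.80, 6.0, 6.5, 5.0)
  featureTableConfig(nPerClass = nPerClass,
                     classMeans = list(mA, mB),
                     classSds = list(rep(sd, 10), rep(sd, 10)),
                     classLabels = c("noPPADS", "PPADS"), seed = seed)
}
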