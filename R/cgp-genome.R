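# Cartesian Genetic Programming core: fixed-length genomes encoding a
# single-row feed-forward graph, protected evaluation, point mutation and
# export of the active subgraph as an infix expression.

# Node outputs are clamped so that any genome maps finite inputs to finite
# outputs (SQR/CUBE/division chains can otherwise overflow the double range).
.CGP_CLAMP <- 1e100

clampVal <- function(x) pmin(pmax(x, -.CGP_CLAMP), .CGP_CLAMP)

#' The CGP function set
#'
#' Arithmetic operators \code{+ - * /}, \code{SQR}, \code{SQRT}, \code{CUBE};
#' constants \code{0} and \code{1}; logical operators \code{AND OR NAND NOR
#' NOT}. All functions are protected (total over the reals): division by
#' zero returns 1, \code{SQRT} acts on the absolute value, and logical
#' operators read an operand as true iff it is greater than 0 and emit
#' 1.0/0.0.
#'
#' @return \code{data.frame} with columns \code{name} and \code{arity}.
#' @export
cgpFunctionSet <- function() {
  data.frame(
    name = c("+", "-", "*", "/", "SQR", "SQRT", "CUBE", "CONST0", "CONST1",
             "AND", "OR", "NAND", "NOR", "NOT"),
    arity = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 2L, 2L, 2L, 2L, 1L))
}

# Protected primitive application, vectorized over operand vectors.
applyFunction <- function(name, a, b) {
  if (name %in% c("+", "-", "*", "/", "AND", "OR", "NAND", "NOR")) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
  }
  v <- switch(name,
    "+" = a + b,
    "-" = a - b,
    "*" = a * b,
    "/" = { q <- a / b; q[b == 0] <- 1; q },
    "SQR" = a * a,
    "SQRT" = sqrt(abs(a)),
    "CUBE" = a * a * a,
    "CONST0" = rep(0, length(a)),
    "CONST1" = rep(1, length(a)),
    "AND" = as.numeric(a > 0 & b > 0),
    "OR" = as.numeric(a > 0 | b > 0),
    "NAND" = as.numeric(!(a > 0 & b > 0)),
    "NOR" = as.numeric(!(a > 0 | b > 0)),
    "NOT" = as.numeric(!(a > 0)),
    stop("unknown function: ", name))
  clampVal(v)
}

# Allowed connection addresses for node k (0-based column index).
allowedAddresses <- function(nInputs, k, levelsBack) {
  lo <- max(0L, k - levelsBack)
  c(seq_len(nInputs) - 1L,
    if (k > 0L && lo < k) nInputs + lo:(k - 1L))
}

#' Create a random valid genome
#'
#' Function genes are drawn uniformly from the function set; each connection
#' gene uniformly over the addresses its column may legally read (inputs
#' plus nodes up to \code{levelsBack} columns earlier); the output gene
#' uniformly over all inputs and nodes. Uses the current RNG stream.
#'
#' @param nInputs number of program inputs (10 for the standard feature
#'   vector).
#' @param nColumns number of single-row nodes (default 70).
#' @param levelsBack connectivity constraint (default \code{nColumns}: full
#'   feed-forward connectivity).
#' @return a valid [CGPGenome-class].
#' @export
randomGenome <- function(nInputs = 10L, nColumns = 70L,
                         levelsBack = nColumns) {
  fs <- cgpFunctionSet()
  nInputs <- as.integer(nInputs); nColumns <- as.integer(nColumns)
  levelsBack <- as.integer(levelsBack)
  funcGene <- sample.int(nrow(fs), nColumns, replace = TRUE)
  connGene <- matrix(0L, 2L, nColumns)
  for (k in seq_len(nColumns) - 1L) {
    addr <- allowedAddresses(nInputs, k, levelsBack)
    connGene[, k + 1L] <- addr[sample.int(length(addr), 2L, replace = TRUE)]
  }
  outputGene <- sample.int(nInputs + nColumns, 1L) - 1L
  new("CGPGenome", nInputs = nInputs, nColumns = nColumns,
      levelsBack = levelsBack, funcGene = as.integer(funcGene),
      connGene = connGene, outputGene = as.integer(outputGene),
      functionSet = fs$name)
}

#' Active nodes of a genome
#'
#' The nodes reachable backwards from the output gene, returned as 0-based
#' column indices in increasing (hence evaluable/topological) order. Nodes
#' outside this set do not influence the program output.
#'
#' @param genome a [CGPGenome-class].
#' @return integer vector of active 0-based node indices (possibly empty,
#'   when the output reads an input directly).
#' @export
activeNodes <- function(genome) {
  fs <- cgpFunctionSet()
  ni <- genome@nInputs
  active <- logical(genome@nColumns)
  stack <- genome@outputGene
  while (length(stack)) {
    a <- stack[[1]]; stack <- stack[-1]
    if (a < ni) next
    k <- a - ni          # 0-based node index
    if (active[k + 1L]) next
    active[k + 1L] <- TRUE
    ar <- fs$arity[genome@funcGene[k + 1L]]
    if (ar >= 1L) stack <- c(stack, genome@connGene[1L, k + 1L])
    if (ar >= 2L) stack <- c(stack, genome@connGene[2L, k + 1L])
  }
  which(active) - 1L
}

#' Evaluate a genome
#'
#' Decodes the active subgraph and evaluates it with the protected function
#' semantics. Evaluation is vectorized: \code{inputs} may be a single
#' numeric vector (length \code{nInputs}) or a matrix/data.frame with one
#' row per case and \code{nInputs} columns.
#'
#' @param genome a [CGPGenome-class].
#' @param inputs numeric vector, matrix or data.frame of finite inputs.
#' @return numeric vector of outputs, one per input row (a single number
#'   for a vector input). Always finite for finite inputs.
#' @export
evaluateGenome <- function(genome, inputs) {
  validObject(genome)
  ni <- genome@nInputs
  single <- is.null(dim(inputs))
  X <- if (single) matrix(as.numeric(inputs), nrow = 1L) else
    as.matrix(inputs)
  if (ncol(X) != ni)
    stop(sprintf("expected %d inputs, got %d", ni, ncol(X)), call. = FALSE)
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  fs <- cgpFunctionSet()
  vals <- vector("list", ni + genome@nColumns)
  for (j in seq_len(ni)) vals[[j]] <- X[, j]
  for (k in activeNodes(genome)) {
    f <- fs$name[genome@funcGene[k + 1L]]
    a <- vals[[genome@connGene[1L, k + 1L] + 1L]]
    b <- vals[[genome@connGene[2L, k + 1L] + 1L]]
    if (is.null(a)) a <- rep(0, nrow(X))   # unreachable only if inactive
    if (is.null(b)) b <- rep(0, nrow(X))
    vals[[ni + k + 1L]] <- applyFunction(f, a, b)
  }
  out <- vals[[genome@outputGene + 1L]]
  if (single) out[[1]] else out
}

#' Point-mutate a genome
#'
#' Each gene (function, connection, output) is independently resampled with
#' probability \code{rate}, uniformly over its valid range; resampling may
#' reproduce the current value, so the per-gene change probability is
#' \code{rate * (1 - 1/rangeSize)}. The input genome is not modified. Uses
#' the current RNG stream.
#'
#' @param genome a [CGPGenome-class].
#' @param rate per-gene mutation probability in [0, 1].
#' @return a new valid [CGPGenome-class].
#' @export
mutateGenome <- function(genome, rate) {
  fs <- cgpFunctionSet()
  ni <- genome@nInputs; nc <- genome@nColumns; lb <- genome@levelsBack
  funcGene <- genome@funcGene
  connGene <- genome@connGene
  outputGene <- genome@outputGene
  nGenes <- 3L * nc + 1L
  hit <- runif(nGenes) < rate
  # gene order: per node (function, conn1, conn2), then the output gene
  for (k in seq_len(nc) - 1L) {
    base <- 3L * k
    if (hit[base + 1L])
      funcGene[k + 1L] <- sample.int(nrow(fs), 1L)
    if (hit[base + 2L] || hit[base + 3L]) {
      addr <- allowedAddresses(ni, k, lb)
      if (hit[base + 2L])
        connGene[1L, k + 1L] <- addr[sample.int(length(addr), 1L)]
      if (hit[base + 3L])
        connGene[2L, k + 1L] <- addr[sample.int(length(addr), 1L)]
    }
  }
  if (hit[nGenes])
    outputGene <- sample.int(ni + nc, 1L) - 1L
  new("CGPGenome", nInputs = ni, nColumns = nc, levelsBack = lb,
      funcGene = as.integer(funcGene), connGene = connGene,
      outputGene = as.integer(outputGene), functionSet = fs$name)
}

# 0-based positions (in the mutation gene order above) of genes that affect
# the program semantics: genes of active nodes plus the output gene.
activeGenePositions <- function(genome) {
  fs <- cgpFunctionSet()
  pos <- integer()
  for (k in activeNodes(genome)) {
    ar <- fs$arity[genome@funcGene[k + 1L]]
    pos <- c(pos, 3L * k,
             if (ar >= 1L) 3L * k + 1L,
             if (ar >= 2L) 3L * k + 2L)
  }
  c(pos, 3L * genome@nColumns)
}

#' Export a genome as a mathematical expression
#'
#' Walks the active subgraph and renders it as a fully parenthesized infix
#' expression over the feature names (\code{SQR}, \code{SQRT}, \code{CUBE}
#' and the logical operators render as function calls; the constants as
#' \code{0} and \code{1}). Also reports which inputs the expression uses —
#' the features the evolved classifier actually depends on.
#'
#' @param genome a [CGPGenome-class].
#' @param featureNames names for the inputs; defaults to [featureNames()].
#' @return list with \code{expression} (character), \code{used_inputs}
#'   (0-based input indices, sorted) and \code{used_names}.
#' @seealso [evalExpression()] for re-evaluating the exported string with
#'   the same protected semantics.
#' @export
toExpression <- function(genome, featureNames = CellTrackCGP::featureNames()) {
  validObject(genome)
  ni <- genome@nInputs
  if (length(featureNames) != ni)
    stop("featureNames must have one entry per input", call. = FALSE)
  fs <- cgpFunctionSet()
  used <- integer()
  memo <- new.env(parent = emptyenv())
  render <- function(addr) {
    key <- as.character(addr)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (addr < ni) {
      used <<- union(used, addr)
      featureNames[addr + 1L]
    } else {
      k <- addr - ni
      f <- fs$name[genome@funcGene[k + 1L]]
      ar <- fs$arity[genome@funcGene[k + 1L]]
      if (f == "CONST0") "0"
      else if (f == "CONST1") "1"
      else if (ar == 1L)
        paste0(f, "(", render(genome@connGene[1L, k + 1L]), ")")
      else if (f %in% c("AND", "OR", "NAND", "NOR"))
        paste0(f, "(", render(genome@connGene[1L, k + 1L]), ", ",
               render(genome@connGene[2L, k + 1L]), ")")
      else
        paste0("(", render(genome@connGene[1L, k + 1L]), " ", f, " ",
               render(genome@connGene[2L, k + 1L]), ")")
    }
    memo[[key]] <- out
    out
  }
  expr <- render(genome@outputGene)
  used <- sort(used)
  list(expression = expr, used_inputs = used,
       used_names = featureNames[used + 1L])
}

#' Evaluate an exported expression
#'
#' Parses and evaluates a [toExpression()] string under the same protected
#' semantics as [evaluateGenome()] (protected division, clamped outputs,
#' \code{SQRT} of the absolute value, > 0 truth convention), with the
#' feature names bound to the supplied values.
#'
#' @param expression character expression from [toExpression()].
#' @param inputs named numeric vector, or a data.frame/matrix with named
#'   columns, supplying a value for every feature name that occurs.
#' @return numeric vector of values (one per row for tabular input).
#' @export
evalExpression <- function(expression, inputs) {
  env <- new.env(parent = baseenv())
  assign("+", function(a, b) applyFunction("+", a, b), envir = env)
  assign("-", function(a, b) applyFunction("-", a, b), envir = env)
  assign("*", function(a, b) applyFunction("*", a, b), envir = env)
  assign("/", function(a, b) applyFunction("/", a, b), envir = env)
  assign("SQR", function(a) applyFunction("SQR", a, a), envir = env)
  assign("SQRT", function(a) applyFunction("SQRT", a, a), envir = env)
  assign("CUBE", function(a) applyFunction("CUBE", a, a), envir = env)
  assign("AND", function(a, b) applyFunction("AND", a, b), envir = env)
  assign("OR", function(a, b) applyFunction("OR", a, b), envir = env)
  assign("NAND", function(a, b) applyFunction("NAND", a, b), envir = env)
  assign("NOR", function(a, b) applyFunction("NOR", a, b), envir = env)
  assign("NOT", function(a) applyFunction("NOT", a, a), envir = env)
  n <- 1L
  if (is.null(dim(inputs))) {
    for (nm in names(inputs)) assign(nm, inputs[[nm]], envir = env)
  } else {
    inputs <- as.data.frame(inputs)
    n <- nrow(inputs)
    for (nm in names(inputs)) assign(nm, inputs[[nm]], envir = env)
  }
  out <- eval(parse(text = expression), envir = env)
  if (length(out) == 1L && n > 1L) out <- rep(out, n)  # constant expression
  out
}
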