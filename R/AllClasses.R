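#' @import methods
NULL

#' Synthetic scene with ground truth
#'
#' Container for a generated time-lapse scene: the rendered 8-bit grayscale
#' frames, the true per-cell trajectories and the true per-frame contact
#' pairs, together with the generating configuration.
#'
#' Coordinates throughout the package are 0-based pixel centres with
#' \code{x} the column and \code{y} the row, origin at the top-left corner.
#'
#' @slot frames list of integer matrices (gray levels 0-255), one per frame,
#'   indexed \code{[row, col]}.
#' @slot tracks \code{data.frame} with columns \code{track_id, frame, x, y};
#'   frames are 0-based and contiguous within a track.
#' @slot contacts \code{data.frame} with columns \code{frame, id_a, id_b}
#'   (\code{id_a < id_b}): cell pairs whose centre distance is at most the
#'   generator's contact radius.
#' @slot config the \code{sceneConfig} list used to generate the scene.
#'
#' @seealso [generateScene()], [sceneConfig()]
#' @export
setClass("SceneTruth",
  representation(frames = "list", tracks = "data.frame",
                 contacts = "data.frame", config = "list"))

setValidity("SceneTruth", function(object) {
  msg <- character()
  if (length(object@frames) == 0L)
    msg <- c(msg, "at least one frame is required")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    msg <- c(msg, "frames must be matrices")
  tr <- object@tracks
  if (nrow(tr)) {
    if (!all(c("track_id", "frame", "x", "y") %in% names(tr)))
      msg <- c(msg, "tracks needs columns track_id, frame, x, y")
    else {
      gap <- vapply(split(tr$frame, tr$track_id),
                    function(f) any(diff(sort(f)) != 1L), logical(1))
      if (any(gap)) msg <- c(msg, "track frames must be contiguous")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cartesian Genetic Programming genome
#'
#' A fixed-length chromosome encoding a feed-forward (acyclic) graph of
#' function nodes on a single row. Addresses are 0-based:
#' \code{0 .. nInputs-1} are the program inputs and \code{nInputs + k}
#' is node \code{k} (0-based column index). Each node carries a function
#' gene (1-based index into the function set) and two connection genes;
#' unary functions read only the first connection, constants read neither,
#' but the genes are always present so the genome length is fixed.
#'
#' @slot nInputs number of program inputs.
#' @slot nColumns number of function nodes (single row).
#' @slot levelsBack connectivity constraint: node \code{k} may read inputs
#'   and nodes in columns \code{k - levelsBack .. k - 1}.
#' @slot funcGene integer vector, length \code{nColumns}; 1-based index into
#'   \code{functionSet}.
#' @slot connGene integer matrix \code{2 x nColumns} of 0-based addresses.
#' @slot outputGene single 0-based address the program output reads.
#' @slot functionSet character vector of function names (see
#'   [cgpFunctionSet()]).
#'
#' @seealso [randomGenome()], [evaluateGenome()], [toExpression()]
#' @export
setClass("CGPGenome",
  representation(nInputs = "integer", nColumns = "integer",
                 levelsBack = "integer", funcGene = "integer",
                 connGene = "matrix", outputGene = "integer",
                 functionSet = "character"))

setValidity("CGPGenome", function(object) {
  msg <- character()
  ni <- object@nInputs; nc <- object@nColumns; lb <- object@levelsBack
  fs <- cgpFunctionSet()
  if (ni < 1L) msg <- c(msg, "nInputs must be >= 1")
  if (nc < 1L) msg <- c(msg, "nColumns must be >= 1")
  if (lb < 1L) msg <- c(msg, "levelsBack must be >= 1")
  if (!identical(object@functionSet, fs$name))
    msg <- c(msg, "functionSet must match cgpFunctionSet()$name")
  if (length(object@funcGene) != nc)
    msg <- c(msg, "funcGene length must equal nColumns")
  else if (any(object@funcGene < 1L | object@funcGene > nrow(fs)))
    msg <- c(msg, "funcGene indices out of range")
  if (!identical(dim(object@connGene), c(2L, nc)))
    msg <- c(msg, "connGene must be a 2 x nColumns matrix")
  else {
    for (k in seq_len(nc)) {
      lo <- max(0L, (k - 1L) - lb)        # earliest readable column
      hi <- ni + (k - 1L) - 1L            # last readable address
      ok <- function(a) (a >= 0L & a < ni) |
        (a >= ni + lo & a <= hi)
      if (!all(ok(object@connGene[, k]))) {
        msg <- c(msg, sprintf("connection genes of node %d violate feed-forward/levels-back", k - 1L))
        break
      }
    }
  }
  if (object@outputGene < 0L || object@outputGene >= ni + nc)
    msg <- c(msg, "outputGene out of range")
  if (length(msg)) msg else TRUE
})

#' Evolved CGP classifier
#'
#' Binary classifier wrapping a [CGPGenome-class] together with the
#' per-feature min/max normalization learned from the training table and the
#' decision rule: a row is assigned \code{positiveLabel} iff the genome
#' output on the normalized (and NA-imputed-to-0) features exceeds
#' \code{threshold}.
#'
#' @slot genome the evolved [CGPGenome-class].
#' @slot featureNames character vector naming the inputs, in order.
#' @slot rangeMin,rangeMax training-set per-feature minima / maxima used for
#'   normalization to [0, 1]; a feature with \code{rangeMin == rangeMax} is
#'   constant and normalizes to 0.
#' @slot threshold decision threshold on the genome output (default 0).
#' @slot positiveLabel label assigned when the output exceeds the threshold.
#'
#' @seealso [evolveClassifier()], [predict,CGPClassifier-method]
#' @export
setClass("CGPClassifier",
  representation(genome = "CGPGenome", featureNames = "character",
                 rangeMin = "numeric", rangeMax = "numeric",
                 threshold = "numeric", positiveLabel = "character"))

setValidity("CGPClassifier", function(object) {
  msg <- character()
  ni <- object@genome@nInputs
  if (length(object@featureNames) != ni)
    msg <- c(msg, "featureNames length must equal genome nInputs")
  if (length(object@rangeMin) != ni || length(object@rangeMax) != ni)
    msg <- c(msg, "normalization ranges must have one entry per input")
  if (any(object@rangeMax < object@rangeMin))
    msg <- c(msg, "rangeMax must be >= rangeMin")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (length(msg)) msg else TRUE
})
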