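#' Accessors for SceneTruth objects
#'
#' @param x a [SceneTruth-class] object.
#' @return \code{frames()} the list of frame matrices; \code{nFrames()} their
#'   number; \code{trueTracks()} the ground-truth trajectory table;
#'   \code{trueContacts()} the ground-truth contact-pair table;
#'   \code{sceneConfigOf()} the generating configuration list.
#' @name SceneTruth-accessors
#' @aliases frames nFrames trueTracks trueContacts sceneConfigOf
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 3, nFrames = 5, fieldWidth = 96,
#'                                 fieldHeight = 96, seed = 1))
#' nFrames(sc)
#' head(trueTracks(sc))
NULL

#' @rdname SceneTruth-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname SceneTruth-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname SceneTruth-accessors
#' @export
setGeneric("trueTracks", function(x) standardGeneric("trueTracks"))
#' @rdname SceneTruth-accessors
#' @export
setGeneric("trueContacts", function(x) standardGeneric("trueContacts"))
#' @rdname SceneTruth-accessors
#' @export
setGeneric("sceneConfigOf", function(x) standardGeneric("sceneConfigOf"))

#' @rdname SceneTruth-accessors
setMethod("frames", "SceneTruth", function(x) x@frames)
#' @rdname SceneTruth-accessors
setMethod("nFrames", "SceneTruth", function(x) length(x@frames))
#' @rdname SceneTruth-accessors
setMethod("trueTracks", "SceneTruth", function(x) x@tracks)
#' @rdname SceneTruth-accessors
setMethod("trueContacts", "SceneTruth", function(x) x@contacts)
#' @rdname SceneTruth-accessors
setMethod("sceneConfigOf", "SceneTruth", function(x) x@config)

setMethod("show", "SceneTruth", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("SceneTruth: %d frames of %d x %d px, %d tracks, %d contact pairs\n",
              length(object@frames), d[2], d[1],
              length(unique(object@tracks$track_id)), nrow(object@contacts)))
})

setMethod("show", "CGPGenome", function(object) {
  act <- activeNodes(object)
  cat(sprintf("CGPGenome: %d inputs, %d x 1 nodes (levels-back %d), %d active\n",
              object@nInputs, object@nColumns, object@levelsBack, length(act)))
})

setMethod("show", "CGPClassifier", function(object) {
  ex <- toExpression(object@genome, object@featureNames)
  cat("CGPClassifier (positive iff output >", object@threshold, "->",
      object@positiveLabel, ")\n")
  cat("  uses:", if (length(ex$used_names)) paste(ex$used_names, collapse = ", ")
                 else "(no inputs)", "\n")
  expr <- ex$expression
  if (nchar(expr) > 200) expr <- paste0(substr(expr, 1, 200), " ...")
  cat("  expression:", expr, "\n")
})
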