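# Training: (1 + lambda) evolution strategy over CGP genomes with
# training-accuracy fitness, min/max feature normalization and a
# output > threshold decision rule.

# Normalize a feature matrix to [0, 1] using stored per-feature ranges;
# constant features (min == max) normalize to 0; NA is imputed to 0.
normalizeFeatures <- function(X, rangeMin, rangeMax) {
  X <- as.matrix(X)
  span <- rangeMax - rangeMin
  for (j in seq_len(ncol(X))) {
    if (span[j] > 0) X[, j] <- (X[, j] - rangeMin[j]) / span[j]
    else X[, j] <- 0
  }
  X[is.na(X)] <- 0
  X
}

#' Training accuracy of a genome on a labeled table
#'
#' The fraction of rows on which the decision rule (genome output on the
#' normalized features greater than \code{threshold} means
#' \code{positiveLabel}) agrees with the row label. Defined also for
#' single-class tables.
#'
#' @param genome a [CGPGenome-class].
#' @param X numeric matrix of normalized inputs (rows = cases).
#' @param labels vector of row labels (two classes at most).
#' @param positiveLabel the label predicted when the output exceeds the
#'   threshold.
#' @param threshold decision threshold (default 0).
#' @return accuracy in [0, 1].
#' @export
cgpFitness <- function(genome, X, labels, positiveLabel, threshold = 0) {
  out <- evaluateGenome(genome, X)
  mean((out > threshold) == (labels == positiveLabel))
}

#' Evolve a CGP classifier
#'
#' Runs a (1 + (populationSize - 1)) evolution strategy: a random initial
#' population is evaluated and its fittest member becomes the parent; each
#' generation the parent is cloned and point-mutated to refill the
#' population, and an offspring whose fitness is at least the parent's
#' replaces it (offspring preferred on ties — neutral drift). Evolution
#' stops when training accuracy reaches 1 or after \code{generations}
#' generations. Offspring whose mutations touch no semantically active gene
#' inherit the parent's fitness without re-evaluation.
#'
#' @param data \code{data.frame} holding the feature columns and a label
#'   column with exactly one or two distinct values.
#' @param params an [evolutionParams()] object.
#' @param labelColumn name of the label column (default \code{"label"}).
#' @param features names of the feature columns; defaults to
#'   [featureNames()] intersected with \code{names(data)}.
#' @param positiveLabel label treated as the positive class; default the
#'   lexicographically larger one.
#' @param threshold decision threshold (default 0).
#' @return list with \code{classifier} (a [CGPClassifier-class]),
#'   \code{fitness} (final training accuracy), \code{trace}
#'   (best-so-far fitness per generation, generation 0 first, monotonically
#'   non-decreasing) and \code{generations} (number of generations run).
#' @examples
#' cfg <- featureTableConfig(nPerClass = 6,
#'   classMeans = list(rep(0, 10), rep(1, 10)),
#'   classSds = list(rep(0, 10), rep(0, 10)), seed = 5)
#' tab <- generateFeatureTable(cfg)
#' fit <- evolveClassifier(tab, evolutionParams(generations = 500, seed = 5))
#' fit$fitness
#' @export
evolveClassifier <- function(data, params = evolutionParams(),
                             labelColumn = "label",
                             features = intersect(featureNames(), names(data)),
                             positiveLabel = NULL, threshold = 0) {
  stopifnot(labelColumn %in% names(data), length(features) >= 1L)
  labels <- as.character(data[[labelColumn]])
  classes <- sort(unique(labels))
  if (length(classes) > 2L)
    stop("binary classification only", call. = FALSE)
  if (is.null(positiveLabel)) positiveLabel <- classes[length(classes)]
  Xraw <- as.matrix(data[, features, drop = FALSE])
  rangeMin <- suppressWarnings(apply(Xraw, 2L, min, na.rm = TRUE))
  rangeMax <- suppressWarnings(apply(Xraw, 2L, max, na.rm = TRUE))
  rangeMin[!is.finite(rangeMin)] <- 0
  rangeMax[!is.finite(rangeMax)] <- 0
  X <- normalizeFeatures(Xraw, rangeMin, rangeMax)
  ni <- length(features)

  withSeed(params$seed, {
    pop <- replicate(params$populationSize,
                     randomGenome(ni, params$nColumns, params$levelsBack),
                     simplify = FALSE)
    fit <- vapply(pop, function(g)
      cgpFitness(g, X, labels, positiveLabel, threshold), numeric(1))
    best <- which.max(fit)               # ties: lowest index
    parent <- pop[[best]]; parentFit <- fit[best]
    trace <- parentFit
    gen <- 0L
    while (gen < params$generations && parentFit < 1) {
      gen <- gen + 1L
      activePos <- activeGenePositions(parent)
      bestChild <- NULL; bestChildFit <- -Inf
      for (i in seq_len(params$populationSize - 1L)) {
        child <- mutateGenome(parent, params$mutationRate)
        changed <- which(child@funcGene != parent@funcGene) - 1L
        changedPos <- c(3L * changed,
                        3L * (which(child@connGene[1L, ] !=
                                      parent@connGene[1L, ]) - 1L) + 1L,
                        3L * (which(child@connGene[2L, ] !=
                                      parent@connGene[2L, ]) - 1L) + 2L,
                        if (child@outputGene != parent@outputGene)
                          3L * parent@nColumns)
        cf <- if (!length(intersect(changedPos, activePos))) parentFit
              else cgpFitness(child, X, labels, positiveLabel, threshold)
        if (cf > bestChildFit) { bestChild <- child; bestChildFit <- cf }
      }
      if (bestChildFit >= parentFit) {   # offspring preferred on ties
        parent <- bestChild; parentFit <- bestChildFit
      }
      trace <- c(trace, parentFit)
    }
    clf <- new("CGPClassifier", genome = parent,
               featureNames = features,
               rangeMin = as.numeric(rangeMin),
               rangeMax = as.numeric(rangeMax),
               threshold = threshold,
               positiveLabel = as.character(positiveLabel))
    list(classifier = clf, fitness = parentFit, trace = trace,
         generations = gen)
  })
}

#' Predict labels with an evolved classifier
#'
#' @param object a [CGPClassifier-class].
#' @param newdata \code{data.frame} containing the classifier's feature
#'   columns (NA features are imputed to 0 after normalization).
#' @param type \code{"label"} (default) or \code{"score"} (the raw genome
#'   output).
#' @return character vector of labels, or numeric scores.
#' @export
setMethod("predict", "CGPClassifier",
  function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    X <- normalizeFeatures(as.matrix(newdata[, object@featureNames,
                                             drop = FALSE]),
                           object@rangeMin, object@rangeMax)
    out <- evaluateGenome(object@genome, X)
    if (type == "score") return(out)
    ifelse(out > object@threshold, object@positiveLabel,
           paste0("not_", object@positiveLabel))
  })

#' Classification accuracy on labeled data
#'
#' @param classifier a [CGPClassifier-class].
#' @param data labeled \code{data.frame}.
#' @param labelColumn name of the label column.
#' @return fraction of rows classified correctly (rows whose label is not
#'   the positive label count as correct when the score does not exceed the
#'   threshold).
#' @export
classifierAccuracy <- function(classifier, data, labelColumn = "label") {
  score <- predict(classifier, data, type = "score")
  truth <- as.character(data[[labelColumn]]) == classifier@positiveLabel
  mean((score > classifier@threshold) == truth)
}

#' Serialize / restore a classifier as JSON
#'
#' The JSON mirrors the genome layout: \code{n_inputs, n_columns, n_rows,
#' levels_back, function_set}, \code{node_genes} (one \code{[function_index,
#' conn1, conn2]} triple per node, 0-based addresses and 0-based function
#' indices) and \code{output_gene}, plus the normalization ranges, decision
#' threshold, positive label and feature names.
#'
#' @param classifier a [CGPClassifier-class].
#' @param path file path.
#' @return \code{writeClassifier} returns \code{path} invisibly;
#'   \code{readClassifier} returns the restored [CGPClassifier-class].
#' @export
writeClassifier <- function(classifier, path) {
  g <- classifier@genome
  obj <- list(
    n_inputs = g@nInputs, n_columns = g@nColumns, n_rows = 1L,
    levels_back = g@levelsBack, function_set = g@functionSet,
    node_genes = lapply(seq_len(g@nColumns), function(k)
      c(g@funcGene[k] - 1L, g@connGene[1L, k], g@connGene[2L, k])),
    output_gene = g@outputGene,
    normalization = list(min = classifier@rangeMin,
                         max = classifier@rangeMax),
    decision_threshold = classifier@threshold,
    positive_label = classifier@positiveLabel,
    feature_names = classifier@featureNames)
  # I(17) significant digits: doubles survive the round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ng <- if (is.matrix(obj$node_genes)) obj$node_genes else
    do.call(rbind, obj$node_genes)
  genome <- new("CGPGenome",
                nInputs = as.integer(obj$n_inputs),
                nColumns = as.integer(obj$n_columns),
                levelsBack = as.integer(obj$levels_back),
                funcGene = as.integer(ng[, 1]) + 1L,
                connGene = rbind(as.integer(ng[, 2]), as.integer(ng[, 3])),
                outputGene = as.integer(obj$output_gene),
                functionSet = as.character(obj$function_set))
  new("CGPClassifier", genome = genome,
      featureNames = as.character(obj$feature_names),
      rangeMin = as.numeric(obj$normalization$min),
      rangeMax = as.numeric(obj$normalization$max),
      threshold = as.numeric(obj$decision_threshold),
      positiveLabel = as.character(obj$positive_label))
}
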