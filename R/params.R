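#' Scene generator configuration
#'
#' Parameters of the synthetic time-lapse generator. Cells are rendered as
#' hard-edged bright disks on a darker background and move as persistent
#' random walks: each frame the heading is perturbed by a wrapped-normal
#' increment whose spread is controlled by \code{turnConcentration}
#' (concentration 0 degenerates to a uniform turn on (-pi, pi]) and the step
#' length is drawn from a normal truncated at 0.
#'
#' Defaults mirror a 24 h acquisition at one frame per 5 minutes
#' (288 frames) of a sparse adherent culture with control-like motility
#' (~3.5 px/frame, moderately persistent).
#'
#' @param fieldWidth,fieldHeight field size in pixels.
#' @param nFrames number of frames.
#' @param nCells initial number of cells.
#' @param cellRadiusMean,cellRadiusSd per-cell radius distribution (px).
#' @param speedMean,speedSd per-step speed distribution (px/frame).
#' @param turnConcentration heading persistence; the per-step heading change
#'   is wrapped normal with sd \code{1/sqrt(turnConcentration)}; 0 gives a
#'   uniform heading change (isotropic walk).
#' @param clumpAttraction strength (px/frame) of drift toward neighbouring
#'   cells within \code{attractionRange}; 0 disables aggregation.
#' @param attractionRange interaction range of the attraction term (px).
#' @param contactSlowdown fractional speed reduction applied to a cell while
#'   it is within \code{contactRadius} of another cell (0 = no slowdown).
#' @param contactRadius centre distance (px) at or under which two cells are
#'   recorded as a ground-truth contact; default twice the mean radius.
#' @param foregroundIntensity,backgroundIntensity 8-bit gray levels of cell
#'   disks and background.
#' @param noiseSd additive Gaussian pixel noise (gray levels).
#' @param divisionRate per-cell per-frame division probability; a daughter
#'   is placed one radius away at a uniform random angle.
#' @param seed integer seed; the scene is a deterministic function of the
#'   configuration including the seed.
#' @return a validated configuration list of class \code{"sceneConfig"}.
#' @seealso [generateScene()]
#' @export
sceneConfig <- function(fieldWidth = 512, fieldHeight = 512, nFrames = 288,
                        nCells = 40, cellRadiusMean = 8, cellRadiusSd = 1,
                        speedMean = 3.5, speedSd = 0.5,
                        turnConcentration = 0.4,
                        clumpAttraction = 0, attractionRange = 6 * cellRadiusMean,
                        contactSlowdown = 0,
                        contactRadius = 2 * cellRadiusMean,
                        foregroundIntensity = 200, backgroundIntensity = 50,
                        noiseSd = 5, divisionRate = 0, seed = 1L) {
  cfg <- list(fieldWidth = fieldWidth, fieldHeight = fieldHeight,
              nFrames = as.integer(nFrames), nCells = as.integer(nCells),
              cellRadiusMean = cellRadiusMean, cellRadiusSd = cellRadiusSd,
              speedMean = speedMean, speedSd = speedSd,
              turnConcentration = turnConcentration,
              clumpAttraction = clumpAttraction,
              attractionRange = attractionRange,
              contactSlowdown = contactSlowdown,
              contactRadius = contactRadius,
              foregroundIntensity = foregroundIntensity,
              backgroundIntensity = backgroundIntensity,
              noiseSd = noiseSd, divisionRate = divisionRate,
              seed = as.integer(seed))
  for (nm in c("cellRadiusSd", "speedMean", "speedSd", "turnConcentration",
               "clumpAttraction", "contactSlowdown", "noiseSd",
               "divisionRate"))
    assertScalarNum(cfg[[nm]], nm, min = 0)
  assertScalarNum(cfg$cellRadiusMean, "cellRadiusMean", min = 1)
  if (cfg$fieldWidth <= 4 * cfg$cellRadiusMean ||
      cfg$fieldHeight <= 4 * cfg$cellRadiusMean)
    stop("field dimensions must exceed 4 * cellRadiusMean", call. = FALSE)
  if (cfg$foregroundIntensity <= cfg$backgroundIntensity)
    stop("foregroundIntensity must exceed backgroundIntensity", call. = FALSE)
  if (any(c(cfg$foregroundIntensity, cfg$backgroundIntensity) < 0) ||
      any(c(cfg$foregroundIntensity, cfg$backgroundIntensity) > 255))
    stop("intensities must be 8-bit gray levels (0-255)", call. = FALSE)
  if (cfg$nFrames < 1L || cfg$nCells < 0L)
    stop("nFrames must be >= 1 and nCells >= 0", call. = FALSE)
  expArea <- cfg$nCells * pi * cfg$cellRadiusMean^2
  if (expArea > 0.5 * cfg$fieldWidth * cfg$fieldHeight)
    stop("overcrowded configuration: expected cell area exceeds half the field",
         call. = FALSE)
  structure(cfg, class = "sceneConfig")
}

#' Detection parameters
#'
#' Controls the per-frame preprocessing (Gaussian blur, fixed threshold,
#' Euclidean distance transform) and the greedy selection of suppressed
#' local maxima used as cell detections.
#'
#' @param blurSigma Gaussian blur sigma in px (0 disables blurring).
#' @param threshold fixed gray-level threshold separating foreground from
#'   background after blurring; default is the midpoint of the synthetic
#'   generator's foreground/background intensities.
#' @param suppressionRadius radius (px) around an accepted maximum within
#'   which lower-scoring maxima are discarded.
#' @param minPeakValue minimum distance-transform value for a detection.
#' @param autoThreshold if \code{TRUE}, ignore \code{threshold} and use
#'   Otsu's method per frame (off by default; the reference pipeline uses a
#'   predetermined fixed threshold).
#' @return validated list of class \code{"detectionParams"}.
#' @export
detectionParams <- function(blurSigma = 2, threshold = 125,
                            suppressionRadius = 8, minPeakValue = 3,
                            autoThreshold = FALSE) {
  assertScalarNum(blurSigma, "blurSigma", 0)
  assertScalarNum(threshold, "threshold", 0)
  if (threshold > 255) stop("threshold must lie within 8-bit range", call. = FALSE)
  assertScalarNum(suppressionRadius, "suppressionRadius", 0)
  assertScalarNum(minPeakValue, "minPeakValue", 0)
  structure(list(blurSigma = blurSigma, threshold = threshold,
                 suppressionRadius = suppressionRadius,
                 minPeakValue = minPeakValue,
                 autoThreshold = isTRUE(autoThreshold)),
            class = "detectionParams")
}

#' Tracking parameters
#'
#' Controls the frame-to-frame Gaussian-weighted search, duplicate pruning
#' and periodic re-detection.
#'
#' @param searchHalfwidth half-width (px) of the square search window
#'   centred on the previous location.
#' @param gaussianSigma sigma (px) of the Gaussian weight favouring
#'   locations near the previous position.
#' @param lostThreshold a track is closed when the weighted maximum in its
#'   window falls below this value.
#' @param duplicateRadius two tracks closer than this (px) at the same frame
#'   are duplicates; the longer-lived one is kept.
#' @param redetectInterval run full detection every this many frames to seed
#'   tracks for cells that appeared or were lost.
#' @return validated list of class \code{"trackingParams"}.
#' @export
trackingParams <- function(searchHalfwidth = 16, gaussianSigma = 8,
                           lostThreshold = 0.5, duplicateRadius = 8,
                           redetectInterval = 10) {
  assertScalarNum(searchHalfwidth, "searchHalfwidth", 1)
  assertScalarNum(gaussianSigma, "gaussianSigma", 0)
  assertScalarNum(lostThreshold, "lostThreshold", 0)
  assertScalarNum(duplicateRadius, "duplicateRadius", 0)
  assertScalarNum(redetectInterval, "redetectInterval", 1)
  structure(list(searchHalfwidth = as.integer(searchHalfwidth),
                 gaussianSigma = gaussianSigma,
                 lostThreshold = lostThreshold,
                 duplicateRadius = duplicateRadius,
                 redetectInterval = as.integer(redetectInterval)),
            class = "trackingParams")
}

#' Contact analysis parameters
#'
#' @param contactRadius centre distance (px) at or under which two cells are
#'   in contact. Point tracks carry no shape, so contact is a centre-distance
#'   criterion; default twice a typical cell radius.
#' @param minClumpSize minimum connected-component size (cells, including
#'   self) that counts as a clump; default 5.
#' @param sixTotal if \code{TRUE}, require contact with five \emph{other}
#'   cells (component size >= 6) instead of a group of five in total.
#' @param postContactWindow number of frames after leaving a clump over
#'   which post-contact statistics are collected; default 3.
#' @return validated list of class \code{"contactParams"}.
#' @export
contactParams <- function(contactRadius = 16, minClumpSize = 5,
                          sixTotal = FALSE, postContactWindow = 3) {
  assertScalarNum(contactRadius, "contactRadius", 0)
  if (contactRadius <= 0) stop("contactRadius must be > 0", call. = FALSE)
  assertScalarNum(minClumpSize, "minClumpSize", 2)
  assertScalarNum(postContactWindow, "postContactWindow", 1)
  if (isTRUE(sixTotal)) minClumpSize <- max(minClumpSize, 6)
  structure(list(contactRadius = contactRadius,
                 minClumpSize = as.integer(minClumpSize),
                 postContactWindow = as.integer(postContactWindow)),
            class = "contactParams")
}

#' Labeled feature-table generator configuration
#'
#' @param nPerClass rows per class.
#' @param classMeans list of two numeric vectors of length 10 (feature means
#'   in standard feature order, see [featureNames()]).
#' @param classSds list of two non-negative numeric vectors of length 10.
#' @param classLabels labels for the two classes.
#' @param seed integer seed.
#' @return validated list of class \code{"featureTableConfig"}.
#' @seealso [generateFeatureTable()]
#' @export
featureTableConfig <- function(nPerClass = 12, classMeans, classSds,
                               classLabels = c("classA", "classB"),
                               seed = 1L) {
  if (!is.list(classMeans) || length(classMeans) != 2L ||
      !all(lengths(classMeans) == 10L))
    stop("classMeans must be a list of two length-10 numeric vectors",
         call. = FALSE)
  if (!is.list(classSds) || length(classSds) != 2L ||
      !all(lengths(classSds) == 10L) ||
      any(unlist(classSds) < 0))
    stop("classSds must be a list of two non-negative length-10 vectors",
         call. = FALSE)
  assertScalarNum(nPerClass, "nPerClass", 1)
  if (length(classLabels) != 2L || anyDuplicated(classLabels))
    stop("classLabels must be two distinct labels", call. = FALSE)
  structure(list(nPerClass = as.integer(nPerClass), classMeans = classMeans,
                 classSds = classSds,
                 classLabels = as.character(classLabels),
                 seed = as.integer(seed)),
            class = "featureTableConfig")
}

#' Evolution-strategy parameters for CGP training
#'
#' Defaults are the reference configuration: 70 single-row columns,
#' population 10, per-gene mutation rate 1%, up to 10,000 generations.
#'
#' @param populationSize individuals per generation (1 parent +
#'   \code{populationSize - 1} mutated clones).
#' @param mutationRate per-gene probability of being resampled uniformly
#'   over its valid range (resampling may reproduce the current value).
#' @param generations maximum number of generations; evolution stops early
#'   when training accuracy reaches 1.
#' @param nColumns,nRows CGP grid size (single row).
#' @param levelsBack connectivity constraint; defaults to \code{nColumns}
#'   (full feed-forward connectivity).
#' @param seed integer seed.
#' @return validated list of class \code{"evolutionParams"}.
#' @seealso [evolveClassifier()]
#' @export
evolutionParams <- function(populationSize = 10, mutationRate = 0.01,
                            generations = 10000, nColumns = 70, nRows = 1,
                            levelsBack = nColumns, seed = 1L) {
  assertScalarNum(populationSize, "populationSize", 2)
  assertScalarNum(mutationRate, "mutationRate", 0)
  if (mutationRate > 1) stop("mutationRate must be in [0, 1]", call. = FALSE)
  assertScalarNum(generations, "generations", 1)
  assertScalarNum(nColumns, "nColumns", 1)
  if (nRows != 1) stop("only single-row (nRows = 1) grids are supported",
                       call. = FALSE)
  assertScalarNum(levelsBack, "levelsBack", 1)
  structure(list(populationSize = as.integer(populationSize),
                 mutationRate = mutationRate,
                 generations = as.integer(generations),
                 nColumns = as.integer(nColumns), nRows = 1L,
                 levelsBack = as.integer(levelsBack),
                 seed = as.integer(seed)),
            class = "evolutionParams")
}
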