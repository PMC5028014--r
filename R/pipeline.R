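# End-to-end orchestration: simulate -> track -> features -> ANOVA ->
# evolve/classify, with artifacts written to an output directory and a
# plain-text report. Configuration is a nested list (or a YAML file with
# the same structure); one global seed drives every stochastic stage.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the structure accepted by [runPipeline()].
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(path)
}

# Per-video derived seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 104729 * i) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: \code{simulate} (synthetic scenes
#' per labeled class), \code{track} (detection + tracking on each video's
#' frames), \code{features} (the ten per-video features), \code{anova}
#' (per-feature one-way ANOVA across the class labels) and \code{evolve}
#' (CGP classifier on a stratified train/test split). Artifacts are written
#' under \code{outDir}: per-video truth and track CSVs, a feature table, an
#' ANOVA table, a classifier JSON and a text report carrying the evolved
#' expression and the features it uses. A rerun with an identical
#' configuration (including the seed) reproduces every artifact byte for
#' byte.
#'
#' @param config nested configuration list (or path to a YAML file):
#'   \describe{
#'     \item{seed}{global integer seed.}
#'     \item{stages}{character vector, default all five.}
#'     \item{classes}{list of \code{list(name=, nVideos=, scene=)} entries,
#'       where \code{scene} holds [sceneConfig()] overrides.}
#'     \item{detection, tracking, contacts, evolution}{parameter overrides
#'       for [detectionParams()], [trackingParams()], [contactParams()],
#'       [evolutionParams()].}
#'     \item{trainFraction}{stratified training fraction for \code{evolve}
#'       (default 0.75).}
#'     \item{writeFrames}{logical; also write each video's frames as a
#'       multi-page TIFF (default \code{FALSE}).}
#'   }
#' @param outDir output directory (created if needed).
#' @return (invisibly) a list with the feature table, ANOVA table, evolved
#'   classifier (or NULL), test accuracy, and paths of the written
#'   artifacts.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "track", "features", "anova",
                                 "evolve")
  det <- do.call(detectionParams, config$detection %||% list())
  trk <- do.call(trackingParams, config$tracking %||% list())
  cntDefaults <- config$contacts %||% list()
  cnt <- do.call(contactParams, cntDefaults)

  scenes <- list(); labels <- character(); trackList <- list()
  paths <- list()

  if ("simulate" %in% stages) {
    stopifnot(length(config$classes) >= 1L)
    vid <- 0L
    for (cls in config$classes) {
      for (j in seq_len(cls$nVideos %||% 1L)) {
        vid <- vid + 1L
        sceneArgs <- cls$scene %||% list()
        sceneArgs$seed <- deriveSeed(seed, vid)
        sc <- generateScene(do.call(sceneConfig, sceneArgs))
        id <- sprintf("%s_%02d", cls$name, j)
        scenes[[id]] <- sc
        labels[id] <- cls$name
        writeTracks(trueTracks(sc),
                    file.path(outDir, paste0(id, "_truth.csv")))
        writeContacts(trueContacts(sc),
                      file.path(outDir, paste0(id, "_truth_contacts.csv")))
        if (isTRUE(config$writeFrames))
          writeFrames(sc, file.path(outDir, paste0(id, ".tif")))
      }
    }
    message(sprintf("[simulate] %d videos, seed %d", length(scenes), seed))
  }

  if ("track" %in% stages) {
    if (!length(scenes)) stop("track stage needs simulated scenes",
                              call. = FALSE)
    for (id in names(scenes)) {
      tr <- runTracking(frames(scenes[[id]]), det, trk)
      trackList[[id]] <- tr
      writeTracks(tr, file.path(outDir, paste0(id, "_tracks.csv")))
    }
    message(sprintf("[track] %d videos tracked", length(trackList)))
  } else if (length(scenes)) {
    trackList <- lapply(scenes, trueTracks)
  }

  feats <- NULL
  if ("features" %in% stages && length(trackList)) {
    feats <- featureTable(trackList, cnt, labels = labels[names(trackList)])
    paths$features <- file.path(outDir, "features.csv")
    writeFeatures(feats, paths$features)
    message(sprintf("[features] %d x %d feature table", nrow(feats), 10L))
  }

  anova <- NULL
  if ("anova" %in% stages && !is.null(feats) &&
      length(unique(feats$label)) >= 2L) {
    anova <- anovaTable(feats)
    paths$anova <- file.path(outDir, "anova.csv")
    write.csv(anova, paths$anova, row.names = FALSE)
    message(sprintf("[anova] %d features tested", nrow(anova)))
  }

  classifier <- NULL; testAccuracy <- NA_real_; fit <- NULL
  if ("evolve" %in% stages && !is.null(feats) &&
      length(unique(feats$label)) == 2L) {
    evoArgs <- config$evolution %||% list()
    evoArgs$seed <- deriveSeed(seed, 0L)
    evo <- do.call(evolutionParams, evoArgs)
    frac <- config$trainFraction %||% 0.75
    idx <- withSeed(deriveSeed(seed, 999L), {
      unlist(lapply(split(seq_len(nrow(feats)), feats$label), function(ix)
        sample(ix, max(1L, round(frac * length(ix))))))
    })
    train <- feats[idx, , drop = FALSE]
    test <- feats[-idx, , drop = FALSE]
    fit <- evolveClassifier(train, evo)
    classifier <- fit$classifier
    if (nrow(test))
      testAccuracy <- classifierAccuracy(classifier, test)
    paths$classifier <- file.path(outDir, "classifier.json")
    writeClassifier(classifier, paths$classifier)
    message(sprintf("[evolve] train acc %.3f after %d generations%s",
                    fit$fitness, fit$generations,
                    if (is.na(testAccuracy)) "" else
                      sprintf(", test acc %.3f", testAccuracy)))
  }

  paths$report <- file.path(outDir, "report.txt")
  writeReport(paths$report, feats, anova, classifier, testAccuracy, fit,
              seed)
  invisible(list(features = feats, anova = anova, classifier = classifier,
                 testAccuracy = testAccuracy, fit = fit, tracks = trackList,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeReport <- function(path, feats, anova, classifier, testAccuracy, fit,
                        seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("CellTrackCGP pipeline report (seed %d)", seed)
  w("=====================================")
  if (!is.null(feats)) {
    w("")
    w("Per-video features:")
    writeLines(capture.output(print(feats, digits = 4)), con)
  }
  if (!is.null(anova) && nrow(anova)) {
    w("")
    w("Per-feature one-way ANOVA across classes")
    w("(no multiple-testing correction is applied across the 10 tests):")
    writeLines(capture.output(print(anova, digits = 4)), con)
  }
  if (!is.null(classifier)) {
    ex <- toExpression(classifier@genome, classifier@featureNames)
    w("")
    w("Evolved classifier (positive class '%s' iff output > %g):",
      classifier@positiveLabel, classifier@threshold)
    w("  expression: %s", ex$expression)
    w("  used features: %s",
      if (length(ex$used_names)) paste(ex$used_names, collapse = ", ")
      else "(none)")
    if (!is.null(fit))
      w("  training accuracy: %.4f (%d generations)", fit$fitness,
        fit$generations)
    if (!is.na(testAccuracy))
      w("  test accuracy: %.4f", testAccuracy)
  }
  invisible(path)
}
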