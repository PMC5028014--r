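# File formats: 8-bit grayscale frames as multi-page TIFF or numbered
# PNG/TIFF files; tracks and contacts as headed CSV with 0-based frames and
# pixel coordinates (x = column, y = row, origin top-left, up to 2 decimals
# in track output).

#' Read a frame stack
#'
#' Accepts a multi-page TIFF file or a directory of numbered single-frame
#' PNG/TIFF images (sorted by file name).
#'
#' @param path file or directory path.
#' @return list of integer matrices (gray levels 0-255), one per frame.
#' @export
readFrames <- function(path) {
  toMatrix <- function(img) {
    m <- EBImage::imageData(img)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- t(m) * 255          # EBImage stores [x, y] in [0, 1]
    m <- round(m)
    storage.mode(m) <- "integer"
    m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames in ", path, call. = FALSE)
    return(lapply(files, function(f) toMatrix(EBImage::readImage(f))))
  }
  img <- EBImage::readImage(path, all = TRUE)
  d <- dim(EBImage::imageData(img))
  if (length(d) == 2L) return(list(toMatrix(img)))
  arr <- EBImage::imageData(img)
  lapply(seq_len(d[length(d)]), function(i) {
    m <- if (length(d) == 3L) arr[, , i] else arr[, , 1, i]
    m <- round(t(m) * 255)
    storage.mode(m) <- "integer"
    m
  })
}

#' Write a frame stack
#'
#' @param frameList list of integer matrices (0-255), or a
#'   [SceneTruth-class].
#' @param path output path: a \code{.tif}/\code{.tiff} file (multi-page) or
#'   a directory (numbered PNG frames).
#' @return \code{path}, invisibly.
#' @export
writeFrames <- function(frameList, path) {
  if (is(frameList, "SceneTruth")) frameList <- frames(frameList)
  arr <- vapply(frameList, function(m) t(m) / 255,
                matrix(0, ncol(frameList[[1]]), nrow(frameList[[1]])))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                        bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frameList))
      EBImage::writeImage(EBImage::Image(arr[, , i]),
                          file.path(path, sprintf("frame_%04d.png", i - 1L)),
                          type = "png", bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read and write track tables
#'
#' Track CSVs have the header \code{track_id,frame,x,y}; frames are 0-based
#' and coordinates are written with up to two decimals.
#'
#' @param tracks a track \code{data.frame}.
#' @param path CSV path.
#' @return \code{writeTracks} returns \code{path} invisibly;
#'   \code{readTracks} the track \code{data.frame}.
#' @export
writeTracks <- function(tracks, path) {
  out <- data.frame(track_id = tracks$track_id,
                    frame = as.integer(tracks$frame),
                    x = round(tracks$x, 2), y = round(tracks$y, 2))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  tr <- read.csv(path)
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tr)))
  tr
}

#' Write contact pairs as CSV (\code{frame,id_a,id_b})
#'
#' @param contacts contact \code{data.frame}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeContacts <- function(contacts, path) {
  write.csv(contacts[, c("frame", "id_a", "id_b")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table as CSV
#'
#' One row per video with the ten feature columns; undefined features are
#' written as empty cells.
#'
#' @param features feature \code{data.frame} (see [featureTable()]).
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(features, path) {
  out <- features
  for (col in intersect(featureNames(), names(out)))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.10g", out[[col]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
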