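# Detection and tracking: per-frame preprocessing to a distance image,
# suppressed-local-maxima detection, Gaussian-weighted frame-to-frame search,
# duplicate pruning and periodic re-detection.

#' Preprocess a frame into a distance image
#'
#' Applies Gaussian blurring (noise suppression), fixed-value thresholding
#' into a binary foreground mask, and the exact Euclidean distance transform:
#' each foreground pixel is assigned its distance to the nearest
#' below-threshold pixel, so centres of cells (or cell groups) score high,
#' cell edges low, and the background exactly 0.
#'
#' @param frame an integer/numeric matrix of gray levels (rows = y,
#'   columns = x).
#' @param params a [detectionParams()] object.
#' @return a numeric matrix of the same shape: the distance image. If no
#'   pixel falls below the threshold, distances are capped at the image
#'   diagonal.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[(row(img) - 31)^2 + (col(img) - 31)^2 <= 100] <- 255
#' d <- preprocessFrame(img, detectionParams(blurSigma = 0, threshold = 128))
#' max(d)  # ~ disk radius
#' @export
preprocessFrame <- function(frame, params = detectionParams()) {
  if (!is.matrix(frame) || !length(frame))
    stop("frame must be a non-empty matrix", call. = FALSE)
  img <- frame
  storage.mode(img) <- "double"
  if (params$blurSigma > 0)
    img <- EBImage::gblur(img, sigma = params$blurSigma)
  thr <- if (params$autoThreshold) otsuLevel(img) else params$threshold
  bin <- (img > thr) * 1
  d <- EBImage::imageData(EBImage::distmap(bin, metric = "euclidean"))
  cap <- sqrt(nrow(frame)^2 + ncol(frame)^2)
  d[!is.finite(d)] <- cap
  d
}

# Otsu threshold on a 0-255 grayscale matrix (optional escape hatch).
otsuLevel <- function(img) {
  v <- as.vector(img)
  h <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  which.max(sigma2) - 1
}

#' Detect cells as suppressed local maxima of a distance image
#'
#' Local maxima (8-neighbourhood, plateaus included) with value at least
#' \code{minPeakValue} are visited from highest to lowest score; a candidate
#' within \code{suppressionRadius} of an already accepted detection is
#' discarded, which suppresses multiple selections inside one cell body.
#' Ties are broken row-major (smaller y, then smaller x), making the result
#' independent of traversal order.
#'
#' @param dist a distance image from [preprocessFrame()].
#' @param params a [detectionParams()] object.
#' @return \code{data.frame} with columns \code{x, y} (0-based pixel
#'   coordinates) and \code{value} (peak height), in acceptance order.
#' @export
detectCells <- function(dist, params = detectionParams()) {
  stopifnot(is.matrix(dist))
  H <- nrow(dist); W <- ncol(dist)
  # pad with -Inf so border pixels compare only against real neighbours
  p <- matrix(-Inf, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- dist
  ctr <- p[2:(H + 1L), 2:(W + 1L)]
  isMax <- ctr >= p[1:H, 2:(W + 1L)] & ctr >= p[3:(H + 2L), 2:(W + 1L)] &
    ctr >= p[2:(H + 1L), 1:W] & ctr >= p[2:(H + 1L), 3:(W + 2L)] &
    ctr >= p[1:H, 1:W] & ctr >= p[1:H, 3:(W + 2L)] &
    ctr >= p[3:(H + 2L), 1:W] & ctr >= p[3:(H + 2L), 3:(W + 2L)] &
    ctr >= params$minPeakValue & ctr > 0
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = numeric(), y = numeric(), value = numeric()))
  cand <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                     value = dist[idx])
  cand <- cand[order(-cand$value, cand$y, cand$x), , drop = FALSE]
  accX <- numeric(); accY <- numeric(); accV <- numeric()
  r2 <- params$suppressionRadius^2
  for (i in seq_len(nrow(cand))) {
    if (!length(accX) ||
        all((accX - cand$x[i])^2 + (accY - cand$y[i])^2 > r2)) {
      accX <- c(accX, cand$x[i]); accY <- c(accY, cand$y[i])
      accV <- c(accV, cand$value[i])
    }
  }
  data.frame(x = accX, y = accY, value = accV)
}

#' Track one cell into the next frame
#'
#' The distance image in a square window centred on the previous location is
#' multiplied by a Gaussian weight \code{exp(-d^2 / (2 gaussianSigma^2))}
#' (d = distance to the previous location); the argmax of the weighted image
#' estimates the new location, preferring cell centres close to the previous
#' position. If the weighted maximum falls below \code{lostThreshold} the
#' cell is reported lost.
#'
#' @param dist distance image of the current frame.
#' @param prev numeric length-2 vector \code{c(x, y)} (0-based).
#' @param params a [trackingParams()] object.
#' @return \code{c(x, y)} of the new location, or \code{NULL} if lost. The
#'   search window is clipped at the field boundary.
#' @export
trackStep <- function(dist, prev, params = trackingParams()) {
  stopifnot(is.matrix(dist), length(prev) == 2L)
  H <- nrow(dist); W <- ncol(dist)
  px <- prev[1]; py <- prev[2]
  if (px < 0 || px > W - 1 || py < 0 || py > H - 1)
    stop("previous location lies outside the field", call. = FALSE)
  hw <- params$searchHalfwidth
  cols <- max(1L, floor(px) + 1L - hw):min(W, floor(px) + 1L + hw)
  rows <- max(1L, floor(py) + 1L - hw):min(H, floor(py) + 1L + hw)
  sub <- dist[rows, cols, drop = FALSE]
  gx <- outer(rep(1, length(rows)), (cols - 1) - px)
  gy <- outer((rows - 1) - py, rep(1, length(cols)))
  w <- sub * exp(-(gx^2 + gy^2) / (2 * params$gaussianSigma^2))
  m <- max(w)
  if (m < params$lostThreshold) return(NULL)
  # row-major tie-break: first index in column-major order per row scan
  hit <- which(w == m, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  c(x = cols[hit[2]] - 1, y = rows[hit[1]] - 1)
}

#' Prune duplicated tracks at a frame
#'
#' When several tracks converge onto the same cell, all but one are
#' removed: tracks are visited in order of decreasing age (number of
#' recorded points; ties broken by lower id) and a track within
#' \code{duplicateRadius} of an already retained one is pruned.
#'
#' @param active \code{data.frame} with columns \code{id, x, y, age}
#'   describing each active track at the frame.
#' @param duplicateRadius pruning radius (px).
#' @return the retained subset of \code{active}, in retention order.
#' @export
pruneDuplicates <- function(active, duplicateRadius) {
  stopifnot(all(c("id", "x", "y", "age") %in% names(active)))
  if (!nrow(active)) return(active)
  ord <- active[order(-active$age, active$id), , drop = FALSE]
  keep <- logical(nrow(ord))
  r2 <- duplicateRadius^2
  for (i in seq_len(nrow(ord))) {
    sel <- which(keep)
    keep[i] <- !length(sel) ||
      all((ord$x[sel] - ord$x[i])^2 + (ord$y[sel] - ord$y[i])^2 > r2)
  }
  ord[keep, , drop = FALSE]
}

#' Track cells through an ordered frame stack
#'
#' Runs the full pipeline: detection on the first frame seeds the tracks;
#' on every subsequent frame each active track is advanced with
#' [trackStep()] (tracks whose weighted maximum is too low are closed, never
#' revived), duplicates are pruned with [pruneDuplicates()], and every
#' \code{redetectInterval} frames a full [detectCells()] pass seeds a new
#' track for any detection farther than \code{duplicateRadius} from all
#' active tracks.
#'
#' @param frameList list of grayscale matrices (ordered frames), or a
#'   [SceneTruth-class] object.
#' @param det [detectionParams()].
#' @param trk [trackingParams()].
#' @return \code{data.frame} with columns \code{track_id, frame, x, y}
#'   (frame 0-based), ordered by track then frame, with an attribute
#'   \code{"status"}: a \code{data.frame} of \code{track_id, status}
#'   (\code{active}, \code{lost} or \code{pruned} as of the final frame).
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 3, nFrames = 8, fieldWidth = 128,
#'                                 fieldHeight = 128, noiseSd = 2, seed = 2))
#' tr <- runTracking(frames(sc))
#' head(tr)
#' @export
runTracking <- function(frameList, det = detectionParams(),
                        trk = trackingParams()) {
  if (is(frameList, "SceneTruth")) frameList <- frames(frameList)
  if (length(frameList) < 2L) stop("need at least 2 frames", call. = FALSE)
  shp <- dim(frameList[[1]])
  if (!all(vapply(frameList, function(f) identical(dim(f), shp), logical(1))))
    stop("all frames must share the same shape", call. = FALSE)

  d0 <- preprocessFrame(frameList[[1]], det)
  det0 <- detectCells(d0, det)
  tracks <- list()   # per id: list(points = matrix(frame, x, y), status)
  if (nrow(det0))
    for (i in seq_len(nrow(det0)))
      tracks[[i]] <- list(points = cbind(frame = 0, x = det0$x[i],
                                         y = det0$y[i]),
                          status = "active")
  nextId <- length(tracks) + 1L

  for (t in seq_along(frameList)[-1] - 1L) {   # frames 1 .. T-1 (0-based)
    dImg <- preprocessFrame(frameList[[t + 1L]], det)
    for (id in seq_along(tracks)) {
      tr <- tracks[[id]]
      if (tr$status != "active") next
      prev <- tr$points[nrow(tr$points), c("x", "y")]
      nxt <- trackStep(dImg, prev, trk)
      if (is.null(nxt)) {
        tracks[[id]]$status <- "lost"
      } else {
        tracks[[id]]$points <- rbind(tr$points,
                                     cbind(frame = t, x = nxt[1], y = nxt[2]))
      }
    }
    actIds <- which(vapply(tracks, function(z) z$status == "active",
                           logical(1)))
    if (length(actIds)) {
      act <- data.frame(
        id = actIds,
        x = vapply(tracks[actIds],
                   function(z) z$points[nrow(z$points), "x"], numeric(1)),
        y = vapply(tracks[actIds],
                   function(z) z$points[nrow(z$points), "y"], numeric(1)),
        age = vapply(tracks[actIds],
                     function(z) nrow(z$points), numeric(1)))
      kept <- pruneDuplicates(act, trk$duplicateRadius)
      for (id in setdiff(actIds, kept$id)) {
        tracks[[id]]$status <- "pruned"
        # drop the point recorded at this frame: the track closes before it
        pts <- tracks[[id]]$points
        tracks[[id]]$points <- pts[pts[, "frame"] < t, , drop = FALSE]
      }
    }
    if (t %% trk$redetectInterval == 0L) {
      dets <- detectCells(dImg, det)
      if (nrow(dets)) {
        actIds <- which(vapply(tracks, function(z) z$status == "active",
                               logical(1)))
        ax <- vapply(tracks[actIds],
                     function(z) z$points[nrow(z$points), "x"], numeric(1))
        ay <- vapply(tracks[actIds],
                     function(z) z$points[nrow(z$points), "y"], numeric(1))
        for (i in seq_len(nrow(dets))) {
          if (!length(ax) ||
              all((ax - dets$x[i])^2 + (ay - dets$y[i])^2 >
                  trk$duplicateRadius^2)) {
            tracks[[nextId]] <- list(points = cbind(frame = t, x = dets$x[i],
                                                    y = dets$y[i]),
                                     status = "active")
            ax <- c(ax, dets$x[i]); ay <- c(ay, dets$y[i])
            nextId <- nextId + 1L
          }
        }
      }
    }
  }

  keep <- vapply(tracks, function(z) nrow(z$points) > 0, logical(1))
  out <- do.call(rbind, lapply(which(keep), function(id) {
    data.frame(track_id = id, frame = as.integer(tracks[[id]]$points[, "frame"]),
               x = tracks[[id]]$points[, "x"], y = tracks[[id]]$points[, "y"])
  }))
  if (is.null(out))
    out <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric())
  rownames(out) <- NULL
  attr(out, "status") <- data.frame(
    track_id = which(keep),
    status = vapply(tracks[keep], function(z) z$status, character(1)))
  out
}

#' Match tracker output against ground truth
#'
#' For each frame, greedily pairs ground-truth positions with estimated
#' positions in order of increasing distance (each used at most once); a
#' truth position is recovered when its paired estimate lies within
#' \code{tol} pixels.
#'
#' @param truth,tracks \code{data.frame}s with \code{track_id, frame, x, y}.
#' @param tol match tolerance in px (default 3).
#' @return list with \code{recovered} (fraction of truth positions matched),
#'   \code{medianError} (median distance over matched pairs) and \code{n}
#'   (number of truth positions).
#' @export
evaluateTracking <- function(truth, tracks, tol = 3) {
  errs <- numeric(); matched <- 0L; total <- 0L
  for (f in unique(truth$frame)) {
    tru <- truth[truth$frame == f, , drop = FALSE]
    est <- tracks[tracks$frame == f, , drop = FALSE]
    total <- total + nrow(tru)
    if (!nrow(est)) next
    d <- outer(seq_len(nrow(tru)), seq_len(nrow(est)), function(i, j)
      euclid(tru$x[i], tru$y[i], est$x[j], est$y[j]))
    ord <- order(d)
    usedT <- logical(nrow(tru)); usedE <- logical(nrow(est))
    for (k in ord) {
      if (d[k] > tol) break
      i <- (k - 1L) %% nrow(tru) + 1L
      j <- (k - 1L) %/% nrow(tru) + 1L
      if (usedT[i] || usedE[j]) next
      usedT[i] <- TRUE; usedE[j] <- TRUE
      matched <- matched + 1L
      errs <- c(errs, d[k])
    }
  }
  list(recovered = if (total) matched / total else NA_real_,
       medianError = if (length(errs)) median(errs) else NA_real_,
       n = total)
}
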