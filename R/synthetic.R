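#' Generate a synthetic time-lapse scene with ground truth
#'
#' Simulates a monolayer-culture video: bright hard-edged disks on a darker
#' background performing persistent random walks, with optional pairwise
#' attraction (producing clumps), optional slowdown while in contact, cells
#' leaving the field (their tracks end), and optional divisions (a daughter
#' is spawned one radius away). Returns the rendered 8-bit frames together
#' with the true trajectories and true contact pairs, so trackers and
#' feature extractors can be validated against known ground truth.
#'
#' Motion model, per frame: the heading is incremented by a wrapped-normal
#' deviate with sd \code{1/sqrt(turnConcentration)} (uniform on (-pi, pi]
#' when the concentration is 0) and the cell advances by a
#' \code{N(speedMean, speedSd)} step truncated at 0, plus, when
#' \code{clumpAttraction > 0}, a drift of that magnitude along the mean unit
#' vector toward neighbours within \code{attractionRange}.
#'
#' @param config a [sceneConfig()] object.
#' @return a [SceneTruth-class] object. Identical configurations (including
#'   the seed) produce bitwise-identical frames and tracks.
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 5, nFrames = 10, fieldWidth = 128,
#'                                 fieldHeight = 128, seed = 7))
#' sc
#' @export
generateScene <- function(config) {
  stopifnot(inherits(config, "sceneConfig"))
  cfg <- config
  W <- cfg$fieldWidth; H <- cfg$fieldHeight
  withSeed(cfg$seed, {
    n0 <- cfg$nCells
    margin <- cfg$cellRadiusMean
    cells <- data.frame(
      id = seq_len(n0),
      x = if (n0) runif(n0, margin, W - 1 - margin) else numeric(),
      y = if (n0) runif(n0, margin, H - 1 - margin) else numeric(),
      heading = if (n0) runif(n0, -pi, pi) else numeric(),
      radius = if (n0) pmax(1, stats::rnorm(n0, cfg$cellRadiusMean,
                                            cfg$cellRadiusSd)) else numeric())
    nextId <- n0 + 1L
    framesOut <- vector("list", cfg$nFrames)
    trackRows <- vector("list", cfg$nFrames)
    contactRows <- vector("list", cfg$nFrames)

    for (t in seq_len(cfg$nFrames) - 1L) {
      n <- nrow(cells)
      if (n) {
        trackRows[[t + 1L]] <- data.frame(track_id = cells$id, frame = t,
                                          x = cells$x, y = cells$y)
        if (n >= 2L) {
          dmat <- as.matrix(stats::dist(cells[, c("x", "y")]))
          idx <- which(upper.tri(dmat) & dmat <= cfg$contactRadius,
                       arr.ind = TRUE)
          if (nrow(idx)) {
            a <- cells$id[idx[, 1]]; b <- cells$id[idx[, 2]]
            contactRows[[t + 1L]] <- data.frame(frame = t,
                                                id_a = pmin(a, b),
                                                id_b = pmax(a, b))
          }
        }
      }
      framesOut[[t + 1L]] <- renderFrame(cells, cfg)

      if (t == cfg$nFrames - 1L) break
      if (n == 0L) next

      # heading update: wrapped normal; concentration 0 -> uniform turn
      if (cfg$turnConcentration > 0) {
        dtheta <- stats::rnorm(n, 0, 1 / sqrt(cfg$turnConcentration))
      } else {
        dtheta <- runif(n, -pi, pi)
      }
      cells$heading <- wrapAngle(cells$heading + dtheta)
      speed <- pmax(0, stats::rnorm(n, cfg$speedMean, cfg$speedSd))

      dx <- numeric(n); dy <- numeric(n); inContact <- rep(FALSE, n)
      if (n >= 2L && (cfg$clumpAttraction > 0 || cfg$contactSlowdown > 0)) {
        dmat <- as.matrix(stats::dist(cells[, c("x", "y")]))
        diag(dmat) <- Inf
        inContact <- apply(dmat <= cfg$contactRadius, 1L, any)
        if (cfg$clumpAttraction > 0) {
          for (i in seq_len(n)) {
            nb <- which(dmat[i, ] <= cfg$attractionRange)
            if (length(nb)) {
              ux <- (cells$x[nb] - cells$x[i]) / dmat[i, nb]
              uy <- (cells$y[nb] - cells$y[i]) / dmat[i, nb]
              nrm <- sqrt(mean(ux)^2 + mean(uy)^2)
              if (nrm > 0) {
                dx[i] <- cfg$clumpAttraction * mean(ux) / nrm
                dy[i] <- cfg$clumpAttraction * mean(uy) / nrm
              }
            }
          }
        }
      }
      if (cfg$contactSlowdown > 0)
        speed[inContact] <- speed[inContact] * (1 - cfg$contactSlowdown)

      cells$x <- cells$x + speed * cos(cells$heading) + dx
      cells$y <- cells$y + speed * sin(cells$heading) + dy

      # cells crossing the boundary exit the simulation
      keep <- cells$x >= 0 & cells$x <= W - 1 & cells$y >= 0 & cells$y <= H - 1
      cells <- cells[keep, , drop = FALSE]

      if (cfg$divisionRate > 0 && nrow(cells)) {
        divides <- runif(nrow(cells)) < cfg$divisionRate
        if (any(divides)) {
          for (i in which(divides)) {
            ang <- runif(1, -pi, pi)
            dx2 <- cells$x[i] + cells$radius[i] * cos(ang)
            dy2 <- cells$y[i] + cells$radius[i] * sin(ang)
            if (dx2 < 0 || dx2 > W - 1 || dy2 < 0 || dy2 > H - 1) next
            cells <- rbind(cells, data.frame(
              id = nextId, x = dx2, y = dy2,
              heading = runif(1, -pi, pi),
              radius = pmax(1, stats::rnorm(1, cfg$cellRadiusMean,
                                            cfg$cellRadiusSd))))
            nextId <- nextId + 1L
          }
        }
      }
    }

    tracks <- do.call(rbind, trackRows[!vapply(trackRows, is.null, logical(1))])
    if (is.null(tracks))
      tracks <- data.frame(track_id = integer(), frame = integer(),
                           x = numeric(), y = numeric())
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    contacts <- do.call(rbind,
                        contactRows[!vapply(contactRows, is.null, logical(1))])
    if (is.null(contacts))
      contacts <- data.frame(frame = integer(), id_a = integer(),
                             id_b = integer())
    rownames(contacts) <- NULL
    new("SceneTruth", frames = framesOut, tracks = tracks,
        contacts = contacts, config = unclass(cfg))
  })
}

# Render one 8-bit frame: background + hard-edged disks + Gaussian noise.
renderFrame <- function(cells, cfg) {
  W <- cfg$fieldWidth; H <- cfg$fieldHeight
  img <- matrix(cfg$backgroundIntensity, nrow = H, ncol = W)
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius[i]; cx <- cells$x[i]; cy <- cells$y[i]
    cols <- max(1L, floor(cx - r) + 1L):min(W, ceiling(cx + r) + 1L)
    rows <- max(1L, floor(cy - r) + 1L):min(H, ceiling(cy + r) + 1L)
    px <- outer(rep(1, length(rows)), cols - 1)   # x of each pixel centre
    py <- outer(rows - 1, rep(1, length(cols)))
    mask <- (px - cx)^2 + (py - cy)^2 <= r^2
    sub <- img[rows, cols, drop = FALSE]
    sub[mask] <- cfg$foregroundIntensity
    img[rows, cols] <- sub
  }
  if (cfg$noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, cfg$noiseSd)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Generate a labeled synthetic feature table
#'
#' Draws \code{nPerClass} rows per class, each of the ten features sampled
#' independently from the class's normal distribution. Used to exercise the
#' CGP classifier with a known class structure.
#'
#' @param config a [featureTableConfig()] object.
#' @return a \code{data.frame} with the ten feature columns (see
#'   [featureNames()]) and a \code{label} column.
#' @examples
#' cfg <- featureTableConfig(nPerClass = 4,
#'   classMeans = list(rep(0, 10), rep(1, 10)),
#'   classSds = list(rep(0.1, 10), rep(0.1, 10)), seed = 3)
#' generateFeatureTable(cfg)
#' @export
generateFeatureTable <- function(config) {
  stopifnot(inherits(config, "featureTableConfig"))
  withSeed(config$seed, {
    rows <- lapply(1:2, function(k) {
      m <- matrix(stats::rnorm(config$nPerClass * 10,
                               mean = rep(config$classMeans[[k]],
                                          each = config$nPerClass),
                               sd = rep(config$classSds[[k]],
                                        each = config$nPerClass)),
                  nrow = config$nPerClass)
      df <- as.data.frame(m)
      names(df) <- featureNames()
      df$label <- config$classLabels[k]
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
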