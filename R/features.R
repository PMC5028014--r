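# The ten per-video features: pooled kinematics (speed, angular velocity)
# overall / in-contact / post-contact, cohesivity, clump statistics and the
# cell-count gain. Undefined features (empty restriction) are NA.

#' Standard feature names
#'
#' The ten per-video features in canonical order: average migration speed,
#' post-contact migration speed, in-contact migration speed, average angular
#' velocity (migratory persistence), post-contact angular velocity,
#' in-contact angular velocity, cohesivity (contacts per cell), average
#' clump size, average contact (clump-membership) duration, and cell count
#' (maximum number tracked minus the number tracked at the start).
#'
#' @return character vector of length 10.
#' @export
featureNames <- function() {
  c("avg_migration_speed", "post_contact_speed", "in_contact_speed",
    "avg_angular_velocity", "post_contact_angular_velocity",
    "in_contact_angular_velocity", "cohesivity", "avg_clump_size",
    "avg_contact_duration", "cell_count")
}

#' Per-step speeds of a track
#'
#' One value per consecutive frame pair: the Euclidean distance between the
#' two positions, in px/frame.
#'
#' @param track \code{data.frame} with \code{frame, x, y} (one track).
#' @return numeric vector of length \code{nrow(track) - 1} (empty for
#'   single-point tracks).
#' @examples
#' stepSpeeds(data.frame(frame = 0:1, x = c(74, 75), y = c(32, 33)))  # sqrt(2)
#' @export
stepSpeeds <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L) return(numeric())
  sqrt(diff(track$x)^2 + diff(track$y)^2)
}

#' Per-step headings of a track
#'
#' The direction of travel \code{atan2(dy, dx)} of each consecutive step, in
#' radians in (-pi, pi]. A zero-displacement step has no direction and
#' yields \code{NA}.
#'
#' @inheritParams stepSpeeds
#' @return numeric vector of headings (NA for zero-displacement steps).
#' @export
stepDirections <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L) return(numeric())
  dx <- diff(track$x); dy <- diff(track$y)
  h <- atan2(dy, dx)
  h[dx == 0 & dy == 0] <- NA_real_
  h
}

#' Per-step angular velocities of a track
#'
#' The rate of change of the direction of travel: for each consecutive pair
#' of headings, the absolute angular difference wrapped to [0, pi]
#' (rad/frame). Pairs involving an undefined heading (zero-displacement
#' step) are NA.
#'
#' @inheritParams stepSpeeds
#' @return numeric vector of length \code{nrow(track) - 2} (empty if the
#'   track is shorter than 3 points).
#' @export
angularVelocities <- function(track) {
  h <- stepDirections(track)
  if (length(h) < 2L) return(numeric())
  angleDiff(h[-length(h)], h[-1])
}

#' Cohesivity of a sequence of contact graphs
#'
#' Mean over frames of twice the edge count divided by the node count (the
#' average number of contacts per cell); frames with no cells are skipped.
#'
#' @param graphs list of [contactGraph()] objects.
#' @return a single number, or NA if no frame has cells.
#' @export
cohesivity <- function(graphs) {
  vals <- vapply(graphs, function(g) {
    if (!length(g$nodes)) return(NA_real_)
    2 * nrow(g$edges) / length(g$nodes)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Pooled mean of per-step values restricted by a frame mask.
# Steps/turns are attributed to the start frame of their first step.
pooledKinematics <- function(tracks, contact) {
  speeds <- numeric(); speedFrame <- integer(); speedId <- integer()
  turns <- numeric(); turnFrame <- integer(); turnId <- integer()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    s <- stepSpeeds(tr)
    if (length(s)) {
      speeds <- c(speeds, s)
      speedFrame <- c(speedFrame, tr$frame[-nrow(tr)])
      speedId <- c(speedId, rep(id, length(s)))
    }
    a <- angularVelocities(tr)
    if (length(a)) {
      turns <- c(turns, a)
      turnFrame <- c(turnFrame, tr$frame[seq_along(a)])
      turnId <- c(turnId, rep(id, length(a)))
    }
  }
  mem <- contact$membership
  post <- contact$postFrames
  inKey <- paste(mem$track_id[mem$member], mem$frame[mem$member])
  postKey <- paste(post$track_id, post$frame)
  list(speeds = speeds,
       speedIn = paste(speedId, speedFrame) %in% inKey,
       speedPost = paste(speedId, speedFrame) %in% postKey,
       turns = turns,
       turnIn = paste(turnId, turnFrame) %in% inKey,
       turnPost = paste(turnId, turnFrame) %in% postKey)
}

meanOrNA <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) mean(x) else NA_real_
}

#' Extract the ten per-video features
#'
#' Combines a track table with its contact analysis into the standard
#' feature vector. Kinematic features pool steps across all tracks (not
#' mean-of-track-means); in-contact statistics restrict to steps whose start
#' frame is a clump-member frame, post-contact statistics to steps whose
#' start frame falls in a post-contact window. Features whose restriction is
#' empty are NA (recorded, and imputed to 0 only at classifier input).
#'
#' @param tracks \code{data.frame} with \code{track_id, frame, x, y}.
#' @param params a [contactParams()] object.
#' @param contact optionally, a precomputed [contactAnalysis()] result.
#' @return named numeric vector of length 10 (see [featureNames()]).
#' @examples
#' tr <- data.frame(track_id = 1, frame = 0:3,
#'                  x = c(0, 1, 2, 3), y = 0)
#' extractFeatures(tr)
#' @export
extractFeatures <- function(tracks, params = contactParams(),
                            contact = NULL) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  if (is.null(contact)) contact <- contactAnalysis(tracks, params)
  kin <- pooledKinematics(tracks, contact)

  clumpSizes <- unlist(lapply(contact$clumps, function(cl)
    vapply(cl, length, numeric(1))))
  ep <- contact$episodes

  counts <- table(tracks$frame)
  cellCount <- if (length(counts)) {
    first <- counts[[as.character(min(tracks$frame))]]
    max(counts) - first
  } else NA_real_

  out <- c(
    avg_migration_speed = meanOrNA(kin$speeds),
    post_contact_speed = meanOrNA(kin$speeds[kin$speedPost]),
    in_contact_speed = meanOrNA(kin$speeds[kin$speedIn]),
    avg_angular_velocity = meanOrNA(kin$turns),
    post_contact_angular_velocity = meanOrNA(kin$turns[kin$turnPost]),
    in_contact_angular_velocity = meanOrNA(kin$turns[kin$turnIn]),
    cohesivity = cohesivity(contact$graphs),
    avg_clump_size = if (length(clumpSizes)) mean(clumpSizes) else NA_real_,
    avg_contact_duration = if (nrow(ep)) mean(ep$duration) else NA_real_,
    cell_count = as.numeric(cellCount))
  out
}

#' Feature table for a set of videos
#'
#' Applies [extractFeatures()] to each element of a named list of track
#' tables and assembles one row per video.
#'
#' @param trackList named list of track \code{data.frame}s.
#' @param params a [contactParams()] object.
#' @param labels optional vector of class labels, one per video.
#' @return \code{data.frame} with \code{video_id}, the ten features, and
#'   (optionally) \code{label}.
#' @export
featureTable <- function(trackList, params = contactParams(), labels = NULL) {
  rows <- lapply(trackList, extractFeatures, params = params)
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(video_id = names(trackList), out)
  if (!is.null(labels)) out$label <- labels
  rownames(out) <- NULL
  out
}
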