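# Contact structure: per-frame contact graphs, clumps (connected components
# of >= minClumpSize cells), clump-membership episodes and post-contact
# windows. Point tracks carry no shape, so "contact" is a centre-distance
# criterion.

#' Build the contact graph at one frame
#'
#' Two cells are in contact when their centre distance is at most
#' \code{contactRadius}.
#'
#' @param positions \code{data.frame} with columns \code{id, x, y} (unique
#'   ids) for the cells present at the frame.
#' @param params a [contactParams()] object.
#' @param frame optional frame index stored in the result.
#' @return list of class \code{"contactGraph"}: \code{frame}, \code{nodes}
#'   (ids), \code{edges} (\code{data.frame} \code{id_a, id_b}, with
#'   \code{id_a < id_b}).
#' @export
contactGraph <- function(positions, params = contactParams(), frame = NA_integer_) {
  stopifnot(all(c("id", "x", "y") %in% names(positions)))
  if (anyDuplicated(positions$id)) stop("ids must be unique", call. = FALSE)
  edges <- data.frame(id_a = integer(), id_b = integer())
  if (nrow(positions) >= 2L) {
    dm <- as.matrix(dist(positions[, c("x", "y")]))
    idx <- which(upper.tri(dm) & dm <= params$contactRadius, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- positions$id[idx[, 1]]; b <- positions$id[idx[, 2]]
      edges <- data.frame(id_a = pmin(a, b), id_b = pmax(a, b))
      edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(frame = frame, nodes = positions$id, edges = edges),
            class = "contactGraph")
}

#' Find clumps in a contact graph
#'
#' A clump is a maximal connected component of the contact graph containing
#' at least \code{minClumpSize} cells (five by default, membership counted
#' including the cell itself).
#'
#' @param graph a [contactGraph()] result.
#' @param params a [contactParams()] object.
#' @return list of integer vectors, one per clump (sorted ids), ordered by
#'   smallest member id.
#' @export
findClumps <- function(graph, params = contactParams()) {
  stopifnot(inherits(graph, "contactGraph"))
  if (!length(graph$nodes)) return(list())
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph$edges$id_a),
                   to = as.character(graph$edges$id_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes)))
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    ids <- sort(as.integer(names(comp$membership)[comp$membership == k]))
    if (length(ids) >= params$minClumpSize) out[[length(out) + 1L]] <- ids
  }
  if (length(out))
    out <- out[order(vapply(out, min, numeric(1)))]
  out
}

#' Clump-membership episodes of each track
#'
#' Converts per-frame clump membership into maximal runs of consecutive
#' member frames per track; an episode's duration is
#' \code{exit_frame - enter_frame + 1}.
#'
#' @param membership \code{data.frame} with columns \code{track_id, frame,
#'   member} (\code{member} logical), covering every frame each track is
#'   active.
#' @return \code{data.frame} with columns \code{track_id, enter_frame,
#'   exit_frame, duration}.
#' @export
clumpEpisodes <- function(membership) {
  stopifnot(all(c("track_id", "frame", "member") %in% names(membership)))
  out <- list()
  for (id in unique(membership$track_id)) {
    m <- membership[membership$track_id == id, , drop = FALSE]
    m <- m[order(m$frame), , drop = FALSE]
    r <- rle(m$member)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        track_id = id, enter_frame = m$frame[starts[k]],
        exit_frame = m$frame[ends[k]])
    }
  }
  ep <- if (length(out)) do.call(rbind, out) else
    data.frame(track_id = integer(), enter_frame = integer(),
               exit_frame = integer())
  ep$duration <- ep$exit_frame - ep$enter_frame + 1L
  rownames(ep) <- NULL
  ep
}

#' Post-contact frames after a clump exit
#'
#' The frames over which post-contact statistics are collected: up to
#' \code{postContactWindow} frames immediately after the episode's exit
#' frame, truncated when the track ends or the cell re-enters a clump.
#'
#' @param exitFrame the episode's (inclusive) exit frame.
#' @param trackFrames all frames at which the track is active.
#' @param memberFrames frames at which the track is a clump member.
#' @param params a [contactParams()] object.
#' @return integer vector of frames (possibly empty).
#' @export
postContactFrames <- function(exitFrame, trackFrames, memberFrames,
                              params = contactParams()) {
  cand <- exitFrame + seq_len(params$postContactWindow)
  out <- integer()
  for (f in cand) {
    if (!(f %in% trackFrames)) break    # track ended
    if (f %in% memberFrames) break      # re-entered a clump
    out <- c(out, f)
  }
  out
}

#' Full contact analysis of a track table
#'
#' Computes, for every frame, the contact graph and its clumps, then derives
#' per-track clump membership, membership episodes, and post-contact frames.
#'
#' @param tracks \code{data.frame} with \code{track_id, frame, x, y}.
#' @param params a [contactParams()] object.
#' @return list with elements \code{graphs} (per-frame [contactGraph()]s,
#'   named by frame), \code{clumps} (per-frame list of clumps),
#'   \code{membership} (\code{track_id, frame, member}), \code{episodes}
#'   (from [clumpEpisodes()]) and \code{postFrames} (\code{data.frame}
#'   \code{track_id, frame} of post-contact frames).
#' @export
contactAnalysis <- function(tracks, params = contactParams()) {
  framesIdx <- sort(unique(tracks$frame))
  graphs <- list(); clumps <- list()
  memberRows <- vector("list", length(framesIdx))
  for (i in seq_along(framesIdx)) {
    f <- framesIdx[i]
    sub <- tracks[tracks$frame == f, , drop = FALSE]
    g <- contactGraph(data.frame(id = sub$track_id, x = sub$x, y = sub$y),
                      params, frame = f)
    cl <- findClumps(g, params)
    graphs[[as.character(f)]] <- g
    clumps[[as.character(f)]] <- cl
    memberIds <- if (length(cl)) unlist(cl) else integer()
    memberRows[[i]] <- data.frame(track_id = sub$track_id, frame = f,
                                  member = sub$track_id %in% memberIds)
  }
  membership <- do.call(rbind, memberRows)
  if (is.null(membership))
    membership <- data.frame(track_id = integer(), frame = integer(),
                             member = logical())
  episodes <- clumpEpisodes(membership)
  postRows <- list()
  for (k in seq_len(nrow(episodes))) {
    id <- episodes$track_id[k]
    tf <- membership$frame[membership$track_id == id]
    mf <- membership$frame[membership$track_id == id & membership$member]
    pf <- postContactFrames(episodes$exit_frame[k], tf, mf, params)
    if (length(pf))
      postRows[[length(postRows) + 1L]] <- data.frame(track_id = id,
                                                      frame = pf)
  }
  postFrames <- if (length(postRows)) do.call(rbind, postRows) else
    data.frame(track_id = integer(), frame = integer())
  rownames(postFrames) <- NULL
  list(graphs = graphs, clumps = clumps, membership = membership,
       episodes = episodes, postFrames = postFrames)
}
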