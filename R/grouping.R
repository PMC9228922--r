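# Group-vs-singleton classification of tracked pedestrians from three
# pairwise similarity criteria (distance, velocity, scale) and short-horizon
# trajectory retention.

#' Pairwise grouping costs between tracked pedestrians
#'
#' For every pair of tracks computes three symmetric cost matrices:
#' `distance` (Euclidean distance between box centres, px), `velocity`
#' (Euclidean difference of the Kalman box velocities, px/frame) and `scale`
#' (`max(w_i,w_j)/min(w_i,w_j) * max(h_i,h_j)/min(h_i,h_j)`, always >= 1).
#' Diagonals are 0, 0 and 1.
#'
#' @param tracks Data frame with columns `track_id`, `cx`, `cy` (centre,
#'   px), `w`, `h` (box size, px, > 0), `vx`, `vy` (px/frame).
#' @return List of three named square matrices.
#' @export
pairwise_costs <- function(tracks) {
  stopifnot(nrow(tracks) >= 1, all(tracks$w > 0), all(tracks$h > 0))
  ids <- as.character(tracks$track_id)
  d <- as.matrix(stats::dist(tracks[, c("cx", "cy")]))
  v <- as.matrix(stats::dist(tracks[, c("vx", "vy")]))
  ratio <- function(x) outer(x, x, pmax) / outer(x, x, pmin)
  s <- ratio(tracks$w) * ratio(tracks$h)
  dimnames(d) <- dimnames(v) <- dimnames(s) <- list(ids, ids)
  list(distance = d, velocity = v, scale = s)
}

#' Form pedestrian groups from pairwise costs
#'
#' A pair of tracks passes when all three costs are within their thresholds;
#' requiring the pass to persist for `persistence_frames` consecutive frames
#' suppresses transient crossings. Passing pairs are merged transitively
#' (two-pedestrian groups sharing a member combine) until no two groups
#' share an element, i.e. the partition is the connected components of the
#' passing-pair graph.
#'
#' @param costs Output of [pairwise_costs()] for the current frame.
#' @param thresholds List with `distance` (px), `velocity` (px/frame) and
#'   `scale` (ratio >= 1) thresholds.
#' @param persistence_frames Consecutive frames a pair must pass before it
#'   links a group (default 1: no persistence requirement).
#' @param history Consecutive-pass-count matrix from the previous frame's
#'   call (or `NULL` on the first frame).
#' @return List with `groups` (list of track-id character vectors, a
#'   partition of all tracks) and `history` (to thread into the next call).
#' @export
form_groups <- function(costs, thresholds, persistence_frames = 1,
                        history = NULL) {
  ids <- rownames(costs$distance)
  n <- length(ids)
  pass <- costs$distance <= thresholds$distance &
    costs$velocity <= thresholds$velocity &
    costs$scale <= thresholds$scale
  diag(pass) <- FALSE
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!is.null(history)) {
    common <- intersect(ids, rownames(history))
    counts[common, common] <- history[common, common]
  }
  counts <- ifelse(pass, counts + 1, 0)
  linked <- counts >= persistence_frames
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  names(groups) <- NULL
  list(groups = groups, history = counts)
}

#' Update short-horizon pedestrian trajectories
#'
#' Appends the current frame's track centres and drops points older than the
#' retention horizon, so each trajectory keeps at most `retention_frames`
#' points (e.g. 60 frames = 2 s at 30 fps).
#'
#' @param trajectories Named list of per-track data frames (columns `frame`,
#'   `x`, `y`), or `NULL`/empty to start fresh.
#' @param tracks Data frame with `track_id`, `cx`, `cy` for the current
#'   frame.
#' @param frame_index Current frame number.
#' @param retention_frames Maximum points retained per track (default 60).
#' @return Updated named list of trajectory data frames.
#' @export
update_trajectories <- function(trajectories, tracks, frame_index,
                                retention_frames = 60) {
  stopifnot(retention_frames >= 1)
  if (is.null(trajectories)) trajectories <- list()
  for (i in seq_len(nrow(tracks))) {
    id <- as.character(tracks$track_id[i])
    pt <- data.frame(frame = as.integer(frame_index),
                     x = tracks$cx[i], y = tracks$cy[i])
    tr <- rbind(trajectories[[id]], pt)
    if (nrow(tr) > retention_frames)
      tr <- tr[(nrow(tr) - retention_frames + 1):nrow(tr), , drop = FALSE]
    rownames(tr) <- NULL
    trajectories[[id]] <- tr
  }
  trajectories
}
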