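# Skeleton canonicalisation and the static / motion / geometric feature
# families extracted per frame, plus 30-step feature windows for the
# two-branch classifier.

#' Canonicalise a pose frame into body coordinates
#'
#' Normalises raw pixel keypoints into a 14-joint canonical skeleton:
#' coordinates are divided by the image width, eyes and ears are dropped, the
#' neck becomes the origin, and every coordinate is divided by the body
#' height, defined as the distance from the neck to the midpoint of the two
#' hips. 17-keypoint (COCO) frames get a synthetic neck at the shoulder
#' midpoint with confidence `min` of the two shoulders. Joints with
#' confidence 0 are filled from the previous canonical skeleton (in body
#' coordinates) and flagged in `missing_mask`; on a first frame without a
#' predecessor they are placed at the origin.
#'
#' @param frame A [pose_frame].
#' @param prev The previous frame's canonical skeleton, or `NULL`.
#' @param image_width Image width in pixels (> 0).
#' @return An object of class `canonical_skeleton` with fields `joints`
#'   (14 x 2), `neck_image_xy` (width-normalised image units), `body_height`
#'   (width-normalised, dimensionless) and `missing_mask` (14 logicals).
#' @export
canonicalise <- function(frame, prev = NULL, image_width) {
  stopifnot(image_width > 0)
  kp <- frame$keypoints
  if (nrow(kp) == 17) kp <- coco17_to_body18(kp)
  # width-normalise, keep the 14 body joints
  xy <- kp[1:14, 1:2, drop = FALSE] / image_width
  conf <- kp[1:14, 3]
  missing <- conf <= 0
  if (missing[J$neck]) {
    if (is.null(prev))
      stop("unusable frame ", frame$frame_index,
           ": neck missing with no previous skeleton")
    # neck position in image units cannot be recovered from body coords;
    # carry the previous neck location forward
    xy[J$neck, ] <- prev$neck_image_xy
  }
  neck <- xy[J$neck, ]
  centred <- sweep(xy, 2, neck)

  hips_missing <- missing[c(J$r_hip, J$l_hip)]
  if (all(hips_missing)) {
    if (is.null(prev))
      stop("unusable frame ", frame$frame_index,
           ": both hips missing with no previous skeleton")
    body_height <- prev$body_height
  } else {
    hip_mid <- colMeans(centred[c(J$r_hip, J$l_hip)[!hips_missing], ,
                                drop = FALSE])
    body_height <- sqrt(sum(hip_mid^2))
  }
  if (body_height <= 1e-9)
    stop("degenerate pose at frame ", frame$frame_index,
         ": neck and hips coincide (body height ~ 0)")

  joints <- centred / body_height
  if (any(missing)) {
    fill <- if (is.null(prev)) matrix(0, 14, 2) else prev$joints
    joints[missing, ] <- fill[missing, , drop = FALSE]
  }
  joints[J$neck, ] <- c(0, 0)
  structure(
    list(joints = joints, neck_image_xy = neck, body_height = body_height,
         missing_mask = missing),
    class = "canonical_skeleton"
  )
}

coco17_to_body18 <- function(kp) {
  out <- matrix(0, 18, 3)
  out[COCO17_TO_BODY18, ] <- kp
  sh <- out[c(J$r_shoulder, J$l_shoulder), , drop = FALSE]
  if (all(sh[, 3] > 0)) {
    out[J$neck, 1:2] <- colMeans(sh[, 1:2, drop = FALSE])
    out[J$neck, 3] <- min(sh[, 3])
  }
  out
}

#' Static features: canonical joint coordinates
#'
#' The 28-dimensional static feature is the flattened canonical skeleton:
#' (x, y) for each of the 14 joints in the fixed order nose, neck, right
#' arm, left arm, right leg, left leg. The neck entries are structurally 0.
#'
#' @param skel A `canonical_skeleton`.
#' @return Numeric vector of length 28.
#' @export
static_features <- function(skel) {
  as.vector(t(skel$joints))
}

#' Motion features: joint, body and box velocities
#'
#' 68 dimensions: 28 joint velocities (difference of canonical body
#' coordinates between adjacent frames; the neck slots are structurally 0
#' because global motion is carried separately), the 2-dimensional body
#' velocity (difference of the width-normalised neck image position),
#' replicated 10 times, and the 2-dimensional tracked-box velocity divided
#' by image width and body height, also replicated 10 times. The 10x
#' replication up-weights whole-body movement relative to per-joint motion.
#'
#' @param skel_t Canonical skeleton at frame t.
#' @param skel_prev Canonical skeleton at frame t-1.
#' @param box_velocity Length-2 (vx, vy) in px/frame, or `NULL` for zeros.
#' @param image_width Image width in pixels.
#' @return Numeric vector of length 68.
#' @export
motion_features <- function(skel_t, skel_prev, box_velocity = NULL,
                            image_width) {
  joint_v <- as.vector(t(skel_t$joints - skel_prev$joints))
  body_v <- skel_t$neck_image_xy - skel_prev$neck_image_xy
  if (is.null(box_velocity)) box_velocity <- c(0, 0)
  box_v <- (as.numeric(box_velocity) / image_width) / skel_t$body_height
  c(joint_v, rep(body_v, 10), rep(box_v, 10))
}

# Limb tree: 13 (parent, child) edges over the canonical 14 joints.
limb_edges <- function() {
  rbind(
    c(J$neck, J$nose),
    c(J$neck, J$r_shoulder), c(J$neck, J$l_shoulder),
    c(J$r_shoulder, J$r_elbow), c(J$r_elbow, J$r_wrist),
    c(J$l_shoulder, J$l_elbow), c(J$l_elbow, J$l_wrist),
    c(J$neck, J$r_hip), c(J$neck, J$l_hip),
    c(J$r_hip, J$r_knee), c(J$r_knee, J$r_ankle),
    c(J$l_hip, J$l_knee), c(J$l_knee, J$l_ankle)
  )
}

# 13 (outer, apex, outer) triples of adjacent joints: one at each shoulder,
# elbow, hip and knee, plus 5 at the neck between circularly consecutive
# incident limbs in the order nose, L shoulder, L hip, R hip, R shoulder.
angle_triples <- function() {
  rbind(
    c(J$neck, J$r_shoulder, J$r_elbow),
    c(J$neck, J$l_shoulder, J$l_elbow),
    c(J$r_shoulder, J$r_elbow, J$r_wrist),
    c(J$l_shoulder, J$l_elbow, J$l_wrist),
    c(J$neck, J$r_hip, J$r_knee),
    c(J$neck, J$l_hip, J$l_knee),
    c(J$r_hip, J$r_knee, J$r_ankle),
    c(J$l_hip, J$l_knee, J$l_ankle),
    c(J$nose, J$neck, J$l_shoulder),
    c(J$l_shoulder, J$neck, J$l_hip),
    c(J$l_hip, J$neck, J$r_hip),
    c(J$r_hip, J$neck, J$r_shoulder),
    c(J$r_shoulder, J$neck, J$nose)
  )
}

END_JOINTS <- c("nose", "r_wrist", "l_wrist", "r_ankle", "l_ankle")

#' Geometric (relational) features
#'
#' 62 dimensions in five blocks over the canonical skeleton:
#' \itemize{
#'   \item 13 limb orientations: `atan2(dy, dx)` of each limb vector (child
#'     minus parent) over the 13-edge limb tree; a zero-length limb yields 0;
#'   \item 13 limb lengths (Euclidean);
#'   \item 13 inner angles in `[0, pi]` at the apex of each adjacent-joint
#'     triple (angle between the two limbs sharing the apex);
#'   \item 13 long lengths: distance between the two outer joints of each
#'     triple;
#'   \item 10 end lengths: all pairwise distances among the five end joints
#'     (nose, both wrists, both ankles).
#' }
#' Orientations are the only block that changes under global rotation; all
#' blocks are invariant to translation and (by canonicalisation) to scale.
#'
#' @param skel A `canonical_skeleton`.
#' @return Numeric vector of length 62.
#' @export
geometric_features <- function(skel) {
  p <- skel$joints
  edges <- limb_edges()
  vec <- p[edges[, 2], , drop = FALSE] - p[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(vec^2))
  orient <- ifelse(len <= 1e-12, 0, atan2(vec[, 2], vec[, 1]))

  tri <- angle_triples()
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  cc <- p[tri[, 3], , drop = FALSE]
  u <- a - b
  v <- cc - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / pmax(nu * nv, 1e-12)
  inner <- ifelse(nu <= 1e-12 | nv <= 1e-12, 0,
                  acos(pmin(pmax(cosang, -1), 1)))
  long_len <- sqrt(rowSums((a - cc)^2))

  ej <- p[match(END_JOINTS, CANONICAL_NAMES), , drop = FALSE]
  pairs <- utils::combn(5, 2)
  end_len <- sqrt(rowSums((ej[pairs[1, ], , drop = FALSE] -
                             ej[pairs[2, ], , drop = FALSE])^2))

  c(orient, len, inner, long_len, end_len)
}

#' Geometric features split into their five named blocks
#'
#' Same values as [geometric_features()], returned as a named list:
#' `limb_orientation` (13), `limb_length` (13), `inner_angle` (13),
#' `long_length` (13), `end_length` (10).
#'
#' @param skel A `canonical_skeleton`.
#' @return Named list of five numeric vectors.
#' @export
geometric_feature_blocks <- function(skel) {
  g <- geometric_features(skel)
  n_limbs <- nrow(limb_edges())
  n_tri <- nrow(angle_triples())
  idx <- cumsum(c(n_limbs, n_limbs, n_tri, n_tri,
                  length(g) - 2 * n_limbs - 2 * n_tri))
  list(limb_orientation = g[1:idx[1]],
       limb_length = g[(idx[1] + 1):idx[2]],
       inner_angle = g[(idx[2] + 1):idx[3]],
       long_length = g[(idx[3] + 1):idx[4]],
       end_length = g[(idx[4] + 1):idx[5]])
}

#' Canonicalise a whole pose sequence
#'
#' Runs [canonicalise()] over a `pose_sequence` in order, threading each
#' frame's canonical skeleton as the `prev` of the next so that missing
#' joints are carried forward.
#'
#' @param seq A `pose_sequence` from [split_by_track()].
#' @param image_width Image width in pixels.
#' @return List of `canonical_skeleton` objects, one per frame.
#' @export
canonicalise_sequence <- function(seq, image_width) {
  skels <- vector("list", length(seq$frames))
  prev <- NULL
  for (i in seq_along(seq$frames)) {
    skels[[i]] <- canonicalise(seq$frames[[i]], prev, image_width)
    prev <- skels[[i]]
  }
  skels
}

frame_feature_pair <- function(skels, frames, i, image_width) {
  prev <- if (i == 1) skels[[1]] else skels[[i - 1]]
  bv <- frames[[i]]$box_velocity
  mot <- if (i == 1) rep(0, 68) else
    motion_features(skels[[i]], prev, bv, image_width)
  list(a = c(static_features(skels[[i]]), mot),
       b = geometric_features(skels[[i]]))
}

# Per-frame branch features for a whole sequence: n x 96 and n x 62.
all_frame_features <- function(seq, image_width, skels) {
  n <- length(seq$frames)
  fa <- matrix(0, n, 96)
  fb <- matrix(0, n, 62)
  for (i in seq_len(n)) {
    fp <- frame_feature_pair(skels, seq$frames, i, image_width)
    fa[i, ] <- fp$a
    fb[i, ] <- fp$b
  }
  list(a = fa, b = fb)
}

#' Extract the two-branch feature window around a mid-key frame
#'
#' Builds the 30-step feature pair for frame-wise classification: steps run
#' from 14 frames before to 15 frames after the centre frame; near sequence
#' boundaries the edge frame's features are repeated. Branch A steps are the
#' 96-dimensional static-and-motion concatenation; branch B steps are the
#' 62-dimensional geometric features.
#'
#' @param seq A `pose_sequence` (length >= 2).
#' @param center 1-based index of the mid-key frame within the sequence.
#' @param image_width Image width in pixels.
#' @param skels Optional pre-computed [canonicalise_sequence()] output.
#' @param feats Optional pre-computed per-frame feature matrices (internal
#'   use by [sequence_windows()]).
#' @return A `feature_window_pair`: list with `branch_a` (30 x 96 matrix),
#'   `branch_b` (30 x 62 matrix), `center_frame`, `track_id`.
#' @export
window_features <- function(seq, center, image_width, skels = NULL,
                            feats = NULL) {
  n <- length(seq$frames)
  if (n < 2) stop("sequence must contain at least 2 frames")
  stopifnot(center >= 1, center <= n)
  if (is.null(feats)) {
    if (is.null(skels)) skels <- canonicalise_sequence(seq, image_width)
    feats <- all_frame_features(seq, image_width, skels)
  }
  idx <- pmin(pmax((center - 14):(center + 15), 1L), n)
  structure(
    list(branch_a = feats$a[idx, , drop = FALSE],
         branch_b = feats$b[idx, , drop = FALSE],
         center_frame = seq$frames[[center]]$frame_index,
         track_id = seq$track_id),
    class = "feature_window_pair"
  )
}

#' Extract feature windows for every frame of a sequence
#'
#' Convenience wrapper: canonicalises once, then calls [window_features()]
#' at each frame position.
#'
#' @inheritParams window_features
#' @return List of `feature_window_pair` objects, one per frame.
#' @export
sequence_windows <- function(seq, image_width) {
  skels <- canonicalise_sequence(seq, image_width)
  feats <- all_frame_features(seq, image_width, skels)
  lapply(seq_along(seq$frames), function(i)
    window_features(seq, i, image_width, feats = feats))
}
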