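# Synthetic 2D skeleton-motion generator: kinematic stick-figure templates
# for the eight action classes, rendered as BODY-18 keypoint streams with
# Gaussian pixel noise, joint dropout, tracked boxes and box velocities, plus
# scripted scenario clips with ground-truth tubes and alerts.

#' Synthetic motion parameters
#'
#' @param image_size Frame size in pixels (default c(704, 480)).
#' @param fps Frames per second (default 30).
#' @param body_height_px Full stick-figure height in pixels (default 160,
#'   a mid-distance pedestrian in a 704 x 480 surveillance view).
#' @param gait_amplitude Walking leg-swing amplitude in pixels (default 12).
#' @param walk_speed Horizontal walking speed in px/frame (default 3).
#' @param torso_incline Lean angle of the upper body in radians
#'   (default 0.6).
#' @param hip_drop Sitting hip height as a fraction of the standing hip
#'   height (default 0.5; crouching uses half of it).
#' @param noise_sigma Gaussian keypoint jitter in pixels (default 1).
#' @param joint_dropout_rate Per-joint probability of a missed detection
#'   (confidence 0); the neck and hips are never dropped so every frame
#'   stays canonicalisable (default 0.02).
#' @param seed Integer seed (default 0).
#' @return A `motion_params` list.
#' @export
motion_params <- function(image_size = c(704, 480), fps = 30,
                          body_height_px = 160, gait_amplitude = 12,
                          walk_speed = 3, torso_incline = 0.6,
                          hip_drop = 0.5, noise_sigma = 1,
                          joint_dropout_rate = 0.02, seed = 0) {
  stopifnot(body_height_px > 0, gait_amplitude >= 0, walk_speed >= 0,
            hip_drop > 0, hip_drop < 1, noise_sigma >= 0,
            joint_dropout_rate >= 0, joint_dropout_rate < 1)
  structure(list(image_size = image_size, fps = fps,
                 body_height_px = body_height_px,
                 gait_amplitude = gait_amplitude, walk_speed = walk_speed,
                 torso_incline = torso_incline, hip_drop = hip_drop,
                 noise_sigma = noise_sigma,
                 joint_dropout_rate = joint_dropout_rate,
                 seed = as.integer(seed)),
            class = "motion_params")
}

# Parametric stick figure: BODY-18 joint positions (px, y downward) for a
# figure standing at horizontal position cx with feet at ground_y.
# Proportions of the full height H: head 0.15, torso 0.35, upper and lower
# limb segments 0.2 each.
stick_figure <- function(cx, ground_y, H, hip_frac = 1, knee_fwd = 0,
                         torso_lean = 0, head_drop = 0, wrists_up = FALSE,
                         leg_swing = 0, arm_swing = 0) {
  hip_y <- ground_y - 0.4 * H * hip_frac
  hips <- rbind(r = c(cx + 0.06 * H, hip_y), l = c(cx - 0.06 * H, hip_y))
  hip_mid <- colMeans(hips)

  # legs: feet stay on the ground; knees bend forward as the hips drop,
  # and swing sinusoidally when walking (opposite phase per leg)
  knee_y <- (hip_y + ground_y) / 2
  knees <- rbind(c(hips[1, 1] + knee_fwd + leg_swing, knee_y),
                 c(hips[2, 1] + knee_fwd - leg_swing, knee_y))
  ankles <- rbind(c(hips[1, 1] + 0.3 * knee_fwd + 1.6 * leg_swing, ground_y),
                  c(hips[2, 1] + 0.3 * knee_fwd - 1.6 * leg_swing, ground_y))

  # upper body, before leaning: neck above the hip midpoint
  neck <- hip_mid + c(0, -0.35 * H)
  nose <- neck + c(0.03 * H, -0.15 * H + head_drop)
  shoulders <- rbind(r = neck + c(0.09 * H, 0.02 * H),
                     l = neck + c(-0.09 * H, 0.02 * H))
  if (wrists_up) {
    elbows <- shoulders + matrix(c(0.14 * H, -0.06 * H,
                                   -0.14 * H, -0.06 * H), 2, byrow = TRUE)
    wrists <- rbind(c(neck[1] + 0.06 * H, nose[2]),
                    c(neck[1] - 0.06 * H, nose[2]))
  } else {
    elbows <- shoulders +
      matrix(c(0.03 * H + arm_swing, 0.18 * H,
               -0.03 * H - arm_swing, 0.18 * H), 2, byrow = TRUE)
    wrists <- elbows +
      matrix(c(0.01 * H + 0.6 * arm_swing, 0.17 * H,
               -0.01 * H - 0.6 * arm_swing, 0.17 * H), 2, byrow = TRUE)
  }
  upper <- rbind(nose = nose, neck = neck,
                 r_shoulder = shoulders[1, ], r_elbow = elbows[1, ],
                 r_wrist = wrists[1, ],
                 l_shoulder = shoulders[2, ], l_elbow = elbows[2, ],
                 l_wrist = wrists[2, ])
  if (torso_lean != 0) {
    R <- matrix(c(cos(torso_lean), sin(torso_lean),
                  -sin(torso_lean), cos(torso_lean)), 2, 2)
    upper <- t(R %*% (t(upper) - hip_mid) + hip_mid)
  }
  nose <- upper["nose", ]
  face <- rbind(r_eye = nose + c(0.025 * H, -0.02 * H),
                l_eye = nose + c(-0.025 * H, -0.02 * H),
                r_ear = nose + c(0.045 * H, 0),
                l_ear = nose + c(-0.045 * H, 0))
  out <- rbind(upper[1:2, , drop = FALSE], upper[3:8, , drop = FALSE],
               hips[1, , drop = FALSE], knees[1, , drop = FALSE],
               ankles[1, , drop = FALSE],
               hips[2, , drop = FALSE], knees[2, , drop = FALSE],
               ankles[2, , drop = FALSE], face)
  rownames(out) <- BODY18_NAMES
  out
}

# Noise-free joint positions for n frames of one action class, starting at
# horizontal position cx. Returns the position list and the final cx.
raw_action_positions <- function(class, n, params, cx) {
  H <- params$body_height_px
  ground_y <- 0.85 * params$image_size[2]
  fps <- params$fps
  pos <- vector("list", n)
  for (t in seq_len(n)) {
    ph <- 2 * pi * (t - 1) / fps   # one gait cycle per second
    pos[[t]] <- switch(
      class,
      Stand = stick_figure(cx, ground_y, H),
      Walk = {
        p <- stick_figure(cx, ground_y, H,
                          leg_swing = params$gait_amplitude * sin(ph),
                          arm_swing = 0.6 * params$gait_amplitude * sin(ph + pi))
        cx <- cx + params$walk_speed
        p
      },
      Sit = stick_figure(cx, ground_y, H, hip_frac = params$hip_drop,
                         knee_fwd = 0.18 * H),
      Crouch = stick_figure(cx, ground_y, H, hip_frac = params$hip_drop / 2,
                            knee_fwd = 0.22 * H, torso_lean = 0.3,
                            head_drop = 0.02 * H),
      Lean = stick_figure(cx, ground_y, H, torso_lean = params$torso_incline),
      LeanHead = stick_figure(cx, ground_y, H,
                              torso_lean = params$torso_incline,
                              head_drop = 0.2 * H),
      Photo = stick_figure(cx, ground_y, H, wrists_up = TRUE),
      Place = {
        # stand -> brief crouch dip -> stand inside the segment
        u <- (t - 1) / max(n - 1, 1)
        dip <- exp(-((u - 0.5) / 0.18)^2)
        stick_figure(cx, ground_y, H,
                     hip_frac = 1 - dip * (1 - params$hip_drop / 2),
                     knee_fwd = dip * 0.22 * H, torso_lean = dip * 0.3)
      },
      stop("unknown action class: ", class)
    )
  }
  list(pos = pos, cx = cx)
}

# Render noise-free joint positions into pose frames: Gaussian jitter, i.i.d.
# joint dropout (neck and hips exempt), joint bounding box + margin, and box
# velocity as the finite difference of box centres.
render_pose_frames <- function(pos, params, track_id, start_frame) {
  n <- length(pos)
  H <- params$body_height_px
  droppable <- !(BODY18_NAMES %in% c("neck", "r_hip", "l_hip"))
  centers <- matrix(0, n, 2)
  boxes <- matrix(0, n, 4)
  kps <- vector("list", n)
  for (t in seq_len(n)) {
    xy <- pos[[t]] + matrix(stats::rnorm(36, 0, params$noise_sigma), 18, 2)
    conf <- rep(1, 18)
    drop <- droppable & stats::runif(18) < params$joint_dropout_rate
    if (t == 1) drop[] <- FALSE
    conf[drop] <- 0
    margin <- 0.05 * H
    vis <- xy[conf > 0, , drop = FALSE]
    box <- c(min(vis[, 1]) - margin, min(vis[, 2]) - margin,
             diff(range(vis[, 1])) + 2 * margin,
             diff(range(vis[, 2])) + 2 * margin)
    boxes[t, ] <- box
    centers[t, ] <- box[1:2] + box[3:4] / 2
    kps[[t]] <- cbind(xy, conf)
  }
  lapply(seq_len(n), function(t) {
    bv <- if (t == 1) c(0, 0) else centers[t, ] - centers[t - 1, ]
    pose_frame(start_frame + t - 1L, track_id, kps[[t]], boxes[t, ],
               box_velocity = bv, fps = params$fps)
  })
}

#' Generate a synthetic single-action pose sequence
#'
#' Renders one action class as a BODY-18 keypoint stream from a kinematic
#' stick-figure template: Walk translates at `walk_speed` with sinusoidal
#' leg/arm swing, Sit and Crouch lower the hips (to `hip_drop` and
#' `hip_drop / 2` of standing hip height) with bent knees, Lean and LeanHead
#' incline the upper body by `torso_incline` (LeanHead also drops the head
#' below the shoulder line), Photo raises both wrists to head height, Place
#' dips from standing into a brief crouch and back. Gaussian pixel noise and
#' i.i.d. joint dropout are applied on top.
#'
#' @param class One of [action_classes()].
#' @param duration_s Duration in seconds.
#' @param params A [motion_params()].
#' @param track_id Track identifier (default 1).
#' @param start_frame First frame index (default 0).
#' @param cx Starting horizontal position in px (default image centre).
#' @return A `pose_sequence`.
#' @export
generate_action <- function(class, duration_s, params = motion_params(),
                            track_id = 1L, start_frame = 0L, cx = NULL) {
  set.seed(params$seed)
  if (is.null(cx)) cx <- params$image_size[1] / 2
  n <- max(2L, round(duration_s * params$fps))
  raw <- raw_action_positions(class, n, params, cx)
  frames <- render_pose_frames(raw$pos, params, track_id, start_frame)
  structure(list(track_id = track_id, fps = params$fps, frames = frames),
            class = "pose_sequence")
}

#' Generate a scripted scenario clip with ground truth
#'
#' Concatenates scripted action segments into one continuous pose stream for
#' a single track. Posture transitions at segment boundaries are linearly
#' interpolated over 0.5 s to create realistic ambiguous boundary frames.
#' Ground-truth tubes equal the script, and ground-truth crisis alerts are
#' obtained by applying the logic-layer rules to the script itself.
#'
#' @param script Data frame with columns `class`, `start_s`, `end_s`:
#'   non-overlapping, increasing segments.
#' @param params A [motion_params()].
#' @param track_id Track identifier (default 1).
#' @param config A [rule_config()] used to derive the ground-truth alerts.
#' @return List with `sequence` (a `pose_sequence`), `gt_tubes` and
#'   `gt_alerts`.
#' @export
generate_scenario <- function(script, params = motion_params(),
                              track_id = 1L, config = rule_config()) {
  if (nrow(script) == 0)
    return(list(sequence = structure(list(track_id = track_id,
                                          fps = params$fps, frames = list()),
                                     class = "pose_sequence"),
                gt_tubes = build_tubes(data.frame()),
                gt_alerts = empty_alerts()))
  stopifnot(all(script$end_s > script$start_s),
            all(script$class %in% action_classes()))
  if (nrow(script) > 1 &&
      any(script$start_s[-1] < script$end_s[-nrow(script)]))
    stop("script segments overlap")
  set.seed(params$seed)
  fps <- params$fps
  cx <- params$image_size[1] / 2
  pos <- list()
  prev_last <- NULL
  blend_n <- round(0.5 * fps)
  for (k in seq_len(nrow(script))) {
    n_k <- round((script$end_s[k] - script$start_s[k]) * fps)
    raw <- raw_action_positions(script$class[k], n_k, params, cx)
    cx <- raw$cx
    seg <- raw$pos
    if (!is.null(prev_last)) {
      for (t in seq_len(min(blend_n, n_k))) {
        w <- t / (min(blend_n, n_k) + 1)
        seg[[t]] <- (1 - w) * prev_last + w * seg[[t]]
      }
    }
    prev_last <- seg[[n_k]]
    pos <- c(pos, seg)
  }
  frames <- render_pose_frames(pos, params, track_id,
                               start_frame = round(script$start_s[1] * fps))
  sequence <- structure(list(track_id = track_id, fps = fps, frames = frames),
                        class = "pose_sequence")
  gt_tubes <- data.frame(
    track_id = as.character(track_id), label = script$class,
    start_frame = as.integer(round(script$start_s * fps)),
    end_frame = as.integer(round(script$end_s * fps)) - 1L,
    start_s = script$start_s, end_s = script$end_s, score = 1,
    stringsAsFactors = FALSE
  )
  list(sequence = sequence, gt_tubes = gt_tubes,
       gt_alerts = detect_crisis(gt_tubes, config))
}

#' Build a labelled training-window set from the generator
#'
#' Generates one long sequence per class and extracts 30-step feature
#' windows at a fixed stride, yielding the `branch_a` (n x 30 x 96) and
#' `branch_b` (n x 30 x 62) arrays consumed by [fit_action_recognizer()].
#'
#' @param classes Character vector of classes to generate.
#' @param windows_per_class Windows per class; a single number (balanced) or
#'   a vector matching `classes` (imbalanced).
#' @param params A [motion_params()].
#' @param stride Frames between consecutive window centres (default 2).
#' @return List with `branch_a`, `branch_b`, `labels` (factor), `classes`.
#' @export
make_training_set <- function(classes, windows_per_class,
                              params = motion_params(), stride = 2) {
  stopifnot(all(windows_per_class >= 1))
  if (length(windows_per_class) == 1)
    windows_per_class <- rep(windows_per_class, length(classes))
  stopifnot(length(windows_per_class) == length(classes))
  image_width <- params$image_size[1]
  total <- sum(windows_per_class)
  Xa <- array(0, c(total, 30, 96))
  Xb <- array(0, c(total, 30, 62))
  labels <- character(total)
  row <- 1L
  for (ci in seq_along(classes)) {
    n_w <- windows_per_class[ci]
    n_frames <- 30 + (n_w - 1) * stride + 30
    p <- params
    p$seed <- params$seed + ci   # distinct noise stream per class
    seqc <- generate_action(classes[ci], n_frames / params$fps, p)
    skels <- canonicalise_sequence(seqc, image_width)
    feats <- all_frame_features(seqc, image_width, skels)
    centers <- 15 + (seq_len(n_w) - 1) * stride
    for (w in seq_len(n_w)) {
      fw <- window_features(seqc, centers[w], image_width, feats = feats)
      Xa[row, , ] <- fw$branch_a
      Xb[row, , ] <- fw$branch_b
      labels[row] <- classes[ci]
      row <- row + 1L
    }
  }
  list(branch_a = Xa, branch_b = Xb,
       labels = factor(labels, levels = classes), classes = classes)
}
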