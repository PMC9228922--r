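# Shared fixtures and independent oracles used across the suite.

# A deterministic hand-built BODY-18 pose in pixels (y downward). Neck at
# (100, 80), hip midpoint at (100, 130) so the body height is exactly 50 px.
hand_keypoints <- function() {
  m <- rbind(
    nose = c(103, 60), neck = c(100, 80),
    r_shoulder = c(112, 82), r_elbow = c(118, 100), r_wrist = c(120, 118),
    l_shoulder = c(88, 82), l_elbow = c(82, 100), l_wrist = c(80, 118),
    r_hip = c(106, 130), r_knee = c(108, 155), r_ankle = c(110, 180),
    l_hip = c(94, 130), l_knee = c(92, 155), l_ankle = c(90, 180),
    r_eye = c(104, 57), l_eye = c(101, 57), r_ear = c(106, 59),
    l_ear = c(99, 59)
  )
  cbind(m, 1)
}

hand_frame <- function(frame_index = 0, keypoints = hand_keypoints(),
                       box = NULL, box_velocity = NULL, track_id = 1L) {
  if (is.null(box)) {
    xy <- keypoints[, 1:2]
    box <- c(min(xy[, 1]), min(xy[, 2]), diff(range(xy[, 1])),
             diff(range(xy[, 2])))
  }
  pose_frame(frame_index, track_id, keypoints, box,
             box_velocity = box_velocity)
}

# Random valid pose frame for property tests: hand pose plus jitter.
random_frame <- function(frame_index = 0, jitter = 5) {
  kp <- hand_keypoints()
  kp[, 1:2] <- kp[, 1:2] + matrix(stats::runif(36, -jitter, jitter), 18, 2)
  hand_frame(frame_index, kp)
}

# Brute-force connected-components oracle via union-find.
oracle_components <- function(ids, pass_pairs) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (p in pass_pairs) parent[[find(p[1])]] <- find(p[2])
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# Brute-force run-length tube oracle: scan labels frame by frame, bridging
# interior void runs of at most max_gap frames between identical labels.
oracle_tubes <- function(labels, fps, max_gap_s) {
  n <- length(labels)
  bridged <- labels
  i <- 1
  while (i <= n) {
    if (bridged[i] == "void") {
      j <- i
      while (j <= n && bridged[j] == "void") j <- j + 1
      if (i > 1 && j <= n && bridged[i - 1] == bridged[j] &&
          (j - i) <= max_gap_s * fps)
        bridged[i:(j - 1)] <- bridged[j]
      i <- j
    } else i <- i + 1
  }
  out <- list()
  i <- 1
  while (i <= n) {
    if (bridged[i] != "void") {
      j <- i
      while (j <= n && bridged[j] == bridged[i]) j <- j + 1
      out[[length(out) + 1]] <- data.frame(
        label = bridged[i], start_frame = i - 1, end_frame = j - 2)
      i <- j
    } else i <- i + 1
  }
  if (length(out) == 0)
    return(data.frame(label = character(), start_frame = integer(),
                      end_frame = integer()))
  do.call(rbind, out)
}

# Timeline data frame from a label vector (frames 0, 1, ...).
label_timeline <- function(labels, confidence = 0.9, track_id = "1") {
  data.frame(frame = seq_along(labels) - 1L,
             track_id = rep(track_id, length(labels)),
             label = labels,
             confidence = rep_len(confidence, length(labels)),
             stringsAsFactors = FALSE)
}

tube_row <- function(label, start_s, end_s, fps = 30, score = 0.9,
                     track_id = "1") {
  data.frame(track_id = track_id, label = label,
             start_frame = as.integer(round(start_s * fps)),
             end_frame = as.integer(round(end_s * fps)),
             start_s = start_s, end_s = end_s, score = score,
             stringsAsFactors = FALSE)
}

# One small trained recognizer shared across tests (lazy, cached).
.cached_model <- new.env()
tiny_recognizer <- function() {
  if (is.null(.cached_model$model)) {
    tr <- make_training_set(c("Crouch", "Stand", "Walk"), 40,
                            motion_params(seed = 11))
    .cached_model$model <- fit_action_recognizer(
      tr, classes = c("Crouch", "Stand", "Walk"), hidden_size = 32,
      epochs = 8, learning_rate_a = 2e-3, learning_rate_b = 2e-3, seed = 11)
  }
  .cached_model$model
}
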