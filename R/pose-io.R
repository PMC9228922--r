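# Pose stream input/output: JSON-lines pose records, per-track sequences, and
# the timeline/tube/alert serialisation formats.

#' Construct a single-person pose frame
#'
#' A pose frame holds one tracked person's 2D keypoints, bounding box and
#' (optionally) box velocity at one video frame. Keypoints follow the BODY-18
#' layout (nose, neck, right arm, left arm, right leg, left leg, eyes, ears);
#' 17-keypoint COCO input is accepted and the neck is synthesised as the
#' shoulder midpoint with confidence equal to the smaller shoulder confidence.
#' Missing keypoints are encoded with confidence 0.
#'
#' @param frame_index Non-negative integer video frame number.
#' @param track_id Track identifier (character or integer).
#' @param keypoints Numeric matrix with 17 or 18 rows and columns (x, y,
#'   confidence); pixel coordinates, x rightward, y downward, 0-based.
#' @param box Numeric length-4 vector (x, y, w, h) in pixels; w, h > 0.
#' @param box_velocity Optional numeric length-2 vector (vx, vy) in
#'   pixels/frame, as produced by a Kalman-filter tracker.
#' @param fps Frames per second used to derive `timestamp_s` (default 30).
#' @return An object of class `pose_frame`.
#' @export
pose_frame <- function(frame_index, track_id, keypoints, box,
                       box_velocity = NULL, fps = 30) {
  keypoints <- as.matrix(keypoints)
  validate_keypoints(keypoints, frame_index)
  box <- as.numeric(box)
  if (length(box) != 4 || box[3] <= 0 || box[4] <= 0)
    stop("box must be (x, y, w, h) with w > 0 and h > 0 (frame ",
         frame_index, ")")
  if (!is.null(box_velocity)) {
    box_velocity <- as.numeric(box_velocity)
    if (length(box_velocity) != 2)
      stop("box_velocity must have length 2")
  }
  structure(
    list(
      frame_index = as.integer(frame_index),
      timestamp_s = as.numeric(frame_index) / fps,
      track_id = track_id,
      keypoints = unname(keypoints),
      box = box,
      box_velocity = box_velocity
    ),
    class = "pose_frame"
  )
}

validate_keypoints <- function(kp, frame_index = NA) {
  if (!is.numeric(kp) || is.null(dim(kp)) || ncol(kp) != 3)
    stop("keypoints must be a numeric matrix with columns (x, y, confidence)")
  if (!nrow(kp) %in% c(17L, 18L))
    stop("keypoint count must be 17 or 18, got ", nrow(kp),
         if (!is.na(frame_index)) paste0(" (frame ", frame_index, ")") else "")
  conf <- kp[, 3]
  if (any(conf < 0 | conf > 1))
    stop("keypoint confidence must lie in [0, 1]")
  invisible(kp)
}

#' Read a pose stream from a JSON-lines file
#'
#' One JSON object per line per (frame, person):
#' `{"frame": int, "track_id": id, "keypoints": [[x,y,c] x 17|18],
#'   "box": [x,y,w,h], "box_velocity": [vx,vy]}` (velocity optional).
#' Records are returned sorted by (frame_index, track_id). 17-keypoint
#' records are stored as read; neck synthesis happens during
#' canonicalisation.
#'
#' @param path Path to a JSONL pose stream.
#' @param fps Frames per second (default 30).
#' @return List of [pose_frame] objects.
#' @export
read_pose_stream <- function(path, fps = 30) {
  if (!file.exists(path)) stop("pose stream not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$frame) || is.null(rec$track_id) ||
        is.null(rec$keypoints) || is.null(rec$box))
      stop("malformed pose record at line ", i, " of ", path)
    kp <- rec$keypoints
    if (is.list(kp)) kp <- do.call(rbind, kp)
    frames[[i]] <- pose_frame(rec$frame, rec$track_id, kp, rec$box,
                              box_velocity = rec$box_velocity, fps = fps)
  }
  sort_pose_frames(frames)
}

#' Read COCO keypoint results JSON
#'
#' Accepts a COCO "person keypoints results" array: objects with `image_id`
#' (used as frame index), flat 51-value `keypoints` (x, y, score per COCO-17
#' joint) and `bbox`; an `id` or `track_id` field supplies the track
#' identifier (a single default track otherwise).
#'
#' @inheritParams read_pose_stream
#' @return List of [pose_frame] objects with 17 keypoints each.
#' @export
read_coco_results <- function(path, fps = 30) {
  if (!file.exists(path)) stop("COCO results not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  frames <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$image_id) || is.null(r$keypoints) || is.null(r$bbox))
      stop("malformed COCO result record ", i, " in ", path)
    kp <- matrix(as.numeric(unlist(r$keypoints)), ncol = 3, byrow = TRUE)
    if (nrow(kp) != 17) stop("COCO record ", i, ": expected 17 keypoints")
    # COCO visibility scores may exceed 1; clamp to [0, 1]
    kp[, 3] <- pmin(pmax(kp[, 3], 0), 1)
    tid <- if (!is.null(r$track_id)) r$track_id else if (!is.null(r$id)) r$id else 1L
    pose_frame(r$image_id, tid, kp, r$bbox, fps = fps)
  })
  sort_pose_frames(frames)
}

sort_pose_frames <- function(frames) {
  if (length(frames) == 0) return(frames)
  fi <- vapply(frames, function(f) f$frame_index, integer(1))
  ti <- vapply(frames, function(f) as.character(f$track_id), character(1))
  frames[order(fi, ti)]
}

#' Write a pose stream as JSON lines
#'
#' Inverse of [read_pose_stream()]: fixed key order, floats rounded to 4
#' decimals, so output is bit-stable for a fixed input.
#'
#' @param frames List of [pose_frame] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(frames, path) {
  fmt <- function(x) {
    s <- formatC(round(as.numeric(x), 4), format = "fg", digits = 15)
    trimws(s)
  }
  lines <- vapply(frames, function(f) {
    kp <- apply(f$keypoints, 1, function(r)
      paste0("[", paste(fmt(r), collapse = ","), "]"))
    tid <- if (is.character(f$track_id))
      paste0("\"", f$track_id, "\"") else fmt(f$track_id)
    s <- paste0(
      "{\"frame\":", f$frame_index,
      ",\"track_id\":", tid,
      ",\"keypoints\":[", paste(kp, collapse = ","), "]",
      ",\"box\":[", paste(fmt(f$box), collapse = ","), "]"
    )
    if (!is.null(f$box_velocity))
      s <- paste0(s, ",\"box_velocity\":[",
                  paste(fmt(f$box_velocity), collapse = ","), "]")
    paste0(s, "}")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Group pose frames into per-track sequences
#'
#' Partitions a validated frame list by track id, preserving frame order
#' within each track. The union of the output frames equals the input.
#'
#' @param frames List of [pose_frame] objects (time-ordered).
#' @param fps Frames per second carried on each sequence (default 30).
#' @return List of `pose_sequence` objects (fields `track_id`, `fps`,
#'   `frames`), in order of first appearance of each track.
#' @export
split_by_track <- function(frames, fps = 30) {
  if (length(frames) == 0) return(list())
  ids <- vapply(frames, function(f) as.character(f$track_id), character(1))
  uniq <- unique(ids)
  lapply(uniq, function(id) {
    fr <- frames[ids == id]
    fi <- vapply(fr, function(f) f$frame_index, integer(1))
    if (any(diff(fi) <= 0))
      stop("frame indices must be strictly increasing within track ", id)
    structure(list(track_id = fr[[1]]$track_id, fps = fps, frames = fr),
              class = "pose_sequence")
  })
}

#' @export
length.pose_sequence <- function(x) length(x$frames)

#' Write and read a frame-wise label timeline
#'
#' The timeline CSV has columns `frame,track_id,label,confidence`, one row per
#' (frame, track); confidence is written with 4 decimals so the file is
#' bit-stable.
#'
#' @param timeline Data frame with columns `frame`, `track_id`, `label`,
#'   `confidence`.
#' @param path Output path.
#' @return `path` invisibly ([write_timeline()]); the timeline data frame
#'   ([read_timeline()]).
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(all(c("frame", "track_id", "label", "confidence") %in%
                  names(timeline)))
  out <- timeline[, c("frame", "track_id", "label", "confidence")]
  out <- out[order(out$frame, as.character(out$track_id)), , drop = FALSE]
  out$confidence <- sprintf("%.4f", out$confidence)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$confidence <- as.numeric(df$confidence)
  df
}

#' Write and read action tubes as JSON
#'
#' Tubes are serialised as an array of objects with sorted keys
#' (`end_frame,end_s,label,score,start_frame,start_s,track_id`) and floats
#' rounded to 4 decimals, so writing is deterministic.
#'
#' @param tubes Data frame of action tubes as produced by [build_tubes()].
#' @param path Output path.
#' @return `path` invisibly ([write_tubes()]); the tubes data frame
#'   ([read_tubes()]).
#' @export
write_tubes <- function(tubes, path) {
  cols <- c("end_frame", "end_s", "label", "score", "start_frame",
            "start_s", "track_id")
  if (nrow(tubes) == 0) {
    writeLines("[]", path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(tubes)))
  out <- tubes[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 4))
  writeLines(as.character(jsonlite::toJSON(out, dataframe = "rows",
                                           auto_unbox = FALSE, digits = NA,
                                           pretty = TRUE)), path)
  invisible(path)
}

#' @rdname write_tubes
#' @export
read_tubes <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0)
    return(data.frame(track_id = character(), label = character(),
                      start_frame = integer(), end_frame = integer(),
                      start_s = numeric(), end_s = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  x[, c("track_id", "label", "start_frame", "end_frame",
        "start_s", "end_s", "score")]
}

#' Write and read crisis alerts as JSON
#'
#' Alerts are serialised with sorted keys and 4-decimal floats; the
#' `description` field mirrors the human-readable alert sentence (e.g.
#' "'Crouch' at timepoint 123.37 s").
#'
#' @param alerts Data frame of alerts as produced by the `detect_*` rules.
#' @param path Output path.
#' @return `path` invisibly ([write_alerts()]); the alerts data frame
#'   ([read_alerts()]).
#' @export
write_alerts <- function(alerts, path) {
  cols <- c("description", "end_s", "kind", "label", "start_s", "track_id")
  if (nrow(alerts) == 0) {
    writeLines("[]", path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(alerts)))
  out <- alerts[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 4))
  writeLines(as.character(jsonlite::toJSON(out, dataframe = "rows",
                                           auto_unbox = FALSE, digits = NA,
                                           pretty = TRUE)), path)
  invisible(path)
}

#' @rdname write_alerts
#' @export
read_alerts <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0) return(empty_alerts())
  x[, c("track_id", "kind", "label", "start_s", "end_s", "description")]
}

empty_alerts <- function() {
  data.frame(track_id = character(), kind = character(), label = character(),
             start_s = numeric(), end_s = numeric(), description = character(),
             stringsAsFactors = FALSE)
}
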