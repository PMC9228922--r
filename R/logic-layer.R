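# The logical layer: frame-wise labels -> action tubes -> counts and crisis
# alerts. Three kinds of alert are raised per tracked person: unit crisis
# actions (Crouch, LeanHead, Place), long-duration Sit or Lean/Stand spans,
# and repetitive mixes of actions within a period.

UNIT_CRISIS_CLASSES <- c("Crouch", "LeanHead", "Place")

#' Crisis-rule configuration
#'
#' @param max_gap_s Void (or inter-tube) gaps up to this many seconds are
#'   bridged when forming tubes and merging Lean/Stand or Sit spans
#'   (default 1).
#' @param long_duration_threshold_s A Sit or Lean/Stand span must strictly
#'   exceed this duration to raise an alert (default 100).
#' @param repetition_period_s Sliding-window length for the repetitive rule
#'   (default 300).
#' @param min_distinct_kinds Number of distinct action kinds (Stand and Lean
#'   count as one kind) that must each recur for the repetitive rule
#'   (default 3, i.e. "more than two").
#' @param min_occurrences_per_kind Occurrences each kind needs inside the
#'   window (default 2, so isolated one-off actions do not read as a
#'   repetitive pattern).
#' @return A `rule_config` list.
#' @export
rule_config <- function(max_gap_s = 1, long_duration_threshold_s = 100,
                        repetition_period_s = 300, min_distinct_kinds = 3,
                        min_occurrences_per_kind = 2) {
  stopifnot(max_gap_s >= 0, long_duration_threshold_s > 0,
            repetition_period_s > 0, min_distinct_kinds >= 1,
            min_occurrences_per_kind >= 1)
  structure(list(max_gap_s = max_gap_s,
                 long_duration_threshold_s = long_duration_threshold_s,
                 repetition_period_s = repetition_period_s,
                 min_distinct_kinds = min_distinct_kinds,
                 min_occurrences_per_kind = min_occurrences_per_kind),
            class = "rule_config")
}

#' Build action tubes from a frame-wise timeline
#'
#' Combines consecutive frames with the same label into maximal tubes,
#' bridging interior runs of void frames of duration at most `max_gap_s`
#' when the same label continues on both sides. The tube score is the mean
#' confidence of its contributing non-void frames.
#'
#' @param timeline Label timeline for one track: data frame with `frame`,
#'   `track_id`, `label` (class or "void"), `confidence`.
#' @param max_gap_s Maximum bridged void gap in seconds (default 1).
#' @param fps Frames per second (default 30).
#' @return Data frame of tubes sorted by start: `track_id`, `label`,
#'   `start_frame`, `end_frame`, `start_s`, `end_s`, `score`.
#' @export
build_tubes <- function(timeline, max_gap_s = 1, fps = 30) {
  empty <- data.frame(track_id = character(), label = character(),
                      start_frame = integer(), end_frame = integer(),
                      start_s = numeric(), end_s = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(timeline) == 0) return(empty)
  if (length(unique(timeline$track_id)) > 1)
    stop("build_tubes expects a single-track timeline")
  timeline <- timeline[order(timeline$frame), , drop = FALSE]
  lab <- as.character(timeline$label)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # bridge interior void runs flanked by the same label
  max_gap_frames <- max_gap_s * fps
  repeat {
    merged <- FALSE
    if (length(r$values) >= 3) {
      for (k in 2:(length(r$values) - 1)) {
        if (r$values[k] == "void" && r$values[k - 1] == r$values[k + 1] &&
            r$values[k - 1] != "void" && r$lengths[k] <= max_gap_frames) {
          r$values[k] <- r$values[k - 1]
          r <- rle(inverse.rle(r))
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "void"
  if (!any(keep)) return(empty)
  out <- lapply(which(keep), function(k) {
    rows <- timeline[starts[k]:ends[k], , drop = FALSE]
    nz <- rows[rows$label != "void", , drop = FALSE]
    data.frame(track_id = as.character(timeline$track_id[1]),
               label = r$values[k],
               start_frame = rows$frame[1],
               end_frame = rows$frame[nrow(rows)],
               start_s = rows$frame[1] / fps,
               end_s = rows$frame[nrow(rows)] / fps,
               score = mean(nz$confidence),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$start_s), , drop = FALSE]
}

#' Expand tubes back to a frame-wise label sequence
#'
#' Inverse of [build_tubes()] at `max_gap_s = 0`: every frame covered by a
#' tube gets its label, all other frames in `frames` are void.
#'
#' @param tubes Tube data frame.
#' @param frames Integer vector of frame indices to label.
#' @return Data frame with `frame` and `label`.
#' @export
expand_tubes <- function(tubes, frames) {
  lab <- rep("void", length(frames))
  for (k in seq_len(nrow(tubes)))
    lab[frames >= tubes$start_frame[k] & frames <= tubes$end_frame[k]] <-
      tubes$label[k]
  data.frame(frame = frames, label = lab, stringsAsFactors = FALSE)
}

#' Count action occurrences
#'
#' Each tube counts as one occurrence of its class, so an action sustained
#' over many frames is counted once.
#'
#' @param tubes Tube data frame for one track.
#' @param classes Class set to report (default [action_classes()]).
#' @return Named integer vector over `classes`.
#' @export
count_actions <- function(tubes, classes = action_classes()) {
  counts <- table(factor(tubes$label, levels = classes))
  stats::setNames(as.integer(counts), classes)
}

#' Unit-action crisis alerts
#'
#' One alert per tube whose class is a unit crisis indicator (Crouch,
#' LeanHead or Place), timestamped at the tube start.
#'
#' @param tubes Tube data frame for one track.
#' @return Alert data frame (`track_id`, `kind`, `label`, `start_s`,
#'   `end_s`, `description`).
#' @export
detect_unit_crisis <- function(tubes) {
  hits <- tubes[tubes$label %in% UNIT_CRISIS_CLASSES, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_alerts())
  data.frame(
    track_id = hits$track_id, kind = "unit_action", label = hits$label,
    start_s = hits$start_s, end_s = hits$end_s,
    description = sprintf("'%s' at timepoint %.2f s", hits$label,
                          hits$start_s),
    stringsAsFactors = FALSE
  )
}

# Merge tubes of the given labels into spans, bridging gaps <= max_gap_s.
merge_spans <- function(tubes, labels, span_label, max_gap_s) {
  sub <- tubes[tubes$label %in% labels, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  sub <- sub[order(sub$start_s), , drop = FALSE]
  start <- sub$start_s[1]; end <- sub$end_s[1]
  spans <- list()
  for (k in seq_len(nrow(sub))[-1]) {
    if (sub$start_s[k] - end <= max_gap_s) {
      end <- max(end, sub$end_s[k])
    } else {
      spans[[length(spans) + 1]] <- c(start, end)
      start <- sub$start_s[k]; end <- sub$end_s[k]
    }
  }
  spans[[length(spans) + 1]] <- c(start, end)
  data.frame(label = span_label,
             start_s = vapply(spans, `[`, numeric(1), 1),
             end_s = vapply(spans, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

#' Long-duration crisis alerts
#'
#' Stand and Lean tubes are first merged into combined "Lean/Stand" spans
#' (the two actions shift into one another without intent), Sit tubes into
#' Sit spans, both bridging gaps of at most `max_gap_s`. A span strictly
#' longer than `threshold_s` raises an alert.
#'
#' @param tubes Tube data frame for one track.
#' @param threshold_s Duration threshold in seconds (default 100).
#' @param max_gap_s Span-merging gap bound in seconds (default 1).
#' @return Alert data frame.
#' @export
detect_long_duration <- function(tubes, threshold_s = 100, max_gap_s = 1) {
  spans <- rbind(
    merge_spans(tubes, c("Lean", "Stand"), "Lean/Stand", max_gap_s),
    merge_spans(tubes, "Sit", "Sit", max_gap_s)
  )
  spans$duration <- spans$end_s - spans$start_s
  hits <- spans[spans$duration > threshold_s, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_alerts())
  hits <- hits[order(hits$start_s), , drop = FALSE]
  data.frame(
    track_id = rep(as.character(tubes$track_id[1]), nrow(hits)),
    kind = "long_duration", label = hits$label,
    start_s = hits$start_s, end_s = hits$end_s,
    description = sprintf(
      "'%s' for a long duration of %.2f s from %.2f to %.2f s",
      hits$label, hits$duration, hits$start_s, hits$end_s),
    stringsAsFactors = FALSE
  )
}

#' Repetitive-pattern crisis alerts
#'
#' Within a sliding window of `repetition_period_s` seconds, an alert is
#' raised when at least `min_distinct_kinds` action kinds each occur at
#' least `min_occurrences_per_kind` times and the qualifying kinds include
#' Sit or Walk (capturing "walk back and forth" and "sit and stand up"
#' patterns). Stand and Lean are treated as a single "Lean/Stand" kind whose
#' occurrences are the merged spans, so a bare Stand/Lean alternation never
#' qualifies.
#'
#' @param tubes Tube data frame for one track.
#' @param config A [rule_config()].
#' @return Alert data frame (at most one alert, for the earliest qualifying
#'   window).
#' @export
detect_repetitive <- function(tubes, config = rule_config()) {
  if (nrow(tubes) == 0) return(empty_alerts())
  ls_spans <- merge_spans(tubes, c("Lean", "Stand"), "Lean/Stand",
                          config$max_gap_s)
  other <- tubes[!tubes$label %in% c("Lean", "Stand"), , drop = FALSE]
  events <- rbind(
    data.frame(kind = other$label, start_s = other$start_s,
               stringsAsFactors = FALSE),
    data.frame(kind = ls_spans$label, start_s = ls_spans$start_s,
               stringsAsFactors = FALSE)
  )
  events <- events[order(events$start_s), , drop = FALSE]
  for (k in seq_len(nrow(events))) {
    t0 <- events$start_s[k]
    win <- events[events$start_s >= t0 &
                    events$start_s <= t0 + config$repetition_period_s, ,
                  drop = FALSE]
    counts <- table(win$kind)
    qualifying <- names(counts)[counts >= config$min_occurrences_per_kind]
    if (length(qualifying) >= config$min_distinct_kinds &&
        any(c("Sit", "Walk") %in% qualifying)) {
      t1 <- max(win$start_s)
      return(data.frame(
        track_id = as.character(tubes$track_id[1]),
        kind = "repetitive_pattern",
        label = paste(sort(qualifying), collapse = "+"),
        start_s = t0, end_s = t1,
        description = sprintf(
          "repetitive pattern of %s between %.2f and %.2f s",
          paste(sort(qualifying), collapse = ", "), t0, t1),
        stringsAsFactors = FALSE
      ))
    }
  }
  empty_alerts()
}

#' Run all crisis rules on one track's tubes
#'
#' @param tubes Tube data frame for one track.
#' @param config A [rule_config()].
#' @return Alert data frame combining unit-action, long-duration and
#'   repetitive-pattern alerts, sorted by start time.
#' @export
detect_crisis <- function(tubes, config = rule_config()) {
  alerts <- rbind(
    detect_unit_crisis(tubes),
    detect_long_duration(tubes, config$long_duration_threshold_s,
                         config$max_gap_s),
    detect_repetitive(tubes, config)
  )
  alerts[order(alerts$start_s), , drop = FALSE]
}

#' Action-graph data for a track
#'
#' Per-class horizontal timeline segments (predicted tubes and, optionally,
#' ground-truth tubes) in long form, ready for plotting or CSV export. Every
#' configured class appears as a factor level even when it has no segments.
#'
#' @param tubes Predicted tube data frame.
#' @param gt_tubes Optional ground-truth tube data frame.
#' @param classes Class set (default [action_classes()]).
#' @return Data frame with `class` (factor over `classes`), `start_s`,
#'   `end_s`, `source` ("pred" or "gt").
#' @export
action_graph_data <- function(tubes, gt_tubes = NULL,
                              classes = action_classes()) {
  seg <- function(tb, src) {
    if (is.null(tb) || nrow(tb) == 0)
      return(data.frame(class = factor(character(), levels = classes),
                        start_s = numeric(), end_s = numeric(),
                        source = character(), stringsAsFactors = FALSE))
    data.frame(class = factor(tb$label, levels = classes),
               start_s = tb$start_s, end_s = tb$end_s,
               source = src, stringsAsFactors = FALSE)
  }
  rbind(seg(tubes, "pred"), seg(gt_tubes, "gt"))
}

#' Plot an action graph
#'
#' Base-graphics rendering of [action_graph_data()]: one row per class,
#' predicted tubes as dashed segments, ground truth as solid segments.
#'
#' @param graph Output of [action_graph_data()].
#' @param main Plot title.
#' @return The graph data, invisibly.
#' @export
plot_action_graph <- function(graph, main = "Action graph") {
  classes <- levels(graph$class)
  ypos <- stats::setNames(seq_along(classes), classes)
  xmax <- if (nrow(graph) > 0) max(graph$end_s) else 1
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0.5, length(classes) + 0.5),
                 yaxt = "n", xlab = "time (s)", ylab = "", main = main)
  graphics::axis(2, at = seq_along(classes), labels = classes, las = 1)
  for (k in seq_len(nrow(graph))) {
    y <- ypos[[as.character(graph$class[k])]]
    pred <- graph$source[k] == "pred"
    graphics::segments(graph$start_s[k], y + if (pred) 0.12 else -0.12,
                       graph$end_s[k], y + if (pred) 0.12 else -0.12,
                       col = if (pred) "darkgreen" else "red",
                       lty = if (pred) 2 else 1, lwd = 3)
  }
  invisible(graph)
}
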