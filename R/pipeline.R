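# End-to-end orchestration: simulate -> extract -> train -> predict ->
# analyze -> evaluate on a scripted synthetic scenario, writing every
# artifact to disk. The thin command-line wrapper in inst/cli/skelact.R
# exposes the same steps as shell subcommands.

#' Run the full pipeline on a scripted synthetic scenario
#'
#' Generates a scenario clip (pose stream + ground truth), builds a labelled
#' training set from the same generator, fits the two-branch recognizer,
#' predicts the frame-wise timeline for the scenario track, applies the
#' logic layer (tubes, counts, crisis alerts, action-graph data), and
#' evaluates temporal detection (AP/mAP grid) and frame-wise classification
#' against the ground truth. All artifacts are written under `out_dir` when
#' given. Fully deterministic for a fixed `seed`.
#'
#' @param script Scenario script (data frame `class`, `start_s`, `end_s`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param params A [motion_params()]; its seed is taken from `seed`.
#' @param classes Classes to train on (default: all eight).
#' @param windows_per_class Training windows per class (default 60).
#' @param hidden_size,epochs LSTM hyperparameters (defaults 48, 12 — sized
#'   for CPU runs).
#' @param learning_rate_a,learning_rate_b Initial Adam learning rates per
#'   branch (default 2e-3, suited to the synthetic training scale).
#' @param confidence_floor Void threshold on fused scores (default 0.5).
#' @param config A [rule_config()].
#' @param iou_thresholds Temporal IoU thresholds for the mAP grid.
#' @param seed Master seed.
#' @return List with `scenario`, `model`, `timeline`, `tubes`, `counts`,
#'   `alerts`, `graph`, `map`, `report`.
#' @export
run_pipeline <- function(script, out_dir = NULL, params = motion_params(),
                         classes = action_classes(), windows_per_class = 60,
                         hidden_size = 48, epochs = 12,
                         learning_rate_a = 2e-3, learning_rate_b = 2e-3,
                         confidence_floor = 0.5, config = rule_config(),
                         iou_thresholds = seq(0.1, 1, by = 0.1), seed = 0) {
  params$seed <- as.integer(seed)
  image_width <- params$image_size[1]

  scenario <- generate_scenario(script, params, config = config)
  train_params <- params
  train_params$seed <- params$seed + 1000L
  train <- make_training_set(classes, windows_per_class, train_params)
  model <- fit_action_recognizer(train, classes = classes,
                                 hidden_size = hidden_size, epochs = epochs,
                                 learning_rate_a = learning_rate_a,
                                 learning_rate_b = learning_rate_b,
                                 confidence_floor = confidence_floor,
                                 seed = seed)
  timeline <- predict(model, scenario$sequence, image_width)
  tubes <- build_tubes(timeline, config$max_gap_s, params$fps)
  counts <- count_actions(tubes, classes)
  alerts <- detect_crisis(tubes, config)
  graph <- action_graph_data(tubes, scenario$gt_tubes, classes)
  map <- map_table(tubes, scenario$gt_tubes, iou_thresholds, classes)
  gt_frames <- expand_tubes(scenario$gt_tubes, timeline$frame)
  report <- classification_report(timeline$label, gt_frames$label, classes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pose_stream(scenario$sequence$frames,
                      file.path(out_dir, "pose_stream.jsonl"))
    write_tubes(scenario$gt_tubes, file.path(out_dir, "gt_tubes.json"))
    write_alerts(scenario$gt_alerts, file.path(out_dir, "gt_alerts.json"))
    write_timeline(timeline, file.path(out_dir, "timeline.csv"))
    write_tubes(tubes, file.path(out_dir, "tubes.json"))
    write_alerts(alerts, file.path(out_dir, "alerts.json"))
    utils::write.csv(graph, file.path(out_dir, "action_graph.csv"),
                     row.names = FALSE)
    ap_df <- data.frame(iou = rownames(map$ap), round(map$ap, 2),
                        mAP = round(map$map, 2), check.names = FALSE)
    utils::write.csv(ap_df, file.path(out_dir, "map_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(counts), accuracy = report$accuracy,
           macro = as.list(report$macro)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = 6)
  }
  list(scenario = scenario, model = model, timeline = timeline,
       tubes = tubes, counts = counts, alerts = alerts, graph = graph,
       map = map, report = report)
}
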