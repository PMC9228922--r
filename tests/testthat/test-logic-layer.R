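test_that("tube building matches the run-length oracle with void bridging", {
  # at 1 fps with a 1 s gap allowance: [A,A,void,A,B,B] -> (A,0-3), (B,4-5)
  tl <- label_timeline(c("A", "A", "void", "A", "B", "B"))
  tubes <- build_tubes(tl, max_gap_s = 1, fps = 1)
  expect_equal(tubes$label, c("A", "B"))
  expect_equal(tubes$start_s, c(0, 4))
  expect_equal(tubes$end_s, c(3, 5))

  # no bridging at max_gap 0
  tubes0 <- build_tubes(label_timeline(c("A", "void", "A")),
                        max_gap_s = 0, fps = 1)
  expect_equal(nrow(tubes0), 2)

  # all void -> nothing; empty timeline -> nothing
  expect_equal(nrow(build_tubes(label_timeline(rep("void", 5)))), 0)
  expect_equal(nrow(build_tubes(label_timeline(character(0)))), 0)

  # tube score is the mean confidence of the contributing non-void frames
  tl2 <- label_timeline(c("A", "void", "A"), confidence = c(0.8, 0.1, 0.6))
  t2 <- build_tubes(tl2, max_gap_s = 1, fps = 1)
  expect_equal(t2$score, 0.7)

  # property: random timelines against the independent oracle
  set.seed(31)
  for (rep in 1:25) {
    labs <- sample(c("Walk", "Sit", "void"), 40, replace = TRUE)
    gap <- sample(c(0, 1, 2), 1)
    got <- build_tubes(label_timeline(labs), max_gap_s = gap, fps = 1)
    want <- oracle_tubes(labs, fps = 1, max_gap_s = gap)
    expect_equal(got$label, want$label)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("max_gap = 0 tubes re-expand to exactly the non-void timeline and
           tube count is monotone in max_gap", {
  set.seed(32)
  for (rep in 1:15) {
    labs <- sample(c("Walk", "Sit", "Stand", "void"), 60, replace = TRUE)
    tl <- label_timeline(labs)
    tubes <- build_tubes(tl, max_gap_s = 0, fps = 1)
    back <- expand_tubes(tubes, tl$frame)
    expect_equal(back$label, labs)
    counts <- vapply(c(0, 1, 3, 10), function(g)
      nrow(build_tubes(tl, max_gap_s = g, fps = 1)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("action counts count each tube once over all classes", {
  tubes <- rbind(tube_row("Walk", 0, 5), tube_row("Walk", 10, 15),
                 tube_row("Sit", 20, 30))
  counts <- count_actions(tubes)
  expect_equal(counts[["Walk"]], 2L)
  expect_equal(counts[["Sit"]], 1L)
  expect_equal(sum(counts), nrow(tubes))
  expect_length(counts, 8)
  expect_equal(sum(count_actions(tubes[0, ])), 0L)
})

test_that("unit crisis actions raise alerts with the expected wording", {
  tubes <- rbind(tube_row("Crouch", 123.37, 125.0),
                 tube_row("Walk", 0, 10))
  alerts <- detect_unit_crisis(tubes)
  expect_equal(nrow(alerts), 1)
  expect_equal(alerts$description, "'Crouch' at timepoint 123.37 s")
  expect_equal(alerts$kind, "unit_action")

  expect_equal(nrow(detect_unit_crisis(rbind(tube_row("Walk", 0, 5),
                                             tube_row("Stand", 5, 9)))), 0)
  two <- detect_unit_crisis(rbind(tube_row("Crouch", 1, 2),
                                  tube_row("Crouch", 5, 6)))
  expect_equal(nrow(two), 2)
})

test_that("long-duration alerts merge Lean/Stand and respect the threshold", {
  # a Lean/Stand span of 18.37-123.37 s: alert of exactly 105.00 s
  tubes <- rbind(tube_row("Lean", 18.37, 60.0), tube_row("Stand", 60.5, 90.0),
                 tube_row("Lean", 90.2, 123.37))
  alerts <- detect_long_duration(tubes, threshold_s = 100)
  expect_equal(nrow(alerts), 1)
  expect_equal(alerts$end_s - alerts$start_s, 105.00, tolerance = 1e-9)
  expect_match(alerts$description, "105\\.00 s from 18\\.37 to 123\\.37 s")

  # Sit span 130.87-247.20 s: 116.33 s
  sit <- detect_long_duration(tube_row("Sit", 130.87, 247.20),
                              threshold_s = 100)
  expect_equal(sit$end_s - sit$start_s, 116.33, tolerance = 1e-9)
  expect_equal(sit$label, "Sit")

  # boundary: a 99 s span does not exceed a 100 s threshold
  expect_equal(nrow(detect_long_duration(tube_row("Lean", 1, 100),
                                         threshold_s = 100)), 0)
  # gaps wider than max_gap_s split the span
  split <- rbind(tube_row("Stand", 0, 60), tube_row("Stand", 70, 130))
  expect_equal(nrow(detect_long_duration(split, threshold_s = 100,
                                         max_gap_s = 1)), 0)
})

test_that("the repetitive rule needs recurring mixed kinds including Sit or
           Walk and never fires on Stand/Lean alternation", {
  cfg <- rule_config(repetition_period_s = 300)
  # genuinely repetitive: Walk and Sit twice each plus a third kind twice
  rep_tubes <- rbind(tube_row("Walk", 0, 10), tube_row("Sit", 15, 25),
                     tube_row("Walk", 30, 40), tube_row("Sit", 45, 55),
                     tube_row("Photo", 60, 65), tube_row("Photo", 70, 75))
  expect_equal(nrow(detect_repetitive(rep_tubes, cfg)), 1)

  # three kinds present but only two recur: silent at the default config
  mixed <- rbind(tube_row("Walk", 0, 10), tube_row("Sit", 15, 25),
                 tube_row("Walk", 30, 40), tube_row("Sit", 45, 55),
                 tube_row("Stand", 60, 75))
  expect_equal(nrow(detect_repetitive(mixed, cfg)), 0)
  # ... but alerts when a single occurrence per kind suffices
  cfg1 <- rule_config(min_occurrences_per_kind = 1)
  a1 <- detect_repetitive(mixed, cfg1)
  expect_equal(nrow(a1), 1)
  expect_match(a1$label, "Walk")

  # Stand/Lean alternation is one merged kind: never an alert
  shift <- rbind(tube_row("Stand", 0, 10), tube_row("Lean", 10.5, 20),
                 tube_row("Stand", 20.5, 30), tube_row("Lean", 30.5, 40))
  expect_equal(nrow(detect_repetitive(shift, cfg)), 0)
  expect_equal(nrow(detect_repetitive(shift, cfg1)), 0)

  # a single long Sit tube is not repetitive
  expect_equal(nrow(detect_repetitive(tube_row("Sit", 0, 200), cfg)), 0)
  # events outside the sliding window do not combine
  sparse <- rbind(tube_row("Walk", 0, 10), tube_row("Sit", 400, 410),
                  tube_row("Walk", 800, 810), tube_row("Sit", 1200, 1210),
                  tube_row("Photo", 1600, 1610), tube_row("Photo", 2000, 2010))
  expect_equal(nrow(detect_repetitive(sparse, cfg)), 0)
})

test_that("detect_crisis is a deterministic combination of the three rules", {
  tubes <- rbind(tube_row("Crouch", 123.37, 125),
                 tube_row("Lean", 18.37, 123.37),
                 tube_row("Sit", 130.87, 247.20))
  a1 <- detect_crisis(tubes)
  a2 <- detect_crisis(tubes)
  expect_identical(a1, a2)
  expect_setequal(a1$kind, c("unit_action", "long_duration"))
  expect_equal(sum(a1$kind == "long_duration"), 2)
})

test_that("action-graph data covers all classes and inverts to its tubes", {
  tubes <- rbind(tube_row("Walk", 0, 5), tube_row("Crouch", 6, 8))
  g <- action_graph_data(tubes, gt_tubes = tube_row("Walk", 0, 5))
  expect_equal(levels(g$class), action_classes())
  expect_equal(sum(g$source == "pred"), 2)
  expect_equal(sum(g$source == "gt"), 1)

  empty <- action_graph_data(tubes[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(levels(empty$class), action_classes())

  # graph segments reconstruct their frames exactly when built at gap 0
  labs <- c(rep("Walk", 6), rep("void", 2), rep("Crouch", 4))
  tl <- label_timeline(labs)
  tb <- build_tubes(tl, max_gap_s = 0, fps = 1)
  expect_equal(expand_tubes(tb, tl$frame)$label, labs)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot_action_graph(g))
})
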