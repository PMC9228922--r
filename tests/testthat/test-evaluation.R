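frame_tube <- function(start_frame, end_frame, label = "Walk", score = 0.9) {
  data.frame(track_id = "1", label = label,
             start_frame = start_frame, end_frame = end_frame,
             start_s = start_frame / 30, end_s = end_frame / 30,
             score = score, stringsAsFactors = FALSE)
}

test_that("temporal IoU uses closed-interval frame counts", {
  a <- frame_tube(0, 10)
  expect_equal(temporal_iou(a, a), 1)
  expect_equal(temporal_iou(a, frame_tube(20, 30)), 0)
  # [0,10] vs [5,15]: 6 shared frames of 16 in the union
  expect_equal(temporal_iou(a, frame_tube(5, 15)), 6 / 16)
  # symmetry
  set.seed(41)
  for (rep in 1:10) {
    x <- frame_tube(sample(0:50, 1), sample(51:100, 1))
    y <- frame_tube(sample(0:50, 1), sample(51:100, 1))
    expect_equal(temporal_iou(x, y), temporal_iou(y, x))
    expect_gte(temporal_iou(x, y), 0)
    expect_lte(temporal_iou(x, y), 1)
  }
})

test_that("class AP reproduces hand-worked precision-recall cases", {
  gt <- frame_tube(0, 29)
  # perfect single match
  expect_equal(class_ap(frame_tube(0, 29), gt, 0.5), 1)
  # no ground truth but predictions -> 0
  expect_equal(class_ap(frame_tube(0, 29), gt[0, ], 0.5), 0)
  # two predictions: higher-scored hits, lower-scored misses;
  # recall 1 is reached while precision is still 1 -> AP 1
  preds <- rbind(frame_tube(0, 29, score = 0.9),
                 frame_tube(100, 129, score = 0.8))
  expect_equal(class_ap(preds, gt, 0.5), 1)
  # reversed scores: the miss comes first; precision at recall 1 is 1/2
  preds2 <- rbind(frame_tube(100, 129, score = 0.9),
                  frame_tube(0, 29, score = 0.8))
  expect_equal(class_ap(preds2, gt, 0.5), 0.5)
  # one-to-one matching: a second hit on the same gt is a false positive
  dup <- rbind(frame_tube(0, 29, score = 0.9),
               frame_tube(0, 29, score = 0.8))
  expect_equal(class_ap(dup, gt, 0.5), 1)
})

test_that("class AP equals an exhaustive-matching oracle on small instances", {
  # independent oracle: same sorted-by-score sweep but with matching done by
  # exhaustive search over all one-to-one assignments per prefix
  oracle_ap <- function(pred, gt, thr) {
    n_gt <- nrow(gt)
    if (n_gt == 0 || nrow(pred) == 0) return(0)
    pred <- pred[order(-pred$score), , drop = FALSE]
    iou <- outer(seq_len(nrow(pred)), seq_len(n_gt),
                 Vectorize(function(i, j) temporal_iou(pred[i, ], gt[j, ])))
    max_tp <- function(k) {
      # maximum matching among the first k predictions (brute force)
      best <- 0
      perms <- function(av, i, used, tp) {
        if (i > k) { best <<- max(best, tp); return(invisible()) }
        perms(av, i + 1, used, tp)
        for (j in av) if (!used[j] && iou[i, j] >= thr) {
          used[j] <- TRUE
          perms(av, i + 1, used, tp + 1)
          used[j] <- FALSE
        }
      }
      perms(seq_len(n_gt), 1, rep(FALSE, n_gt), 0)
      best
    }
    tps <- vapply(seq_len(nrow(pred)), max_tp, numeric(1))
    recall <- tps / n_gt
    precision <- tps / seq_len(nrow(pred))
    p_int <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * p_int)
  }
  set.seed(42)
  for (rep in 1:25) {
    # gt tubes far apart so each prediction overlaps at most one gt (the
    # greedy and exhaustive matchings then agree and validate the sweep)
    n_gt <- sample(1:4, 1)
    gt <- do.call(rbind, lapply(seq_len(n_gt), function(j)
      frame_tube(1000 * j, 1000 * j + sample(20:80, 1))))
    n_p <- sample(1:4, 1)
    pred <- do.call(rbind, lapply(seq_len(n_p), function(i) {
      j <- sample(n_gt, 1)
      frame_tube(1000 * j + sample(-40:40, 1),
                 1000 * j + sample(10:120, 1),
                 score = stats::runif(1))
    }))
    for (thr in c(0.3, 0.5, 0.7))
      expect_equal(class_ap(pred, gt, thr), oracle_ap(pred, gt, thr),
                   tolerance = 1e-12)
  }
})

test_that("the AP grid is monotone in the IoU threshold with exact-match
           behaviour at threshold 1", {
  gt <- rbind(frame_tube(0, 29), frame_tube(100, 129, "Sit"))
  pred <- rbind(frame_tube(0, 29, score = 0.9),
                frame_tube(101, 129, "Sit", score = 0.8))
  m <- map_table(pred, gt)
  expect_equal(dim(m$ap), c(10L, 8L))
  # perfect Walk prediction: 100 everywhere including threshold 1.0
  expect_equal(unname(m$ap[, "Walk"]), rep(100, 10))
  # near-miss Sit prediction: 100 until its IoU (29/30), 0 at threshold 1.0
  expect_equal(m$ap["1.0", "Sit"], 0)
  expect_equal(m$ap["0.9", "Sit"], 100)
  # monotone non-increasing per class on random instances
  set.seed(43)
  for (rep in 1:10) {
    gt_r <- do.call(rbind, lapply(1:3, function(j)
      frame_tube(200 * j, 200 * j + sample(20:100, 1))))
    pr_r <- do.call(rbind, lapply(1:4, function(i)
      frame_tube(sample(0:700, 1), sample(701:900, 1),
                 score = stats::runif(1))))
    ap <- map_table(pr_r, gt_r)$ap
    for (cl in colnames(ap)) expect_true(all(diff(ap[, cl]) <= 1e-9))
  }
  # empty predictions -> all zeros
  expect_true(all(map_table(pred[0, ], gt)$ap == 0))
  expect_equal(m$map, rowMeans(m$ap))
})

test_that("the classification report follows the standard definitions", {
  classes <- c("Walk", "Sit")
  perfect <- classification_report(c("Walk", "Sit", "Walk"),
                                   c("Walk", "Sit", "Walk"), classes)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  # contingency with TP=3, FP=1, FN=1 for Walk
  gt <- c(rep("Walk", 4), rep("Sit", 4))
  pred <- c("Walk", "Walk", "Walk", "Sit", "Walk", "Sit", "Sit", "Sit")
  rep_ <- classification_report(pred, gt, classes)
  walk <- rep_$per_class[rep_$per_class$class == "Walk", ]
  expect_equal(walk$precision, 0.75)
  expect_equal(walk$recall, 0.75)
  expect_equal(walk$support, 4)
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / 8)
  # void predictions count against recall but not precision
  repv <- classification_report(c("void", "Walk"), c("Walk", "Walk"), classes)
  expect_equal(repv$per_class$recall[1], 0.5)
  expect_equal(repv$per_class$precision[1], 1)
})

test_that("crisis metrics reproduce the clip-level confusion arithmetic", {
  alert <- function(kind = "unit_action", label = "Crouch", t = 10)
    data.frame(track_id = "1", kind = kind, label = label, start_s = t,
               end_s = t + 2, description = "", stringsAsFactors = FALSE)
  none <- alert()[0, ]
  # 5 crisis / 10 normal clips; detector fires on 4 crisis and 1 normal
  gt <- c(lapply(1:5, function(i) alert(t = 10 * i)),
          rep(list(none), 10))
  pred <- c(lapply(1:4, function(i) alert(t = 10 * i + 1)), list(none),
            list(alert(t = 3)), rep(list(none), 9))
  m <- crisis_metrics(pred, gt)
  expect_equal(m$video[c("TP", "FP", "TN", "FN")],
               list(TP = 4L, FP = 1L, TN = 9L, FN = 1L))
  expect_equal(m$video$accuracy, 13 / 15)
  expect_equal(m$video$recall, 0.8)
  # behaviour level: 4 of 5 behaviours matched within tolerance
  expect_equal(m$behaviour$total_behaviours, 5)
  expect_equal(m$behaviour$correct, 4)
  expect_equal(m$behaviour$missed, 1)
  expect_equal(m$behaviour$false, 1)

  # no alerts anywhere
  m0 <- crisis_metrics(rep(list(none), 15), gt)
  expect_equal(m0$video$TP, 0L)
  expect_equal(m0$video$TN, 10L)

  # matching respects kind, label and the time tolerance
  mk <- crisis_metrics(list(alert(label = "Place", t = 10)),
                       list(alert(label = "Crouch", t = 10)))
  expect_equal(mk$behaviour$correct, 0)
  mt <- crisis_metrics(list(alert(t = 30)), list(alert(t = 10)))
  expect_equal(mt$behaviour$correct, 0)
})
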