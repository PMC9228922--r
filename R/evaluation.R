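# Evaluation: temporal action detection (AP/mAP over IoU thresholds),
# frame-wise classification metrics, and clip-level crisis identification.

#' Temporal IoU of two action tubes
#'
#' Tubes are closed frame intervals; the IoU is the ratio of intersecting to
#' union frame counts (`end - start + 1` arithmetic).
#'
#' @param a,b Tube rows (or lists) with `start_frame` and `end_frame`.
#' @return IoU in \code{[0, 1]}.
#' @export
temporal_iou <- function(a, b) {
  inter <- min(a$end_frame, b$end_frame) - max(a$start_frame, b$start_frame) + 1
  if (inter <= 0) return(0)
  union <- (a$end_frame - a$start_frame + 1) + (b$end_frame - b$start_frame + 1) -
    inter
  inter / union
}

#' Average precision for one action class
#'
#' Predictions are sorted by score (descending) and matched greedily,
#' one-to-one, to the unmatched ground-truth tube of highest IoU, a match
#' requiring IoU at or above the threshold. AP is the area under the
#' all-points interpolated precision-recall curve.
#'
#' @param pred Predicted tubes of one class (needs `start_frame`,
#'   `end_frame`, `score`).
#' @param gt Ground-truth tubes of the same class.
#' @param iou_threshold Temporal IoU threshold in (0, 1].
#' @return AP in \code{[0, 1]}; 0 when there is no ground truth.
#' @export
class_ap <- function(pred, gt, iou_threshold) {
  n_gt <- nrow(gt)
  if (n_gt == 0 || nrow(pred) == 0) return(0)
  pred <- pred[order(-pred$score), , drop = FALSE]
  matched <- rep(FALSE, n_gt)
  tp <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    ious <- vapply(seq_len(n_gt), function(j)
      temporal_iou(pred[i, ], gt[j, ]), numeric(1))
    ious[matched] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      matched[j] <- TRUE
      tp[i] <- 1
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # all-points interpolation: running maximum of precision from the right
  p_interp <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * p_interp)
}

#' Per-class AP grid and mAP over IoU thresholds
#'
#' Computes class-wise average precision at each temporal IoU threshold and
#' the unweighted class mean (mAP) per threshold.
#'
#' @param pred Predicted tubes (all classes) with `label`, `start_frame`,
#'   `end_frame`, `score`.
#' @param gt Ground-truth tubes with `label`, `start_frame`, `end_frame`.
#' @param thresholds IoU thresholds (default 0.1 to 1.0 in steps of 0.1).
#' @param classes Class set (default [action_classes()]).
#' @return List with `ap` (thresholds x classes matrix, percent) and `map`
#'   (named vector, percent).
#' @export
map_table <- function(pred, gt, thresholds = seq(0.1, 1, by = 0.1),
                      classes = action_classes()) {
  ap <- matrix(0, length(thresholds), length(classes),
               dimnames = list(sprintf("%.1f", thresholds), classes))
  for (cl in classes) {
    p <- pred[pred$label == cl, , drop = FALSE]
    g <- gt[gt$label == cl, , drop = FALSE]
    for (k in seq_along(thresholds))
      ap[k, cl] <- 100 * class_ap(p, g, thresholds[k])
  }
  list(ap = ap, map = rowMeans(ap))
}

#' Frame-wise classification report
#'
#' Standard per-class precision, recall, F1 and support over aligned
#' frame-wise label vectors, plus the full confusion matrix, overall
#' accuracy and macro averages. All configured classes are always reported.
#'
#' @param pred,gt Aligned character vectors of frame labels.
#' @param classes Class set (default [action_classes()]).
#' @return List with `per_class` (data frame), `confusion` (gt rows x
#'   pred columns), `accuracy`, `macro` (precision/recall/f1).
#' @export
classification_report <- function(pred, gt, classes = action_classes()) {
  stopifnot(length(pred) == length(gt))
  levels_all <- union(classes, c("void"))
  cm <- table(gt = factor(gt, levels = levels_all),
              pred = factor(pred, levels = levels_all))
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = sum(cm[cl, ]), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(
    per_class = per,
    confusion = cm,
    accuracy = sum(diag(cm)) / max(sum(cm), 1),
    macro = c(precision = mean(per$precision), recall = mean(per$recall),
              f1 = mean(per$f1))
  )
}

#' Clip-level and behaviour-level crisis identification metrics
#'
#' Video level: a clip is predicted as a crisis clip when it produced at
#' least one alert; TP/FP/TN/FN are counted against the per-clip ground
#' truth together with accuracy, precision and recall. Behaviour level: each
#' ground-truth crisis behaviour is matched to at most one predicted alert
#' of the same kind (and label, for unit actions) whose start lies within
#' `tolerance_s` seconds; the table reports total behaviours, total
#' identifications, correct, false and missed.
#'
#' @param pred_alerts Named list: per clip, an alert data frame.
#' @param gt_alerts Named list: per clip, the ground-truth alert data frame
#'   (empty for normal clips).
#' @param tolerance_s Behaviour-matching time tolerance (default 5 s).
#' @return List with `video` (TP, FP, TN, FN, accuracy, precision, recall)
#'   and `behaviour` (total_behaviours, total_identified, correct, false,
#'   missed, precision, recall).
#' @export
crisis_metrics <- function(pred_alerts, gt_alerts, tolerance_s = 5) {
  stopifnot(length(pred_alerts) == length(gt_alerts))
  n <- length(pred_alerts)
  pred_pos <- vapply(pred_alerts, function(a) nrow(a) > 0, logical(1))
  gt_pos <- vapply(gt_alerts, function(a) nrow(a) > 0, logical(1))
  tp <- sum(pred_pos & gt_pos); fp <- sum(pred_pos & !gt_pos)
  tn <- sum(!pred_pos & !gt_pos); fn <- sum(!pred_pos & gt_pos)

  total_beh <- 0L; correct <- 0L; total_ident <- 0L
  for (i in seq_len(n)) {
    gt <- gt_alerts[[i]]; pr <- pred_alerts[[i]]
    total_beh <- total_beh + nrow(gt)
    total_ident <- total_ident + nrow(pr)
    if (nrow(gt) == 0 || nrow(pr) == 0) next
    used <- rep(FALSE, nrow(pr))
    for (j in seq_len(nrow(gt))) {
      cand <- which(!used & pr$kind == gt$kind[j] &
                      (gt$kind[j] != "unit_action" | pr$label == gt$label[j]) &
                      abs(pr$start_s - gt$start_s[j]) <= tolerance_s)
      if (length(cand) > 0) {
        k <- cand[which.min(abs(pr$start_s[cand] - gt$start_s[j]))]
        used[k] <- TRUE
        correct <- correct + 1L
      }
    }
  }
  list(
    video = list(TP = tp, FP = fp, TN = tn, FN = fn,
                 accuracy = (tp + tn) / max(n, 1),
                 precision = if (tp + fp > 0) tp / (tp + fp) else 0,
                 recall = if (tp + fn > 0) tp / (tp + fn) else 0),
    behaviour = list(total_behaviours = total_beh,
                     total_identified = total_ident,
                     correct = correct,
                     false = total_ident - correct,
                     missed = total_beh - correct,
                     precision = if (total_ident > 0)
                       correct / total_ident else 0,
                     recall = if (total_beh > 0) correct / total_beh else 0)
  )
}
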