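# The two-branch action recognizer: branch A consumes 96-dim static+motion
# windows, branch B 62-dim geometric windows; class scores are combined by
# element-wise multiplication followed by softmax, unless the branches'
# validation accuracies differ by more than a threshold, in which case
# branch A is used alone.

#' Fuse two class-score vectors
#'
#' Element-wise product of the two probability vectors followed by softmax.
#' Fusion is symmetric, maps (uniform, uniform) to uniform, and fusing with
#' a uniform vector preserves the argmax of the other operand.
#'
#' @param p_a,p_b Probability vectors (or matrices with one row per window)
#'   of equal length/width.
#' @return Fused probability vector/matrix; rows sum to 1.
#' @export
fuse_scores <- function(p_a, p_b) {
  if (is.null(dim(p_a))) {
    if (length(p_a) != length(p_b)) stop("score vectors differ in length")
    return(as.vector(softmax_rows(matrix(p_a * p_b, nrow = 1))))
  }
  if (!all(dim(p_a) == dim(p_b))) stop("score matrices differ in shape")
  softmax_rows(p_a * p_b)
}

#' Choose between fused scores and branch A alone
#'
#' When branch A's validation accuracy exceeds branch B's by more than
#' `threshold_pct` percentage points, fusing drags the result below branch A
#' alone, so branch A alone is used; otherwise the scores are fused.
#'
#' @param val_acc_a,val_acc_b Branch validation accuracies in percent.
#' @param threshold_pct Accuracy-gap threshold in percentage points
#'   (default 20).
#' @return A `fusion_policy` list with `mode` ("fuse" or "branch_a_only"),
#'   the accuracy gap and the threshold.
#' @export
select_fusion_policy <- function(val_acc_a, val_acc_b, threshold_pct = 20) {
  stopifnot(val_acc_a >= 0, val_acc_a <= 100, val_acc_b >= 0,
            val_acc_b <= 100, threshold_pct >= 0)
  gap <- val_acc_a - val_acc_b
  structure(list(
    mode = if (gap > threshold_pct) "branch_a_only" else "fuse",
    acc_gap_pct = gap, acc_gap_threshold_pct = threshold_pct
  ), class = "fusion_policy")
}

apply_policy <- function(policy, p_a, p_b) {
  if (policy$mode == "branch_a_only") p_a else fuse_scores(p_a, p_b)
}

#' Fit the two-branch action recognizer
#'
#' Trains branch A on the 96-dimensional static+motion windows and branch B
#' on the 62-dimensional geometric windows (each a stacked-LSTM network, see
#' [train_branch()]), then selects the fusion policy from the two branches'
#' validation accuracies.
#'
#' @param windows A labelled window set as produced by
#'   [make_training_set()]: list with `branch_a` (n x 30 x 96 array),
#'   `branch_b` (n x 30 x 62 array) and `labels`.
#' @param classes Class ordering (default [action_classes()] restricted to
#'   the labels present).
#' @param hidden_size,dropout_rate,epochs,batch_size,lr_halving_period_epochs
#'   Shared branch hyperparameters (see [branch_config()]).
#' @param learning_rate_a,learning_rate_b Initial learning rates per branch.
#' @param acc_gap_threshold_pct Accuracy-gap threshold for
#'   [select_fusion_policy()] (default 20).
#' @param confidence_floor Fused probabilities below this floor yield a
#'   `void` frame label at prediction time (default 0.5).
#' @param seed Integer seed for both branches.
#' @return An object of class `action_recognizer`.
#' @export
fit_action_recognizer <- function(windows, classes = NULL,
                                  hidden_size = 128, dropout_rate = 0.5,
                                  epochs = 30, batch_size = 32,
                                  lr_halving_period_epochs = 30,
                                  learning_rate_a = 1e-3,
                                  learning_rate_b = 1e-3,
                                  acc_gap_threshold_pct = 20,
                                  confidence_floor = 0.5, seed = 1) {
  labels <- as.character(windows$labels)
  if (is.null(classes)) {
    known <- action_classes()
    classes <- c(intersect(known, unique(labels)),
                 sort(setdiff(unique(labels), known)))
  }
  cfg_a <- branch_config(96, length(classes), hidden_size = hidden_size,
                         dropout_rate = dropout_rate,
                         learning_rate_init = learning_rate_a,
                         lr_halving_period_epochs = lr_halving_period_epochs,
                         epochs = epochs, batch_size = batch_size, seed = seed)
  cfg_b <- branch_config(62, length(classes), hidden_size = hidden_size,
                         dropout_rate = dropout_rate,
                         learning_rate_init = learning_rate_b,
                         lr_halving_period_epochs = lr_halving_period_epochs,
                         epochs = epochs, batch_size = batch_size, seed = seed)
  branch_a <- train_branch(windows$branch_a, labels, cfg_a, classes = classes)
  branch_b <- train_branch(windows$branch_b, labels, cfg_b, classes = classes)
  policy <- select_fusion_policy(branch_a$val_accuracy, branch_b$val_accuracy,
                                 acc_gap_threshold_pct)
  structure(list(
    branch_a = branch_a, branch_b = branch_b, policy = policy,
    classes = classes, confidence_floor = confidence_floor, seed = seed
  ), class = "action_recognizer")
}

#' Fused window scores from a fitted recognizer
#'
#' @param model An `action_recognizer`.
#' @param branch_a,branch_b Window arrays (n x 30 x 96 and n x 30 x 62).
#' @return Matrix of policy-combined class probabilities (n x classes).
#' @export
score_windows <- function(model, branch_a, branch_b) {
  p_a <- predict(model$branch_a, branch_a)
  p_b <- predict(model$branch_b, branch_b)
  p <- apply_policy(model$policy, p_a, p_b)
  colnames(p) <- model$classes
  p
}

# Probability-scale confidences for the void decision. Softmax over a
# product of probabilities preserves the argmax but compresses the maximum
# towards uniform (it can never exceed e / (e + C - 1)), so the confidence
# compared against the floor is the renormalised product - the posterior
# under a branch-independence reading - rather than the softmaxed score.
confidence_scores <- function(model, branch_a, branch_b) {
  p_a <- predict(model$branch_a, branch_a)
  if (model$policy$mode == "branch_a_only") return(p_a)
  p_b <- predict(model$branch_b, branch_b)
  q <- p_a * p_b
  q / rowSums(q)
}

#' Frame-wise action prediction for a pose sequence
#'
#' Labels every frame of a tracked pose sequence by treating it as the
#' mid-key frame of a 30-frame window (14 before, 15 after, edge frames
#' repeated at the boundaries), scoring both branches and combining them
#' under the fitted fusion policy. Frames whose best combined probability
#' (the renormalised branch-score product, or branch A's probability when
#' the policy disables fusion) falls below the confidence floor are
#' labelled `void`.
#'
#' @param object A fitted `action_recognizer`.
#' @param seq A `pose_sequence` (see [split_by_track()]).
#' @param image_width Image width in pixels.
#' @param confidence_floor Overrides the model's floor if given.
#' @param ... Unused.
#' @return A label timeline: data frame with columns `frame`, `track_id`,
#'   `label` (class or "void") and `confidence` (best fused probability).
#' @export
predict.action_recognizer <- function(object, seq, image_width,
                                      confidence_floor = NULL, ...) {
  if (!object$branch_a$trained) stop("recognizer is not trained")
  floor_p <- if (is.null(confidence_floor)) object$confidence_floor
             else confidence_floor
  wins <- sequence_windows(seq, image_width)
  n <- length(wins)
  Xa <- array(0, c(n, 30, 96))
  Xb <- array(0, c(n, 30, 62))
  for (i in seq_len(n)) {
    Xa[i, , ] <- wins[[i]]$branch_a
    Xb[i, , ] <- wins[[i]]$branch_b
  }
  conf_p <- confidence_scores(object, Xa, Xb)
  conf <- apply(conf_p, 1, max)
  lab <- object$classes[max.col(conf_p, ties.method = "first")]
  lab[conf < floor_p] <- "void"
  data.frame(
    frame = vapply(seq$frames, function(f) f$frame_index, integer(1)),
    track_id = rep(as.character(seq$track_id), n),
    label = lab, confidence = conf, stringsAsFactors = FALSE
  )
}

#' @export
print.action_recognizer <- function(x, ...) {
  cat("Two-branch skeleton action recognizer\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  branch A (static+motion, 96-d): validation accuracy %.2f%%\n",
              x$branch_a$val_accuracy))
  cat(sprintf("  branch B (geometric, 62-d):     validation accuracy %.2f%%\n",
              x$branch_b$val_accuracy))
  cat(sprintf("  fusion policy: %s (gap %.2f, threshold %.0f)\n",
              x$policy$mode, x$policy$acc_gap_pct,
              x$policy$acc_gap_threshold_pct))
  cat(sprintf("  confidence floor: %.2f\n", x$confidence_floor))
  invisible(x)
}

#' @export
summary.action_recognizer <- function(object, ...) {
  out <- list(
    classes = object$classes,
    val_accuracy = c(branch_a = object$branch_a$val_accuracy,
                     branch_b = object$branch_b$val_accuracy),
    policy = object$policy,
    history_a = object$branch_a$history,
    history_b = object$branch_b$history
  )
  class(out) <- "summary.action_recognizer"
  out
}

#' @export
print.summary.action_recognizer <- function(x, ...) {
  cat("Two-branch skeleton action recognizer\n\n")
  cat("Validation accuracy (%):\n")
  print(round(x$val_accuracy, 2))
  cat(sprintf("\nFusion policy: %s (accuracy gap %.2f points, threshold %.0f)\n",
              x$policy$mode, x$policy$acc_gap_pct,
              x$policy$acc_gap_threshold_pct))
  cat("\nBranch A training history (last 5 epochs):\n")
  print(utils::tail(x$history_a, 5), row.names = FALSE)
  cat("\nBranch B training history (last 5 epochs):\n")
  print(utils::tail(x$history_b, 5), row.names = FALSE)
  invisible(x)
}
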