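# Evaluation metrics, per-sequence prediction timelines and false-alert
# smoothing.

#' Multiclass classification metrics
#'
#' Computes the confusion matrix and, per class in a one-vs-rest view, the
#' true/false positive/negative counts, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and `F1 = 2PR / (P + R)`. Reported precision, recall and
#' F1 are macro averages across classes; accuracy is the fraction of correct
#' predictions (the multiclass reading of the binary
#' `(TP + TN) / (TP + TN + FP + FN)` formula). A class with no predicted
#' positives gets precision 0, and a class absent from the truth gets
#' recall 0, each with a warning.
#'
#' @param predicted,truth equal-length label vectors (character or factor)
#'   over a closed label set.
#' @param labels optional label set; defaults to the union of the factor
#'   levels (or observed values) of both vectors.
#' @return An object of class `metrics_report`: accuracy, macro_precision,
#'   macro_recall, macro_f1, a per-class data frame and the confusion count
#'   matrix (rows = truth, columns = predicted).
#' @export
compute_metrics <- function(predicted, truth, labels = NULL) {
  if (length(predicted) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(predicted), length(truth)), call. = FALSE)
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (is.null(labels))
    labels <- sort(unique(c(levels(factor(predicted)), levels(factor(truth)))))
  predicted <- as.character(predicted); truth <- as.character(truth)
  unknown <- setdiff(unique(c(predicted, truth)), labels)
  if (length(unknown))
    stop(sprintf("labels outside the closed label set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  predicted <- factor(predicted, levels = labels)
  truth <- factor(truth, levels = labels)
  conf <- table(truth = truth, predicted = predicted)
  n <- length(truth)
  per <- lapply(labels, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- n - tp - fp - fn
    if (tp + fn == 0L)
      warning(sprintf("class '%s' absent from the truth; its recall is set to 0", cl),
              call. = FALSE)
    if (tp + fp == 0L)
      warning(sprintf("class '%s' never predicted; its precision is set to 0", cl),
              call. = FALSE)
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = sum(diag(conf)) / n,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 per_class = per, confusion = unclass(conf), n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Predict a per-window timeline for a whole pose sequence
#'
#' Runs the full pipeline on one sequence — previous-frame-relative
#' conversion (skipped if the sequence is already relative), glitch clamping,
#' dense sliding windows, classifier forward pass — and returns one labeled
#' prediction per window, ordered by start frame. Because the pipeline works
#' on relative poses, the timeline is invariant to rigid transforms of the
#' absolute trajectory.
#'
#' @param model a trained `gait_model` (its `classes` field names the
#'   outputs).
#' @param seq a `pose_sequence` (absolute or relative).
#' @param t_max glitch-clamping threshold in meters.
#' @param stride window hop in frames (default 1, dense).
#' @return A data frame with `start_frame` (0-based), `label`, `max_prob`
#'   and one `prob_<class>` column per class.
#' @export
predict_sequence <- function(model, seq, t_max = 0.1, stride = 1L) {
  stopifnot(inherits(model, "gait_model"), inherits(seq, "pose_sequence"))
  if (seq$frame_kind == "absolute-to-initial") seq <- preprocess_sequence(seq)
  seq <- clamp_glitches(seq, t_max)
  wins <- suppressWarnings(window_sequence(seq, model$config$K, stride))
  if (!length(wins))
    stop(sprintf("sequence too short: %d frames but the model needs %d",
                 nrow(seq$poses), model$config$K), call. = FALSE)
  pr <- predict(model, wins, type = "prob")
  cls <- colnames(pr)
  out <- data.frame(start_frame = vapply(wins, attr, 0L, "start_frame"),
                    label = cls[max.col(pr, ties.method = "first")],
                    max_prob = apply(pr, 1L, max), stringsAsFactors = FALSE)
  colnames(pr) <- paste0("prob_", cls)
  cbind(out, as.data.frame(pr))
}

#' Smooth a prediction timeline and flag false alerts
#'
#' Isolated or low-confidence windows are common sources of false alerts in
#' per-frame monitoring. A window is flagged when its maximum class
#' probability falls below `p_threshold` or when it belongs to a run of
#' identical labels shorter than `min_run` windows. Flagged windows are
#' relabeled to the label of the nearest non-flagged run (ties broken toward
#' the earlier run). With `p_threshold = 0` and `min_run = 1` the timeline
#' is returned unchanged.
#'
#' @param timeline a data frame from [predict_sequence()] (needs `label` and
#'   `max_prob` columns).
#' @param p_threshold minimum acceptable prediction probability, in `[0, 1]`.
#' @param min_run minimum acceptable run length in windows (`>= 1`).
#' @return The timeline with smoothed `label`, the original labels in
#'   `raw_label`, and a logical `flagged` column.
#' @export
smooth_predictions <- function(timeline, p_threshold = 0.5, min_run = 1L) {
  if (!is.data.frame(timeline) || nrow(timeline) == 0L)
    stop("empty prediction timeline", call. = FALSE)
  if (!all(c("label", "max_prob") %in% names(timeline)))
    stop("timeline needs `label` and `max_prob` columns", call. = FALSE)
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold must be in [0, 1]", call. = FALSE)
  if (min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  lab <- as.character(timeline$label)
  one_pass <- function(lab) {
    runs <- rle(lab)
    run_id <- rep(seq_along(runs$lengths), runs$lengths)
    run_len <- runs$lengths[run_id]
    flagged <- timeline$max_prob < p_threshold | run_len < min_run
    new_lab <- lab
    if (any(flagged) && !all(flagged)) {
      ok_idx <- which(!flagged)
      for (i in which(flagged)) {
        d <- abs(ok_idx - i)
        # nearest non-flagged window; ties toward the earlier run
        new_lab[i] <- lab[ok_idx[which.min(d)]]
      }
    }
    list(label = new_lab, flagged = flagged)
  }
  first <- one_pass(lab)
  # relabeling can merge runs and change which windows are considered
  # isolated, so iterate to a fixed point (labels from a finite set; in
  # practice this converges in one or two passes)
  cur <- first$label
  for (k in seq_len(nrow(timeline))) {
    nxt <- one_pass(cur)$label
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  timeline$raw_label <- lab
  timeline$label <- cur
  timeline$flagged <- first$flagged
  timeline
}
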