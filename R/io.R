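# File formats, dataset manifests, configuration and the end-to-end
# pipeline.
#
# Pose files are plain CSV (columns frame, t_sec, tx, ty, tz, rx, ry, rz,
# rw; comma-separated, header required, '.' decimal separator) or JSONL (one
# pose object per line with the same fields), with a JSON sidecar
# `<path>.json` carrying subject_id, label, rate_hz and frame_kind.
# Frame indices are 0-based throughout.

FORMAT_VERSION <- "1"

#' Write a pose sequence to disk
#'
#' @param seq a `pose_sequence`.
#' @param path output path; extension `.jsonl` selects the JSONL layout,
#'   anything else CSV. A metadata sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- nrow(seq$poses)
  df <- data.frame(frame = seq_len(n) - 1L,
                   t_sec = (seq_len(n) - 1L) / seq$rate_hz)
  df <- cbind(df, as.data.frame(seq$poses))
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  meta <- list(format_version = FORMAT_VERSION, subject_id = seq$subject_id,
               label = seq$label, rate_hz = seq$rate_hz,
               frame_kind = seq$frame_kind)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a pose sequence from disk
#'
#' Validates the file as it is read: required columns must be present,
#' frame indices strictly increasing, all values finite, and quaternion
#' norms within `1e-3` of 1 (they are renormalized on the way in).
#' Frame kind and trial metadata come from the `<path>.json` sidecar when
#' present.
#'
#' @param path a CSV or JSONL pose file written by [write_pose_file()] (or
#'   any file in the documented schema).
#' @return A `pose_sequence`.
#' @export
read_pose_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L)
    stop(sprintf("empty pose file: %s", path), call. = FALSE)
  df <- if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop(sprintf("empty pose file: %s", path), call. = FALSE)
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l))))
  } else {
    read.csv(path)
  }
  if (nrow(df) == 0L) stop(sprintf("empty pose file: %s", path), call. = FALSE)
  need <- c("frame", POSE_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("pose file %s is missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (any(diff(df$frame) <= 0))
    stop(sprintf("non-monotone frame indices in %s (first at frame %d)",
                 path, df$frame[which(diff(df$frame) <= 0)[1] + 1L]),
         call. = FALSE)
  vals <- as.matrix(df[, POSE_COLS])
  if (!all(is.finite(vals))) {
    bad <- which(!apply(is.finite(vals), 1L, all))[1]
    stop(sprintf("non-finite pose value at frame %d of %s", df$frame[bad],
                 path), call. = FALSE)
  }
  qn <- sqrt(rowSums(vals[, 4:7, drop = FALSE]^2))
  bad <- which(abs(qn - 1) > 1e-3)
  if (length(bad))
    stop(sprintf("non-unit quaternion (norm %.4f) at frame %d of %s",
                 qn[bad[1]], df$frame[bad[1]], path), call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  pose_sequence(vals,
                rate_hz = meta$rate_hz %||% 30,
                subject_id = meta$subject_id %||% NA_character_,
                label = meta$label %||% NA_character_,
                frame_kind = meta$frame_kind %||% "absolute-to-initial")
}

#' Write a dataset (sequences + manifest) to a directory
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory; created if needed. Sequences are written as
#'   `<seq_id>.csv` plus sidecars, and the manifest as `manifest.json`.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$file <- paste0(man$seq_id, ".csv")
  for (i in seq_len(nrow(man)))
    write_pose_file(dataset$sequences[[man$seq_id[i]]],
                    file.path(dir, man$file[i]))
  obj <- list(format_version = FORMAT_VERSION, patterns = dataset$patterns,
              rate_hz = dataset$rate_hz, rng_seed = dataset$rng_seed,
              entries = man)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest and its sequences
#'
#' Validates the manifest: every referenced file must exist and parse, and
#' the train/val/test splits must be subject-disjoint.
#'
#' @param path a `manifest.json` written by [write_dataset()], or the
#'   directory containing it.
#' @return A `gait_dataset`.
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop(sprintf("no manifest at %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$entries
  need <- c("seq_id", "subject_id", "label", "split", "role", "file")
  if (!all(need %in% names(man)))
    stop("manifest entries are missing required fields", call. = FALSE)
  check_split_disjoint(man)
  dir <- dirname(path)
  sequences <- list()
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    sq <- read_pose_file(f)
    sq$subject_id <- man$subject_id[i]
    sq$label <- man$label[i]
    sequences[[man$seq_id[i]]] <- sq
  }
  structure(list(sequences = sequences,
                 manifest = man[, setdiff(names(man), "file")],
                 patterns = obj$patterns, rate_hz = obj$rate_hz,
                 rng_seed = obj$rng_seed),
            class = "gait_dataset")
}

check_split_disjoint <- function(man) {
  tab <- unique(man[, c("subject_id", "split")])
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stop(sprintf("subjects appear in more than one split: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read a YAML pipeline configuration
#'
#' A single YAML file with optional `model`, `train` and `simulate`
#' sections whose fields mirror [model_config()], [train_config()] and
#' [make_dataset()]. Missing fields keep the package defaults (which
#' themselves follow the reference recipe: K = 60, N = 30, D = 16,
#' t_max = 0.1 m, 30 Hz, 1600 epochs, batch 256, learning rate 2e-4 decayed
#' by 20% every 400 epochs, 50 fine-tuning epochs at 1e-4).
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return A list with `model` (`model_config`), `train` (`train_config`),
#'   `simulate` (list) and `t_max`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(model = do.call(model_config, raw$model %||% list()),
       train = do.call(train_config, raw$train %||% list()),
       simulate = raw$simulate %||% list(),
       t_max = raw$t_max %||% 0.1)
}

#' Run the end-to-end pipeline on a dataset
#'
#' Preprocesses and windows all sequences, trains the classifier on the
#' `train` split with selection on `val`, evaluates the `test` split before
#' fine-tuning, then fine-tunes per test subject on that subject's
#' `fine-tune` sequences and re-evaluates. Writes a metrics JSON report,
#' confusion matrices (CSV), the selected checkpoint and per-sequence
#' clamped-pose counts to `out_dir`.
#'
#' @param dataset a `gait_dataset`, or a path to a `manifest.json` /
#'   dataset directory.
#' @param model_cfg a [model_config()]; its `n_classes` must match the
#'   dataset patterns.
#' @param train_cfg a [train_config()].
#' @param out_dir output directory.
#' @param t_max glitch-clamping threshold in meters.
#' @param with_fine_tuning run the per-subject fine-tuning stage
#'   (default `TRUE`).
#' @param seed seed controlling model initialization (training shuffling is
#'   seeded by `train_cfg$rng_seed`).
#' @return A list with the trained `model`, `history`, `pre_ft` metrics,
#'   and (when fine-tuning) `post_ft` metrics plus `per_subject` detail.
#' @export
run_pipeline <- function(dataset, model_cfg = model_config(),
                         train_cfg = train_config(), out_dir = NULL,
                         t_max = 0.1, with_fine_tuning = TRUE, seed = 1L) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "gait_dataset"))
  check_split_disjoint(dataset$manifest)
  if (model_cfg$n_classes != length(dataset$patterns))
    stop(sprintf("model has %d classes but the dataset carries %d patterns",
                 model_cfg$n_classes, length(dataset$patterns)), call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  K <- model_cfg$K
  train_set <- build_window_set(dataset, "train", NULL, K, t_max = t_max)
  val_set <- build_window_set(dataset, "val", NULL, K, t_max = t_max)
  test_set <- build_window_set(dataset, "test", "test", K, t_max = t_max)

  model <- build_model(model_cfg, seed = seed)
  fit <- train_model(model, train_set, val_set, train_cfg)
  pre <- compute_metrics(predict_window_set(fit$model, test_set,
                                            train_cfg$precision), test_set$y)
  out <- list(model = fit$model, history = fit$history,
              best_epoch = fit$best_epoch, pre_ft = pre)

  if (with_fine_tuning) {
    subjects <- unique(dataset$manifest$subject_id[dataset$manifest$split == "test"])
    per_subject <- list()
    preds <- character(); truths <- character()
    for (sid in subjects) {
      ft_set <- build_window_set(subset_dataset(dataset, sid), NULL,
                                 "fine-tune", K, t_max = t_max)
      ft_model <- fine_tune(fit$model, ft_set, train_cfg)
      keep <- test_set$subject == sid
      sub_set <- list(x = test_set$x[, , keep, drop = FALSE],
                      y = test_set$y[keep], subject = test_set$subject[keep])
      class(sub_set) <- "window_set"
      p <- predict_window_set(ft_model, sub_set, train_cfg$precision)
      per_subject[[sid]] <- compute_metrics(p, sub_set$y)
      preds <- c(preds, as.character(p))
      truths <- c(truths, as.character(sub_set$y))
    }
    out$post_ft <- compute_metrics(preds, truths, labels = levels(test_set$y))
    out$per_subject <- per_subject
  }

  if (!is.null(out_dir)) {
    save_model(out$model, file.path(out_dir, "checkpoint.json"))
    report <- list(
      seed = seed, best_epoch = out$best_epoch,
      pre_ft = metrics_to_list(out$pre_ft),
      post_ft = if (!is.null(out$post_ft)) metrics_to_list(out$post_ft))
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write.csv(as.data.frame(out$pre_ft$confusion),
              file.path(out_dir, "confusion_pre_ft.csv"), row.names = FALSE)
    clamp_log <- clamp_counts(dataset, t_max)
    write.csv(clamp_log, file.path(out_dir, "clamped_poses.csv"),
              row.names = FALSE)
    pg_log("run_pipeline: outputs written to %s", out_dir)
  }
  out
}

subset_dataset <- function(dataset, subject_id) {
  keep <- dataset$manifest$subject_id == subject_id
  structure(list(sequences = dataset$sequences[dataset$manifest$seq_id[keep]],
                 manifest = dataset$manifest[keep, , drop = FALSE],
                 patterns = dataset$patterns, rate_hz = dataset$rate_hz),
            class = "gait_dataset")
}

metrics_to_list <- function(m) {
  list(accuracy = m$accuracy, macro_precision = m$macro_precision,
       macro_recall = m$macro_recall, macro_f1 = m$macro_f1, n = m$n)
}

# per-sequence count of relative poses exceeding t_max (the desk-scale
# realization of warning the wearer about tracking glitches)
clamp_counts <- function(dataset, t_max = 0.1) {
  rows <- lapply(names(dataset$sequences), function(id) {
    sq <- dataset$sequences[[id]]
    if (sq$frame_kind == "absolute-to-initial") sq <- preprocess_sequence(sq)
    mag <- sqrt(rowSums(sq$poses[, 1:3, drop = FALSE]^2))
    data.frame(seq_id = id, n_frames = nrow(sq$poses),
               n_clamped = sum(mag > t_max), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
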