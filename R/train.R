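# Training, subject-specific fine-tuning, and window-set assembly.

#' Training hyperparameter configuration
#'
#' Defaults follow the reference recipe: Adam on the cross-entropy loss for
#' 1600 epochs with batch size 256, learning rate 0.0002 decayed by 20%
#' every 400 epochs, selecting the epoch with the highest validation
#' accuracy (ties broken toward the earlier epoch). Fine-tuning runs 50
#' epochs at a reduced learning rate of 0.0001 and keeps the final-epoch
#' weights.
#'
#' @param epochs training epochs (default 1600).
#' @param batch_size minibatch size (default 256).
#' @param lr_init initial learning rate (default 2e-4).
#' @param lr_decay multiplicative decay factor applied every `decay_every`
#'   epochs (default 0.8, i.e. a 20% decay).
#' @param decay_every decay period in epochs (default 400).
#' @param ft_epochs fine-tuning epochs (default 50).
#' @param ft_lr fine-tuning learning rate (default 1e-4).
#' @param rng_seed seed for batch shuffling (weight initialization is seeded
#'   in [build_model()]).
#' @param precision `"single"` (float32 arithmetic, the convention of GPU
#'   training frameworks and the default) or `"double"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1600L, batch_size = 256L, lr_init = 2e-4,
                         lr_decay = 0.8, decay_every = 400L, ft_epochs = 50L,
                         ft_lr = 1e-4, rng_seed = 1L,
                         precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]", call. = FALSE)
  if (epochs < 0 || batch_size < 1L) stop("epochs must be >= 0 and batch_size >= 1", call. = FALSE)
  if (lr_init <= 0 || ft_lr <= 0 || decay_every < 1L)
    stop("learning rates must be > 0 and decay_every >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 ft_epochs = as.integer(ft_epochs), ft_lr = ft_lr,
                 rng_seed = as.integer(rng_seed), precision = precision),
            class = "train_config")
}

#' Assemble labeled windows from a dataset split
#'
#' Runs each selected sequence through the standard pipeline — convert to
#' previous-frame-relative poses, clamp tracking glitches at `t_max`, cut
#' sliding windows — and stacks the windows of all sequences into one
#' labeled set.
#'
#' @param dataset a `gait_dataset` from [make_dataset()] (or any list with
#'   `sequences` and a `manifest` data frame).
#' @param split which split(s) to take (`"train"`, `"val"`, `"test"`), or
#'   `NULL` for all.
#' @param role which role(s) to take (`"fit"`, `"fine-tune"`, `"test"`), or
#'   `NULL` for all.
#' @param K,stride window length and hop in frames.
#' @param t_max glitch-clamping threshold in meters.
#' @param max_frames optional cap: only the first `max_frames` frames of
#'   each sequence are used (the fine-tuning-length ablation knob).
#' @return An object of class `window_set`: list with `x` (7 x K x n array),
#'   `y` (factor of labels), `subject`, `seq_id`, `start_frame`.
#' @export
build_window_set <- function(dataset, split = NULL, role = NULL, K = 60L,
                             stride = 1L, t_max = 0.1, max_frames = NULL) {
  man <- dataset$manifest
  keep <- rep(TRUE, nrow(man))
  if (!is.null(split)) keep <- keep & man$split %in% split
  if (!is.null(role)) keep <- keep & man$role %in% role
  man <- man[keep, , drop = FALSE]
  if (nrow(man) == 0L) stop("no sequences match the requested split/role", call. = FALSE)
  xs <- list(); ys <- character(); subj <- character()
  sid <- character(); sf <- integer()
  for (i in seq_len(nrow(man))) {
    sq <- dataset$sequences[[man$seq_id[i]]]
    if (!is.null(max_frames) && nrow(sq$poses) > max_frames)
      sq$poses <- sq$poses[seq_len(max_frames), , drop = FALSE]
    rel <- clamp_glitches(preprocess_sequence(sq), t_max)
    wins <- suppressWarnings(window_sequence(rel, K, stride))
    if (!length(wins)) next
    xs[[length(xs) + 1L]] <- wins
    ys <- c(ys, rep(man$label[i], length(wins)))
    subj <- c(subj, rep(man$subject_id[i], length(wins)))
    sid <- c(sid, rep(man$seq_id[i], length(wins)))
    sf <- c(sf, vapply(wins, attr, 0L, "start_frame"))
  }
  wins <- unlist(xs, recursive = FALSE)
  if (!length(wins)) stop("no windows could be cut from the selected sequences", call. = FALSE)
  x <- stack_windows(wins, K)
  structure(list(x = x, y = factor(ys, levels = dataset$patterns %||% sort(unique(ys))),
                 subject = subj, seq_id = sid, start_frame = sf),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows (7 x %d), %d subjects\n",
              dim(x$x)[3], dim(x$x)[2], length(unique(x$subject))))
  print(table(x$y))
  invisible(x)
}

# one optimization run: Adam + optional stepped LR schedule + model selection
sgd_run <- function(model, set, epochs, batch_size, lr_at_epoch, seed,
                    precision, val_set = NULL, select = c("final", "best_val")) {
  select <- match.arg(select)
  cfg <- model$config
  pe <- positional_encoding(cfg$K - cfg$N + 1L, cfg$D)
  single <- precision == "single"
  xsrc <- if (single) cpp_pack_windows(set$x) else set$x
  val_src <- if (!is.null(val_set)) {
    if (single) cpp_pack_windows(val_set$x) else val_set$x
  }
  n <- dim(set$x)[3]
  y0 <- as.integer(set$y) - 1L
  par <- model$par
  m <- numeric(length(par)); v <- numeric(length(par)); step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     val_accuracy = numeric())
  best_par <- par; best_acc <- -Inf; best_epoch <- 0L
  if (epochs > 0L) with_seed(seed, {
    for (e in seq_len(epochs)) {
      lr <- lr_at_epoch(e)
      perm <- sample.int(n) - 1L
      losses <- numeric(0)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- perm[s:min(n, s + batch_size - 1L)]
        out <- cpp_nn_loss_grad(par, xsrc, idx, y0[idx + 1L], unclass(cfg),
                                pe, single)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * out$grad
        v <- b2 * v + (1 - b2) * out$grad^2
        mh <- m / (1 - b1^step)
        vh <- v / (1 - b2^step)
        par <- par - lr * mh / (sqrt(vh) + eps)
        losses <- c(losses, out$loss)
      }
      va <- NA_real_
      if (!is.null(val_set)) {
        mdl <- model; mdl$par <- par
        va <- mean(predict_window_set(mdl, val_set, precision,
                                      xsrc = val_src) == val_set$y)
        if (va > best_acc) { best_acc <- va; best_par <- par; best_epoch <- e }
      }
      hist[nrow(hist) + 1L, ] <- list(e, mean(losses), lr, va)
    }
  })
  if (select == "best_val" && !is.null(val_set) && epochs > 0L) {
    par <- best_par
  } else best_epoch <- epochs
  model$par <- par
  list(model = model, history = hist, best_epoch = best_epoch)
}

# hard labels for a window set, on the model's class levels
predict_window_set <- function(model, set, precision = "single", xsrc = NULL) {
  if (is.null(xsrc))
    xsrc <- if (precision == "single") cpp_pack_windows(set$x) else set$x
  logits <- matrix(0, dim(set$x)[3], model$config$n_classes)
  n <- nrow(logits)
  pe <- positional_encoding(model$config$K - model$config$N + 1L,
                            model$config$D)
  for (s in seq(1L, n, by = 2048L)) {
    idx <- s:min(n, s + 2047L)
    logits[idx, ] <- cpp_nn_forward(model$par, xsrc, idx - 1L,
                                    unclass(model$config), pe,
                                    precision == "single")
  }
  factor(levels(set$y)[max.col(logits, ties.method = "first")],
         levels = levels(set$y))
}

#' Train the classifier
#'
#' Minimizes the cross-entropy loss with Adam under the stepped
#' learning-rate schedule of `config`, evaluating validation accuracy after
#' every epoch and returning the checkpoint with the highest validation
#' accuracy (ties resolved toward the earliest epoch). Training and
#' validation subjects must be disjoint. Fully reproducible given the
#' configuration seeds.
#'
#' @param model a freshly built (or pre-trained) `gait_model`.
#' @param train_set,val_set labeled `window_set`s from
#'   [build_window_set()].
#' @param config a [train_config()].
#' @return A list with `model` (selected checkpoint), `history` (per-epoch
#'   loss, learning rate and validation accuracy) and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "gait_model"), inherits(config, "train_config"))
  check_window_set(train_set, "train_set")
  check_window_set(val_set, "val_set")
  if (dim(train_set$x)[3] == 0L || dim(val_set$x)[3] == 0L)
    stop("empty training or validation set", call. = FALSE)
  if (nlevels(train_set$y) != model$config$n_classes)
    stop(sprintf("label set has %d classes but the model was built for %d",
                 nlevels(train_set$y), model$config$n_classes), call. = FALSE)
  if (!identical(levels(train_set$y), levels(val_set$y)))
    stop("train and validation sets carry different label sets", call. = FALSE)
  overlap <- intersect(unique(train_set$subject), unique(val_set$subject))
  if (length(overlap))
    stop(sprintf("subjects appear in both splits: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  lr_fun <- function(e) config$lr_init *
    config$lr_decay^((e - 1L) %/% config$decay_every)
  fit <- sgd_run(model, train_set, config$epochs, config$batch_size, lr_fun,
                 config$rng_seed, config$precision, val_set, "best_val")
  fit$model$classes <- levels(train_set$y)
  fit
}

#' Fine-tune the classifier on one subject's calibration data
#'
#' Briefly re-trains all weights (no layer freezing) on windows from a
#' single subject — typically one trial per walking pattern — for
#' `ft_epochs` epochs at the reduced rate `ft_lr`, returning the final-epoch
#' weights.
#'
#' @param model a trained `gait_model`.
#' @param subject_set a `window_set` whose windows all come from one
#'   subject.
#' @param config a [train_config()]; only the fine-tuning fields and
#'   `batch_size`/`rng_seed`/`precision` are used.
#' @return The fine-tuned `gait_model`.
#' @export
fine_tune <- function(model, subject_set, config = train_config()) {
  stopifnot(inherits(model, "gait_model"), inherits(config, "train_config"))
  check_window_set(subject_set, "subject_set")
  subj <- unique(subject_set$subject)
  if (length(subj) != 1L)
    stop(sprintf("fine-tuning data must come from a single subject, got: %s",
                 paste(subj, collapse = ", ")), call. = FALSE)
  if (nlevels(subject_set$y) != model$config$n_classes)
    stop("label set does not match the model's classes", call. = FALSE)
  fit <- sgd_run(model, subject_set, config$ft_epochs, config$batch_size,
                 function(e) config$ft_lr,
                 derive_seed(config$rng_seed, 97L), config$precision,
                 val_set = NULL, select = "final")
  fit$model$classes <- model$classes %||% levels(subject_set$y)
  fit$model
}

check_window_set <- function(set, what) {
  if (!inherits(set, "window_set"))
    stop(sprintf("`%s` must be a window_set", what), call. = FALSE)
  if (anyNA(set$y)) stop(sprintf("`%s` has missing labels", what), call. = FALSE)
  invisible(TRUE)
}

#' Train and evaluate across several seeds
#'
#' Repeats build-train-evaluate with different initialization/shuffling
#' seeds and reports each replicate's test metrics plus their mean and
#' standard deviation, the conventional way of summarizing run-to-run
#' training variability.
#'
#' @param train_set,val_set,test_set labeled `window_set`s.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; its `rng_seed` is combined with each
#'   replicate seed.
#' @param seeds integer vector of replicate seeds.
#' @return A list with `per_seed` (data frame of accuracy / macro metrics
#'   per seed) and `summary` (mean and sd per metric).
#' @export
evaluate_replicates <- function(train_set, val_set, test_set, model_cfg,
                                train_cfg, seeds = 1:3) {
  rows <- lapply(seeds, function(s) {
    mdl <- build_model(model_cfg, seed = s)
    cfgs <- train_cfg
    cfgs$rng_seed <- derive_seed(train_cfg$rng_seed, s)
    fit <- train_model(mdl, train_set, val_set, cfgs)
    rep <- compute_metrics(predict_window_set(fit$model, test_set,
                                              cfgs$precision), test_set$y)
    data.frame(seed = s, accuracy = rep$accuracy,
               macro_precision = rep$macro_precision,
               macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1)
  })
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, -1, drop = FALSE]
  list(per_seed = per_seed,
       summary = data.frame(metric = names(num),
                            mean = vapply(num, mean, 0),
                            sd = vapply(num, sd, 0)))
}
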