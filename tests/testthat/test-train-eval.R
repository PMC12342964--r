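# metrics, prediction timelines, smoothing, and the training/fine-tuning
# machinery at desk scale

test_that("metrics match hand-computable cases", {
  r <- compute_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(r$macro_recall, 1)
  expect_equal(r$macro_f1, 1)
  r <- compute_metrics(c("a", "a", "b", "b"), c("b", "b", "a", "a"))
  expect_equal(r$accuracy, 0)
  expect_equal(r$macro_f1, 0)
  expect_equal(sum(r$confusion), 4)
  expect_equal(sum(diag(r$confusion)), 0)
})

test_that("metrics equal the brute-force counting oracle on random labelings", {
  set.seed(50)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    labels <- letters[1:k]
    n <- sample(1:500, 1)
    truth <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    got <- suppressWarnings(compute_metrics(pred, truth, labels = labels))
    want <- metrics_oracle(pred, truth, labels)
    expect_identical(got$accuracy, want$accuracy)
    expect_identical(got$macro_precision, want$precision)
    expect_identical(got$macro_recall, want$recall)
    expect_identical(got$macro_f1, want$f1)
    expect_equal(sum(got$confusion), n)
    expect_equal(got$accuracy, sum(diag(got$confusion)) / sum(got$confusion))
  }
})

test_that("metrics guard their inputs and warn on degenerate classes", {
  expect_error(compute_metrics(c("a", "b"), c("a")), "length mismatch")
  expect_error(compute_metrics("a", "z", labels = c("a", "b")), "outside")
  expect_warning(expect_warning(
    compute_metrics(c("a", "a"), c("a", "a"), labels = c("a", "b")),
    "absent"), "never predicted")
})

test_that("timeline smoothing applies the probability and run-length rules", {
  tl <- data.frame(start_frame = 0:7,
                   label = c("a", "a", "a", "a", "b", "a", "a", "a"),
                   max_prob = c(rep(0.9, 4), 0.4, rep(0.9, 3)))
  # identity configuration
  out <- smooth_predictions(tl, p_threshold = 0, min_run = 1)
  expect_identical(out$label, tl$label)
  expect_false(any(out$flagged))
  # the low-confidence isolated 'b' is flagged and relabeled 'a'
  out <- smooth_predictions(tl, p_threshold = 0.5, min_run = 1)
  expect_identical(out$label, rep("a", 8))
  expect_identical(which(out$flagged), 5L)
  expect_identical(out$raw_label, tl$label)
  # run-length rule alone also removes it
  out <- smooth_predictions(transform(tl, max_prob = 0.9), p_threshold = 0,
                            min_run = 2)
  expect_identical(out$label, rep("a", 8))
  # uniform confident timeline is untouched
  uni <- data.frame(label = rep("b", 5), max_prob = rep(0.8, 5))
  out <- smooth_predictions(uni, p_threshold = 0.5, min_run = 3)
  expect_false(any(out$flagged))
  expect_error(smooth_predictions(uni[0, ], 0.5, 1), "empty")
})

test_that("smoothing is idempotent on random timelines", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    tl <- data.frame(label = sample(c("a", "b", "c"), n, TRUE, prob = c(.5, .3, .2)),
                     max_prob = runif(n, 0.2, 1))
    s1 <- smooth_predictions(tl, p_threshold = 0.5, min_run = 2)
    s2 <- smooth_predictions(s1[, c("label", "max_prob")], p_threshold = 0.5,
                             min_run = 2)
    expect_identical(s2$label, s1$label)
  }
})

test_that("predict_sequence yields one dense prediction per window", {
  ds <- small_dataset()
  mdl <- build_model(model_config(n_classes = 3), seed = 2)
  mdl$classes <- ds$patterns
  sq <- ds$sequences[[1]]
  tl <- predict_sequence(mdl, sq)
  # relative sequence has the same length; L - K + 1 windows
  expect_equal(nrow(tl), nrow(sq$poses) - 60 + 1)
  expect_equal(tl$start_frame, 0:(nrow(tl) - 1))
  expect_true(all(tl$label %in% ds$patterns))
  expect_equal(rowSums(as.matrix(tl[, grep("^prob_", names(tl))])),
               rep(1, nrow(tl)), tolerance = 1e-5)
  # rigid-transformed trajectory gives the identical timeline
  G <- pose_to_transform(c(2, 0.3, -5, random_unit_quat()))
  tl2 <- predict_sequence(mdl, transform_sequence(sq, G))
  expect_equal(tl2$label, tl$label)
  expect_equal(tl2$max_prob, tl$max_prob, tolerance = 1e-6)
  short <- pose_sequence(sq$poses[1:30, ])
  expect_error(predict_sequence(mdl, short), "too short")
})

test_that("training runs are reproducible and epochs = 0 is the identity", {
  ds <- small_dataset()
  tr <- build_window_set(ds, "train", K = 60)
  va <- build_window_set(ds, "val", K = 60)
  mdl <- build_model(model_config(n_classes = 3), seed = 4)
  cfg0 <- train_config(epochs = 0)
  fit0 <- train_model(mdl, tr, va, cfg0)
  expect_identical(fit0$model$par, mdl$par)
  expect_equal(nrow(fit0$history), 0)
  cfg <- train_config(epochs = 2, rng_seed = 9)
  f1 <- train_model(mdl, tr, va, cfg)
  f2 <- train_model(mdl, tr, va, cfg)
  expect_identical(f1$model$par, f2$model$par)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 2)
  expect_false(identical(f1$model$par, mdl$par))
})

test_that("training rejects invalid split setups", {
  ds <- small_dataset()
  tr <- build_window_set(ds, "train", K = 60)
  va <- build_window_set(ds, "val", K = 60)
  mdl4 <- build_model(model_config(n_classes = 4), seed = 1)
  expect_error(train_model(mdl4, tr, va, train_config(epochs = 1)), "classes")
  mdl <- build_model(model_config(n_classes = 3), seed = 1)
  expect_error(train_model(mdl, tr, tr, train_config(epochs = 1)),
               "both splits")
})

test_that("fine-tuning is single-subject, final-epoch, and changes weights", {
  ds <- small_dataset()
  tr <- build_window_set(ds, "train", K = 60)
  mdl <- build_model(model_config(n_classes = 3), seed = 6)
  mdl$classes <- ds$patterns
  expect_error(fine_tune(mdl, tr, train_config()), "single subject")
  ft_set <- build_window_set(ds, "test", "fine-tune", K = 60)
  cfg <- train_config(ft_epochs = 0)
  expect_identical(fine_tune(mdl, ft_set, cfg)$par, mdl$par)
  cfg <- train_config(ft_epochs = 1, rng_seed = 3)
  ft1 <- fine_tune(mdl, ft_set, cfg)
  ft2 <- fine_tune(mdl, ft_set, cfg)
  expect_identical(ft1$par, ft2$par)
  expect_false(identical(ft1$par, mdl$par))
})

test_that("the multi-seed runner reports per-seed metrics with mean and sd", {
  ds <- small_dataset()
  tr <- build_window_set(ds, "train", K = 60)
  va <- build_window_set(ds, "val", K = 60)
  te <- build_window_set(ds, "test", "test", K = 60)
  rep <- suppressWarnings(evaluate_replicates(tr, va, te,
                                              model_config(n_classes = 3),
                                              train_config(epochs = 1),
                                              seeds = 1:2))
  expect_equal(nrow(rep$per_seed), 2)
  expect_true(all(c("accuracy", "macro_f1") %in% names(rep$per_seed)))
  expect_equal(rep$summary$mean[rep$summary$metric == "accuracy"],
               mean(rep$per_seed$accuracy))
  expect_false(anyNA(rep$summary$sd))
})
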