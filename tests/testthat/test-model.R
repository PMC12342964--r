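# CNN-Transformer model: parameter counting, token geometry, forward-pass
# validity, and validation of the compiled kernels against independent
# references

test_that("parameter count matches the closed-form per-stage sums", {
  cfg <- model_config()  # K=60, N=30, D=16, 2 layers, 2 heads, d_ff=16, 4 classes
  layout <- posegait:::param_layout(cfg)
  # convolutional encoder: 16 filters of size 7 x 30 plus biases
  expect_equal(sum(layout$sizes[c("conv_W", "conv_b")]), 16 * 7 * 30 + 16)
  # one encoder layer: attention 4 * D(D+1), two layer norms, feed-forward
  l1 <- sum(layout$sizes[grep("^l1_", names(layout$sizes))])
  expect_equal(l1, 4 * 16 * 17 + 2 * 32 + 2 * (16 * 16 + 16))
  expect_equal(l1, 1696L)
  # linear head
  expect_equal(sum(layout$sizes[c("head_W", "head_b")]), 16 * 4 + 4)
  expect_equal(count_parameters(build_model(cfg, seed = 1)), 6836L)
  # pure function of the config, not the seed
  expect_equal(count_parameters(build_model(cfg, seed = 99)), 6836L)
  # 3-class variant drops one head row
  expect_equal(count_parameters(model_config(n_classes = 3)), 6836L - 17L)
})

test_that("token-count law K - N + 1 holds across window geometries", {
  for (KN in list(c(60L, 30L), c(60L, 60L), c(10L, 3L), c(8L, 4L))) {
    cfg <- model_config(K = KN[1], N = KN[2], D = 4, n_heads = 2, d_ff = 4,
                        n_classes = 3)
    mdl <- build_model(cfg, seed = 1)
    tok <- encode_window(mdl, matrix(rnorm(7 * KN[1]), 7))
    expect_equal(dim(tok), c(KN[1] - KN[2] + 1L, 4L))
  }
  # the reference geometry: 60-frame window, 30-frame kernel -> 31 tokens
  mdl <- build_model(model_config(), seed = 1)
  expect_equal(nrow(encode_window(mdl, matrix(rnorm(7 * 60), 7))), 31L)
})

test_that("encoder activations are non-negative before positional encoding", {
  mdl <- build_model(tiny_config(), seed = 3)
  set.seed(8)
  w <- matrix(rnorm(7 * 8), 7)
  raw <- encode_window(mdl, w, add_positional = FALSE)
  expect_true(all(raw >= 0))
  pe <- positional_encoding(5, 4)
  expect_equal(encode_window(mdl, w), raw + t(pe), tolerance = 1e-12)
})

test_that("model construction is deterministic given the seed", {
  cfg <- tiny_config()
  expect_identical(build_model(cfg, seed = 5)$par, build_model(cfg, seed = 5)$par)
  expect_false(identical(build_model(cfg, seed = 5)$par,
                         build_model(cfg, seed = 6)$par))
})

test_that("config validation rejects inconsistent geometries", {
  expect_error(model_config(K = 10, N = 20), "exceed")
  expect_error(model_config(D = 15, n_heads = 2), "divisible")
  expect_error(model_config(n_classes = 1), "n_classes")
})

test_that("forward pass yields valid, batch-independent probabilities", {
  cfg <- tiny_config()
  mdl <- build_model(cfg, seed = 11)
  set.seed(12)
  x <- random_windows(6)
  pr <- predict(mdl, x)
  expect_equal(dim(pr), c(6L, 3L))
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  # batch composition does not change per-window outputs
  pr_single <- t(sapply(1:6, function(i) predict(mdl, x[, , i, drop = FALSE])[1, ]))
  expect_equal(unname(pr), unname(pr_single), tolerance = 1e-6)
  # repeated evaluation is deterministic
  expect_identical(pr, predict(mdl, x))
  # extreme but finite inputs stay valid distributions
  pr_ext <- predict(mdl, random_windows(4, sd = 10))
  expect_false(any(!is.finite(pr_ext)))
  expect_equal(rowSums(pr_ext), rep(1, 4), tolerance = 1e-6)
})

test_that("compiled forward pass matches the pure-R reference network", {
  set.seed(13)
  for (cfg in list(tiny_config(),
                   model_config(K = 12, N = 5, D = 6, n_heads = 3, d_ff = 5,
                                n_classes = 4),
                   model_config(K = 9, N = 9, D = 4, n_heads = 2, d_ff = 3,
                                n_classes = 2))) {
    mdl <- build_model(cfg, seed = 21)
    x <- random_windows(3, K = cfg$K)
    pe <- positional_encoding(cfg$K - cfg$N + 1, cfg$D)
    ref <- t(sapply(1:3, function(i) posegait:::nn_forward_ref(mdl$par, x[, , i], cfg)))
    got <- posegait:::cpp_nn_forward(mdl$par, x, 0:2, unclass(cfg), pe, FALSE)
    expect_lt(max(abs(ref - got)), 1e-10)
    # float path agrees to single precision
    gotf <- posegait:::cpp_nn_forward(mdl$par, x, 0:2, unclass(cfg), pe, TRUE)
    expect_lt(max(abs(ref - gotf)), 1e-4)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  mdl <- build_model(cfg, seed = 31)
  set.seed(32)
  x <- random_windows(4)
  y <- c(0L, 2L, 1L, 0L)
  pe <- positional_encoding(5, 4)
  g <- posegait:::cpp_nn_loss_grad(mdl$par, x, 0:3, y, unclass(cfg), pe, FALSE)
  lossf <- function(p)
    posegait:::cpp_nn_loss_grad(p, x, 0:3, y, unclass(cfg), pe, FALSE)$loss
  idx <- sort(sample(length(mdl$par), 80))
  num <- vapply(idx, function(j) {
    p1 <- mdl$par; p1[j] <- p1[j] + 1e-5
    p2 <- mdl$par; p2[j] <- p2[j] - 1e-5
    (lossf(p1) - lossf(p2)) / 2e-5
  }, 0)
  expect_lt(max(abs(g$grad[idx] - num)), 1e-7)
})

test_that("checkpoints round-trip through JSON", {
  mdl <- build_model(tiny_config(), seed = 41)
  mdl$classes <- c("normal", "ml", "ap")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mdl, path)
  back <- load_model(path)
  expect_equal(back$par, mdl$par)
  expect_equal(back$classes, mdl$classes)
  expect_equal(unclass(back$config), unclass(mdl$config))
  set.seed(42)
  x <- random_windows(2)
  expect_equal(predict(back, x), predict(mdl, x))
})
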