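# Lightweight CNN-Transformer walking-pattern classifier.
#
# Architecture: a 2-D convolution with D filters of size 1 x N slides over
# the 7-channel, 7 x 1 x K input window (stride 1) and, after a ReLU, encodes
# every N consecutive camera poses into a D-dimensional token (K - N + 1
# tokens in total).  Fixed sinusoidal positional encodings are added, two
# Transformer encoder layers (two-head self-attention + feed-forward,
# residual connections, post-layer-norm) mix the tokens, the final layer's
# output is averaged over tokens, and a linear head produces class logits.
#
# With the defaults (K = 60, N = 30, D = 16, 2 layers, 2 heads, d_ff = 16,
# 4 classes) the model has 6836 trainable parameters: 3376 in the
# convolutional encoder, 1696 per encoder layer, and 68 in the head.

#' Model hyperparameter configuration
#'
#' @param K input window length in frames (default 60, i.e. 2 s at 30 Hz).
#' @param N convolution kernel length in frames (default 30, i.e. 1 s);
#'   must satisfy `N <= K`.
#' @param D token / latent dimension (default 16); must be divisible by
#'   `n_heads`.
#' @param n_layers number of Transformer encoder layers (default 2).
#' @param n_heads self-attention heads per layer (default 2).
#' @param d_ff feed-forward hidden width (default 16).
#' @param n_classes number of walking-pattern classes (3 or 4 in practice).
#' @param pos_encoding positional-encoding type; only `"sinusoidal"` (fixed,
#'   non-learnable) is implemented.
#' @return An object of class `model_config`.
#' @export
model_config <- function(K = 60L, N = 30L, D = 16L, n_layers = 2L,
                         n_heads = 2L, d_ff = 16L, n_classes = 4L,
                         pos_encoding = "sinusoidal") {
  K <- as.integer(K); N <- as.integer(N); D <- as.integer(D)
  n_layers <- as.integer(n_layers); n_heads <- as.integer(n_heads)
  d_ff <- as.integer(d_ff); n_classes <- as.integer(n_classes)
  pos_encoding <- match.arg(pos_encoding)
  if (N > K) stop("N must not exceed K", call. = FALSE)
  if (N < 1L || K < 1L) stop("K and N must be >= 1", call. = FALSE)
  if (D %% n_heads != 0L) stop("D must be divisible by n_heads", call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (n_layers < 1L || d_ff < 1L) stop("n_layers and d_ff must be >= 1", call. = FALSE)
  structure(list(K = K, N = N, D = D, n_layers = n_layers, n_heads = n_heads,
                 d_ff = d_ff, n_classes = n_classes,
                 pos_encoding = pos_encoding),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> K=%d N=%d D=%d layers=%d heads=%d d_ff=%d classes=%d (%s PE)\n",
              x$K, x$N, x$D, x$n_layers, x$n_heads, x$d_ff, x$n_classes,
              x$pos_encoding))
  invisible(x)
}

# canonical parameter layout shared with the C++ kernels; order matters
param_layout <- function(cfg) {
  shp <- list(conv_W = c(cfg$D, 7L * cfg$N), conv_b = c(cfg$D, 1L))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    shp[[paste0(pre, "Wq")]] <- c(cfg$D, cfg$D)
    shp[[paste0(pre, "bq")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "Wk")]] <- c(cfg$D, cfg$D)
    shp[[paste0(pre, "bk")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "Wv")]] <- c(cfg$D, cfg$D)
    shp[[paste0(pre, "bv")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "Wo")]] <- c(cfg$D, cfg$D)
    shp[[paste0(pre, "bo")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "ln1_g")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "ln1_b")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "W1")]] <- c(cfg$d_ff, cfg$D)
    shp[[paste0(pre, "b1")]] <- c(cfg$d_ff, 1L)
    shp[[paste0(pre, "W2")]] <- c(cfg$D, cfg$d_ff)
    shp[[paste0(pre, "b2")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "ln2_g")]] <- c(cfg$D, 1L)
    shp[[paste0(pre, "ln2_b")]] <- c(cfg$D, 1L)
  }
  shp$head_W <- c(cfg$n_classes, cfg$D)
  shp$head_b <- c(cfg$n_classes, 1L)
  sizes <- vapply(shp, prod, numeric(1))
  list(shapes = shp, sizes = sizes,
       offsets = cumsum(c(0, sizes[-length(sizes)])),
       total = sum(sizes))
}

# view one named parameter block of a flat parameter vector as a matrix
param_block <- function(par, layout, name) {
  i <- match(name, names(layout$shapes))
  d <- layout$shapes[[i]]
  matrix(par[(layout$offsets[i] + 1):(layout$offsets[i] + layout$sizes[i])],
         d[1], d[2])
}

#' Fixed sinusoidal positional encoding
#'
#' Standard interleaved sine/cosine encoding: dimension pairs `(2i, 2i + 1)`
#' carry `sin(pos / 10000^(2i/D))` and `cos(pos / 10000^(2i/D))` for token
#' position `pos = 0, 1, ...`. Non-learnable, so it contributes no
#' parameters.
#'
#' @param n_tokens number of token positions.
#' @param D encoding dimension.
#' @return A `D x n_tokens` matrix (one column per token position).
#' @export
positional_encoding <- function(n_tokens, D) {
  pe <- matrix(0, D, n_tokens)
  pos <- seq_len(n_tokens) - 1
  for (i in seq_len(ceiling(D / 2)) - 1L) {
    angle <- pos / 10000^(2 * i / D)
    pe[2L * i + 1L, ] <- sin(angle)
    if (2L * i + 2L <= D) pe[2L * i + 2L, ] <- cos(angle)
  }
  pe
}

#' Build a CNN-Transformer walking-pattern classifier
#'
#' Initializes all trainable weights deterministically from `seed`
#' (uniform fan-in initialization for the convolution, projections and
#' linear layers; layer-norm gains 1 and offsets 0).
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `gait_model` holding the flat parameter
#'   vector, the configuration, the class labels it predicts (set during
#'   training) and the initialization seed.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  layout <- param_layout(config)
  par <- numeric(layout$total)
  with_seed(seed, {
    for (i in seq_along(layout$shapes)) {
      nm <- names(layout$shapes)[i]
      d <- layout$shapes[[i]]
      idx <- (layout$offsets[i] + 1):(layout$offsets[i] + layout$sizes[i])
      if (grepl("ln[12]_g$", nm)) {
        par[idx] <- 1
      } else if (grepl("ln[12]_b$", nm)) {
        par[idx] <- 0
      } else if (d[2] == 1L) {           # bias: U(-1/sqrt(fan_in), ...)
        fan_in <- switch(nm, conv_b = 7L * config$N, config$D)
        if (grepl("b1$", nm)) fan_in <- config$D
        if (grepl("b2$", nm)) fan_in <- config$d_ff
        b <- 1 / sqrt(fan_in)
        par[idx] <- runif(length(idx), -b, b)
      } else {                            # weight: U(-1/sqrt(fan_in), ...)
        b <- 1 / sqrt(d[2])
        par[idx] <- runif(length(idx), -b, b)
      }
    }
  })
  structure(list(par = par, config = config, seed = as.integer(seed),
                 classes = NULL, version = "1"),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %d parameters", count_parameters(x)))
  if (!is.null(x$classes))
    cat(sprintf(", classes: %s", paste(x$classes, collapse = ", ")))
  cat("\n")
  print(x$config)
  invisible(x)
}

#' Count trainable model parameters
#'
#' The count is a pure function of the model configuration: the
#' convolutional encoder has `D * (7N + 1)` parameters, each encoder layer
#' `4 D (D + 1) + d_ff (D + 1) + D (d_ff + 1) + 4 D`, and the head
#' `n_classes * (D + 1)`.
#'
#' @param model a `gait_model` (or a `model_config`).
#' @return Integer number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  cfg <- if (inherits(model, "model_config")) model else model$config
  as.integer(param_layout(cfg)$total)
}

#' Encode one window into a token sequence
#'
#' Applies the convolutional camera-pose-sequence encoder: each group of `N`
#' consecutive relative poses is mapped to a `D`-dimensional token (ReLU
#' activation), yielding exactly `K - N + 1` tokens, to which the fixed
#' sinusoidal positional encoding is added.
#'
#' @param model a `gait_model`.
#' @param window a `relative_window` (7 x K matrix) from
#'   [window_sequence()], or any 7 x K numeric matrix.
#' @param add_positional add the positional encoding (default `TRUE`); with
#'   `FALSE` the raw ReLU activations are returned, which are non-negative.
#' @return A `(K - N + 1) x D` matrix of tokens (rows = token positions).
#' @export
encode_window <- function(model, window, add_positional = TRUE) {
  stopifnot(inherits(model, "gait_model"))
  cfg <- model$config
  X <- unclass(window)
  if (!is.matrix(X) || nrow(X) != 7L || ncol(X) != cfg$K)
    stop(sprintf("window must be a 7 x %d matrix", cfg$K), call. = FALSE)
  layout <- param_layout(cfg)
  Wc <- param_block(model$par, layout, "conv_W")
  bc <- param_block(model$par, layout, "conv_b")
  n_tok <- cfg$K - cfg$N + 1L
  Cm <- matrix(0, 7L * cfg$N, n_tok)     # im2col: one column per token
  for (t in seq_len(n_tok))
    Cm[, t] <- as.vector(X[, t:(t + cfg$N - 1L)])
  Z <- Wc %*% Cm + as.vector(bc)
  Z[Z < 0] <- 0
  if (add_positional) Z <- Z + positional_encoding(n_tok, cfg$D)
  t(Z)
}

# stack windows (list of 7 x K matrices or 7 x K x B array) into an array
stack_windows <- function(windows, K) {
  if (is.array(windows) && length(dim(windows)) == 3L) {
    stopifnot(dim(windows)[1] == 7L, dim(windows)[2] == K)
    return(windows)
  }
  if (inherits(windows, "relative_window")) windows <- list(windows)
  stopifnot(is.list(windows), length(windows) >= 1L)
  arr <- array(0, c(7L, K, length(windows)))
  for (i in seq_along(windows)) {
    w <- unclass(windows[[i]])
    if (!is.matrix(w) || nrow(w) != 7L || ncol(w) != K)
      stop(sprintf("window %d is not a 7 x %d matrix", i, K), call. = FALSE)
    arr[, , i] <- w
  }
  arr
}

# batched forward pass through the C++ kernel; returns logits (B x C)
model_logits <- function(model, x, single = FALSE, chunk = 2048L) {
  cfg <- model$config
  x <- stack_windows(x, cfg$K)
  B <- dim(x)[3]
  pe <- positional_encoding(cfg$K - cfg$N + 1L, cfg$D)
  out <- matrix(0, B, cfg$n_classes)
  for (s in seq(1L, B, by = chunk)) {
    idx <- s:min(B, s + chunk - 1L)
    out[idx, ] <- cpp_nn_forward(model$par, x, idx - 1L, unclass(cfg), pe,
                                 single)
  }
  out
}

#' Run the classifier over a batch of windows
#'
#' Each window is processed independently (predictions never depend on batch
#' composition). Probabilities are softmax-normalized logits.
#'
#' @param model a `gait_model`.
#' @param windows a `relative_window`, a list of them, or a `7 x K x B`
#'   array.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @return A `B x n_classes` probability matrix (rows sum to 1), or a label
#'   vector when `type = "class"`.
#' @export
predict.gait_model <- function(object, windows, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  logits <- model_logits(object, windows)
  pr <- softmax_rows(logits)
  cls <- object$classes %||% as.character(seq_len(object$config$n_classes))
  colnames(pr) <- cls
  if (type == "class") cls[max.col(pr, ties.method = "first")] else pr
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# pure-R reference forward pass for one 7 x K window (double precision).
# Mirrors the C++ kernel op-for-op and is used as its correctness oracle.
nn_forward_ref <- function(par, X, cfg) {
  layout <- param_layout(cfg)
  blk <- function(nm) param_block(par, layout, nm)
  n_tok <- cfg$K - cfg$N + 1L
  dh <- cfg$D %/% cfg$n_heads
  Cm <- matrix(0, 7L * cfg$N, n_tok)
  for (t in seq_len(n_tok)) Cm[, t] <- as.vector(X[, t:(t + cfg$N - 1L)])
  Z <- blk("conv_W") %*% Cm + as.vector(blk("conv_b"))
  Z[Z < 0] <- 0
  Xt <- Z + positional_encoding(n_tok, cfg$D)
  layer_norm <- function(M, g, b) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    Xh <- sweep(sweep(M, 2L, mu), 2L, sqrt(v + 1e-5), "/")
    sweep(Xh * as.vector(g), 1L, as.vector(b), "+")
  }
  for (l in seq_len(cfg$n_layers)) {
    p <- sprintf("l%d_", l)
    Q <- blk(paste0(p, "Wq")) %*% Xt + as.vector(blk(paste0(p, "bq")))
    Km <- blk(paste0(p, "Wk")) %*% Xt + as.vector(blk(paste0(p, "bk")))
    V <- blk(paste0(p, "Wv")) %*% Xt + as.vector(blk(paste0(p, "bv")))
    Ctx <- matrix(0, cfg$D, n_tok)
    for (h in seq_len(cfg$n_heads)) {
      r <- ((h - 1L) * dh + 1L):(h * dh)
      S <- crossprod(Q[r, , drop = FALSE], Km[r, , drop = FALSE]) / sqrt(dh)
      A <- t(apply(S, 1L, function(s) { s <- exp(s - max(s)); s / sum(s) }))
      Ctx[r, ] <- V[r, , drop = FALSE] %*% t(A)
    }
    O <- blk(paste0(p, "Wo")) %*% Ctx + as.vector(blk(paste0(p, "bo")))
    Y <- layer_norm(Xt + O, blk(paste0(p, "ln1_g")), blk(paste0(p, "ln1_b")))
    Hf <- blk(paste0(p, "W1")) %*% Y + as.vector(blk(paste0(p, "b1")))
    Hf[Hf < 0] <- 0
    F2 <- blk(paste0(p, "W2")) %*% Hf + as.vector(blk(paste0(p, "b2")))
    Xt <- layer_norm(Y + F2, blk(paste0(p, "ln2_g")), blk(paste0(p, "ln2_b")))
  }
  m <- rowMeans(Xt)
  as.vector(blk("head_W") %*% m + as.vector(blk("head_b")))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON: weights, configuration, class labels,
#' initialization seed and a format version.
#'
#' @param model a `gait_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `gait_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  obj <- list(format = "posegait-checkpoint-1",
              config = unclass(model$config), seed = model$seed,
              classes = model$classes, par = model$par)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "posegait-checkpoint-1"))
    stop("not a recognized model checkpoint", call. = FALSE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  m <- structure(list(par = as.numeric(obj$par), config = cfg,
                      seed = as.integer(obj$seed),
                      classes = obj$classes, version = "1"),
                 class = "gait_model")
  if (length(m$par) != param_layout(cfg)$total)
    stop("checkpoint parameter vector does not match its configuration",
         call. = FALSE)
  m
}
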