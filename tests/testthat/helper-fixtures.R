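# shared fixtures: random rotations/poses built in code, tiny model configs,
# and a lazily-built cache for objects reused across test files

random_unit_quat <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[4] < 0) q <- -q
  q
}

random_transform <- function(t_scale = 1) {
  P <- diag(4)
  P[1:3, 1:3] <- quat_to_rotmat(random_unit_quat())
  P[1:3, 4] <- rnorm(3, 0, t_scale)
  P
}

random_pose <- function(t_scale = 1) c(rnorm(3, 0, t_scale), random_unit_quat())

# small absolute pose sequence with non-trivial rotations
random_walk_sequence <- function(n = 50, step = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- diag(4)
  poses <- matrix(0, n, 7)
  poses[1, ] <- c(0, 0, 0, 0, 0, 0, 1)
  for (i in 2:n) {
    d <- diag(4)
    ang <- rnorm(3, 0, 0.05)
    d[1:3, 1:3] <- quat_to_rotmat(c(sin(ang / 2), sqrt(1 - sum(sin(ang / 2)^2))))
    d[1:3, 4] <- c(rnorm(2, 0, step / 4), -abs(rnorm(1, step, step / 4)))
    P <- P %*% d
    poses[i, ] <- transform_to_pose(P)
  }
  pose_sequence(poses, rate_hz = 30)
}

tiny_config <- function(n_classes = 3L)
  model_config(K = 8L, N = 4L, D = 4L, n_layers = 2L, n_heads = 2L,
               d_ff = 4L, n_classes = n_classes)

random_windows <- function(n, K = 8L, sd = 0.5) array(rnorm(7 * K * n, 0, sd), c(7, K, n))

# cache shared across test files within one test run
.pg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pg_cache)) assign(key, force(expr), envir = .pg_cache)
  get(key, envir = .pg_cache)
}

# a small labeled dataset reused by train/eval tests
small_dataset <- function() cached("small_dataset", {
  make_dataset(3, 1, 1, patterns = c("normal", "ml", "ap"), rng_seed = 404)
})

# brute-force one-vs-rest counting oracle, independent of compute_metrics
metrics_oracle <- function(pred, truth, labels) {
  pred <- as.character(pred); truth <- as.character(truth)
  per <- lapply(labels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  })
  m <- do.call(rbind, per)
  list(accuracy = mean(pred == truth), precision = mean(m[, "p"]),
       recall = mean(m[, "r"]), f1 = mean(m[, "f"]))
}

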