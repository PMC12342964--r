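# SE(3) pose algebra and the relative-pose preprocessing pipeline

test_that("quaternion-to-rotation conversion handles closed-form and random cases", {
  expect_equal(quat_to_rotmat(c(0, 0, 0, 1)), diag(3))
  # quarter turn about the vertical (third) axis
  expect_equal(quat_to_rotmat(c(0, 0, sqrt(2) / 2, sqrt(2) / 2)),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    q <- random_unit_quat()
    R <- quat_to_rotmat(q)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
    # q and -q encode the same rotation
    expect_equal(R, quat_to_rotmat(-q), tolerance = 1e-12)
  }
})

test_that("quaternion conversion validates its input", {
  expect_error(quat_to_rotmat(c(1, 2, 3)), "4 components")
  expect_error(quat_to_rotmat(c(0, 0, 0, 2)), "norm")
  expect_error(quat_to_rotmat(c(NA, 0, 0, 1)), "non-finite")
  # small deviations are renormalized silently
  expect_equal(quat_to_rotmat(c(0, 0, 0, 1 + 5e-4)), diag(3), tolerance = 1e-9)
})

test_that("pose <-> transform conversions round-trip", {
  expect_equal(pose_to_transform(c(0, 0, 0, 0, 0, 0, 1)), diag(4))
  P <- pose_to_transform(c(1, 2, 3, 0, 0, 0, 1))
  expect_equal(P[1:3, 4], c(1, 2, 3))
  expect_equal(P[1:3, 1:3], diag(3))
  # half-turn about the first axis has quaternion (1, 0, 0, 0)
  Rx <- diag(c(1, -1, -1))
  P <- diag(4); P[1:3, 1:3] <- Rx
  expect_equal(unname(transform_to_pose(P)), c(0, 0, 0, 1, 0, 0, 0),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    p <- random_pose()
    back <- transform_to_pose(pose_to_transform(p))
    expect_equal(unname(back[1:3]), p[1:3], tolerance = 1e-9)
    # canonical sign: compare up to quaternion sign
    expect_lt(min(max(abs(back[4:7] - p[4:7])),
                  max(abs(back[4:7] + p[4:7]))), 1e-9)
    expect_gte(back[7], 0)
  }
})

test_that("relative_pose composes back to the current pose", {
  P <- random_transform()
  expect_equal(relative_pose(P, P), diag(4), tolerance = 1e-9)
  expect_equal(relative_pose(P, diag(4)), P, tolerance = 1e-12)
  # pure translation closed form
  A <- diag(4); A[1:3, 4] <- c(1, 2, 3)
  B <- diag(4); B[1:3, 4] <- c(1, 2, 2.9)
  expect_equal(relative_pose(B, A)[1:3, 4], c(0, 0, -0.1))
  set.seed(3)
  for (i in 1:25) {
    Pc <- random_transform(); Pp <- random_transform()
    expect_equal(Pp %*% relative_pose(Pc, Pp), Pc, tolerance = 1e-9)
  }
})

test_that("preprocessing yields identity-led relative sequences with closed forms", {
  # static sequence -> all identity relative poses
  static <- pose_sequence(matrix(rep(c(0, 0, 0, 0, 0, 0, 1), 5), 5, byrow = TRUE))
  rel <- preprocess_sequence(static)
  expect_equal(rel$frame_kind, "relative-to-previous")
  expect_equal(unname(rel$poses), matrix(rep(c(0, 0, 0, 0, 0, 0, 1), 5), 5,
                                         byrow = TRUE))
  # constant-velocity straight walk: -0.03 m along Z per frame
  walk <- pose_sequence(cbind(0, 0, -0.03 * (0:9), 0, 0, 0, 1))
  rel <- preprocess_sequence(walk)
  expect_equal(unname(rel$poses[1, ]), c(0, 0, 0, 0, 0, 0, 1))
  for (i in 2:10) expect_equal(unname(rel$poses[i, 1:3]), c(0, 0, -0.03))
  expect_error(preprocess_sequence(pose_sequence(matrix(c(0, 0, 0, 0, 0, 0, 1), 1))),
               "at least 2")
  expect_error(preprocess_sequence(rel), "already relative")
})

test_that("vectorized preprocessing matches the scalar SE(3) reference", {
  set.seed(4)
  for (i in 1:5) {
    sq <- random_walk_sequence(60)
    expect_equal(preprocess_sequence(sq)$poses,
                 posegait:::preprocess_sequence_ref(sq)$poses,
                 tolerance = 1e-12)
  }
})

test_that("relative sequences are invariant to the trial's starting pose", {
  set.seed(5)
  for (i in 1:10) {
    sq <- random_walk_sequence(40)
    G <- random_transform(2)
    rel <- preprocess_sequence(sq)
    relG <- preprocess_sequence(transform_sequence(sq, G))
    expect_lt(max(abs(rel$poses - relG$poses)), 1e-9)
  }
})

test_that("cumulative composition reconstructs the absolute trajectory", {
  set.seed(6)
  sq <- random_walk_sequence(500)
  back <- accumulate_poses(preprocess_sequence(sq))
  expect_lt(max(abs(back$poses - sq$poses)), 1e-6)
})

test_that("glitch clamping resets only strictly-exceeding poses and is idempotent", {
  poses <- rbind(c(0, 0, -0.03, 0, 0, 0, 1),
                 c(0, 0, -0.15, 0.1, 0, 0, sqrt(1 - 0.01)),   # |T| > t_max
                 c(0, 0, -0.1, 0, 0, 0, 1),                    # exactly t_max
                 c(0.05, 0, -0.05, 0, 0, 0, 1))
  sq <- pose_sequence(poses, frame_kind = "relative-to-previous")
  out <- clamp_glitches(sq, t_max = 0.1)
  expect_equal(unname(out$poses[2, ]), c(0, 0, 0, 0, 0, 0, 1))
  expect_identical(out$poses[c(1, 3, 4), ], sq$poses[c(1, 3, 4), ])
  expect_equal(attr(out, "clamped_frames"), 1L)
  # idempotent
  out2 <- clamp_glitches(out, t_max = 0.1)
  expect_identical(out2$poses, out$poses)
  # below-threshold sequences pass through bit-identically
  small <- pose_sequence(poses[c(1, 4), , drop = FALSE],
                         frame_kind = "relative-to-previous")
  expect_identical(clamp_glitches(small, 0.1)$poses, small$poses)
  expect_error(clamp_glitches(random_walk_sequence(10), 0.1), "relative")
})

test_that("window counts follow floor((L - K) / stride) + 1", {
  mk <- function(L) pose_sequence(cbind(0, 0, -0.01 * (1:L), 0, 0, 0, 1),
                                  frame_kind = "relative-to-previous")
  expect_length(window_sequence(mk(60), K = 60), 1L)
  expect_length(window_sequence(mk(480), K = 60), 421L)
  expect_warning(w <- window_sequence(mk(59), K = 60), "shorter")
  expect_length(w, 0L)
  expect_length(window_sequence(mk(100), K = 60, stride = 10), 5L)
  w <- window_sequence(mk(100), K = 60, stride = 10)
  expect_equal(vapply(w, attr, 0L, "start_frame"), seq(0L, 40L, 10L))
  expect_true(all(vapply(w, function(x) identical(dim(unclass(x)), c(7L, 60L)),
                         TRUE)))
})

test_that("stride-K windows tile the sequence exactly", {
  set.seed(7)
  sq <- preprocess_sequence(random_walk_sequence(130))
  K <- 25L
  wins <- window_sequence(sq, K = K, stride = K)
  tiled <- do.call(cbind, lapply(wins, unclass))
  expect_identical(unname(tiled), unname(t(sq$poses[1:(K * length(wins)), ])))
})
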