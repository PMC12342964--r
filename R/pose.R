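# SE(3) pose representation and relative-pose preprocessing.
#
# A single camera pose is a 7-vector (tx, ty, tz, rx, ry, rz, rw): translation
# in meters followed by a unit quaternion (Qi, Qj, Qk, Qr).  The tracker frame
# has +X to the right, +Y up and +Z to the back of the device, so forward
# walking progresses along -Z.

POSE_COLS <- c("tx", "ty", "tz", "rx", "ry", "rz", "rw")
FRAME_KINDS <- c("absolute-to-initial", "relative-to-previous")
GAIT_LABELS <- c("normal", "ml", "ap", "combined")

identity_pose <- function() c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0, rw = 1)

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternion components are ordered `(rx, ry, rz, rw)`, i.e. the vector part
#' first and the scalar part last. `q` and `-q` map to the same rotation.
#'
#' @param q numeric length-4 quaternion. Its norm must be within `1e-3` of 1;
#'   it is renormalized internally before conversion.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' quat_to_rotmat(c(0, 0, sqrt(2) / 2, sqrt(2) / 2))  # 90 degrees about +Z
#' @export
quat_to_rotmat <- function(q) {
  if (length(q) != 4L) stop("quaternion must have 4 components", call. = FALSE)
  stop_if_not_finite(q, "quaternion")
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-3)
    stop(sprintf("quaternion norm %.6f deviates from 1 by more than 1e-3", n),
         call. = FALSE)
  q <- q / n
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, ncol = 3L)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses Shepperd's numerically stable branch selection and returns the
#' canonical representative with a non-negative scalar component (`rw >= 0`).
#'
#' @param R 3x3 rotation matrix; orthogonality is checked within `1e-6`.
#' @return Numeric length-4 quaternion `(rx, ry, rz, rw)`.
#' @export
rotmat_to_quat <- function(R) {
  check_rotation(R, tol = 1e-6)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, 0.25 * s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c(0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s, (R[3, 2] - R[2, 3]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s, (R[1, 3] - R[3, 1]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s,
           0.25 * s, (R[2, 1] - R[1, 2]) / s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[4] < 0) q <- -q
  q
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L))
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  stop_if_not_finite(R, "rotation matrix")
  if (max(abs(R %*% t(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop(sprintf("matrix is not a proper rotation within tolerance %g", tol),
         call. = FALSE)
  invisible(TRUE)
}

#' Convert a 7-vector pose to a 4x4 homogeneous transform
#'
#' @param p numeric length-7 pose `(tx, ty, tz, rx, ry, rz, rw)`.
#' @return A 4x4 homogeneous rigid-transform matrix.
#' @seealso [transform_to_pose()] for the inverse conversion.
#' @export
pose_to_transform <- function(p) {
  if (length(p) != 7L) stop("pose must have 7 components", call. = FALSE)
  p <- as.numeric(p)
  stop_if_not_finite(p[1:3], "translation")
  P <- diag(4)
  P[1:3, 1:3] <- quat_to_rotmat(p[4:7])
  P[1:3, 4] <- p[1:3]
  P
}

#' Convert a 4x4 homogeneous transform to a 7-vector pose
#'
#' The returned quaternion uses the canonical sign (`rw >= 0`); the
#' translation is copied exactly.
#'
#' @param P 4x4 homogeneous rigid transform with a proper rotation block.
#' @return Numeric length-7 pose.
#' @export
transform_to_pose <- function(P) {
  check_transform(P)
  p <- c(P[1:3, 4], rotmat_to_quat(P[1:3, 1:3]))
  names(p) <- POSE_COLS
  p
}

check_transform <- function(P, tol = 1e-6) {
  if (!is.matrix(P) || any(dim(P) != 4L))
    stop("transform must be a 4x4 matrix", call. = FALSE)
  if (max(abs(P[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of a rigid transform must be (0, 0, 0, 1)", call. = FALSE)
  check_rotation(P[1:3, 1:3], tol)
  invisible(TRUE)
}

#' Express a pose relative to another pose
#'
#' Computes the transform taking the previous camera frame to the current one:
#' the rotation is `R_prev^-1 R_curr` and the translation is
#' `R_prev^-1 (T_curr - T_prev)`, so that `P_prev %*% relative_pose(P_curr,
#' P_prev)` recovers `P_curr`.
#'
#' @param P_curr,P_prev 4x4 homogeneous rigid transforms.
#' @return A 4x4 homogeneous rigid transform.
#' @export
relative_pose <- function(P_curr, P_prev) {
  check_transform(P_curr)
  check_transform(P_prev)
  Rp <- P_prev[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- crossprod(Rp, P_curr[1:3, 1:3])
  out[1:3, 4] <- crossprod(Rp, P_curr[1:3, 4] - P_prev[1:3, 4])
  out
}

#' Construct a pose sequence
#'
#' A pose sequence is an ordered, timestamped set of 7-vector camera poses
#' with a sampling rate, an optional subject identifier and walking-pattern
#' label, and a frame kind stating whether each pose is expressed relative to
#' the initial pose of the trial (`"absolute-to-initial"`, the tracker's
#' native output) or to the immediately preceding pose
#' (`"relative-to-previous"`, the model-ready representation).
#'
#' @param poses numeric matrix or data frame with columns
#'   `tx, ty, tz, rx, ry, rz, rw`, one row per frame.
#' @param rate_hz sampling rate in Hz (default 30).
#' @param subject_id optional subject identifier.
#' @param label optional walking-pattern label, one of
#'   `"normal", "ml", "ap", "combined"`.
#' @param frame_kind `"absolute-to-initial"` or `"relative-to-previous"`.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(poses, rate_hz = 30, subject_id = NA_character_,
                          label = NA_character_,
                          frame_kind = "absolute-to-initial") {
  if (is.data.frame(poses)) poses <- as.matrix(poses[, POSE_COLS])
  if (!is.matrix(poses) || ncol(poses) != 7L)
    stop("`poses` must be a matrix with 7 columns (tx..rw)", call. = FALSE)
  colnames(poses) <- POSE_COLS
  if (nrow(poses) < 1L) stop("a pose sequence needs at least one pose", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  frame_kind <- match.arg(frame_kind, FRAME_KINDS)
  if (!is.na(label)) label <- match.arg(label, GAIT_LABELS)
  stop_if_not_finite(poses, "pose matrix")
  qn <- sqrt(rowSums(poses[, 4:7, drop = FALSE]^2))
  bad <- which(abs(qn - 1) > 1e-3)
  if (length(bad))
    stop(sprintf("non-unit quaternion (norm %.4f) at frame %d", qn[bad[1]],
                 bad[1] - 1L), call. = FALSE)
  poses[, 4:7] <- poses[, 4:7, drop = FALSE] / qn
  structure(list(poses = poses, rate_hz = rate_hz, subject_id = subject_id,
                 label = label, frame_kind = frame_kind),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %g Hz [%s]\n", nrow(x$poses),
              x$rate_hz, x$frame_kind))
  cat(sprintf("  subject: %s  label: %s\n", x$subject_id, x$label))
  invisible(x)
}

#' @export
length.pose_sequence <- function(x) nrow(x$poses)

#' Apply a fixed rigid transform to every pose of an absolute sequence
#'
#' Left-multiplies each absolute pose by `G`, emulating a change of the
#' trial's starting location and heading. The previous-frame-relative
#' representation produced by [preprocess_sequence()] is invariant to this.
#'
#' @param seq a `pose_sequence` with `frame_kind = "absolute-to-initial"`.
#' @param G 4x4 homogeneous rigid transform.
#' @return A transformed `pose_sequence`.
#' @export
transform_sequence <- function(seq, G) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame_kind != "absolute-to-initial")
    stop("transform_sequence() applies to absolute-to-initial sequences",
         call. = FALSE)
  check_transform(G)
  out <- t(apply(seq$poses, 1L, function(p)
    transform_to_pose(G %*% pose_to_transform(p))))
  seq$poses <- out
  colnames(seq$poses) <- POSE_COLS
  seq
}

# batched Hamilton product of quaternion rows (x, y, z, w); satisfies
# quat_to_rotmat(quat_mul(a, b)) == quat_to_rotmat(a) %*% quat_to_rotmat(b)
quat_mul <- function(q1, q2) {
  x1 <- q1[, 1]; y1 <- q1[, 2]; z1 <- q1[, 3]; w1 <- q1[, 4]
  x2 <- q2[, 1]; y2 <- q2[, 2]; z2 <- q2[, 3]; w2 <- q2[, 4]
  cbind(w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
        w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2)
}

quat_conj <- function(q) cbind(-q[, 1], -q[, 2], -q[, 3], q[, 4])

# rotate vector rows v by quaternion rows q: v + 2 w (u x v) + 2 u x (u x v)
quat_rotate <- function(q, v) {
  u <- q[, 1:3, drop = FALSE]; w <- q[, 4]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- cr(u, v)
  v + 2 * w * t1 + 2 * cr(u, t1)
}

#' Convert an absolute pose sequence to previous-frame-relative poses
#'
#' The tracker reports each pose relative to the initial pose of the trial,
#' which varies between walks. Re-expressing pose `i` relative to pose
#' `i - 1` removes this dependence on the starting location and heading.
#' Element 0 of the output is defined as the identity pose, so the output has
#' the same length as the input and frame indices stay aligned.
#'
#' The conversion runs as vectorized quaternion algebra over all frames at
#' once: the relative rotation is `conj(q_prev) * q_curr` and the relative
#' translation is `T_curr - T_prev` rotated into the previous camera frame.
#'
#' @param seq a `pose_sequence` with `frame_kind = "absolute-to-initial"` and
#'   at least 2 frames.
#' @return A `pose_sequence` with `frame_kind = "relative-to-previous"`.
#' @export
preprocess_sequence <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame_kind != "absolute-to-initial")
    stop("sequence is already relative-to-previous", call. = FALSE)
  n <- nrow(seq$poses)
  if (n < 2L) stop("need at least 2 frames to form relative poses", call. = FALSE)
  tr <- seq$poses[, 1:3, drop = FALSE]
  qt <- seq$poses[, 4:7, drop = FALSE]
  prev <- 1:(n - 1L); curr <- 2:n
  q_rel <- quat_mul(quat_conj(qt[prev, , drop = FALSE]),
                    qt[curr, , drop = FALSE])
  q_rel <- q_rel / sqrt(rowSums(q_rel^2))
  flip <- q_rel[, 4] < 0
  q_rel[flip, ] <- -q_rel[flip, , drop = FALSE]
  t_rel <- quat_rotate(quat_conj(qt[prev, , drop = FALSE]),
                       tr[curr, , drop = FALSE] - tr[prev, , drop = FALSE])
  out <- matrix(0, n, 7L, dimnames = list(NULL, POSE_COLS))
  out[1L, ] <- identity_pose()
  out[curr, 1:3] <- t_rel
  out[curr, 4:7] <- q_rel
  seq$poses <- out
  seq$frame_kind <- "relative-to-previous"
  seq
}

# scalar reference implementation via explicit SE(3) matrix algebra; the
# vectorized quaternion path above is checked against it in the tests
preprocess_sequence_ref <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- nrow(seq$poses)
  if (n < 2L) stop("need at least 2 frames to form relative poses", call. = FALSE)
  out <- matrix(0, n, 7L, dimnames = list(NULL, POSE_COLS))
  out[1L, ] <- identity_pose()
  P_prev <- pose_to_transform(seq$poses[1L, ])
  for (i in 2:n) {
    P_curr <- pose_to_transform(seq$poses[i, ])
    out[i, ] <- transform_to_pose(relative_pose(P_curr, P_prev))
    P_prev <- P_curr
  }
  seq$poses <- out
  seq$frame_kind <- "relative-to-previous"
  seq
}

#' Reconstruct an absolute trajectory from relative poses
#'
#' Cumulatively composes a previous-frame-relative sequence back into
#' absolute-to-initial poses (the inverse of [preprocess_sequence()] when no
#' clamping has occurred).
#'
#' @param seq a `pose_sequence` with `frame_kind = "relative-to-previous"`.
#' @return A `pose_sequence` with `frame_kind = "absolute-to-initial"`.
#' @export
accumulate_poses <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame_kind != "relative-to-previous")
    stop("accumulate_poses() expects a relative-to-previous sequence", call. = FALSE)
  n <- nrow(seq$poses)
  out <- matrix(0, n, 7L, dimnames = list(NULL, POSE_COLS))
  P <- pose_to_transform(seq$poses[1L, ])
  out[1L, ] <- transform_to_pose(P)
  if (n > 1L) for (i in 2:n) {
    P <- P %*% pose_to_transform(seq$poses[i, ])
    out[i, ] <- transform_to_pose(P)
  }
  seq$poses <- out
  seq$frame_kind <- "absolute-to-initial"
  seq
}

#' Reset glitched relative poses to static
#'
#' Tracking occasionally produces sudden large jumps in the reported pose.
#' Any relative pose whose translation magnitude (Euclidean norm) strictly
#' exceeds `t_max` is reset to static, i.e. replaced by the identity pose (no
#' translation or rotation); all other poses are left untouched. The default
#' `t_max` of 0.1 m reflects the distance a walker can plausibly cover in one
#' 30 Hz frame.
#'
#' @param seq a `pose_sequence` with `frame_kind = "relative-to-previous"`.
#' @param t_max maximum plausible per-frame translation, in meters.
#' @return The clamped `pose_sequence`, with attribute `clamped_frames`
#'   holding the 0-based indices of reset frames.
#' @export
clamp_glitches <- function(seq, t_max = 0.1) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame_kind != "relative-to-previous")
    stop("clamp_glitches() applies to relative-to-previous sequences", call. = FALSE)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  mag <- sqrt(rowSums(seq$poses[, 1:3, drop = FALSE]^2))
  hit <- which(mag > t_max)
  if (length(hit)) {
    seq$poses[hit, ] <- rep(identity_pose(), each = length(hit))
    pg_log("clamp_glitches: reset %d of %d poses (t_max = %g m)",
           length(hit), nrow(seq$poses), t_max)
  }
  attr(seq, "clamped_frames") <- hit - 1L
  seq
}

#' Cut sliding windows from a relative pose sequence
#'
#' Concatenates every `K` consecutive relative poses into a model input
#' window. With the default `K = 60` at 30 Hz each window spans 2 seconds,
#' enough to contain at least one full gait cycle; `stride = 1` yields dense
#' per-frame windows.
#'
#' @param seq a `pose_sequence` with `frame_kind = "relative-to-previous"`.
#' @param K window length in frames.
#' @param stride hop between consecutive window starts, in frames.
#' @return A list of `relative_window` objects (7 x K matrices with
#'   attributes `start_frame` (0-based) and `K`); empty if the sequence is
#'   shorter than `K`.
#' @export
window_sequence <- function(seq, K = 60L, stride = 1L) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$frame_kind != "relative-to-previous")
    stop("window_sequence() applies to relative-to-previous sequences", call. = FALSE)
  K <- as.integer(K); stride <- as.integer(stride)
  if (K < 1L || stride < 1L) stop("K and stride must be >= 1", call. = FALSE)
  L <- nrow(seq$poses)
  if (L < K) {
    warning(sprintf("sequence of %d frames is shorter than K = %d; no windows",
                    L, K), call. = FALSE)
    return(list())
  }
  n_win <- (L - K) %/% stride + 1L
  lapply(seq_len(n_win), function(j) {
    s <- (j - 1L) * stride
    structure(t(seq$poses[(s + 1L):(s + K), , drop = FALSE]),
              start_frame = s, K = K, class = "relative_window")
  })
}
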