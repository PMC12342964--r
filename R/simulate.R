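# Synthetic gait simulator.
#
# Generates labeled absolute pose sequences emulating short straight-line
# walks recorded by a chest-mounted tracker at 30 Hz: a smooth forward
# trajectory along -Z with vertical bob at twice the step frequency, lateral
# sway at the step frequency, small pitch/roll coupling, per-step phase and
# amplitude jitter, and additive sensor noise.  Instability patterns amplify
# and perturb the center-of-mass proxy: medial-lateral (ml) instability
# amplifies lateral sway and roll with alternating per-step offsets,
# anterior-posterior (ap) instability amplifies vertical bob and pitch with
# per-step dips, and the combined pattern applies both, blended by a
# subject-specific balance parameter so that some subjects' combined gait
# leans ml-like and others ap-like.

#' Draw per-subject kinematic parameters
#'
#' Samples a subject's gait parameters from documented uniform ranges:
#' walking speed 0.9-1.4 m/s, step frequency 1.6-2.1 Hz, vertical bob
#' amplitude 0.015-0.035 m, lateral sway amplitude 0.01-0.03 m, instability
#' gains 1.8-2.8, per-step phase jitter 0.05-0.15 rad and sensor noise
#' 0.001-0.003 per component.  Subjects perform instability patterns more
#' slowly than normal walking (speed factor 0.55-0.75), and a combined-balance
#' parameter in 0.3-0.7 sets how much their combined pattern leans toward the
#' ml (1) versus ap (0) signature.
#'
#' @param rng_seed integer seed; the draw is a pure function of it.
#' @param subject_id optional identifier stored with the parameters.
#' @return An object of class `subject_params`.
#' @export
sample_subject <- function(rng_seed, subject_id = sprintf("subj%05d", rng_seed)) {
  p <- with_seed(rng_seed, list(
    subject_id = subject_id,
    walk_speed = runif(1, 0.9, 1.4),
    step_freq = runif(1, 1.6, 2.1),
    bob_amp = runif(1, 0.015, 0.035),
    sway_amp = runif(1, 0.01, 0.03),
    ap_gain = runif(1, 1.8, 2.8),
    ml_gain = runif(1, 1.8, 2.8),
    phase_jitter = runif(1, 0.05, 0.15),
    sensor_noise = runif(1, 0.001, 0.003),
    unstable_speed_factor = runif(1, 0.55, 0.75),
    combined_balance = runif(1, 0.3, 0.7),
    pitch_amp = runif(1, 0.03, 0.06),
    roll_amp = runif(1, 0.03, 0.06),
    bob_phase = runif(1, 0, 2 * pi),
    rng_seed = as.integer(rng_seed)
  ))
  structure(p, class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> %s: speed %.2f m/s, step %.2f Hz, bob %.3f m, sway %.3f m\n",
              x$subject_id, x$walk_speed, x$step_freq, x$bob_amp, x$sway_amp))
  invisible(x)
}

# piecewise-constant per-step value, indexed by step number (0-based)
step_value <- function(vals, step_idx) vals[pmin(step_idx + 1L, length(vals))]

#' Simulate one labeled walking trial
#'
#' Generates an absolute-to-initial pose sequence for a straight walk of
#' `distance_m` meters sampled at `rate_hz`. Pose 0 is exactly the identity;
#' forward progress accumulates along -Z. Instability trials are walked at
#' the subject's reduced instability speed, so they span more frames than
#' normal trials of the same distance.
#'
#' @param subject a `subject_params` object from [sample_subject()].
#' @param label walking-pattern label: `"normal"`, `"ml"`, `"ap"` or
#'   `"combined"`.
#' @param distance_m walk length in meters (default 8).
#' @param rate_hz sampling rate in Hz (default 30).
#' @param seed integer seed for the trial's stochastic components (per-step
#'   jitter and sensor noise); defaults to the subject's own seed.
#' @return A `pose_sequence` with `frame_kind = "absolute-to-initial"`.
#' @export
simulate_walk <- function(subject, label, distance_m = 8, rate_hz = 30,
                          seed = subject$rng_seed) {
  stopifnot(inherits(subject, "subject_params"))
  label <- match.arg(label, GAIT_LABELS)
  if (!is.numeric(distance_m) || distance_m <= 0) stop("distance_m must be > 0", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)

  speed <- subject$walk_speed *
    (if (label == "normal") 1 else subject$unstable_speed_factor)
  n <- max(1L, floor(distance_m / speed * rate_hz) + 1L)
  t <- (seq_len(n) - 1L) / rate_hz

  # pattern gains: how strongly the ml / ap signatures are expressed
  w <- subject$combined_balance
  g_ml <- switch(label, normal = 1, ap = 1, ml = subject$ml_gain,
                 combined = 1 + (subject$ml_gain - 1) * 2 * w)
  g_ap <- switch(label, normal = 1, ml = 1, ap = subject$ap_gain,
                 combined = 1 + (subject$ap_gain - 1) * 2 * (1 - w))

  poses <- with_seed(seed, {
    f <- subject$step_freq
    n_steps <- floor(f * t[n]) + 2L
    # cumulative per-step phase jitter keeps the oscillation phase-continuous
    jit <- cumsum(rnorm(n_steps, 0, subject$phase_jitter))
    step_idx <- pmin(floor(f * t), n_steps - 1L)
    phi <- 2 * pi * f * t + step_value(jit, step_idx)

    # per-step perturbations, only active when the corresponding gain > 1
    ml_off <- (-1)^(seq_len(n_steps) - 1L) *
      subject$sway_amp * (g_ml - 1) * runif(n_steps, 0.6, 1.2)
    ap_dip <- subject$bob_amp * (g_ap - 1) * abs(rnorm(n_steps, 0.6, 0.3))
    amp_mod_ml <- 1 + (g_ml - 1) * 0.2 * rnorm(n_steps)
    amp_mod_ap <- 1 + (g_ap - 1) * 0.2 * rnorm(n_steps)

    x <- g_ml * subject$sway_amp * step_value(amp_mod_ml, step_idx) * sin(phi) +
      (g_ml > 1) * step_value(ml_off, step_idx)
    y <- g_ap * subject$bob_amp * step_value(amp_mod_ap, step_idx) *
      sin(2 * phi + subject$bob_phase) -
      (g_ap > 1) * step_value(ap_dip, step_idx)
    # forward progress with mild within-step speed modulation
    z <- -speed * t - 0.2 * speed / (2 * pi * f) * sin(phi + 0.7)

    roll <- g_ml * subject$roll_amp * sin(phi + 0.4) +
      (g_ml > 1) * step_value(ml_off, step_idx) * 2
    pitch <- g_ap * subject$pitch_amp * sin(2 * phi + subject$bob_phase + 0.3) +
      (g_ap > 1) * step_value(ap_dip, step_idx) * 1.5
    yaw <- 0.02 * sin(phi + 1.1)

    # small-angle quaternion: pitch about X, yaw about Y, roll about Z
    q <- euler_to_quat(pitch, yaw, roll)
    out <- cbind(x, y, z, q)
    out[, 1:3] <- out[, 1:3] + matrix(rnorm(3 * n, 0, subject$sensor_noise), n)
    out[, 4:7] <- out[, 4:7] + matrix(rnorm(4 * n, 0, subject$sensor_noise), n)
    out
  })
  qn <- sqrt(rowSums(poses[, 4:7, drop = FALSE]^2))
  poses[, 4:7] <- poses[, 4:7] / qn
  flip <- poses[, 7] < 0
  poses[flip, 4:7] <- -poses[flip, 4:7]

  # re-express relative to the first pose so pose 0 is exactly the identity
  q0c <- quat_conj(poses[1L, 4:7, drop = FALSE])[rep(1L, nrow(poses)), ,
                                                 drop = FALSE]
  t0 <- poses[rep(1L, nrow(poses)), 1:3, drop = FALSE]
  poses[, 1:3] <- quat_rotate(q0c, poses[, 1:3, drop = FALSE] - t0)
  poses[, 4:7] <- quat_mul(q0c, poses[, 4:7, drop = FALSE])
  flip <- poses[, 7] < 0
  poses[flip, 4:7] <- -poses[flip, 4:7]
  poses[1L, ] <- identity_pose()

  pose_sequence(poses, rate_hz = rate_hz, subject_id = subject$subject_id,
                label = label, frame_kind = "absolute-to-initial")
}

# quaternion from small Euler angles (X, then Y, then Z axis), vectorized
euler_to_quat <- function(ax, ay, az) {
  cx <- cos(ax / 2); sx <- sin(ax / 2)
  cy <- cos(ay / 2); sy <- sin(ay / 2)
  cz <- cos(az / 2); sz <- sin(az / 2)
  cbind(rx = sx * cy * cz - cx * sy * sz,
        ry = cx * sy * cz + sx * cy * sz,
        rz = cx * cy * sz - sx * sy * cz,
        rw = cx * cy * cz + sx * sy * sz)
}

#' Inject tracking-jump glitches into an absolute sequence
#'
#' Adds a step discontinuity of magnitude `jump_m` (in a random direction) to
#' the translation of `n_glitches` distinct frames and all frames after them,
#' emulating the sudden large jumps a visual-inertial tracker occasionally
#' produces. After [preprocess_sequence()], each glitch shows up as exactly
#' one relative pose with translation magnitude `jump_m`-ish, which
#' [clamp_glitches()] can reset.
#'
#' @param seq an absolute-to-initial `pose_sequence`.
#' @param n_glitches number of glitches to inject (`>= 0`).
#' @param jump_m jump magnitude in meters; must exceed 0.1 so the glitch is
#'   clampable at the default threshold.
#' @param seed integer seed controlling glitch frames and directions.
#' @return The glitched `pose_sequence`, with attribute `glitch_frames`
#'   (0-based frame indices).
#' @export
inject_glitches <- function(seq, n_glitches, jump_m = 0.5, seed = 1L) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (n_glitches < 0) stop("n_glitches must be >= 0", call. = FALSE)
  if (jump_m <= 0.1) stop("jump_m must exceed 0.1 m", call. = FALSE)
  n <- nrow(seq$poses)
  if (n_glitches > n - 1L)
    stop("n_glitches exceeds the number of non-initial frames", call. = FALSE)
  if (n_glitches == 0L) {
    attr(seq, "glitch_frames") <- integer(0)
    return(seq)
  }
  with_seed(seed, {
    frames <- sort(sample(2:n, n_glitches))
    for (k in frames) {
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2)) * jump_m
      seq$poses[k:n, 1:3] <- sweep(seq$poses[k:n, 1:3, drop = FALSE], 2L, d, "+")
    }
    attr(seq, "glitch_frames") <- frames - 1L
    seq
  })
}

#' Generate a labeled, subject-disjoint gait dataset
#'
#' Emulates the walking-trial protocol: every subject performs each walking
#' pattern `trials_per_pattern` times over `distance_m` meters at `rate_hz`.
#' Subjects are split disjointly into train/val/test groups. For each test
#' subject, the first trial of each pattern is tagged `"fine-tune"` (the
#' subject-specific calibration data) and the second `"test"`; all other
#' sequences are tagged `"fit"`.
#'
#' @param n_train_subjects,n_val_subjects,n_test_subjects subject counts per
#'   split (all `>= 1`).
#' @param trials_per_pattern trials each subject performs per pattern
#'   (default 2).
#' @param patterns walking patterns to include; the first three of
#'   `"normal", "ml", "ap", "combined"` give the 3-pattern task, all four the
#'   4-pattern task.
#' @param distance_m,rate_hz trial geometry (defaults 8 m at 30 Hz).
#' @param glitch_rate fraction of sequences receiving one injected tracking
#'   glitch (default 0.05).
#' @param jump_m glitch magnitude in meters.
#' @param rng_seed integer seed; the dataset is a pure function of it.
#' @return An object of class `gait_dataset`: a list with `sequences` (named
#'   list of `pose_sequence`) and `manifest` (data frame with `seq_id`,
#'   `subject_id`, `label`, `split`, `role`).
#' @export
make_dataset <- function(n_train_subjects, n_val_subjects, n_test_subjects,
                         trials_per_pattern = 2L,
                         patterns = c("normal", "ml", "ap"),
                         distance_m = 8, rate_hz = 30,
                         glitch_rate = 0.05, jump_m = 0.5, rng_seed = 1L) {
  counts <- c(n_train_subjects, n_val_subjects, n_test_subjects)
  if (any(counts < 1L) || trials_per_pattern < 1L)
    stop("all subject counts and trials_per_pattern must be >= 1", call. = FALSE)
  patterns <- match.arg(patterns, GAIT_LABELS, several.ok = TRUE)
  n_sub <- sum(counts)
  split <- rep(c("train", "val", "test"), counts)

  seeds <- with_seed(rng_seed, sample.int(99999989L, n_sub * (1L + 2L *
    length(patterns) * trials_per_pattern)))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  sequences <- list()
  rows <- list()
  for (s in seq_len(n_sub)) {
    sid <- sprintf("S%03d", s)
    subject <- sample_subject(next_seed(), subject_id = sid)
    for (lab in patterns) {
      for (trial in seq_len(trials_per_pattern)) {
        sq <- simulate_walk(subject, lab, distance_m, rate_hz,
                            seed = next_seed())
        gseed <- next_seed()
        if ((gseed %% 1e6) / 1e6 < glitch_rate)
          sq <- inject_glitches(sq, 1L, jump_m, seed = gseed)
        role <- if (split[s] == "test") {
          if (trial == 1L) "fine-tune" else "test"
        } else "fit"
        seq_id <- sprintf("%s_%s_t%d", sid, lab, trial)
        sequences[[seq_id]] <- sq
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, subject_id = sid, label = lab,
          split = split[s], role = role, n_frames = nrow(sq$poses),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(sequences = sequences,
                 manifest = do.call(rbind, rows),
                 patterns = patterns, rate_hz = rate_hz,
                 distance_m = distance_m, rng_seed = as.integer(rng_seed)),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d sequences, %d subjects, patterns: %s\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              paste(x$patterns, collapse = ", ")))
  print(table(x$manifest$split, x$manifest$label))
  invisible(x)
}
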