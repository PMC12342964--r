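# synthetic gait generator: determinism, documented ranges, pattern
# signatures, glitch injection, dataset protocol

test_that("subject sampling is deterministic and respects documented ranges", {
  expect_identical(sample_subject(0), sample_subject(0))
  subs <- lapply(1:200, sample_subject)
  rng <- function(f) range(vapply(subs, `[[`, 0, f))
  expect_true(all(rng("walk_speed") >= 0.9 & rng("walk_speed") <= 1.4))
  expect_true(all(rng("step_freq") >= 1.6 & rng("step_freq") <= 2.1))
  expect_true(all(rng("bob_amp") >= 0.015 & rng("bob_amp") <= 0.035))
  expect_true(all(rng("sway_amp") >= 0.01 & rng("sway_amp") <= 0.03))
  expect_true(all(rng("ap_gain") >= 1.8 & rng("ap_gain") <= 2.8))
  expect_true(all(rng("ml_gain") >= 1.8 & rng("ml_gain") <= 2.8))
  # distinct seeds give distinct parameter draws
  expect_gt(length(unique(vapply(subs, `[[`, 0, "walk_speed"))), 190)
})

test_that("simulated walks start at identity and cover the distance forward", {
  s <- sample_subject(10)
  sq <- simulate_walk(s, "normal", distance_m = 8, rate_hz = 30)
  expect_s3_class(sq, "pose_sequence")
  expect_equal(unname(sq$poses[1, ]), c(0, 0, 0, 0, 0, 0, 1))
  n <- nrow(sq$poses)
  expect_equal(n, floor(8 / s$walk_speed * 30) + 1)
  # net displacement is ~8 m along -Z in the initial-pose frame
  expect_lt(abs(-sq$poses[n, 3] - 8), 0.5)
  expect_lt(max(abs(sq$poses[n, 1:2])), 0.5)
  # quaternions all unit within 1e-6 (constructor renormalizes; check raw)
  expect_lt(max(abs(sqrt(rowSums(sq$poses[, 4:7]^2)) - 1)), 1e-6)
  # degenerate distance still yields a valid one-pose-or-more sequence
  tiny <- simulate_walk(s, "normal", distance_m = 1e-4)
  expect_gte(nrow(tiny$poses), 1)
  expect_equal(unname(tiny$poses[1, ]), c(0, 0, 0, 0, 0, 0, 1))
  expect_error(simulate_walk(s, "sideways"), "arg")
})

test_that("instability trials are slower, hence longer, than normal trials", {
  s <- sample_subject(21)
  n_normal <- nrow(simulate_walk(s, "normal")$poses)
  n_ml <- nrow(simulate_walk(s, "ml")$poses)
  expect_gt(n_ml, n_normal)
})

test_that("pattern signatures show in relative-translation variability", {
  rel_sds <- function(seed) {
    s <- sample_subject(seed)
    out <- sapply(c("normal", "ml", "ap", "combined"), function(lab) {
      r <- preprocess_sequence(simulate_walk(s, lab, seed = seed + 7))
      c(lat = sd(r$poses[-1, "tx"]), vert = sd(r$poses[-1, "ty"]))
    })
    out
  }
  # per-subject strict contrasts (the DERIVED paired checks)
  m <- rel_sds(101)
  expect_gt(m["lat", "ml"], m["lat", "normal"])
  expect_gt(m["vert", "ap"], m["vert", "normal"])
  # orthogonal-contrast property averaged over many subjects: ml & combined
  # exceed normal & ap laterally; ap & combined exceed normal & ml vertically
  ms <- sapply(1:20, function(i) rel_sds(1000 + i), simplify = "array")
  lat <- rowMeans(ms["lat", , ]); vert <- rowMeans(ms["vert", , ])
  expect_gt(min(lat["ml"], lat["combined"]), max(lat["normal"], lat["ap"]))
  expect_gt(min(vert["ap"], vert["combined"]), max(vert["normal"], vert["ml"]))
})

test_that("glitch injection creates exactly the requested clampable jumps", {
  s <- sample_subject(31)
  sq <- simulate_walk(s, "normal")
  expect_identical(inject_glitches(sq, 0, seed = 1)$poses, sq$poses)
  g1 <- inject_glitches(sq, 1, jump_m = 0.5, seed = 5)
  rel <- preprocess_sequence(g1)
  mag <- sqrt(rowSums(rel$poses[, 1:3]^2))
  expect_equal(sum(mag > 0.1), 1L)
  # clamped glitched sequence equals clamped clean sequence away from glitches
  rel_clean <- clamp_glitches(preprocess_sequence(sq), 0.1)
  rel_clamp <- clamp_glitches(rel, 0.1)
  glitch_frame <- attr(g1, "glitch_frames") + 1L
  keep <- setdiff(seq_len(nrow(sq$poses)), glitch_frame)
  expect_lt(max(abs(rel_clamp$poses[keep, ] - rel_clean$poses[keep, ])), 1e-9)
  expect_error(inject_glitches(sq, nrow(sq$poses) + 5, seed = 1), "exceeds")
  expect_error(inject_glitches(sq, 1, jump_m = 0.05, seed = 1), "exceed 0.1")
})

test_that("dataset generation follows the two-trials-per-pattern protocol", {
  ds <- make_dataset(10, 3, 3, patterns = c("normal", "ml", "ap", "combined"),
                     rng_seed = 99)
  man <- ds$manifest
  expect_equal(nrow(man), (10 + 3 + 3) * 4 * 2)  # 128 sequences
  # subject-disjoint splits
  tab <- unique(man[, c("subject_id", "split")])
  expect_false(any(duplicated(tab$subject_id)))
  # fine-tune / test tagging: one trial each per pattern for test subjects
  test_man <- man[man$split == "test", ]
  ft <- table(test_man$subject_id, test_man$role)
  expect_true(all(ft[, "fine-tune"] == 4))
  expect_true(all(ft[, "test"] == 4))
  expect_true(all(man$role[man$split != "test"] == "fit"))
})

test_that("dataset generation is a pure function of its seed", {
  d1 <- make_dataset(2, 1, 1, rng_seed = 7)
  d2 <- make_dataset(2, 1, 1, rng_seed = 7)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(lapply(d1$sequences, `[[`, "poses"),
                   lapply(d2$sequences, `[[`, "poses"))
  d3 <- make_dataset(2, 1, 1, rng_seed = 8)
  expect_false(identical(d1$sequences[[1]]$poses, d3$sequences[[1]]$poses))
})
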