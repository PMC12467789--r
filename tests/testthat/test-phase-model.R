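test_that("contralateral coupling is the documented involution", {
  expect_identical(contralateral_phase(1), 3L)
  expect_identical(contralateral_phase(2), 0L)
  expect_identical(contralateral_phase(0), 2L)
  expect_identical(contralateral_phase(3), 1L)
  for (p in 0:3)
    expect_identical(contralateral_phase(contralateral_phase(p)), p)
  expect_error(contralateral_phase(4), "phase code")
})

test_that("stage_of maps legal pairs and rejects illegal ones", {
  s <- stage_of(2, 0)
  expect_equal(s$name, "Gait20")
  expect_equal(s$class, 1L)
  expect_equal(stage_of(1, 3)$name, "Gait13")
  expect_equal(stage_of(1, 3)$class, 4L)
  expect_equal(stage_of(3, 1)$class, 2L)
  expect_equal(stage_of(0, 2)$class, 3L)
  err <- tryCatch(stage_of(0, 0), error = conditionMessage)
  expect_match(err, "left=0")
  expect_match(err, "right=0")
  expect_error(stage_of(1, 0), "illegal")
})

test_that("stages advance cyclically with period four", {
  expect_equal(next_stage("Gait31")$name, "Gait02")
  expect_equal(next_stage("Gait02")$name, "Gait13")
  expect_equal(next_stage("Gait13")$name, "Gait20")
  expect_equal(next_stage("Gait20")$name, "Gait31")
  for (nm in c("Gait20", "Gait31", "Gait02", "Gait13")) {
    out <- nm
    for (i in 1:4) out <- next_stage(out)$name
    expect_equal(out, nm)
    expect_equal(prev_stage(next_stage(nm))$name, nm)
  }
})

test_that("labeler recovers simulator ground truth on noiseless gait", {
  rec <- fixture_recording("normal", duration = 20, noise_sd = 0)
  lab <- fixture_labels(rec)
  agree <- mean(lab$phase_left == rec$phase_left &
                lab$phase_right == rec$phase_right)
  expect_gte(agree, 0.99)
  # pathological patterns: foot-drop and staggering stay exact; scissor's
  # boundaries are blurred by clip saturation and degrade gracefully
  for (p in c("foot_drop", "staggering")) {
    r <- fixture_recording(p, duration = 20, noise_sd = 0)
    l <- fixture_labels(r)
    expect_gte(mean(l$phase_left == r$phase_left &
                    l$phase_right == r$phase_right), 0.99)
  }
  r <- fixture_recording("scissor", duration = 20, noise_sd = 0)
  l <- fixture_labels(r)
  expect_gte(mean(l$phase_left == r$phase_left &
                  l$phase_right == r$phase_right), 0.90)
})

test_that("degenerate and forced inputs follow the documented rules", {
  # constant input: no events, tie rule (0, 2) everywhere, always legal
  lab <- label_phases(rep(60, 50), rep(60, 50))
  expect_true(all(lab$phase_left == 0L))
  expect_true(all(lab$phase_right == 2L))
  # strictly increasing left ramp forces left swing / right stance
  n <- 60
  lab <- label_phases(seq(0, 59), rep(60, n))
  w <- 10  # after the arming transient
  expect_true(all(lab$phase_left[w:n] == 2L))
  expect_true(all(lab$phase_right[w:n] == 0L))
  expect_error(label_phases(1:3, 1:3, labeler_config(trend_window = 5)),
               "trend_window")
  expect_error(label_phases(1:10, 1:5), "equal length")
})

test_that("labeler is side-symmetric on simulated recordings", {
  rec <- fixture_recording("foot_drop", duration = 15, noise_sd = 0)
  sag <- sagittal_channels(rec)
  lab <- label_phases(sag$left, sag$right)
  mir <- label_phases(sag$right, sag$left)
  expect_identical(mir$phase_left, lab$phase_right)
  expect_identical(mir$phase_right, lab$phase_left)
})

test_that("toe-off detection scans 1->2 transitions", {
  # series (1-based indexing): transitions into swing at positions 3 and 7
  expect_identical(detect_toe_off(c(1, 1, 2, 2, 0, 1, 2)), c(3L, 7L))
  expect_identical(detect_toe_off(c(0, 0, 2, 2)), integer(0))
  expect_identical(detect_toe_off(integer(0)), integer(0))
  # on noiseless simulations detected events sit on true-phase resets
  rec <- fixture_recording("normal", duration = 20, noise_sd = 0)
  lab <- fixture_labels(rec)
  ev <- detect_toe_off(lab$phase_left)
  resets <- which(rec$true_phase == 0)
  expect_true(all(vapply(ev, function(i) min(abs(resets - i)), 1) <= 1))
})

test_that("every labeled frame is a legal stage and stages follow order", {
  for (p in c("normal", "scissor", "foot_drop", "staggering")) {
    rec <- fixture_recording(p, duration = 15)
    lab <- fixture_labels(rec)
    # stage_of errors on any illegal pair, so this loop is the assertion
    seqs <- stage_sequence(lab$phase_left, lab$phase_right)
    expect_true(length(seqs) > 4)
    for (i in seq_len(length(seqs) - 1L))
      expect_equal(next_stage(seqs[i])$name, seqs[i + 1L])
  }
})
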