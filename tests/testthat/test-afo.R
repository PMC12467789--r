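test_that("reconstruction is the harmonic sum plus offset", {
  expect_equal(afo_reconstruct(afo_state(alpha = 0, alpha0 = 7)), 7)
  expect_equal(afo_reconstruct(afo_state(n_osc = 1, alpha = 2,
                                         phases = pi / 2, alpha0 = 0)), 2)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    st <- afo_state(n_osc = n, omega = runif(1, 1, 10),
                    phases = runif(n, 0, 2 * pi),
                    alpha = rnorm(n, sd = 5), alpha0 = rnorm(1, sd = 5))
    oracle <- sum(vapply(seq_len(n), function(k)
      st$alpha[k] * sin(st$phases[k]), 1)) + st$alpha0
    expect_lt(abs(afo_reconstruct(st) - oracle), 1e-12)
  }
})

test_that("a single adaptation step matches hand arithmetic", {
  st <- afo_state(n_osc = 1, phases = 0, omega = 2 * pi, alpha = 1,
                  alpha0 = 0, gain_phase = 1, gain_freq = 1, gain_amp = 1)
  out <- afo_step(st, theta_t = 1, dt = 0.01)
  # e = 1 - (1 * sin(0) + 0) = 1
  expect_lt(abs(out$phases[1] - 0.01 * (2 * pi + 1)), 1e-12)
  expect_lt(abs(out$omega - (2 * pi + 0.01)), 1e-12)
  expect_lt(abs(out$alpha[1] - 1), 1e-12)    # sin(0) = 0: amplitude frozen
  expect_lt(abs(out$alpha0 - 0.01), 1e-12)
  expect_error(afo_step(st, NaN, 0.01), "non-finite")
  expect_error(afo_step(st, 1, 0), "dt")
})

test_that("zero tracking error freezes the learned quantities", {
  st <- afo_state(n_osc = 3, phases = c(0.3, 0.7, 1.1), omega = 5,
                  alpha = c(4, 2, 1), alpha0 = 60)
  out <- afo_step(st, afo_reconstruct(st), dt = 0.01)
  expect_equal(out$omega, st$omega)
  expect_equal(out$alpha, st$alpha)
  expect_equal(out$alpha0, st$alpha0)
  expect_equal(out$phases, (st$phases + 0.01 * (1:3) * 5) %% (2 * pi))
})

test_that("phase percent wraps the first oscillator onto 0-100", {
  expect_equal(afo_phase_percent(afo_state(phases = 0)), 0)
  expect_equal(afo_phase_percent(afo_state(phases = 3 * pi)), 50)
  expect_lt(afo_phase_percent(afo_state(phases = 2 * pi - 1e-9)), 100)
  expect_gt(afo_phase_percent(afo_state(phases = 2 * pi - 1e-3)), 99.9)
  for (k in -2:2)
    expect_equal(afo_phase_percent(afo_state(phases = 1 + 2 * pi * k)),
                 afo_phase_percent(afo_state(phases = 1)))
})

test_that("explicit Euler at the sample rate tracks a refined integrator", {
  theta_fun <- function(t) 2 * sin(2 * pi * t) + 5
  run_at <- function(fs, Tend) {
    st <- afo_state(omega = 2 * pi * 0.9, alpha = c(1, 0, 0), alpha0 = 5)
    dt <- 1 / fs
    for (t in seq(0, Tend - dt, by = dt))
      st <- afo_step(st, theta_fun(t), dt)
    st
  }
  coarse <- run_at(500, 1)
  fine <- run_at(500 * 100, 1)
  expect_lt(max(abs(coarse$phases - fine$phases)), 1e-3)
  expect_lt(abs(coarse$omega - fine$omega), 1e-3)
  expect_lt(max(abs(coarse$alpha - fine$alpha)), 1e-3)
  expect_lt(abs(coarse$alpha0 - fine$alpha0), 1e-3)
})

test_that("the pool recovers the frequency of a pure sinusoid", {
  t <- seq(0, 30, by = 0.01)
  theta <- 10 * sin(2 * pi * 1 * t) + 60
  init <- afo_state(omega = 0.8 * 2 * pi, alpha = c(sd(theta), 0, 0),
                    alpha0 = mean(theta))
  tr <- afo_run(theta, 100, init = init)
  expect_lt(abs(tr$final_state$omega / (2 * pi) - 1), 0.02)
})

test_that("tracking error RMS decreases over successive cycles", {
  t <- seq(0, 20, by = 0.01)
  theta <- 10 * sin(2 * pi * t) + 60
  tr <- afo_run(theta, 100,
                init = afo_state(omega = 2 * pi * 0.85,
                                 alpha = c(sd(theta), 0, 0),
                                 alpha0 = mean(theta)))
  e <- theta - tr$theta_hat
  rms <- vapply(split(e, floor(t)), function(z) sqrt(mean(z^2)), 1)
  expect_lt(rms[length(rms) - 1], 0.25 * rms[1])
  expect_true(all(diff(rms[2:15]) < 0))
})

test_that("toe-off resets pin the trace to zero and bound the error", {
  rec <- fixture_recording("foot_drop", duration = 30, noise_sd = 0)
  ev <- which(rec$true_phase == 0)
  tr <- afo_run(sagittal_channels(rec)$left, rec$sample_rate,
                toe_off_events = ev)
  expect_true(all(tr$phi[ev] == 0))
  i0 <- ev[6]; n <- length(tr$phi)       # after a 5-cycle transient
  expect_lt(circular_phase_error(tr$phi[i0:n], rec$true_phase[i0:n]), 10)
  expect_error(afo_run(rec$ankle[, "L_ay"], 100, toe_off_events = 10^7),
               "out of range")
})

test_that("the phase-zeroing reset variant remains available", {
  rec <- fixture_recording("normal", duration = 10, noise_sd = 0)
  ev <- which(rec$true_phase == 0)
  tr <- afo_run(sagittal_channels(rec)$left, 100, ev, reset_mode = "zero")
  expect_true(all(tr$phi[ev] == 0))
  expect_true(all(tr$phi >= 0 & tr$phi < 100))
})
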