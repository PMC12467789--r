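# Synthetic bilateral gait generator.
#
# Each recording is built cycle by cycle, anchored at left toe-off.  Within
# a cycle the left leg passes through swing, swing termination, stance and
# pre-swing; the right leg is the contralateral mirror (stance, pre-swing,
# swing, termination), so every frame forms a legal walking stage by
# construction.  Sagittal ankle waveforms are piecewise smoothstep curves
# (flat stance plateau, pre-swing descent to the toe-off minimum, swing
# ascent to the heel-strike maximum, termination descent back to the
# plateau).  Segment boundaries are quantized to the sample grid so that
# ground-truth labels, extrema and continuous phase coincide exactly on the
# noiseless template; Gaussian sensor noise is added last.

.gait_patterns <- c("normal", "scissor", "foot_drop", "staggering")

# Sagittal waveform control values, degrees.  These are artifact constants
# shaped after typical ankle Euler-angle traces: a mid-range stance plateau,
# a pronounced heel-strike peak on healthy legs, a suppressed peak on the
# foot-drop affected side, and a raw scissor template that saturates against
# the configured clip band.
.wave_params <- function(pattern, cfg) {
  base <- list(vmin = 40, vmax = 90, plateau = 65)
  switch(pattern,
    normal = list(left = base, right = base),
    scissor = {
      w <- list(vmin = 48, vmax = 83, plateau = 78)
      list(left = w, right = w)
    },
    foot_drop = list(
      left  = list(vmin = 40, vmax = 72, plateau = 65),  # no heel-strike peak
      right = base
    ),
    staggering = list(
      left  = list(vmin = 55, vmax = 55 + cfg$ascend_range_affected,
                   plateau = 65),
      right = list(vmin = 55, vmax = 55 + cfg$ascend_range_healthy,
                   plateau = 65)
    )
  )
}

#' Simulation configuration for synthetic gait recordings
#'
#' Houses the pattern-specific characteristics of the three pathological
#' gaits: the scissor ankle range confined to a narrow clip band with a
#' blurred stance/pre-swing boundary; foot-drop with a short affected-side
#' stance (uniform 150-200 ms around a 175 ms mean by default) against a
#' long healthy-side stance / affected-side swing (uniform 350-700 ms), and
#' a suppressed heel-strike maximum on the affected side; staggering with a
#' reduced affected-side ascending (swing) range of 19.60 degrees against
#' 29.64 degrees on the healthy side, plus strong cycle-to-cycle timing
#' jitter.  Foot-drop and staggering are unilateral with the affected side
#' on the left; scissor is bilaterally symmetric.
#'
#' @param pattern One of `"normal"`, `"scissor"`, `"foot_drop"`,
#'   `"staggering"`.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Recording length, seconds; must cover at least two mean
#'   cycles.
#' @param mean_cycle Mean gait-cycle duration, seconds (ignored for
#'   foot-drop, whose cycle duration follows from the stance draws).
#' @param cycle_jitter_cv Coefficient of variation of the cycle duration.
#'   `NULL` selects a pattern default: 0.12 for staggering (irregular step
#'   timing), 0.05 otherwise.
#' @param noise_sd Additive Gaussian sensor noise, degrees, applied to all
#'   angle channels after the template is built.
#' @param affected_stance_ms,healthy_stance_ms Mean stance durations (ms)
#'   for the foot-drop affected and healthy sides; draws are uniform within
#'   +/- 25 ms and +/- 175 ms of the respective means.
#' @param ankle_range_clip Two ordered degrees; the scissor sagittal ankle
#'   template is hard-clipped into this band.
#' @param ascend_range_affected,ascend_range_healthy Swing ascent ranges
#'   (degrees) of the staggering affected/healthy sides.
#' @param seed Integer seed; a recording is a deterministic function of its
#'   configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pattern = "normal", sample_rate = 100, duration = 30,
                       mean_cycle = 1.0, cycle_jitter_cv = NULL,
                       noise_sd = 0.5,
                       affected_stance_ms = 175, healthy_stance_ms = 525,
                       ankle_range_clip = c(50, 80),
                       ascend_range_affected = 19.60,
                       ascend_range_healthy = 29.64,
                       seed = 1L) {
  pattern <- match.arg(pattern, .gait_patterns)
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (duration < 2 * mean_cycle)
    stop("duration must cover at least two mean cycles", call. = FALSE)
  if (is.null(cycle_jitter_cv))
    cycle_jitter_cv <- if (pattern == "staggering") 0.12 else 0.05
  if (cycle_jitter_cv < 0 || cycle_jitter_cv >= 0.5)
    stop("cycle_jitter_cv must lie in [0, 0.5)", call. = FALSE)
  if (length(ankle_range_clip) != 2L ||
      ankle_range_clip[1] >= ankle_range_clip[2])
    stop("ankle_range_clip must be an ordered pair", call. = FALSE)
  structure(list(
    pattern = pattern, sample_rate = sample_rate, duration = duration,
    mean_cycle = mean_cycle, cycle_jitter_cv = cycle_jitter_cv,
    noise_sd = noise_sd,
    affected_stance_ms = affected_stance_ms,
    healthy_stance_ms = healthy_stance_ms,
    ankle_range_clip = ankle_range_clip,
    ascend_range_affected = ascend_range_affected,
    ascend_range_healthy = ascend_range_healthy,
    seed = as.integer(seed)), class = "sim_config")
}

# cubic smoothstep: C1 ramp with zero slope at both ends
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Draw integer segment lengths (frames) for one cycle.
# Left-leg order: swing s1, termination s2, stance s3, pre-swing s4.
.draw_cycle <- function(cfg) {
  fs <- cfg$sample_rate
  if (cfg$pattern == "foot_drop") {
    s_aff <- stats::runif(1, cfg$affected_stance_ms - 25,
                          cfg$affected_stance_ms + 25) / 1000
    s_hea <- stats::runif(1, cfg$healthy_stance_ms - 175,
                          cfg$healthy_stance_ms + 175) / 1000
    D <- max(20L, round((s_aff + s_hea) / 0.8 * fs))
    s1 <- max(2L, round(s_hea * fs))          # L swing = R (healthy) stance
    s3 <- max(2L, round(s_aff * fs))          # L (affected) stance
    s2 <- max(1L, round(0.1 * D))
    s4 <- max(1L, D - s1 - s2 - s3)
  } else {
    d <- stats::rnorm(1, cfg$mean_cycle, cfg$cycle_jitter_cv * cfg$mean_cycle)
    d <- min(max(d, 0.5 * cfg$mean_cycle), 1.5 * cfg$mean_cycle)
    D <- max(20L, round(d * fs))
    s1 <- round(0.4 * D); s2 <- round(0.1 * D); s3 <- round(0.4 * D)
    s4 <- max(1L, D - s1 - s2 - s3)
  }
  c(s1, s2, s3, s4)
}

# Piecewise sagittal waveform over one cycle of integer segments `seg`,
# for the leg whose cycle starts at its own toe-off when `swing_first`,
# or at the contralateral timeline (stance, pre-swing, swing, termination)
# otherwise.  Returns the angle at frames 0..D-1.
.leg_wave <- function(seg, wp, swing_first) {
  s1 <- seg[1]; s2 <- seg[2]; s3 <- seg[3]; s4 <- seg[4]
  if (swing_first) {
    y <- c(
      wp$vmin + (wp$vmax - wp$vmin) * .smoothstep((0:(s1 - 1)) / s1),
      wp$vmax + (wp$plateau - wp$vmax) * .smoothstep((0:(s2 - 1)) / s2),
      rep(wp$plateau, s3),
      wp$plateau + (wp$vmin - wp$plateau) * .smoothstep((0:(s4 - 1)) / s4))
  } else {
    y <- c(
      rep(wp$plateau, s1),
      wp$plateau + (wp$vmin - wp$plateau) * .smoothstep((0:(s2 - 1)) / s2),
      wp$vmin + (wp$vmax - wp$vmin) * .smoothstep((0:(s3 - 1)) / s3),
      wp$vmax + (wp$plateau - wp$vmax) * .smoothstep((0:(s4 - 1)) / s4))
  }
  y
}

# phase labels over one cycle for the left (swing-first) / right timeline
.leg_labels <- function(seg, swing_first) {
  if (swing_first)
    rep(c(2L, 3L, 0L, 1L), seg)
  else
    rep(c(0L, 1L, 2L, 3L), seg)
}

#' Simulate a bilateral gait recording with ground truth
#'
#' Generates synchronized ankle (6 channels: left/right yaw, pitch, roll
#' Euler angles; pitch is the sagittal channel), thigh and shank sagittal
#' channels, exact per-frame phase labels for both legs, and a continuous
#' ground-truth phase in percent that resets to zero exactly at left
#' toe-off frames.  Labels and the continuous phase are derived from the
#' noiseless template, so they remain exact ground truth at any noise
#' level.
#'
#' @param config A [sim_config()].
#' @return A `gait_recording`: list with `t` (seconds), `ankle` (T x 6
#'   matrix, columns `L_ax, L_ay, L_az, R_ax, R_ay, R_az`), `limb` (T x 4
#'   matrix, columns `L_thigh, L_shank, R_thigh, R_shank`), integer vectors
#'   `phase_left`, `phase_right`, numeric `true_phase` in `[0, 100)`,
#'   `pattern` and `sample_rate`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sample_rate
  total <- round(config$duration * fs)

  segs <- list(); D <- integer(0)
  while (sum(D) < total) {
    s <- .draw_cycle(config)
    segs[[length(segs) + 1L]] <- s
    D <- c(D, sum(s))
  }
  if (length(D) < 2L && sum(D[1]) > total)
    stop("duration too short for one full gait cycle", call. = FALSE)

  wp <- .wave_params(config$pattern, config)
  n_cyc <- length(D)
  sag_l <- numeric(0); sag_r <- numeric(0)
  lab_l <- integer(0); lab_r <- integer(0)
  phase <- numeric(0); u_l <- numeric(0); u_r <- numeric(0)
  for (k in seq_len(n_cyc)) {
    s <- segs[[k]]; d <- D[k]
    sag_l <- c(sag_l, .leg_wave(s, wp$left, swing_first = TRUE))
    sag_r <- c(sag_r, .leg_wave(s, wp$right, swing_first = FALSE))
    lab_l <- c(lab_l, .leg_labels(s, TRUE))
    lab_r <- c(lab_r, .leg_labels(s, FALSE))
    iu <- 0:(d - 1)
    phase <- c(phase, 100 * iu / d)
    u_l <- c(u_l, iu / d)
    u_r <- c(u_r, ((iu - (s[1] + s[2])) %% d) / d)  # right leg's own cycle
  }
  keep <- seq_len(min(total, length(sag_l)))
  sag_l <- sag_l[keep]; sag_r <- sag_r[keep]
  lab_l <- lab_l[keep]; lab_r <- lab_r[keep]
  phase <- phase[keep]; u_l <- u_l[keep]; u_r <- u_r[keep]
  n <- length(keep)

  if (config$pattern == "scissor") {
    clip <- config$ankle_range_clip
    sag_l <- pmin(pmax(sag_l, clip[1]), clip[2])
    sag_r <- pmin(pmax(sag_r, clip[1]), clip[2])
  }

  # non-sagittal ankle channels: low-amplitude cycle-locked sinusoids
  yaw_l  <- 5 + 2.5 * sin(2 * pi * u_l + 0.6)
  roll_l <- -3 + 3.5 * sin(2 * pi * u_l + 2.1)
  yaw_r  <- 5 + 2.5 * sin(2 * pi * u_r + 0.6)
  roll_r <- -3 + 3.5 * sin(2 * pi * u_r + 2.1)

  # sagittal thigh/shank targets, smooth cycle-locked curves
  thigh <- function(u) 75 + 12 * sin(2 * pi * u + 0.3) +
    4 * sin(4 * pi * u + 1.1)
  shank <- function(u) 55 + 18 * sin(2 * pi * u - 0.9) +
    5 * sin(4 * pi * u + 0.4)

  ankle <- cbind(L_ax = yaw_l, L_ay = sag_l, L_az = roll_l,
                 R_ax = yaw_r, R_ay = sag_r, R_az = roll_r)
  limb <- cbind(L_thigh = thigh(u_l), L_shank = shank(u_l),
                R_thigh = thigh(u_r), R_shank = shank(u_r))
  if (config$noise_sd > 0) {
    ankle <- ankle + matrix(stats::rnorm(n * 6, 0, config$noise_sd), n, 6)
    limb <- limb + matrix(stats::rnorm(n * 4, 0, config$noise_sd), n, 4)
  }

  structure(list(
    t = (seq_len(n) - 1L) / fs,
    ankle = ankle, limb = limb,
    phase_left = lab_l, phase_right = lab_r,
    true_phase = phase,
    pattern = config$pattern, sample_rate = fs,
    config = config), class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> pattern=%s, %d frames @ %g Hz (%.1f s)\n",
              x$pattern, length(x$t), x$sample_rate,
              length(x$t) / x$sample_rate))
  invisible(x)
}

#' Complete-cycle boundaries of a recording
#'
#' Cycles are delimited by left toe-off, i.e. the frames where the
#' ground-truth continuous phase resets to zero.
#'
#' @param rec A `gait_recording`.
#' @return List of half-open integer intervals `c(start, end)` (1-based,
#'   `end` exclusive) covering consecutive complete cycles; empty if the
#'   recording contains no complete cycle.
#' @export
cycle_boundaries <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  starts <- which(rec$true_phase == 0)
  if (length(starts) < 2L) return(list())
  lapply(seq_len(length(starts) - 1L), function(k)
    c(start = starts[k], end = starts[k + 1L]))
}

#' Sagittal ankle channels of a recording
#'
#' Convenience accessor: the pitch (`*_ay`) columns carry the sagittal
#' Euler angle used for phase labeling and oscillator input.
#'
#' @param rec A `gait_recording`.
#' @return List with numeric vectors `left` and `right`.
#' @export
sagittal_channels <- function(rec) {
  list(left = rec$ankle[, "L_ay"], right = rec$ankle[, "R_ay"])
}
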