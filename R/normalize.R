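# Gait-cycle length normalization.
#
# Cycles from the same gait differ in frame count, so point-by-point
# ensemble statistics require a common length.  Within a phase the sagittal
# angle changes approximately linearly, which justifies plain linear
# interpolation: the longest cycle serves as the reference and every
# shorter cycle is stretched onto its grid.

#' Interpolation points for stretching a series of length n to length m
#'
#' Computes `x_i = i / (m - 1) * (n - 1)` for `i = 0, ..., m - 1`: m evenly
#' spaced query points spanning the knot interval `[0, n - 1]` of the
#' shorter series.
#'
#' @param m Target length (the reference, longest cycle), `m >= n`.
#' @param n Source length, `n >= 2`.
#' @return Numeric vector of length `m`, strictly increasing, with
#'   endpoints 0 and `n - 1`.
#' @export
interp_points <- function(m, n) {
  if (n < 2L) stop("source length n must be >= 2", call. = FALSE)
  if (m < n)
    stop("m must be >= n: the shorter series is the one extended",
         call. = FALSE)
  # multiply before dividing: integer query points (knot hits, and the
  # whole grid when m = n) come out bit-exact
  (seq_len(m) - 1) * (n - 1) / (m - 1)
}

#' Stretch a series to a reference length by linear interpolation
#'
#' Evaluates the piecewise-linear interpolant of `B` (knots at 0, 1, ...,
#' n - 1) at the [interp_points()] grid:
#' `y_i = b_j + (b_{j+1} - b_j) / (x_{j+1} - x_j) * (x_i - x_j)`.
#' When a query point coincides with a knot the knot value is returned
#' exactly, so the first and last samples are always preserved and
#' `m = n` returns the input unchanged.
#'
#' @param B Numeric series of length `n >= 2` (degrees).
#' @param m Target length, `m >= n`.
#' @return Numeric series of length `m`.
#' @export
resample_linear <- function(B, m) {
  n <- length(B)
  x <- interp_points(m, n)
  j <- pmin(floor(x), n - 2)         # left knot index, 0-based
  frac <- x - j
  out <- B[j + 1] + (B[j + 2] - B[j + 1]) * frac
  at_knot <- frac == 0               # exact at knots: no floating drift
  out[at_knot] <- B[j[at_knot] + 1]
  at_right <- frac == 1              # clamped final interval hits knot j+1
  out[at_right] <- B[j[at_right] + 2]
  out
}

#' Ensemble statistics of variable-length gait cycles
#'
#' Resamples every cycle to the length of the longest one, then computes
#' the pointwise ensemble mean and sample standard deviation on a 0-100%
#' cycle axis (the usual "mean +/- standard deviation" summary of gait
#' curves).
#'
#' @param cycles List of >= 2 numeric series, each of length >= 2
#'   (degrees).
#' @return A `cycle_ensemble`: list with `cycles` (the input), `ref_length`,
#'   `aligned` (matrix, one row per cycle), `mean`, `sd` (sample SD,
#'   n - 1 denominator) and `percent` (0-100 axis).
#' @export
ensemble_stats <- function(cycles) {
  if (!is.list(cycles) || length(cycles) < 2L)
    stop("need at least 2 cycles", call. = FALSE)
  if (any(vapply(cycles, length, 1L) < 2L))
    stop("every cycle must have length >= 2", call. = FALSE)
  m <- max(vapply(cycles, length, 1L))
  aligned <- t(vapply(cycles, resample_linear, numeric(m), m = m))
  structure(list(
    cycles = cycles,
    ref_length = m,
    aligned = aligned,
    mean = colMeans(aligned),
    sd = apply(aligned, 2, stats::sd),
    percent = seq(0, 100, length.out = m)), class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf("<cycle_ensemble> %d cycles aligned to %d points\n",
              nrow(x$aligned), x$ref_length))
  invisible(x)
}

#' Extract and summarize one channel of a recording by gait cycle
#'
#' Convenience wrapper: slices `channel` at the recording's cycle
#' boundaries and runs [ensemble_stats()].
#'
#' @param rec A `gait_recording`.
#' @param channel Column name of the ankle or limb matrix (e.g. `"L_ay"`).
#' @return A `cycle_ensemble`.
#' @export
cycle_ensemble_of <- function(rec, channel = "L_ay") {
  cb <- cycle_boundaries(rec)
  if (length(cb) < 2L) stop("recording has fewer than 2 complete cycles",
                            call. = FALSE)
  y <- if (channel %in% colnames(rec$ankle)) rec$ankle[, channel]
       else if (channel %in% colnames(rec$limb)) rec$limb[, channel]
       else stop("unknown channel: ", channel, call. = FALSE)
  ensemble_stats(lapply(cb, function(b) y[b[1]:(b[2] - 1L)]))
}
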