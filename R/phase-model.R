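# Four-phase / four-stage gait scheme with bilateral coupling.
#
# Single-leg phase codes: 0 stance, 1 pre-swing (heel-off to toe-off),
# 2 swing, 3 swing termination (heel-strike to foot-flat).  The two legs are
# rigidly coupled: when one leg is in pre-swing the other is in swing
# termination, and when one leg swings the other stands.  The four legal
# bilateral combinations are the walking stages Gait20, Gait31, Gait02 and
# Gait13 (first digit = left foot phase, second = right foot phase).

.stage_table <- data.frame(
  name  = c("Gait20", "Gait31", "Gait02", "Gait13"),
  left  = c(2L, 3L, 0L, 1L),
  right = c(0L, 1L, 2L, 3L),
  class = c(1L, 2L, 3L, 4L),
  stringsAsFactors = FALSE
)

# cyclic order of stages during forward walking
.stage_cycle <- c("Gait20", "Gait31", "Gait02", "Gait13")

.check_phase <- function(p, arg = "p") {
  if (length(p) != 1L || is.na(p) || !(p %in% 0:3))
    stop(sprintf("`%s` must be a single phase code in {0,1,2,3}, got: %s",
                 arg, paste(p, collapse = ",")), call. = FALSE)
  as.integer(p)
}

#' Contralateral phase of a single-leg gait phase
#'
#' During walking the two legs are phase-locked: pre-swing (1) on one side
#' implies swing termination (3) on the other, and swing (2) implies
#' stance (0).  The map is an involution.
#'
#' @param p Integer phase code in `{0, 1, 2, 3}` (0 stance, 1 pre-swing,
#'   2 swing, 3 swing termination).
#' @return The phase code of the opposite leg.
#' @examples
#' contralateral_phase(1)  # 3
#' contralateral_phase(2)  # 0
#' @export
contralateral_phase <- function(p) {
  p <- .check_phase(p)
  c(`0` = 2L, `1` = 3L, `2` = 0L, `3` = 1L)[[as.character(p)]]
}

#' Walking stage from a left/right phase pair
#'
#' Maps a legal (left, right) phase pair to its stage code.  Stages carry a
#' classifier class index: Gait20 = 1, Gait31 = 2, Gait02 = 3, Gait13 = 4.
#'
#' @param left,right Single-leg phase codes.
#' @return An object of class `gait_stage`: list with `name`, `left`,
#'   `right` and `class` (integer 1-4).
#' @examples
#' stage_of(2, 0)$name   # "Gait20"
#' stage_of(1, 3)$class  # 4
#' @export
stage_of <- function(left, right) {
  left <- .check_phase(left, "left"); right <- .check_phase(right, "right")
  hit <- which(.stage_table$left == left & .stage_table$right == right)
  if (length(hit) != 1L)
    stop(sprintf(
      "illegal phase pair: left=%d, right=%d (legal pairs: 20, 31, 02, 13)",
      left, right), call. = FALSE)
  structure(as.list(.stage_table[hit, ]), class = "gait_stage")
}

#' @export
print.gait_stage <- function(x, ...) {
  cat(sprintf("<gait_stage> %s (left=%d, right=%d, class %d)\n",
              x$name, x$left, x$right, x$class))
  invisible(x)
}

.stage_by_name <- function(name) {
  hit <- which(.stage_table$name == name)
  if (length(hit) != 1L) stop("unknown stage name: ", name, call. = FALSE)
  structure(as.list(.stage_table[hit, ]), class = "gait_stage")
}

.as_stage_name <- function(s) {
  if (inherits(s, "gait_stage")) return(s$name)
  if (is.character(s) && length(s) == 1L && s %in% .stage_table$name) return(s)
  stop("expected a `gait_stage` or a stage name", call. = FALSE)
}

#' Next walking stage in the gait cycle
#'
#' Stages advance cyclically: Gait31 -> Gait02 -> Gait13 -> Gait20 -> Gait31.
#'
#' @param s A `gait_stage` (from [stage_of()]) or a stage name.
#' @return The following `gait_stage`.
#' @export
next_stage <- function(s) {
  nm <- .as_stage_name(s)
  i <- match(nm, .stage_cycle)
  .stage_by_name(.stage_cycle[i %% 4L + 1L])
}

#' Previous walking stage in the gait cycle
#'
#' Inverse of [next_stage()].
#'
#' @param s A `gait_stage` or stage name.
#' @return The preceding `gait_stage`.
#' @export
prev_stage <- function(s) {
  nm <- .as_stage_name(s)
  i <- match(nm, .stage_cycle)
  .stage_by_name(.stage_cycle[(i - 2L) %% 4L + 1L])
}

#' Labeler configuration for trend-based phase identification
#'
#' Thresholds for the deterministic trend/extremum labeler that replaces
#' manual phase annotation.  Slopes are computed on a short smoothed window;
#' an ascent or descent must exceed `stance_band` degrees of excursion to be
#' accepted as a swing-related event, which suppresses chatter on the flat
#' stance plateau.
#'
#' @param trend_window Frames used for slope smoothing (>= 2).
#' @param rise_threshold Minimum positive slope (degrees/frame) that arms an
#'   ascent.
#' @param fall_threshold Minimum descent rate (degrees/frame, positive
#'   number) that arms a descent.
#' @param stance_band Minimum excursion (degrees) from the last extremum for
#'   an ascent/descent to count as a real swing event rather than plateau
#'   noise.
#' @return A `labeler_config` list.
#' @export
labeler_config <- function(trend_window = 5L, rise_threshold = 0.2,
                           fall_threshold = 0.2, stance_band = 5) {
  trend_window <- as.integer(trend_window)
  if (trend_window < 2L) stop("trend_window must be >= 2", call. = FALSE)
  if (rise_threshold <= 0 || fall_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(trend_window = trend_window,
                 rise_threshold = rise_threshold,
                 fall_threshold = fall_threshold,
                 stance_band = stance_band),
            class = "labeler_config")
}

# centered moving-average smoother used for slope estimation only
.smooth_ma <- function(y, w) {
  if (w <= 1L) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  na <- is.na(s)          # edges where the centered window does not fit
  s[na] <- y[na]
  s
}

# centered finite-difference slope, degrees per frame
.slope <- function(y, h) {
  n <- length(y)
  i_fwd <- pmin(seq_len(n) + h, n)
  i_bwd <- pmax(seq_len(n) - h, 1L)
  (y[i_fwd] - y[i_bwd]) / (i_fwd - i_bwd)
}

# Detect apex (local max after an armed ascent) and valley (local min after
# an armed descent) events of one angle series, plus "rise" events marking
# the frame at which an ascent's excursion first exceeds the stance band (a
# confirmed swing with no completed apex yet; used only to pin the initial
# stage).  Returns a data.frame with columns idx, type.  Extremum indices
# are refined to the raw-series extremum near the slope sign change; exact
# ties (saturated plateaus) resolve to the middle tied frame.
.extremum_events <- function(y, cfg) {
  w <- cfg$trend_window
  ys <- .smooth_ma(y, w)
  sl <- .slope(ys, max(1L, floor(w / 2)))
  n <- length(y)
  idx <- integer(0); type <- character(0)
  mode <- "none"; ref <- y[1]; rise_flagged <- FALSE
  for (i in seq_len(n)) {
    if (mode == "none") {
      if (sl[i] >= cfg$rise_threshold) {
        mode <- "rising"; ref <- y[i]; rise_flagged <- FALSE
      } else if (sl[i] <= -cfg$fall_threshold) {
        mode <- "falling"; ref <- y[i]
      }
    } else if (mode == "rising") {
      if (!rise_flagged && y[i] - ref >= cfg$stance_band) {
        idx <- c(idx, i); type <- c(type, "rise")
        rise_flagged <- TRUE
      }
      if (sl[i] <= 0) {
        if (max(y[max(1L, i - w):i]) - ref >= cfg$stance_band) {
          j <- .refine_extremum(y, i, w, maximum = TRUE)
          idx <- c(idx, j); type <- c(type, "apex")
        }
        mode <- "none"
      }
    } else { # falling
      if (sl[i] >= 0) {
        if (ref - min(y[max(1L, i - w):i]) >= cfg$stance_band) {
          j <- .refine_extremum(y, i, w, maximum = FALSE)
          idx <- c(idx, j); type <- c(type, "valley")
        }
        mode <- "none"
      }
    }
  }
  data.frame(idx = idx, type = type, stringsAsFactors = FALSE)
}

.refine_extremum <- function(y, i, w, maximum) {
  lo <- max(1L, i - 2L * w); hi <- min(length(y), i + w)
  seg <- y[lo:hi]
  ext <- if (maximum) max(seg) else min(seg)
  ties <- which(abs(seg - ext) <= 1e-9)
  # saturated (clipped) extrema form a tied plateau; take its middle frame
  lo + ties[ceiling(length(ties) / 2)] - 1L
}

#' Label per-frame gait phases from bilateral sagittal ankle angles
#'
#' Deterministic replacement for manual phase annotation.  The sagittal
#' ankle angle rises steeply during swing and falls during pre-swing and
#' swing termination, so the four stage transitions of a stride coincide
#' with extrema of one side: the left apex starts Gait31, the right valley
#' (right toe-off) starts Gait02, the right apex starts Gait13 and the left
#' valley (left toe-off) starts Gait20.  A per-side trend detector arms on a
#' sustained rise/fall (see [labeler_config()]) and emits the extremum that
#' ends it; a stage state machine then consumes events in [next_stage()]
#' order, which guarantees every emitted (left, right) pair is legal.
#'
#' Frames before the first detected event are assigned the stage preceding
#' it; a series with no events at all (e.g. constant input) is labeled
#' (0, 2) throughout.  Transition frames belong to the newer stage.
#'
#' @param sagittal_left,sagittal_right Equal-length numeric series of
#'   sagittal ankle Euler angles, degrees.
#' @param cfg A [labeler_config()].
#' @return A list with integer vectors `phase_left` and `phase_right`.
#' @export
label_phases <- function(sagittal_left, sagittal_right,
                         cfg = labeler_config()) {
  n <- length(sagittal_left)
  if (length(sagittal_right) != n)
    stop("left and right series must have equal length", call. = FALSE)
  if (n < cfg$trend_window)
    stop("series shorter than trend_window", call. = FALSE)

  ev_l <- .extremum_events(sagittal_left, cfg)
  ev_r <- .extremum_events(sagittal_right, cfg)
  map <- function(d, apex, valley, rise) {
    if (!nrow(d)) return(NULL)
    data.frame(idx = d$idx,
               enters = c(apex = apex, valley = valley, rise = rise)[d$type],
               arm = d$type == "rise", stringsAsFactors = FALSE)
  }
  ev <- rbind(map(ev_l, "Gait31", "Gait20", "Gait20"),
              map(ev_r, "Gait13", "Gait02", "Gait02"))
  pl <- integer(n); pr <- integer(n)
  if (is.null(ev) || nrow(ev) == 0L) {           # tie rule: no events at all
    pl[] <- 0L; pr[] <- 2L
    return(list(phase_left = pl, phase_right = pr))
  }
  ev <- ev[order(ev$idx), , drop = FALSE]

  # The stage before the first event is back-filled from it: an extremum
  # implies the preceding stage; a confirmed rise implies that side was
  # already swinging, so its stage extends to the start.  Thereafter only
  # events matching the expected next stage advance the machine (stray
  # events are ignored).
  cur <- if (ev$arm[1]) .stage_by_name(ev$enters[1])
         else prev_stage(ev$enters[1])
  pos <- 1L
  for (k in seq_len(nrow(ev))) {
    if (ev$arm[k]) next
    want <- next_stage(cur)$name
    if (ev$enters[k] != want) next
    i <- ev$idx[k]
    if (i > pos) {
      pl[pos:(i - 1L)] <- cur$left; pr[pos:(i - 1L)] <- cur$right
    }
    cur <- .stage_by_name(want)
    pos <- max(pos, i)
  }
  pl[pos:n] <- cur$left; pr[pos:n] <- cur$right
  list(phase_left = pl, phase_right = pr)
}

#' Detect left toe-off events from a phase label series
#'
#' Toe-off ends pre-swing: it is the 1 -> 2 transition of the label series.
#'
#' @param labels_left Integer phase codes for the left leg.
#' @return Integer indices (1-based) of the first swing frame of each
#'   toe-off; possibly empty.
#' @export
detect_toe_off <- function(labels_left) {
  n <- length(labels_left)
  if (n < 2L) return(integer(0))
  which(labels_left[-1L] == 2L & labels_left[-n] == 1L) + 1L
}

#' Collapse per-frame stage labels to a run-length stage sequence
#'
#' @param phase_left,phase_right Per-frame phase code vectors.
#' @return Character vector of stage names with consecutive duplicates
#'   removed.
#' @export
stage_sequence <- function(phase_left, phase_right) {
  nm <- vapply(seq_along(phase_left), function(i)
    stage_of(phase_left[i], phase_right[i])$name, character(1))
  nm[c(TRUE, nm[-1L] != nm[-length(nm)])]
}
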