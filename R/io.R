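# CSV round-tripping for gait recordings.
#
# One row per frame, header
#   t,L_ax,L_ay,L_az,R_ax,R_ay,R_az,L_thigh,L_shank,R_thigh,R_shank,
#   phase_L,phase_R,true_phase
# with angles in degrees and UTF-8 encoding.  Numeric columns are written
# at full double precision so write -> read is lossless.

.rec_header <- c("t", "L_ax", "L_ay", "L_az", "R_ax", "R_ay", "R_az",
                 "L_thigh", "L_shank", "R_thigh", "R_shank",
                 "phase_L", "phase_R", "true_phase")

#' Write a gait recording to CSV
#'
#' @param rec A `gait_recording`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  df <- data.frame(t = rec$t, rec$ankle, rec$limb,
                   phase_L = rec$phase_left, phase_R = rec$phase_right,
                   true_phase = rec$true_phase, check.names = FALSE)
  colnames(df) <- .rec_header
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gait recording from CSV
#'
#' Validates the header, numeric content and time ordering; errors name
#' the offending column.
#'
#' @param path CSV file written by [write_recording()] (or conforming to
#'   its dialect).
#' @param pattern Gait pattern to record on the object (the dialect does
#'   not store it); default `"unknown"`.
#' @return A `gait_recording`.
#' @export
read_recording <- function(path, pattern = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.rec_header, colnames(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 2L)
    stop("insufficient frames: need at least 2 rows", call. = FALSE)
  for (cn in .rec_header) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v))
      stop("non-numeric cell(s) in column ", cn, call. = FALSE)
  }
  if (is.unsorted(df$t, strictly = TRUE))
    stop("time column `t` must be strictly increasing", call. = FALSE)
  if (!all(df$phase_L %in% 0:3) || !all(df$phase_R %in% 0:3))
    stop("phase labels must be integer codes 0-3", call. = FALSE)
  fs <- 1 / stats::median(diff(df$t))
  structure(list(
    t = df$t,
    ankle = as.matrix(df[, .rec_header[2:7]]),
    limb = as.matrix(df[, .rec_header[8:11]]),
    phase_left = as.integer(df$phase_L),
    phase_right = as.integer(df$phase_R),
    true_phase = df$true_phase,
    pattern = pattern, sample_rate = fs, config = NULL),
    class = "gait_recording")
}

#' Export a stage label sequence as two-digit strings
#'
#' @param phase_left,phase_right Per-frame phase codes.
#' @return Character vector like `"20"`, `"31"`.
#' @export
stage_strings <- function(phase_left, phase_right) {
  sprintf("%d%d", phase_left, phase_right)
}
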