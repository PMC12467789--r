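# Angle-phase feature fusion.
#
# The predictor input couples the spatial information of the six ankle
# Euler channels with the temporal information of the continuous gait
# phase: seven consecutive frames of (6 angles + 1 phase) form a 7 x 7
# window, paired with the four sagittal thigh/shank angles at a target
# frame `horizon` seconds past the window.  Dropping the phase column
# yields the 7 x 6 phase-free variant used as the fusion-ablation control.

#' Build fused prediction samples from a recording and a phase trace
#'
#' One sample per valid anchor frame: the input window covers frames
#' `a - window + 1, ..., a` (columns `L_ax, L_ay, L_az, R_ax, R_ay, R_az,
#' phi`) and the target is the limb channel vector at frame
#' `a + round(horizon * sample_rate)`.  Rounding is half-away-from-zero.
#'
#' @param rec A `gait_recording`.
#' @param phi A `phase_trace` aligned with `rec` (or a bare numeric vector
#'   of phase percents of the same length).
#' @param horizon Prediction horizon, seconds (0 predicts the window's last
#'   frame).
#' @param window Window length in frames (default 7).
#' @return A `fusion_set`: list with arrays `X` (n x window x 7), `X76`
#'   (n x window x 6), matrix `y` (n x 4), `anchors` (frame index of each
#'   window end), `target_frames`, `horizon`, `window` and `sample_rate`.
#'   Empty (`n = 0`) with a warning when the recording is too short.
#' @export
build_samples <- function(rec, phi, horizon = 0, window = 7L) {
  stopifnot(inherits(rec, "gait_recording"))
  p <- if (inherits(phi, "phase_trace")) phi$phi else as.numeric(phi)
  nT <- length(rec$t)
  if (length(p) != nT)
    stop("recording and phase trace are not aligned", call. = FALSE)
  window <- as.integer(window)
  h_frames <- .round_half_away(horizon * rec$sample_rate)
  n <- nT - (window - 1L) - h_frames
  if (n < 1L) {
    warning("recording too short for a single sample", call. = FALSE)
    n <- 0L
  }
  X <- array(NA_real_, c(n, window, 7L),
             dimnames = list(NULL, NULL,
                             c(colnames(rec$ankle), "phi")))
  y <- matrix(NA_real_, n, 4L, dimnames = list(NULL, colnames(rec$limb)))
  anchors <- integer(n)
  if (n > 0L) {
    anchors <- (window:(window + n - 1L))
    feat <- cbind(rec$ankle, phi = p)
    for (k in seq_len(window))
      X[, k, ] <- feat[anchors - window + k, , drop = FALSE]
    y[, ] <- rec$limb[anchors + h_frames, , drop = FALSE]
  }
  structure(list(X = X, X76 = X[, , 1:6, drop = FALSE], y = y,
                 anchors = anchors, target_frames = anchors + h_frames,
                 horizon = horizon, window = window,
                 sample_rate = rec$sample_rate), class = "fusion_set")
}

.round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' @export
print.fusion_set <- function(x, ...) {
  cat(sprintf("<fusion_set> %d samples, window %d, horizon %g s\n",
              nrow(x$y), x$window, x$horizon))
  invisible(x)
}

#' Number of samples in a fusion set
#' @param x A `fusion_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$y)

#' Split specification for repeated train/validation/test partitions
#'
#' @param ratios Numeric triple `(train, val, test)` summing to 1.
#' @param repeats Number of independent seeded splits.
#' @param seed Integer seed.
#' @param block Logical; `FALSE` (default) splits samples at random,
#'   matching the printed protocol.  `TRUE` splits along time into
#'   contiguous train/validation/test blocks and drops training samples
#'   whose frames overlap a validation/test window, avoiding temporal
#'   leakage between overlapping windows.
#' @param kfold `NULL` (default) for repeated random splits, or an integer
#'   `k >= 3` for k-fold rotation: one seeded permutation is cut into k
#'   folds, and repeat r holds out fold r as test and the following fold
#'   as validation (`repeats` is then forced to k and `ratios` ignored).
#' @return A `split_spec` list.
#' @export
split_spec <- function(ratios = c(0.6, 0.2, 0.2), repeats = 5L, seed = 1L,
                       block = FALSE, kfold = NULL) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be a triple summing to 1", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (!is.null(kfold)) {
    kfold <- as.integer(kfold)
    if (kfold < 3L) stop("kfold must be >= 3", call. = FALSE)
    repeats <- kfold
  }
  structure(list(ratios = ratios, repeats = as.integer(repeats),
                 seed = as.integer(seed), block = isTRUE(block),
                 kfold = kfold),
            class = "split_spec")
}

#' Partition fusion samples into train/validation/test sets
#'
#' Produces `spec$repeats` independent, seeded, disjoint and exhaustive
#' partitions at the configured ratios.
#'
#' @param samples A `fusion_set` or an integer sample count.
#' @param spec A [split_spec()].
#' @return List of length `repeats`; each element has integer index
#'   vectors `train`, `val`, `test`.
#' @export
split_samples <- function(samples, spec = split_spec()) {
  n <- if (inherits(samples, "fusion_set")) n_samples(samples)
       else as.integer(samples)
  if (n < 10L) stop("too few samples to split (need >= 10)", call. = FALSE)
  set.seed(spec$seed)
  if (!is.null(spec$kfold)) {
    k <- spec$kfold
    fold <- sample(rep_len(seq_len(k), n))
    return(lapply(seq_len(k), function(r) {
      va <- r %% k + 1L
      list(train = which(!(fold %in% c(r, va))),
           val = which(fold == va),
           test = which(fold == r))
    }))
  }
  lapply(seq_len(spec$repeats), function(r) {
    n_tr <- round(spec$ratios[1] * n)
    n_va <- round(spec$ratios[2] * n)
    if (spec$block) {
      off <- sample.int(n, 1L)            # random rotation of the timeline
      idx <- ((seq_len(n) + off - 2L) %% n) + 1L
      tr <- idx[seq_len(n_tr)]
      va <- idx[n_tr + seq_len(n_va)]
      te <- idx[(n_tr + n_va + 1L):n]
      if (inherits(samples, "fusion_set")) {
        # drop training samples whose window frames touch a held-out
        # anchor or target frame
        anc <- samples$anchors; tf <- samples$target_frames
        w <- samples$window
        held <- unique(c(anc[c(va, te)], tf[c(va, te)]))
        tr <- tr[!vapply(tr, function(s)
          any(((anc[s] - w + 1L):anc[s]) %in% held), logical(1))]
      }
      list(train = tr, val = va, test = te)
    } else {
      perm <- sample.int(n)
      list(train = perm[seq_len(n_tr)],
           val = perm[n_tr + seq_len(n_va)],
           test = perm[(n_tr + n_va + 1L):n])
    }
  })
}

#' Subset a fusion set
#'
#' @param x A `fusion_set`.
#' @param idx Integer sample indices.
#' @param phase Logical; `FALSE` selects the 7 x 6 phase-free variant.
#' @return List with array `X` and matrix `y` ready for model training.
#' @export
fusion_subset <- function(x, idx, phase = TRUE) {
  list(X = if (phase) x$X[idx, , , drop = FALSE]
           else x$X76[idx, , , drop = FALSE],
       y = x$y[idx, , drop = FALSE])
}
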