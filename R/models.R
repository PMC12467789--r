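# Stage classifiers and lower-limb angle predictors.
#
# Classification: the instantaneous six ankle Euler angles are mapped to
# the four walking stages either by a compact 1-D convolutional network
# (convolving across the channel axis, stride-1 same-padded pooling,
# softmax over 4 classes, cross-entropy, Adam) or by an RBF-kernel
# support-vector classifier (C = 1) as the comparison baseline.
#
# Prediction: 7-frame angle(-phase) windows are mapped to the four
# sagittal thigh/shank angles by a convolutional-recurrent hybrid
# (conv -> LSTM -> dense), with convolution-only, recurrence-only and
# phase-free (7 x 6) ablations sharing the same layer hyperparameters.
# Inputs and targets are standardized internally on training statistics
# (predictions are returned in degrees); this is a conditioning choice,
# not a feature of the data pipeline.

#' Stage-classifier specification
#'
#' @param kind `"cnn"` or `"svm"`.
#' @param conv_filters Filters of the two convolution blocks (cnn).
#' @param kernel Convolution kernel length (cnn).
#' @param dense_units Hidden dense width (cnn).
#' @param epochs,learning_rate,batch_size Training schedule (cnn); the
#'   defaults are 100 epochs at learning rate 0.001.
#' @param cost Regularization parameter C of the RBF support-vector
#'   classifier (svm).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("cnn", "svm"), conv_filters = c(16L, 32L),
                            kernel = 3L, dense_units = 32L, epochs = 100L,
                            learning_rate = 0.001, batch_size = 32L,
                            cost = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), cost = cost),
            class = "classifier_spec")
}

#' Per-frame stage-classification dataset from a recording
#'
#' @param rec A `gait_recording`.
#' @param labels Optional list with `phase_left`, `phase_right` (e.g. from
#'   [label_phases()]); defaults to the recording's ground truth.
#' @return List with `x` (n x 6 ankle matrix) and `class` (integer 1-4
#'   stage classes).
#' @export
stage_dataset <- function(rec, labels = NULL) {
  pl <- if (is.null(labels)) rec$phase_left else labels$phase_left
  pr <- if (is.null(labels)) rec$phase_right else labels$phase_right
  cls <- vapply(seq_along(pl), function(i) stage_of(pl[i], pr[i])$class, 1L)
  list(x = rec$ankle, class = cls)
}

.standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  list(center = ctr, scale = scl)
}
.std_apply <- function(x, s) sweep(sweep(x, 2, s$center), 2, s$scale, "/")
.std_invert <- function(x, s) sweep(sweep(x, 2, s$scale, "*"), 2, s$center, "+")

.classifier_net <- function(spec) {
  f <- spec$conv_filters
  list(.layer_conv1d(1L, f[1], spec$kernel), .layer_relu(), .layer_maxpool(),
       .layer_conv1d(f[1], f[2], spec$kernel), .layer_relu(), .layer_maxpool(),
       .layer_flatten(),
       .layer_dense(6L * f[2], spec$dense_units, relu = TRUE),
       .layer_dense(spec$dense_units, 4L))
}

.check_features6 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 6L)
    stop("classifier features must have 6 channels, got ", ncol(x),
         call. = FALSE)
  x
}

#' Train a walking-stage classifier
#'
#' @param spec A [classifier_spec()].
#' @param train,val Lists with `x` (n x 6 matrix) and `class` (integers
#'   1-4), e.g. from [stage_dataset()]; `val` is only used by the cnn for
#'   the per-epoch validation loss (it may be `NULL`).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `gait_classifier` with elements `kind`, `spec`, the fitted
#'   model, the feature scaler, and (cnn) a per-epoch loss `history`.
#' @export
train_classifier <- function(spec, train, val = NULL, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- .check_features6(train$x); y <- as.integer(train$class)
  missing_cls <- setdiff(1:4, unique(y))
  if (length(missing_cls))
    stop("class absent from training data: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  if (spec$kind == "svm") {
    fit <- e1071::svm(x, factor(y, levels = 1:4), kernel = "radial",
                      cost = spec$cost, scale = TRUE)
    return(structure(list(kind = "svm", spec = spec, model = fit,
                          seed = seed), class = "gait_classifier"))
  }
  scaler <- .standardizer(x)
  xs <- .std_apply(x, scaler)
  Xa <- array(xs, c(nrow(xs), 6L, 1L))
  if (is.null(val)) val <- train
  xv <- .std_apply(.check_features6(val$x), scaler)
  Xv <- array(xv, c(nrow(xv), 6L, 1L))
  net <- .classifier_net(spec)
  fit <- .train_network(net, Xa, y, Xv, as.integer(val$class),
                        .loss_softmax_ce, spec$epochs, spec$batch_size,
                        spec$learning_rate)
  structure(list(kind = "cnn", spec = spec, model = fit$net,
                 scaler = scaler, history = fit$history, seed = seed),
            class = "gait_classifier")
}

#' Predict walking stages
#'
#' @param classifier A fitted `gait_classifier`.
#' @param features 6-channel ankle angle vector or n x 6 matrix.
#' @return List with `class` (integer 1-4; ties resolve to the lowest
#'   class index), `stage` (stage names), and `prob` (softmax
#'   probabilities, cnn) or `decision` (decision values, svm).
#' @export
predict_stage <- function(classifier, features) {
  stopifnot(inherits(classifier, "gait_classifier"))
  x <- .check_features6(features)
  if (classifier$kind == "svm") {
    dv <- attr(stats::predict(classifier$model, x, decision.values = TRUE),
               "decision.values")
    votes <- matrix(0, nrow(x), 4L)
    for (j in seq_len(ncol(dv))) {
      pair <- strsplit(colnames(dv)[j], "/")[[1]]
      a <- as.integer(pair[1]); b <- as.integer(pair[2])
      pos <- dv[, j] > 0
      votes[, a] <- votes[, a] + pos
      votes[, b] <- votes[, b] + !pos
    }
    cls <- apply(votes, 1, which.max)   # ties -> lowest class index
    out <- list(class = as.integer(cls), decision = dv)
  } else {
    xs <- .std_apply(x, classifier$scaler)
    fw <- .net_forward(classifier$model,
                       .seq_slice(array(xs, c(nrow(xs), 6L, 1L))),
                       keep_cache = FALSE)
    p <- .softmax(fw$out)
    cls <- apply(p, 1, which.max)
    out <- list(class = as.integer(cls), prob = p)
  }
  out$stage <- .stage_table$name[out$class]
  out
}

#' Angle-predictor specification
#'
#' The hybrid model is a same-padded 1-D convolution block over the
#' 7-frame time axis feeding an LSTM whose last hidden state is read out
#' by a dense layer; the ablations remove one layer group while keeping
#' every remaining hyperparameter identical.  `cnn_lstm76` is the hybrid
#' on phase-free 7 x 6 input.
#'
#' @param kind `"cnn_lstm"`, `"cnn_only"`, `"lstm_only"` or
#'   `"cnn_lstm76"`.
#' @param conv_filters Convolution filters.
#' @param kernel Convolution kernel length.
#' @param lstm_units LSTM hidden units.
#' @param epochs,learning_rate,batch_size Training schedule; defaults 100
#'   epochs, 0.001, 32; loss is mean squared error.
#' @param standardize Standardize inputs and targets on training
#'   statistics (predictions are always returned in degrees).
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(kind = c("cnn_lstm", "cnn_only", "lstm_only",
                                    "cnn_lstm76"),
                           conv_filters = 64L, kernel = 3L,
                           lstm_units = 64L, epochs = 100L,
                           learning_rate = 0.001, batch_size = 32L,
                           standardize = TRUE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 lstm_units = as.integer(lstm_units),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 standardize = isTRUE(standardize),
                 n_channels = if (kind == "cnn_lstm76") 6L else 7L),
            class = "predictor_spec")
}

.predictor_net <- function(spec) {
  cin <- spec$n_channels
  switch(spec$kind,
    cnn_lstm = , cnn_lstm76 = list(
      conv = .layer_conv1d(cin, spec$conv_filters, spec$kernel),
      conv_relu = .layer_relu(),
      lstm = .layer_lstm(spec$conv_filters, spec$lstm_units),
      last = .layer_last(),
      head = .layer_dense(spec$lstm_units, 4L)),
    cnn_only = list(
      conv = .layer_conv1d(cin, spec$conv_filters, spec$kernel),
      conv_relu = .layer_relu(),
      last = .layer_last(),
      head = .layer_dense(spec$conv_filters, 4L)),
    lstm_only = list(
      lstm = .layer_lstm(cin, spec$lstm_units),
      last = .layer_last(),
      head = .layer_dense(spec$lstm_units, 4L)))
}

.check_pred_input <- function(X, spec, window = NULL) {
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  if (length(dim(X)) != 3L || dim(X)[3] != spec$n_channels)
    stop(sprintf("predictor `%s` expects windows with %d channels, got %s",
                 spec$kind, spec$n_channels,
                 paste(dim(X), collapse = "x")), call. = FALSE)
  X
}

#' Train a lower-limb angle predictor
#'
#' @param spec A [predictor_spec()].
#' @param train,val Lists with `X` (n x window x channels array) and `y`
#'   (n x 4 matrix of sagittal thigh/shank angles, degrees), e.g. from
#'   [fusion_subset()]; `val` supplies the per-epoch validation loss
#'   (defaults to the training set when `NULL`).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An `angle_predictor` with the fitted network, scalers, the
#'   per-epoch `history` (train/val MSE in standardized units) and
#'   `val_deteriorated`, `TRUE` when the validation loss rose over the
#'   last ten epochs (an early-stopping advisory, also emitted as a
#'   warning).
#' @export
train_predictor <- function(spec, train, val = NULL, seed = 1L) {
  stopifnot(inherits(spec, "predictor_spec"))
  X <- .check_pred_input(train$X, spec)
  y <- as.matrix(train$y)
  if (ncol(y) != 4L) stop("targets must have 4 channels", call. = FALSE)
  if (is.null(val)) val <- list(X = X, y = y)
  Xv <- .check_pred_input(val$X, spec); yv <- as.matrix(val$y)
  set.seed(as.integer(seed))
  nch <- dim(X)[3]
  sx <- if (spec$standardize)
    .standardizer(matrix(X, ncol = nch)) else NULL
  sy <- if (spec$standardize) .standardizer(y) else NULL
  scale_X <- function(A) {
    if (is.null(sx)) return(A)
    array(.std_apply(matrix(A, ncol = nch), sx), dim(A))
  }
  ys <- if (is.null(sy)) y else .std_apply(y, sy)
  yvs <- if (is.null(sy)) yv else .std_apply(yv, sy)
  net <- .predictor_net(spec)
  fit <- .train_network(net, scale_X(X), ys, scale_X(Xv), yvs,
                        .loss_mse, spec$epochs, spec$batch_size,
                        spec$learning_rate)
  # early-stopping advisory: median val loss of the last 5 epochs against
  # the preceding 5 (robust to per-epoch SGD noise)
  h <- fit$history$val
  tail10 <- h[max(1L, length(h) - 9L):length(h)]
  k <- length(tail10)
  recent <- stats::median(tail10[max(1L, k - 4L):k])
  before <- stats::median(tail10[seq_len(max(1L, k - 5L))])
  deteriorated <- !all(is.finite(tail10)) || recent > 1.5 * before + 1e-10
  if (deteriorated)
    warning("validation loss deteriorated over the last 10 epochs; ",
            "consider fewer epochs", call. = FALSE)
  structure(list(spec = spec, model = fit$net, scaler_x = sx, scaler_y = sy,
                 history = fit$history, val_deteriorated = deteriorated,
                 seed = seed), class = "angle_predictor")
}

#' Predict lower-limb sagittal angles
#'
#' @param predictor A fitted `angle_predictor`.
#' @param X A single window (window x channels matrix) or an
#'   n x window x channels array.
#' @return n x 4 matrix of predicted angles, degrees (a single window
#'   yields a length-4 vector).
#' @export
predict_angles <- function(predictor, X) {
  stopifnot(inherits(predictor, "angle_predictor"))
  single <- length(dim(X)) == 2L
  X <- .check_pred_input(X, predictor$spec)
  nch <- dim(X)[3]
  if (!is.null(predictor$scaler_x))
    X <- array(.std_apply(matrix(X, ncol = nch), predictor$scaler_x), dim(X))
  out <- .net_forward(predictor$model, .seq_slice(X),
                      keep_cache = FALSE)$out
  if (!is.null(predictor$scaler_y)) out <- .std_invert(out, predictor$scaler_y)
  colnames(out) <- c("L_thigh", "L_shank", "R_thigh", "R_shank")
  if (single) out[1, ] else out
}

#' Layer-group hyperparameters of a predictor specification
#'
#' Exposes the ablation contract: the layer groups of `cnn_only` and
#' `lstm_only` are strict subsets of the hybrid's, with identical
#' hyperparameters for every retained group.
#'
#' @param spec A [predictor_spec()].
#' @return Named list of layer groups and their hyperparameters.
#' @export
predictor_layers <- function(spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  groups <- list()
  if (spec$kind %in% c("cnn_lstm", "cnn_lstm76", "cnn_only"))
    groups$conv <- list(filters = spec$conv_filters, kernel = spec$kernel,
                        padding = "same", activation = "relu")
  if (spec$kind %in% c("cnn_lstm", "cnn_lstm76", "lstm_only"))
    groups$lstm <- list(units = spec$lstm_units)
  groups$head <- list(units = 4L)
  groups
}
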