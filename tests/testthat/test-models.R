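# The layer engine is validated against finite-difference gradients; the
# model-level contracts (determinism, separable-data sanity, ablation
# structure) are tested on small fixtures with reduced epochs where the
# property does not depend on the full schedule.

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  B <- 4; Tn <- 7; C <- 5
  net <- list(.layer_conv1d(C, 6), .layer_relu(), .layer_maxpool(),
              .layer_lstm(6, 8), .layer_last(), .layer_dense(8, 3))
  X <- array(rnorm(B * Tn * C), c(B, Tn, C))
  y <- matrix(rnorm(B * 3), B, 3)
  xs <- .seq_slice(X)
  check_net <- function(net, loss_fn, target) {
    fw <- .net_forward(net, xs)
    ls <- loss_fn(fw$out, target)
    gr <- .net_backward(net, fw$caches, ls$dlogits)
    eps <- 1e-6; worst <- 0
    for (l in seq_along(net)) for (nm in names(net[[l]]$params)) {
      P <- net[[l]]$params[[nm]]
      for (i in sample(length(P), min(6, length(P)))) {
        n2 <- net
        n2[[l]]$params[[nm]][i] <- P[i] + eps
        lp <- loss_fn(.net_forward(n2, xs, FALSE)$out, target)$loss
        n2[[l]]$params[[nm]][i] <- P[i] - eps
        lm <- loss_fn(.net_forward(n2, xs, FALSE)$out, target)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[l]][[nm]][i]
        worst <- max(worst, abs(num - ana) /
                       max(1e-8, abs(num) + abs(ana)))
      }
    }
    worst
  }
  expect_lt(check_net(net, .loss_mse, y), 1e-5)
  net2 <- list(.layer_conv1d(C, 4), .layer_relu(), .layer_maxpool(),
               .layer_conv1d(4, 5), .layer_relu(), .layer_flatten(),
               .layer_dense(Tn * 5, 6, relu = TRUE), .layer_dense(6, 4))
  fw <- .net_forward(net2, xs)
  ycls <- sample(4, B, replace = TRUE)
  ls <- .loss_softmax_ce(fw$out, ycls)
  gr <- .net_backward(net2, fw$caches, ls$dlogits)
  eps <- 1e-6
  for (l in c(1, 4, 7, 8)) for (nm in names(net2[[l]]$params)) {
    P <- net2[[l]]$params[[nm]]
    i <- sample(length(P), 1)
    n2 <- net2
    n2[[l]]$params[[nm]][i] <- P[i] + eps
    lp <- .loss_softmax_ce(.net_forward(n2, xs, FALSE)$out, ycls)$loss
    n2[[l]]$params[[nm]][i] <- P[i] - eps
    lm <- .loss_softmax_ce(.net_forward(n2, xs, FALSE)$out, ycls)$loss
    expect_lt(abs((lp - lm) / (2 * eps) - gr[[l]][[nm]][i]), 1e-5)
  }
})

test_that("both classifier kinds separate well-separated clusters", {
  d <- fixture_clusters()
  tr <- list(x = d$x[1:300, ], class = d$class[1:300])
  te <- list(x = d$x[301:400, ], class = d$class[301:400])
  cnn <- train_classifier(classifier_spec("cnn", epochs = 30), tr, seed = 1)
  expect_gte(mean(predict_stage(cnn, te$x)$class == te$class), 0.99)
  svm <- train_classifier(classifier_spec("svm"), tr, seed = 1)
  expect_gte(mean(predict_stage(svm, te$x)$class == te$class), 0.99)
  # training points of the separable set come back with their own class
  expect_gte(mean(predict_stage(cnn, tr$x)$class == tr$class), 0.99)
})

test_that("classifier training is deterministic and validates input", {
  d <- fixture_clusters(n = 200)
  tr <- list(x = d$x, class = d$class)
  a <- train_classifier(classifier_spec("cnn", epochs = 5), tr, seed = 3)
  b <- train_classifier(classifier_spec("cnn", epochs = 5), tr, seed = 3)
  expect_identical(predict_stage(a, d$x)$prob, predict_stage(b, d$x)$prob)
  expect_error(train_classifier(classifier_spec("cnn"),
                                list(x = d$x[d$class != 4, ],
                                     class = d$class[d$class != 4])),
               "class absent.*4")
  expect_error(predict_stage(a, matrix(1, 2, 5)), "6 channels")
})

test_that("softmax probabilities normalize and map onto stages", {
  d <- fixture_clusters(n = 120)
  cl <- train_classifier(classifier_spec("cnn", epochs = 5),
                         list(x = d$x, class = d$class), seed = 2)
  pr <- predict_stage(cl, d$x)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
  expect_identical(pr$stage,
                   c("Gait20", "Gait31", "Gait02", "Gait13")[pr$class])
})

test_that("the hybrid predictor fits clean periodic gait closely", {
  rec <- fixture_recording("normal", duration = 20, noise_sd = 0)
  fs <- build_samples(rec, rec$true_phase, horizon = 0)
  sp <- split_samples(fs, split_spec(repeats = 1, seed = 3))[[1]]
  pd <- suppressWarnings(train_predictor(
    predictor_spec("cnn_lstm", epochs = 40),
    fusion_subset(fs, sp$train), fusion_subset(fs, sp$val), seed = 1))
  te <- fusion_subset(fs, sp$test)
  pred <- predict_angles(pd, te$X)
  expect_lt(rmse(te$y, pred), 2)
  for (j in 1:4) expect_gt(pcc(te$y[, j], pred[, j]), 0.9)
  expect_true(all(is.finite(pd$history$val)))
  # inference contracts
  expect_equal(dim(pred), c(length(sp$test), 4L))
  expect_identical(pred, predict_angles(pd, te$X))
  one <- predict_angles(pd, te$X[1, , ])
  expect_length(one, 4)
  expect_equal(unname(one), unname(pred[1, ]))
  expect_error(predict_angles(pd, te$X[, , 1:6]), "expects windows")
})

test_that("predictor training is seed-reproducible", {
  rec <- fixture_recording("normal", duration = 12)
  fs <- build_samples(rec, rec$true_phase, horizon = 0)
  sp <- split_samples(fs, split_spec(repeats = 1, seed = 5))[[1]]
  tr <- fusion_subset(fs, sp$train); va <- fusion_subset(fs, sp$val)
  a <- suppressWarnings(train_predictor(
    predictor_spec("cnn_lstm", epochs = 3), tr, va, seed = 11))
  b <- suppressWarnings(train_predictor(
    predictor_spec("cnn_lstm", epochs = 3), tr, va, seed = 11))
  expect_identical(a$history, b$history)
  expect_identical(predict_angles(a, va$X), predict_angles(b, va$X))
})

test_that("ablations share hyperparameters and drop one layer group", {
  full <- predictor_layers(predictor_spec("cnn_lstm"))
  expect_setequal(names(full), c("conv", "lstm", "head"))
  cnn <- predictor_layers(predictor_spec("cnn_only"))
  lstm <- predictor_layers(predictor_spec("lstm_only"))
  p76 <- predictor_layers(predictor_spec("cnn_lstm76"))
  expect_setequal(names(cnn), c("conv", "head"))
  expect_setequal(names(lstm), c("lstm", "head"))
  expect_identical(full[names(cnn)], cnn)
  expect_identical(full[names(lstm)], lstm)
  expect_identical(full, p76)          # 7 x 6 variant: same layers
  # input-shape contract
  expect_equal(predictor_spec("cnn_lstm76")$n_channels, 6L)
  expect_equal(predictor_spec("cnn_lstm")$n_channels, 7L)
  rec <- fixture_recording("normal", duration = 12)
  fs <- build_samples(rec, rec$true_phase, horizon = 0)
  sp <- split_samples(fs, split_spec(repeats = 1))[[1]]
  expect_error(suppressWarnings(train_predictor(
    predictor_spec("cnn_lstm76", epochs = 2),
    fusion_subset(fs, sp$train, phase = TRUE))), "6 channels")
})

test_that("ablation variants train on the same data shapes", {
  rec <- fixture_recording("normal", duration = 12)
  fs <- build_samples(rec, rec$true_phase, horizon = 0)
  sp <- split_samples(fs, split_spec(repeats = 1, seed = 2))[[1]]
  tr <- fusion_subset(fs, sp$train); va <- fusion_subset(fs, sp$val)
  for (kind in c("cnn_only", "lstm_only")) {
    pd <- suppressWarnings(train_predictor(
      predictor_spec(kind, epochs = 3), tr, va, seed = 1))
    pred <- predict_angles(pd, va$X)
    expect_true(all(is.finite(pred)))
    expect_equal(ncol(pred), 4L)
  }
})
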