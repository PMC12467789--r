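test_that("rmse matches hand arithmetic and a brute-force oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, -3)), 3)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(50, sd = 10); b <- rnorm(50, sd = 10)
    acc <- 0
    for (k in seq_along(a)) acc <- acc + (a[k] - b[k])^2
    expect_lt(abs(rmse(a, b) - sqrt(acc / length(a))), 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("pcc matches its definition and honors affine invariance", {
  set.seed(3)
  x <- rnorm(40)
  expect_equal(pcc(2 * x + 5, x), 1)
  expect_equal(pcc(x, -x), -1)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    n <- length(a)
    cov_o <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
    sd_o <- function(v) sqrt(sum((v - mean(v))^2) / (n - 1))
    expect_lt(abs(pcc(a, b) - cov_o / (sd_o(a) * sd_o(b))), 1e-12)
  }
  expect_error(pcc(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pcc(1:3, 1:4), "equal length")
})

test_that("confusion counts, accuracies and aggregation are consistent", {
  perfect <- confusion(c(1, 2, 3, 4, 1), c(1, 2, 3, 4, 1))
  expect_equal(perfect$overall, 1)
  expect_equal(sum(diag(perfect$counts)), 5)
  one_err <- confusion(rep(1:4, each = 5), c(2, rep(1, 4), rep(2:4, each = 5)))
  expect_equal(one_err$overall, 19 / 20)
  expect_equal(unname(one_err$per_class[1]), 4 / 5)
  expect_true(all(rowSums(one_err$counts) == 5))
  expect_error(confusion(c(1, 5), c(1, 1)), "unknown class")
  s <- confusion_summary(list(perfect, one_err))
  expect_equal(s$overall_mean, mean(c(1, 0.95)))
  expect_equal(s$overall_sd, sd(c(1, 0.95)))
})

test_that("misclassifications concentrate in adjacent stages", {
  rec <- fixture_recording("foot_drop", duration = 20)
  lab <- fixture_labels(rec)
  truth <- stage_dataset(rec)$class
  pred <- stage_dataset(rec, lab)$class
  cm <- confusion(truth, pred)$counts
  off <- sum(cm) - sum(diag(cm))
  # stage adjacency in cycle order: class k borders k-1 and k+1 (mod 4)
  adj <- 0
  for (a in 1:4) for (b in 1:4)
    if (a != b && (abs(a - b) %in% c(1, 3))) adj <- adj + cm[a, b]
  expect_gt(off, 0)
  expect_gte(adj / off, 0.95)
})

test_that("model comparison reproduces the rank statistic by hand", {
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(20, 21, 22))
  out <- compare_models(g)
  # hand computation: ranks 1..9 without ties,
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  expect_equal(out$H, 12 / (9 * 10) * 3 * ((2 - 5)^2 + (5 - 5)^2 +
                                             (8 - 5)^2))
  expect_lt(out$p, 0.05)
  expect_s3_class(out$pairwise, "data.frame")
  expect_equal(out$adjust, "holm")
  # extreme separation yields a smaller pairwise p than mild separation
  sep_p <- function(shift) {
    gg <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) + shift,
               c = c(1, 2, 3, 4) + 2 * shift)
    r <- compare_models(gg, alpha = 1)
    r$pairwise$p[r$pairwise$group1 == "a" & r$pairwise$group2 == "c"]
  }
  expect_lte(sep_p(10), sep_p(2) + 1e-12)
})

test_that("identical groups give a null omnibus result with a warning", {
  expect_warning(out <- compare_models(list(a = rep(1, 4), b = rep(1, 4))),
                 "tied")
  expect_equal(out$H, 0)
  expect_equal(out$p, 1)
  expect_null(out$pairwise)
  expect_error(compare_models(list(a = 1:3)), "2 groups")
  expect_error(compare_models(list(a = 1:2, b = 1:2)), "3 values")
})

test_that("evaluation reports round-trip through JSON losslessly", {
  rec <- fixture_recording("normal", duration = 12)
  fs <- build_samples(rec, rec$true_phase, horizon = 0)
  sp <- split_samples(fs, split_spec(repeats = 1, seed = 4))[[1]]
  pd <- suppressWarnings(train_predictor(
    predictor_spec("cnn_only", epochs = 2),
    fusion_subset(fs, sp$train), seed = 1))
  rep1 <- evaluate_predictor(pd, fusion_subset(fs, sp$test),
                             gait = "normal", horizon = 0,
                             repeat_index = 1L)
  expect_gte(rep1$rmse, 0)
  expect_true(abs(rep1$pcc) <= 1)
  path <- tempfile(fileext = ".json")
  write_reports(list(rep1), path)
  back <- read_reports(path)[[1]]
  expect_equal(back$rmse, rep1$rmse)
  expect_equal(back$pcc, rep1$pcc)
  expect_equal(back$per_channel$rmse, rep1$per_channel$rmse)
  expect_equal(back$model, rep1$model)
  tab <- report_table(list(rep1, rep1), tempfile(fileext = ".csv"))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("model", "gait", "horizon", "repeat", "rmse", "pcc"))
})
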