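# Accuracy metrics and model comparison.
#
# RMSE and the Pearson correlation coefficient are the two accuracy
# metrics for angle prediction; stage classification is summarized by a
# 4 x 4 confusion matrix with overall and per-class accuracy.  Repeat-level
# PCC values of competing models are compared with the Kruskal-Wallis
# omnibus test followed, when significant, by Dunn's pairwise z tests with
# Holm adjustment.

#' Root mean square error, degrees
#'
#' `sqrt(mean((actual - predicted)^2))`, computed over all elements of
#' equal-shaped inputs.
#'
#' @param actual,predicted Numeric vectors or matrices of equal length.
#' @return Non-negative RMSE.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  sqrt(mean((as.numeric(actual) - as.numeric(predicted))^2))
}

#' Pearson correlation coefficient
#'
#' Covariance of the two series over the product of their standard
#' deviations; undefined (an error) when either series has zero variance.
#'
#' @param actual,predicted Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted))
    stop("inputs must have equal length", call. = FALSE)
  if (length(actual) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(actual) < 1e-15 || stats::sd(predicted) < 1e-15)
    stop("PCC undefined: an input series has zero variance", call. = FALSE)
  stats::cov(actual, predicted) / (stats::sd(actual) * stats::sd(predicted))
}

#' Confusion matrix and accuracies for stage classification
#'
#' @param true_classes,predicted_classes Integer classes in 1-4.
#' @return List with `counts` (4 x 4, rows = truth), `overall` accuracy and
#'   `per_class` accuracy (diagonal over row support; `NaN` for absent
#'   classes).
#' @export
confusion <- function(true_classes, predicted_classes) {
  if (length(true_classes) != length(predicted_classes))
    stop("inputs must have equal length", call. = FALSE)
  if (!all(c(true_classes, predicted_classes) %in% 1:4))
    stop("unknown class code (expected 1-4)", call. = FALSE)
  f <- function(x) factor(x, levels = 1:4)
  counts <- table(true = f(true_classes), predicted = f(predicted_classes))
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(true = .stage_table$name,
                                   predicted = .stage_table$name))
  support <- rowSums(counts)
  list(counts = counts,
       overall = sum(diag(counts)) / sum(counts),
       per_class = diag(counts) / support)
}

#' Aggregate per-repeat confusion results
#'
#' @param reps List of [confusion()] results from repeated experiments.
#' @return List with `overall_mean`, `overall_sd`, `per_class_mean`,
#'   `per_class_sd`.
#' @export
confusion_summary <- function(reps) {
  ov <- vapply(reps, `[[`, numeric(1), "overall")
  pc <- vapply(reps, `[[`, numeric(4), "per_class")
  list(overall_mean = mean(ov), overall_sd = stats::sd(ov),
       per_class_mean = rowMeans(pc),
       per_class_sd = apply(pc, 1, stats::sd))
}

# Dunn's pairwise z tests on pooled ranks (with tie correction), as the
# post hoc to a significant Kruskal-Wallis result.
.dunn_test <- function(values, groups, adjust = "holm") {
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- unique(groups)
  rbar <- tapply(r, groups, mean)[lv]
  ni <- tapply(r, groups, length)[lv]
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, adjust),
             stringsAsFactors = FALSE)
}

#' Compare model performance distributions
#'
#' Kruskal-Wallis omnibus test on repeat-level metric values (e.g. PCC per
#' repeat per model); when the omnibus p-value is below `alpha`, Dunn's
#' pairwise z tests are run with the named multiple-comparison adjustment.
#'
#' @param metric_by_model Named list of numeric vectors, one per model
#'   (>= 2 groups of >= 3 values each).
#' @param alpha Omnibus significance threshold gating the post hoc.
#' @param adjust Adjustment method for [stats::p.adjust()] applied to
#'   Dunn's pairwise p-values.
#' @return List with `H`, `df`, `p`, `adjust`, and `pairwise` (a data
#'   frame of Dunn z / p / adjusted p, or `NULL` when the omnibus is not
#'   significant).  Fully tied input yields `H = 0`, `p = 1` with a
#'   warning.
#' @export
compare_models <- function(metric_by_model, alpha = 0.05, adjust = "holm") {
  if (!is.list(metric_by_model) || length(metric_by_model) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(metric_by_model, length, 1L) < 3L))
    stop("each group needs at least 3 values", call. = FALSE)
  if (is.null(names(metric_by_model)))
    names(metric_by_model) <- paste0("model", seq_along(metric_by_model))
  values <- unlist(metric_by_model, use.names = FALSE)
  groups <- rep(names(metric_by_model),
                vapply(metric_by_model, length, 1L))
  if (length(unique(values)) == 1L) {
    warning("all values tied across groups; H set to 0, p to 1",
            call. = FALSE)
    return(list(H = 0, df = length(metric_by_model) - 1L, p = 1,
                adjust = adjust, pairwise = NULL))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              p = kw$p.value, adjust = adjust, pairwise = NULL)
  if (kw$p.value < alpha)
    out$pairwise <- .dunn_test(values, groups, adjust)
  out
}

#' Evaluate an angle predictor on a test set
#'
#' @param predictor A fitted `angle_predictor`.
#' @param test List with `X` and `y` (see [fusion_subset()]).
#' @param model_id,gait,horizon,repeat_index Metadata recorded in the
#'   report.
#' @return An `eval_report`: list with `rmse` (degrees, over all four
#'   channels), `pcc` (mean of the per-channel coefficients),
#'   `per_channel` (data frame), `pred_time_s`, and the metadata.
#' @export
evaluate_predictor <- function(predictor, test, model_id = predictor$spec$kind,
                               gait = NA_character_, horizon = NA_real_,
                               repeat_index = NA_integer_) {
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_angles(predictor, test$X)
  dt <- proc.time()[["elapsed"]] - t0
  y <- as.matrix(test$y)
  per <- data.frame(
    channel = colnames(pred),
    rmse = vapply(1:4, function(j) rmse(y[, j], pred[, j]), 1),
    pcc = vapply(1:4, function(j) pcc(y[, j], pred[, j]), 1))
  structure(list(rmse = rmse(y, pred), pcc = mean(per$pcc),
                 per_channel = per, pred_time_s = dt,
                 model = model_id, gait = gait, horizon = horizon,
                 repeat_index = repeat_index), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s | gait=%s horizon=%s rep=%s | RMSE %.3f deg, PCC %.4f\n",
    x$model, x$gait, x$horizon, x$repeat_index, x$rmse, x$pcc))
  invisible(x)
}

#' Write / read evaluation reports as JSON
#'
#' Round-trips losslessly (full double precision).  The wall-clock
#' `pred_time_s` field is a runtime diagnostic and is not serialized, so
#' identical experiments produce identical artifacts.
#'
#' @param reports A list of `eval_report` objects (or one report).
#' @param path File path.
#' @return `read_reports()` returns the list of reports (with
#'   `pred_time_s = NA`).
#' @export
write_reports <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    r <- unclass(r)
    r$pred_time_s <- NULL
    r
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Tabulate evaluation reports as a CSV-ready data frame
#'
#' One row per report, keyed by model, gait, horizon and repeat — the
#' layout used for cross-model result tables.
#'
#' @param reports List of `eval_report` objects.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame with columns `model`, `gait`, `horizon`, `repeat`,
#'   `rmse`, `pcc`.
#' @export
report_table <- function(reports, path = NULL) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, gait = r$gait, horizon = r$horizon,
               `repeat` = r$repeat_index, rmse = r$rmse, pcc = r$pcc,
               check.names = FALSE, stringsAsFactors = FALSE)))
  if (!is.null(path))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(r) {
    r$per_channel <- as.data.frame(r$per_channel,
                                   stringsAsFactors = FALSE)
    r$pred_time_s <- NA_real_
    structure(r, class = "eval_report")
  })
}
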