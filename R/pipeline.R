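# End-to-end pipeline: simulate -> label -> oscillator phase -> fused
# features -> train/evaluate models, with every intermediate written to
# disk.  A single global seed fans out deterministically to per-stage
# seeds, so each stage is independently reproducible and a rerun with the
# same configuration produces byte-identical artifacts.

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]; can be written to and
#' read from YAML.  Unknown keys are rejected.
#'
#' @param gait Gait pattern to simulate.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param sim Named list of [sim_config()] overrides (e.g. `duration`).
#' @param labeler Named list of [labeler_config()] overrides.
#' @param afo Named list of [afo_state()] overrides (gains, `n_osc`).
#' @param horizons Numeric vector of prediction horizons, seconds.
#' @param predictors Character vector of [predictor_spec()] kinds to train.
#' @param predictor Named list of [predictor_spec()] overrides shared by
#'   all trained predictors (e.g. `epochs`).
#' @param classifiers Character vector of [classifier_spec()] kinds.
#' @param classifier Named list of [classifier_spec()] overrides shared by
#'   all trained classifiers.
#' @param split Named list of [split_spec()] overrides (`ratios`,
#'   `repeats`, `block`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gait = "foot_drop", seed = 1L, sim = list(),
                            labeler = list(), afo = list(),
                            horizons = c(0, 0.5),
                            predictors = c("cnn_lstm", "cnn_lstm76"),
                            predictor = list(),
                            classifiers = "cnn",
                            classifier = list(),
                            split = list()) {
  cfg <- list(gait = gait, seed = as.integer(seed), sim = sim,
              labeler = labeler, afo = afo, horizons = horizons,
              predictors = predictors, predictor = predictor,
              classifiers = classifiers, classifier = classifier,
              split = split)
  .validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.pipeline_keys <- c("gait", "seed", "sim", "labeler", "afo", "horizons",
                    "predictors", "predictor", "classifiers", "classifier",
                    "split")

.validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stopifnot(cfg$gait %in% .gait_patterns,
            all(cfg$predictors %in% c("cnn_lstm", "cnn_only", "lstm_only",
                                      "cnn_lstm76")),
            all(cfg$classifiers %in% c("cnn", "svm")))
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns a validated
#'   `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic per-stage seed derivation from the global seed
# (double arithmetic to avoid 32-bit overflow, result well below 2^31)
.stage_seed <- function(seed, stage) {
  offsets <- c(sim = 101, split = 211, classifier = 307, predictor = 401)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483)
}

#' Run the full gait-analysis pipeline
#'
#' simulate -> label -> oscillator phase -> fused features -> train ->
#' evaluate.  Every intermediate artifact is written under `out_dir`:
#' `recording.csv` (the simulated recording), `labels.csv` (trend-labeler
#' output and stage strings), `phase.csv` (estimated continuous phase),
#' `classification.json` (per-classifier confusion summaries),
#' `reports.json` / `reports.csv` (one evaluation report per predictor,
#' horizon and repeat) and `manifest.json` (configuration and derived
#' seeds).  A stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if absent.
#' @return The list of evaluation reports, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim_args <- c(list(pattern = config$gait,
                     seed = .stage_seed(config$seed, "sim")), config$sim)
  rec <- stage("simulate", {
    simulate_recording(do.call(sim_config, sim_args))
  })
  write_recording(rec, file.path(out_dir, "recording.csv"))

  lab <- stage("label", {
    sag <- sagittal_channels(rec)
    label_phases(sag$left, sag$right,
                 do.call(labeler_config, config$labeler))
  })
  utils::write.csv(
    data.frame(phase_L = lab$phase_left, phase_R = lab$phase_right,
               stage = stage_strings(lab$phase_left, lab$phase_right)),
    file.path(out_dir, "labels.csv"), row.names = FALSE, quote = FALSE)

  phi <- stage("afo", {
    ev <- detect_toe_off(lab$phase_left)
    do.call(afo_run, c(list(theta = sagittal_channels(rec)$left,
                            sample_rate = rec$sample_rate,
                            toe_off_events = ev), config$afo))
  })
  utils::write.csv(
    data.frame(t = sprintf("%.6f", phi$t),
               phi_hat = sprintf("%.8f", phi$phi)),
    file.path(out_dir, "phase.csv"), row.names = FALSE, quote = FALSE)

  cls_out <- stage("classify", {
    ds <- stage_dataset(rec, lab)
    spd <- do.call(split_spec,
                   c(list(seed = .stage_seed(config$seed, "split")),
                     config$split))
    sp <- split_samples(length(ds$class), spd)
    lapply(stats::setNames(config$classifiers, config$classifiers),
           function(kind) {
      reps <- lapply(seq_along(sp), function(r) {
        cl <- train_classifier(
          do.call(classifier_spec, c(list(kind = kind), config$classifier)),
          list(x = ds$x[sp[[r]]$train, ], class = ds$class[sp[[r]]$train]),
          list(x = ds$x[sp[[r]]$val, ], class = ds$class[sp[[r]]$val]),
          seed = .stage_seed(config$seed, "classifier") + r)
        pr <- predict_stage(cl, ds$x[sp[[r]]$test, ])
        confusion(ds$class[sp[[r]]$test], pr$class)
      })
      s <- confusion_summary(reps)
      s$per_class_mean <- as.list(s$per_class_mean)
      s$per_class_sd <- as.list(s$per_class_sd)
      s
    })
  })
  jsonlite::write_json(cls_out, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)

  reports <- stage("predict", {
    out <- list()
    for (h in config$horizons) {
      fs <- build_samples(rec, phi, horizon = h)
      spd <- do.call(split_spec,
                     c(list(seed = .stage_seed(config$seed, "split")),
                       config$split))
      sp <- split_samples(fs, spd)
      for (kind in config$predictors) {
        use_phase <- kind != "cnn_lstm76"
        for (r in seq_along(sp)) {
          pd <- suppressWarnings(train_predictor(
            do.call(predictor_spec, c(list(kind = kind), config$predictor)),
            fusion_subset(fs, sp[[r]]$train, phase = use_phase),
            fusion_subset(fs, sp[[r]]$val, phase = use_phase),
            seed = .stage_seed(config$seed, "predictor") + r))
          out[[length(out) + 1L]] <- evaluate_predictor(
            pd, fusion_subset(fs, sp[[r]]$test, phase = use_phase),
            model_id = kind, gait = config$gait, horizon = h,
            repeat_index = r)
        }
      }
    }
    out
  })
  write_reports(reports, file.path(out_dir, "reports.json"))
  report_table(reports, file.path(out_dir, "reports.csv"))

  manifest <- list(
    config = unclass(config),
    derived_seeds = lapply(stats::setNames(nm = c("sim", "split",
                                                  "classifier", "predictor")),
                           function(s) .stage_seed(config$seed, s)),
    package_version = tryCatch(
      as.character(utils::packageVersion("gaitfuse")),
      error = function(e) "unknown"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(reports)
}
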