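#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end flow: input (a CSV path with
#' column roles, or synthetic-generator parameters), VIF thresholds, the
#' event-imputation threshold, the alpha cut and membership rounding, the
#' LSTM hyperparameters, survival horizons and the master seed.  The
#' configuration serializes to a single JSON file that fully reproduces a
#' run; the seed propagates to every stochastic stage.
#'
#' @param input Path to a CSV information system, or `NULL` to generate
#'   synthetic data.
#' @param roles Named list of column roles for `input` (`decision`,
#'   `time`, `event`, `categorical`).
#' @param synth Named list of [generate_synthetic()] arguments (used when
#'   `input` is `NULL`).
#' @param vif_threshold_low,vif_threshold_high VIF band boundaries.
#' @param event_threshold CDF threshold of [impute_events()].
#' @param alpha,rounding_dp [quantize()] parameters.
#' @param lstm An [lstm_config()].
#' @param horizons_years Survival horizons.
#' @param n_boot Bootstrap replicates for survival confidence intervals.
#' @param seed Master seed.
#' @param output_dir Directory receiving the run artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, roles = list(),
                            synth = list(n_objects = 500),
                            vif_threshold_low = 10,
                            vif_threshold_high = 15,
                            event_threshold = 0.5,
                            alpha = 0.97, rounding_dp = 2,
                            lstm = lstm_config(),
                            horizons_years = c(1, 5, 10),
                            n_boot = 200, seed = 1,
                            output_dir = tempfile("rsfas_run")) {
  stopifnot(inherits(lstm, "lstm_config"))
  structure(list(input = input, roles = roles, synth = synth,
                 vif_threshold_low = vif_threshold_low,
                 vif_threshold_high = vif_threshold_high,
                 event_threshold = event_threshold,
                 alpha = alpha, rounding_dp = rounding_dp,
                 lstm = lstm, horizons_years = horizons_years,
                 n_boot = n_boot, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr, log) {
  log(paste0("stage ", name, ": start"))
  out <- tryCatch(expr, error = function(e)
    stop("pipeline aborted at stage '", name, "': ",
         conditionMessage(e), call. = FALSE))
  log(paste0("stage ", name, ": done"))
  out
}

#' Run the end-to-end stage-prediction pipeline
#'
#' Executes, in order: load (or synthesize) the information system, VIF
#' feature reduction, Weibull fitting with event imputation for records
#' lacking an observed event, alpha-class quantization, a stratified
#' train/test split with LSTM training, evaluation on the held-out split,
#' and the stage-based survival report.  Every intermediate artifact is
#' written to `config$output_dir` together with a manifest recording the
#' configuration, input hashes and package version.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects (`data`, `reduced`,
#'   `vif_report`, `weibull_fit`, `ordinal`, `model`, `metrics`,
#'   `survival`, `stage_table`) and `artifacts`, the named file paths
#'   (reduced and ordinal CSVs, model archive, metrics JSON, survival CSV,
#'   log).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synth = list(n_objects = 120, n_genes = 4,
#'                                     effect_size = 1, noise_frac = 0.015),
#'                        lstm = lstm_config(units = 4, epochs = 5),
#'                        n_boot = 20)
#' run <- run_pipeline(cfg)
#' run$metrics$accuracy
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log <- function(msg) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg,
                           "\n", file = log_path, append = TRUE, sep = "")
  manifest <- list(config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("rsfas")),
                   stages_completed = character())
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA,
    force = TRUE)
  on.exit(write_manifest())

  data <- pipeline_stage("load", {
    if (!is.null(config$input)) {
      manifest$input_md5 <- unname(tools::md5sum(config$input))
      do.call(read_information_system,
              c(list(path = config$input), config$roles))
    } else {
      do.call(generate_synthetic,
              utils::modifyList(list(seed = config$seed), config$synth))
    }
  }, log)
  if (is.null(data$decision_attribute))
    stop("pipeline aborted at stage 'validate': no decision attribute",
         call. = FALSE)
  manifest$stages_completed <- c(manifest$stages_completed, "load")

  red <- pipeline_stage("vif", reduce_by_vif(
    data, config$vif_threshold_low, config$vif_threshold_high), log)
  reduced_path <- file.path(config$output_dir, "reduced.csv")
  write_information_system(red$system, reduced_path)
  utils::write.csv(red$report, file.path(config$output_dir,
                                         "vif_report.csv"),
                   row.names = FALSE)
  manifest$stages_completed <- c(manifest$stages_completed, "vif")

  wb <- pipeline_stage("weibull_events", {
    sys <- red$system
    tm <- sys$values[, sys$time_attribute]
    fit <- if (!is.null(sys$event_attribute) &&
               sum(sys$values[, sys$event_attribute]) >= 2) {
      fit_weibull_mle(tm, sys$values[, sys$event_attribute])
    } else {
      # no usable event indicator yet: moment-match an assumed shape
      sh <- config$synth$weibull_shape %||% 1.5
      list(shape = sh, scale = weibull_scale_moment(mean(tm), sh))
    }
    list(fit = fit,
         system = impute_events(sys, fit, config$event_threshold,
                                respect_observed = TRUE))
  }, log)
  manifest$stages_completed <- c(manifest$stages_completed,
                                 "weibull_events")

  ordinal <- pipeline_stage("rsfas", quantize(
    wb$system, alpha = config$alpha, rounding_dp = config$rounding_dp), log)
  ordinal_path <- file.path(config$output_dir, "ordinal.csv")
  write_information_system(ordinal, ordinal_path)
  manifest$stages_completed <- c(manifest$stages_completed, "rsfas")

  model <- pipeline_stage("train", {
    cfg <- config$lstm; cfg$seed <- config$seed
    lstm_train(ordinal, cfg)
  }, log)
  model_path <- file.path(config$output_dir, "model.rds")
  saveRDS(model, model_path)
  manifest$stages_completed <- c(manifest$stages_completed, "train")

  metrics <- pipeline_stage("evaluate", {
    test <- match(model$test_ids, ordinal$object_ids)
    y <- ordinal$values[test, ordinal$decision_attribute]
    pred <- predict(model, ordinal$values[test, , drop = FALSE])
    probs <- predict(model, ordinal$values[test, , drop = FALSE],
                     type = "prob")
    rep <- evaluate_predictions(y, pred, probs,
                                classes = model$classes)
    rep$train_accuracy <- model$train_accuracy
    rep$test_accuracy <- model$test_accuracy
    rep
  }, log)
  metrics_path <- file.path(config$output_dir, "metrics.json")
  jsonlite::write_json(
    list(accuracy = metrics$accuracy,
         train_accuracy = metrics$train_accuracy,
         test_accuracy = metrics$test_accuracy,
         macro = as.list(metrics$macro), kappa = metrics$kappa,
         kl_divergence = metrics$kl_divergence,
         roc_auc = if (!is.null(metrics$roc_auc))
           list(per_class = as.list(metrics$roc_auc$per_class),
                macro = metrics$roc_auc$macro),
         per_class = metrics$per_class),
    metrics_path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    na = "null")
  manifest$stages_completed <- c(manifest$stages_completed, "evaluate")

  surv <- pipeline_stage("survival", {
    sys <- wb$system
    stage_report(model, sys, horizons_years = config$horizons_years,
                 n_boot = config$n_boot, seed = config$seed)
  }, log)
  survival_path <- file.path(config$output_dir, "survival.csv")
  utils::write.csv(surv$table, survival_path, row.names = FALSE)
  manifest$stages_completed <- c(manifest$stages_completed, "survival")

  manifest$artifact_md5 <- as.list(tools::md5sum(
    c(reduced_path, ordinal_path, metrics_path, survival_path)))
  invisible(list(
    data = data, reduced = red$system, vif_report = red$report,
    weibull_fit = wb$fit, ordinal = ordinal, model = model,
    metrics = metrics, survival = surv$summary, stage_table = surv$table,
    artifacts = c(reduced = reduced_path, ordinal = ordinal_path,
                  model = model_path, metrics = metrics_path,
                  survival = survival_path, log = log_path)))
}

#' Stage-based survival report
#'
#' One row per stage and horizon: object count, the input event rate
#' ("existing events", from the recorded indicator grouped by the true
#' stage), the predicted-group event rate ("observed events", the event
#' rate among objects the model assigns to that stage), the per-stage
#' Weibull-vs-exponential likelihood-ratio statistic and concordance index
#' of a proportional-hazards fit on the numeric conditional attributes,
#' and the horizon survival estimates with bootstrap confidence intervals
#' from [survival_summary()].  Stages with no objects or too few events
#' are flagged rather than fatal.
#'
#' @param model An [lstm_train()] result (used for the predicted-group
#'   event rates); pass `NULL` to skip them.
#' @param is An [information_system()] carrying time, event and decision
#'   attributes.
#' @param horizons_years,ci_level,n_boot,seed Passed to
#'   [survival_summary()].
#' @return A list with `table` (the report) and `summary` (the underlying
#'   `survival_summary`).
#' @export
stage_report <- function(model, is, horizons_years = c(1, 5, 10),
                         ci_level = 0.95, n_boot = 200, seed = 1) {
  stopifnot(inherits(is, "information_system"))
  if (is.null(is$time_attribute) || is.null(is$event_attribute) ||
      is.null(is$decision_attribute))
    stop("stage report needs time, event and decision attributes",
         call. = FALSE)
  time <- is$values[, is$time_attribute]
  event <- is$values[, is$event_attribute]
  stage <- is$values[, is$decision_attribute]
  summ <- survival_summary(time, event, stage, horizons_years,
                           ci_level, n_boot, seed)

  pred_stage <- if (!is.null(model))
    as.numeric(predict(model, is$values)) else rep(NA_real_, length(stage))

  covs <- is$attributes$name[is$attributes$kind == "numeric"]
  per_stage <- lapply(sort(unique(stage)), function(s) {
    sel <- stage == s
    psel <- !is.na(pred_stage) & pred_stage == s
    lr <- NA_real_; cidx <- NA_real_
    if (sum(event[sel]) >= 2 && length(covs)) {
      ph <- tryCatch({
        X <- scale(is$values[sel, covs, drop = FALSE])
        X <- X[, apply(X, 2, function(z) all(is.finite(z))), drop = FALSE]
        fw <- fit_weibull_mle(time[sel], event[sel], X)
        fe <- fit_weibull_mle(time[sel], event[sel], X, shape_fixed = 1)
        risk <- drop(X %*% fw$beta)
        ci <- if (stats::var(risk) > 0)
          survival::concordance(
            survival::Surv(time[sel], event[sel]) ~ risk,
            reverse = TRUE)$concordance else NA_real_
        list(lr = 2 * (fw$log_likelihood - fe$log_likelihood), ci = ci)
      }, error = function(e) NULL)
      if (!is.null(ph)) { lr <- ph$lr; cidx <- ph$ci }
    }
    data.frame(stage = s, n = sum(sel),
               input_event_pct = 100 * mean(event[sel]),
               predicted_event_pct =
                 if (any(psel)) 100 * mean(event[psel]) else NA_real_,
               lr_statistic = lr, c_index = cidx,
               flagged = sum(event[sel]) < 2)
  })
  base <- do.call(rbind, per_stage)
  tab <- merge(base,
               summ$table[, c("stage", "horizon_years",
                              "survival_estimate", "mle_survival",
                              "ci_lower", "ci_upper")],
               by = "stage")
  tab <- tab[order(tab$stage, tab$horizon_years), ]
  rownames(tab) <- NULL
  list(table = tab, summary = summ)
}
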