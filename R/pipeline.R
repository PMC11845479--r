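# End-to-end orchestration: simulate (or load) -> segment -> features ->
# train -> detect -> indices -> validate, with one seed controlling every
# stage and a self-describing output directory.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis with its default:
#' 1.28 s windows, 120 s record limit, 20% variance and 95% correlation
#' feature filters, 8:2 split, 80% PCA target variance, 5 CV folds, the
#' 0.5 / 8 s onset rule, the 0.3 / 3-segment endpoint rule and the 4 s
#' recurrence window. Unknown keys are rejected.
#'
#' @param ... overrides for the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, algorithm = "random_forest",
    n_train_records = 60L, n_eval_records = 50L,
    window_s = 1.28, max_record_s = 120,
    variance_threshold = 0.20, correlation_threshold = 0.95,
    train_fraction = 0.8, pca_target_variance = 0.80, folds = 5L,
    onset_threshold = 0.5, onset_min_s = 8,
    end_threshold = 0.3, end_run = 3L, recurrence_window_s = 4,
    notch_hz = 50, lowpass_hz = 30, preprocess_enabled = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated records
#'
#' Generates a training set, trains and tunes a classifier, simulates an
#' independent evaluation set, detects each seizure, computes the eight
#' quality indices, and validates them against the simulator's ground
#' truth. With `out_dir` set, writes a self-describing run directory
#' (config snapshot, model summary, annotations, index table, validation
#' report).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A list: `model`, `annotations`, `indices` (computed),
#'   `reference` (ground-truth indices), `validation`, `exclusions`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  train_tab <- generate_training_set(config$n_train_records, seed = seed)
  model <- train_classifier(
    train_tab, algorithm = config$algorithm, seed = seed,
    train_fraction = config$train_fraction,
    pca_target_variance = config$pca_target_variance, folds = config$folds,
    variance_threshold = config$variance_threshold,
    correlation_threshold = config$correlation_threshold)

  set.seed(seed + 1L)
  eval_seeds <- sample.int(2^31 - 1, config$n_eval_records)
  ranges <- default_config_ranges()
  records <- vector("list", config$n_eval_records)
  truth <- vector("list", config$n_eval_records)
  for (i in seq_len(config$n_eval_records)) {
    cfg <- synth_config(seed = eval_seeds[i])
    set.seed(eval_seeds[i])
    for (nm in names(ranges))
      cfg[[nm]] <- stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
    g <- generate_record(cfg, record_id = sprintf("eval_%03d", i))
    records[[i]] <- g$record
    truth[[i]] <- g$annotation
  }

  annotations <- lapply(records, function(r) {
    if (config$preprocess_enabled)
      r <- preprocess(r, config$notch_hz, config$lowpass_hz)
    annotate_record(model, r,
                    onset_threshold = config$onset_threshold,
                    onset_min_s = config$onset_min_s,
                    end_threshold = config$end_threshold,
                    end_run = config$end_run,
                    recurrence_window_s = config$recurrence_window_s,
                    window_s = config$window_s)
  })
  statuses <- vapply(annotations, function(a) a$status, "")
  exclusions <- vapply(annotations, function(a)
    if (!is.null(a$exclusion)) a$exclusion else "none", "")

  computed <- indices_table(records, annotations)
  reference <- indices_table(records, truth)
  validation <- validate_indices(computed, reference)

  out <- list(model = model, annotations = annotations,
              indices = computed, reference = reference,
              validation = validation,
              statuses = statuses, exclusions = exclusions,
              config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(computed, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(reference, file.path(out_dir, "indices_reference.csv"),
                     row.names = FALSE)
    utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    ann_json <- lapply(seq_along(annotations), function(i) {
      a <- annotations[[i]]
      list(record_id = records[[i]]$record_id, status = a$status,
           onset_time = a$onset_time, endpoint_time = a$endpoint_time,
           duration = a$duration,
           trace = a$trace)
    })
    jsonlite::write_json(ann_json, file.path(out_dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    model_summary <- list(
      algorithm = model$spec$algorithm,
      best_params = model$spec$best_params,
      n_fits = model$n_fits,
      n_components = model$pipeline$n_components,
      held_out = model$report[c("tp", "tn", "fp", "fn", "accuracy", "mcc",
                                "roc_auc")])
    jsonlite::write_json(model_summary, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}
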