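# Supervised pipeline: class balancing, stratified split, min-max scaling,
# PCA, MCC-scored cross-validated grid search over five classifier
# families, and evaluation. "ictal" is the positive class throughout.

label_levels <- c("non_ictal", "ictal")

as_label_factor <- function(x) factor(as.character(x), levels = label_levels)

#' Balance a feature table by random undersampling
#'
#' Randomly reduces the majority class (without replacement) to the
#' minority class count. Deterministic for a fixed seed.
#'
#' @param table a `feature_table` with both labels present.
#' @param seed integer seed.
#' @return The balanced `feature_table`.
#' @export
undersample <- function(table, seed = 1L) {
  counts <- table(table$label)
  if (length(counts) < 2L)
    stop("undersample: both labels must be present")
  n_min <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(names(counts), function(lb) {
    idx <- which(table$label == lb)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  as_feature_table(table[sort(keep), , drop = FALSE])
}

#' Stratified train/test split
#'
#' Splits a feature table 8:2 (by default) with per-class rounding: each
#' class contributes `round(train_fraction * n_class)` training rows, so a
#' balanced table of 2 x 9745 rows yields 15592 training and 3898 test
#' rows.
#'
#' @param table a `feature_table`.
#' @param train_fraction fraction of rows for training, in (0, 1).
#' @param seed integer seed.
#' @param stratified if `FALSE`, split without regard to class.
#' @return A list with elements `train` and `test`, both `feature_table`s.
#' @export
split_table <- function(table, train_fraction = 0.8, seed = 1L,
                        stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_table: train_fraction must be strictly between 0 and 1")
  counts <- table(table$label)
  if (any(counts < 5L))
    stop("split_table: need at least 5 rows per class")
  set.seed(seed)
  if (stratified) {
    tr_idx <- unlist(lapply(names(counts), function(lb) {
      idx <- which(table$label == lb)
      sample(idx, round(train_fraction * length(idx)))
    }))
  } else {
    tr_idx <- sample(nrow(table), round(train_fraction * nrow(table)))
  }
  tr_idx <- sort(tr_idx)
  list(train = as_feature_table(table[tr_idx, , drop = FALSE]),
       test = as_feature_table(table[-tr_idx, , drop = FALSE]))
}

#' Fit min-max scaling and PCA on training rows, project both sets
#'
#' The scaler and the PCA basis are fitted on the training rows only; the
#' number of retained components is the smallest count whose cumulative
#' explained variance reaches `pca_target_variance`. Test values may leave
#' [0, 1] when they fall outside the training range; a zero-range feature
#' scales to 0 with a warning.
#'
#' @param train,test `feature_table`s (test may be `NULL`).
#' @param pca_target_variance target cumulative explained variance.
#' @return A list: `pipeline` (scaler parameters, PCA rotation, centre,
#'   explained-variance fractions, `n_components`), `train` and `test`
#'   (each a list with projected matrix `x` and factor `y`).
#' @export
fit_transform <- function(train, test = NULL, pca_target_variance = 0.80) {
  fn <- feature_cols(train)
  xtr <- as.matrix(train[, fn, drop = FALSE])
  mins <- apply(xtr, 2, min)
  rngs <- apply(xtr, 2, max) - mins
  if (any(rngs == 0)) {
    warning("fit_transform: zero-range feature(s) scaled to 0: ",
            paste(fn[rngs == 0], collapse = ", "))
  }
  scale_mm <- function(m) {
    out <- sweep(m, 2, mins)
    out <- sweep(out, 2, ifelse(rngs == 0, 1, rngs), "/")
    out[, rngs == 0] <- 0
    out
  }
  str_ <- scale_mm(xtr)
  if (all(apply(str_, 2, stats::var) == 0))
    stop("fit_transform: training table is constant; nothing to fit")
  pca <- stats::prcomp(str_, center = TRUE, scale. = FALSE)
  evf <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(evf) >= pca_target_variance - 1e-12)[1]
  if (is.na(k)) k <- length(evf)
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  project <- function(m) sweep(scale_mm(m), 2, pca$center) %*% rot
  pipeline <- list(feature_names = fn, mins = mins, ranges = rngs,
                   center = pca$center, rotation = rot,
                   explained_variance = evf, n_components = k,
                   pca_target_variance = pca_target_variance)
  out <- list(
    pipeline = pipeline,
    train = list(x = project(xtr), y = as_label_factor(train$label)))
  if (!is.null(test)) {
    xte <- as.matrix(test[, fn, drop = FALSE])
    out$test <- list(x = project(xte), y = as_label_factor(test$label))
  }
  out
}

apply_pipeline <- function(pipeline, table_or_matrix) {
  m <- if (is.data.frame(table_or_matrix)) {
    as.matrix(table_or_matrix[, pipeline$feature_names, drop = FALSE])
  } else {
    table_or_matrix[, pipeline$feature_names, drop = FALSE]
  }
  out <- sweep(m, 2, pipeline$mins)
  out <- sweep(out, 2, ifelse(pipeline$ranges == 0, 1, pipeline$ranges), "/")
  out[, pipeline$ranges == 0] <- 0
  sweep(out, 2, pipeline$center) %*% pipeline$rotation
}

#' Classifier specification with a hyperparameter grid
#'
#' The five supported families are `decision_tree` (rpart),
#' `random_forest` (randomForest), `svc` (e1071 SVM), `knn` (class::knn)
#' and `gradient_boosting` (xgboost). Default grids are small grids centred
#' on hyperparameter ranges known to work for ictal/non-ictal segment
#' classification (e.g. an RBF-kernel SVM with C = 10 is reachable).
#'
#' @param algorithm one of the five family names.
#' @param grid named list of hyperparameter value vectors; `NULL` for the
#'   default grid.
#' @return A `classifier_spec` list with `algorithm`, `grid`,
#'   `best_params` (filled by [tune()]).
#' @export
classifier_spec <- function(algorithm = c("decision_tree", "random_forest",
                                          "svc", "knn", "gradient_boosting"),
                            grid = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid) || !nrow(expand.grid(grid)))
    stop("classifier_spec: grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid, best_params = NULL,
                 cv_results = NULL),
            class = "classifier_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    decision_tree = list(maxdepth = c(5, 10, 15), minsplit = c(8, 20)),
    random_forest = list(ntree = c(50, 75), nodesize = c(1, 3)),
    svc = list(kernel = "radial", cost = c(1, 10), gamma = c(NA, 0.1)),
    knn = list(k = c(5, 7, 9)),
    gradient_boosting = list(nrounds = 125, max_depth = c(3, 5),
                             eta = c(0.1, 0.3)))
}

# gamma = NA encodes the "scale" convention 1 / (n_features * var(x)).
resolve_gamma <- function(gamma, x) {
  if (is.na(gamma)) 1 / (ncol(x) * stats::var(as.vector(x))) else gamma
}

fit_model <- function(algorithm, params, x, y, seed = 1L) {
  set.seed(seed)
  df <- data.frame(x)
  df$.y <- y
  model <- switch(algorithm,
    decision_tree = rpart::rpart(
      .y ~ ., data = df, method = "class",
      parms = list(split = "information"),
      control = rpart::rpart.control(maxdepth = params$maxdepth,
                                     minsplit = params$minsplit,
                                     cp = 1e-4)),
    random_forest = randomForest::randomForest(
      x, y, ntree = params$ntree, nodesize = params$nodesize),
    svc = e1071::svm(
      x, y, kernel = params$kernel, cost = params$cost,
      gamma = resolve_gamma(params$gamma, x), probability = TRUE),
    knn = list(x = x, y = y, k = params$k),  # lazy learner
    gradient_boosting = xgboost::xgboost(
      x, y, nrounds = params$nrounds, max_depth = params$max_depth,
      learning_rate = params$eta, nthread = 1, verbosity = 0),
    stop("unknown algorithm: ", algorithm))
  list(algorithm = algorithm, params = params, model = model,
       feature_dim = ncol(x), seed = seed)
}

# Returns list(class = factor, prob = numeric p(ictal)).
predict_model <- function(fit, x) {
  alg <- fit$algorithm
  if (alg == "decision_tree") {
    pr <- predict(fit$model, data.frame(x), type = "prob")[, "ictal"]
  } else if (alg == "random_forest") {
    pr <- predict(fit$model, x, type = "prob")[, "ictal"]
  } else if (alg == "svc") {
    pred <- predict(fit$model, x, probability = TRUE)
    pr <- attr(pred, "probabilities")[, "ictal"]
  } else if (alg == "knn") {
    pred <- class::knn(fit$model$x, x, fit$model$y, k = fit$model$k,
                       prob = TRUE)
    win <- attr(pred, "prob")
    pr <- ifelse(pred == "ictal", win, 1 - win)
  } else if (alg == "gradient_boosting") {
    # type = "response" is P(second factor level) = P(ictal)
    pr <- predict(fit$model, x, type = "response")
  }
  cls <- factor(ifelse(pr > 0.5, "ictal", "non_ictal"),
                levels = label_levels)
  list(class = cls, prob = as.numeric(pr))
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lb in levels(y)) {
    idx <- which(y == lb)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Tune a classifier by MCC-scored cross-validated grid search
#'
#' Exhaustive search over the grid; each cell is scored by the mean
#' Matthews correlation coefficient across stratified folds. Ties are
#' broken by first-in-grid order; a cell that fails to fit scores -1 for
#' that fold and is recorded, not fatal.
#'
#' @param spec a [classifier_spec()].
#' @param x projected training matrix; `y` factor of labels.
#' @param y label factor with levels `non_ictal`, `ictal`.
#' @param folds number of cross-validation folds.
#' @param seed integer seed (controls fold assignment and model fits).
#' @return `spec` with `best_params`, `cv_results` (per-cell mean MCC) and
#'   attribute `n_fits`.
#' @export
tune <- function(spec, x, y, folds = 5L, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), folds >= 2L)
  cells <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  fold <- stratified_folds(y, folds, seed)
  n_fits <- 0L
  scores <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    params <- as.list(cells[ci, , drop = FALSE])
    fold_mcc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fold_mcc[f] <- tryCatch({
        fit <- fit_model(spec$algorithm, params, x[tr, , drop = FALSE],
                         y[tr], seed = seed + f)
        pred <- predict_model(fit, x[!tr, , drop = FALSE])
        confusion_mcc(pred$class, y[!tr])
      }, error = function(e) {
        warning("tune: cell ", ci, " fold ", f, " failed: ",
                conditionMessage(e))
        -1
      })
      n_fits <- n_fits + 1L
    }
    scores[ci] <- mean(fold_mcc)
  }
  best <- which.max(scores)  # first maximum = first-in-grid tie-break
  spec$best_params <- as.list(cells[best, , drop = FALSE])
  spec$cv_results <- cbind(cells, mean_mcc = scores)
  attr(spec, "n_fits") <- n_fits
  spec
}

confusion_counts <- function(pred, truth) {
  list(tp = sum(pred == "ictal" & truth == "ictal"),
       tn = sum(pred == "non_ictal" & truth == "non_ictal"),
       fp = sum(pred == "ictal" & truth == "non_ictal"),
       fn = sum(pred == "non_ictal" & truth == "ictal"))
}

confusion_mcc <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  metrics_from_confusion(cc$tp, cc$tn, cc$fp, cc$fn)$mcc
}

#' Classification metrics from confusion counts
#'
#' Accuracy, per-class precision/recall/F1, support-weighted averages and
#' the Matthews correlation coefficient from the four confusion counts
#' (positive class "ictal"). A zero denominator defines the affected
#' metric as 0 and raises the `zero_denominator` flag; values are never
#' rounded here.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return A list with the counts, `accuracy`, `precision`, `recall`,
#'   `f1` (each a named vector for ictal/non_ictal), `weighted_precision`,
#'   `weighted_recall`, `weighted_f1`, `mcc`, `n`, `zero_denominator`.
#' @export
metrics_from_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("metrics_from_confusion: empty confusion matrix")
  flag <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { flag <<- TRUE; 0 } else num / den
  }
  prec_i <- safe_div(tp, tp + fp)
  prec_n <- safe_div(tn, tn + fn)
  rec_i <- safe_div(tp, tp + fn)
  rec_n <- safe_div(tn, tn + fp)
  f1_i <- if (prec_i + rec_i == 0) 0 else 2 * prec_i * rec_i / (prec_i + rec_i)
  f1_n <- if (prec_n + rec_n == 0) 0 else 2 * prec_n * rec_n / (prec_n + rec_n)
  sup_i <- tp + fn; sup_n <- tn + fp
  wavg <- function(a, b) (a * sup_i + b * sup_n) / n
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) { flag <- TRUE; 0 } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
       accuracy = (tp + tn) / n,
       precision = c(ictal = prec_i, non_ictal = prec_n),
       recall = c(ictal = rec_i, non_ictal = rec_n),
       f1 = c(ictal = f1_i, non_ictal = f1_n),
       weighted_precision = wavg(prec_i, prec_n),
       weighted_recall = wavg(rec_i, rec_n),
       weighted_f1 = wavg(f1_i, f1_n),
       mcc = mcc, zero_denominator = flag)
}

#' Evaluate a fitted model on a test set
#'
#' @param fit a fitted model from [fit_model()] via [train_classifier()].
#' @param x projected test matrix.
#' @param y true labels.
#' @return An `evaluation_report`: the output of
#'   [metrics_from_confusion()] plus `roc_auc` (from predicted
#'   probabilities; `NA` if unavailable) and the per-row correctness
#'   vector used for classifier comparison tests.
#' @export
evaluate <- function(fit, x, y) {
  pred <- predict_model(fit, x)
  cc <- confusion_counts(pred$class, y)
  rep <- metrics_from_confusion(cc$tp, cc$tn, cc$fp, cc$fn)
  rep$roc_auc <- tryCatch(
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = pred$prob,
                                   levels = label_levels,
                                   direction = "<", quiet = TRUE))),
    error = function(e) NA_real_)
  rep$correct <- as.integer(pred$class == y)
  rep$prob <- pred$prob
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: n=%d acc=%.3f mcc=%.3f auc=%s>\n",
              x$n, x$accuracy, x$mcc,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

#' Balance, split, transform, tune and fit one classifier family
#'
#' Runs the full supervised pipeline on a labelled feature table:
#' variance and correlation filters, random undersampling, stratified 8:2
#' split, min-max + PCA (80% target variance), MCC-scored grid search and
#' a final fit on the full training set, evaluated on the held-out test
#' rows.
#'
#' @param table labelled `feature_table`.
#' @param algorithm classifier family (see [classifier_spec()]).
#' @param seed integer master seed.
#' @param grid optional hyperparameter grid.
#' @param train_fraction,pca_target_variance,folds pipeline constants.
#' @param variance_threshold,correlation_threshold feature-filter
#'   thresholds; `NA` skips a filter.
#' @return An `ect_model`: `pipeline`, `spec` (with `best_params`), `fit`,
#'   `report` (held-out [evaluate()] output), `n_fits`, `seed`.
#' @export
train_classifier <- function(table, algorithm = "random_forest", seed = 1L,
                             grid = NULL, train_fraction = 0.8,
                             pca_target_variance = 0.80, folds = 5L,
                             variance_threshold = 0.20,
                             correlation_threshold = 0.95) {
  if (!is.na(variance_threshold))
    table <- variance_filter(table, variance_threshold)
  if (!is.na(correlation_threshold))
    table <- correlation_filter(table, correlation_threshold)
  table <- undersample(table, seed = seed)
  sp <- split_table(table, train_fraction = train_fraction, seed = seed)
  tf <- fit_transform(sp$train, sp$test, pca_target_variance)
  spec <- classifier_spec(algorithm, grid)
  spec <- tune(spec, tf$train$x, tf$train$y, folds = folds, seed = seed)
  fit <- fit_model(algorithm, spec$best_params, tf$train$x, tf$train$y,
                   seed = seed)
  report <- evaluate(fit, tf$test$x, tf$test$y)
  structure(list(pipeline = tf$pipeline, spec = spec, fit = fit,
                 report = report, n_fits = attr(spec, "n_fits"),
                 seed = seed),
            class = "ect_model")
}

#' @export
print.ect_model <- function(x, ...) {
  cat(sprintf("<ect_model: %s, %d PC(s), held-out MCC %.3f, %d CV fits>\n",
              x$spec$algorithm, x$pipeline$n_components, x$report$mcc,
              x$n_fits))
  invisible(x)
}

#' Per-segment ictal probabilities for a record
#'
#' Segments a record, extracts features for every post-baseline segment,
#' applies the fitted scaler/PCA, and returns the model's ictal
#' probability per segment together with segment start times.
#'
#' @param model an `ect_model` from [train_classifier()].
#' @param record an [eeg_record].
#' @param window_s,max_record_s segmentation constants.
#' @return A list: `time` (segment starts, s), `prob` (p(ictal)),
#'   `status` (segmentation status), `stimulus_end`.
#' @export
predict_ictal_probability <- function(model, record, window_s = 1.28,
                                      max_record_s = 120) {
  segs <- segment_record(record, window_s = window_s,
                         max_record_s = max_record_s)
  if (segs$status != "ok" || !length(segs$start_time)) {
    return(list(time = numeric(0), prob = numeric(0), status = segs$status,
                stimulus_end = record$stimulus_end))
  }
  feats <- t(vapply(segs$samples,
                    function(s) extract_features(s, segs$sampling_rate),
                    numeric(length(ictal_feature_names))))
  x <- apply_pipeline(model$pipeline, feats)
  pred <- predict_model(model$fit, x)
  list(time = segs$start_time, prob = pred$prob, status = segs$status,
       stimulus_end = record$stimulus_end)
}
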