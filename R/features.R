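# Per-segment feature extraction and the two feature filters applied
# before model training. The default set has 34 features spanning spectral
# frequency/energy descriptors and time-domain statistical moments.

ictal_feature_names <- c(
  "pow_delta", "pow_theta", "pow_alpha", "pow_beta",
  "relpow_delta", "relpow_theta", "relpow_alpha", "relpow_beta",
  "pow_total", "spec_centroid", "spec_entropy", "dom_freq",
  "spec_spread", "median_freq",
  "mean", "variance", "sd", "skewness", "kurtosis", "rms", "mean_abs",
  "peak_to_peak", "iqr", "median",
  "zero_crossings", "line_length", "hjorth_mobility", "hjorth_complexity",
  "energy", "slope_sign_changes", "acf_lag1", "sample_entropy",
  "mean_abs_diff1", "mean_abs_diff2")

#' Names of the default per-segment features
#'
#' @return Character vector of the 34 feature names, in extraction order.
#' @export
feature_names <- function() ictal_feature_names

#' Extract the default feature vector from one segment
#'
#' Computes 34 features from one channel of a segment: absolute and
#' relative band powers (delta, theta, alpha, beta), total 0.7-25 Hz power,
#' spectral centroid/entropy/spread, dominant and median frequency, the
#' usual amplitude statistics (mean, variance, SD, skewness, kurtosis, RMS,
#' mean absolute amplitude, peak-to-peak, IQR, median), and waveform
#' descriptors (zero crossings, line length, Hjorth mobility and
#' complexity, energy, slope sign changes, lag-1 autocorrelation, sample
#' entropy with m = 2 and r = 0.2 SD, mean absolute first and second
#' differences). All features are defined (never NaN) on constant
#' segments: moments above the variance, spectral shape descriptors and
#' entropy take their limit convention 0.
#'
#' @param x numeric sample vector (one channel of one segment) or a
#'   samples x channels matrix, in which case channel 1 is used.
#' @param sampling_rate sampling frequency in Hz.
#' @return Named numeric vector of length 34.
#' @export
extract_features <- function(x, sampling_rate = 200) {
  if (is.matrix(x)) x <- x[, 1]
  n <- length(x)
  if (n < 2L) stop("extract_features: segment needs at least 2 samples")

  sp <- segment_psd(x, sampling_rate)
  df <- sampling_rate / n
  bands <- eeg_bands()
  bp <- vapply(bands, function(b) {
    sum(sp$psd[sp$freq >= b[1] & sp$freq < b[2]]) * df
  }, numeric(1))
  insel <- sp$freq >= 0.7 & sp$freq < 25
  total <- sum(sp$psd[insel]) * df
  rel <- if (total > 0) bp / total else bp * 0

  f_in <- sp$freq[insel]; p_in <- sp$psd[insel]
  psum <- sum(p_in)
  if (psum > 0) {
    pn <- p_in / psum
    centroid <- sum(f_in * pn)
    spread <- sqrt(sum((f_in - centroid)^2 * pn))
    nz <- pn[pn > 0]
    sentropy <- -sum(nz * log(nz)) / log(length(pn))
    domf <- f_in[which.max(p_in)]
    medf <- f_in[which(cumsum(pn) >= 0.5)[1]]
  } else {
    centroid <- spread <- sentropy <- domf <- medf <- 0
  }

  mu <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  skw <- if (s > 0) mean((x - mu)^3) / (mean((x - mu)^2)^1.5) else 0
  krt <- if (s > 0) mean((x - mu)^4) / (mean((x - mu)^2)^2) - 3 else 0

  d1 <- diff(x)
  d2 <- diff(d1)
  sgn <- sign(x); sgn[sgn == 0] <- 1
  zc <- sum(diff(sgn) != 0)
  sgn_d <- sign(d1); sgn_d[sgn_d == 0] <- 1
  ssc <- sum(diff(sgn_d) != 0)
  var_d1 <- stats::var(d1)
  mob <- if (v > 0) sqrt(var_d1 / v) else 0
  var_d2 <- stats::var(d2)
  mob_d <- if (var_d1 > 0) sqrt(var_d2 / var_d1) else 0
  cplx <- if (mob > 0) mob_d / mob else 0
  ac1 <- if (s > 0) stats::cor(x[-n], x[-1]) else 0
  if (is.na(ac1)) ac1 <- 0

  out <- c(
    bp[["delta"]], bp[["theta"]], bp[["alpha"]], bp[["beta"]],
    rel[["delta"]], rel[["theta"]], rel[["alpha"]], rel[["beta"]],
    total, centroid, sentropy, domf, spread, medf,
    mu, v, s, skw, krt, sqrt(mean(x^2)), mean(abs(x)),
    max(x) - min(x), stats::IQR(x), stats::median(x),
    zc, sum(abs(d1)), mob, cplx,
    sum(x^2), ssc, ac1, sample_entropy(x),
    mean(abs(d1)), if (length(d2)) mean(abs(d2)) else 0)
  names(out) <- ictal_feature_names
  out
}

#' Sample entropy of a short signal
#'
#' SampEn(m = 2, r = 0.2 SD) with the Chebyshev distance, computed exactly
#' over all template pairs. Degenerate inputs (constant signal, or no
#' template matches) return 0 so the feature table never carries NaN.
#'
#' @param x numeric vector.
#' @param m template length.
#' @param r_frac tolerance as a fraction of the SD.
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0 || n <= m + 1L) return(0)
  r <- r_frac * s
  D <- abs(outer(x, x, "-"))
  cheb <- function(len) {
    idx <- seq_len(n - len)
    M <- D[idx, idx]
    for (k in seq_len(len - 1L)) M <- pmax(M, D[idx + k, idx + k])
    (sum(M < r) - length(idx)) / 2  # matching pairs, excluding self-matches
  }
  B <- cheb(m)
  A <- cheb(m + 1L)
  if (B == 0 || A == 0) return(0)
  -log(A / B)
}

#' Build a feature table from labelled segments
#'
#' One row per segment, columns `record_id`, `segment_index`, `label` and
#' the 34 features. Typically fed by [generate_training_set()] or by
#' segmenting and labelling real records.
#'
#' @param segments an `eeg_segments` object, or a list of them.
#' @param keep_labels which labels to keep as rows; the default keeps only
#'   segments usable for supervised training.
#' @return A `data.frame` of class `feature_table` with attribute
#'   `feature_names`.
#' @export
build_feature_table <- function(segments,
                                keep_labels = c("ictal", "non_ictal")) {
  if (inherits(segments, "eeg_segments")) segments <- list(segments)
  rows <- list()
  meta <- list()
  for (seg in segments) {
    keep <- which(seg$label %in% keep_labels)
    for (k in keep) {
      rows[[length(rows) + 1L]] <-
        extract_features(seg$samples[[k]], seg$sampling_rate)
      meta[[length(meta) + 1L]] <-
        data.frame(record_id = seg$record_id, segment_index = k,
                   label = seg$label[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("build_feature_table: no segments with kept labels")
  tab <- cbind(do.call(rbind, meta),
               as.data.frame(do.call(rbind, rows)))
  as_feature_table(tab)
}

as_feature_table <- function(df) {
  fn <- setdiff(names(df), c("record_id", "segment_index", "label"))
  stopifnot(!anyDuplicated(fn))
  attr(df, "feature_names") <- fn
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_cols <- function(table) attr(table, "feature_names")

#' Drop low-variance features
#'
#' Each feature is min-max scaled to [0, 1] for assessment only; features
#' whose scaled variance is at most `threshold` times the maximum variance
#' attainable by a [0, 1] variable (0.25, reached by a balanced 0/1
#' column) are dropped. Returned values are the original, unscaled ones.
#'
#' @param table a `feature_table`.
#' @param threshold fraction of the maximal attainable scaled variance.
#' @return The filtered `feature_table`.
#' @export
variance_filter <- function(table, threshold = 0.20) {
  stopifnot(nrow(table) >= 2L)
  fn <- feature_cols(table)
  keep <- vapply(fn, function(f) {
    x <- table[[f]]
    rng <- max(x) - min(x)
    if (rng == 0) return(FALSE)
    stats::var((x - min(x)) / rng) > threshold * 0.25
  }, logical(1))
  if (!any(keep))
    stop("variance_filter: all features dropped; threshold too aggressive")
  as_feature_table(table[, c("record_id", "segment_index", "label", fn[keep])])
}

#' Drop highly correlated features
#'
#' Scans features in table order; a feature whose absolute Pearson
#' correlation with any already-kept feature is at least `threshold` is
#' dropped (the later member of each pair goes). Deterministic, and
#' invariant to affine rescaling of any column.
#'
#' @param table a `feature_table` with at least 3 rows.
#' @param threshold absolute correlation at or above which to drop.
#' @return The filtered `feature_table`.
#' @export
correlation_filter <- function(table, threshold = 0.95) {
  stopifnot(nrow(table) >= 3L)
  fn <- feature_cols(table)
  cm <- abs(stats::cor(as.matrix(table[, fn, drop = FALSE])))
  cm[is.na(cm)] <- 0
  kept <- character(0)
  for (f in fn) {
    if (!length(kept) || all(cm[f, kept] < threshold)) kept <- c(kept, f)
  }
  as_feature_table(table[, c("record_id", "segment_index", "label", kept)])
}
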