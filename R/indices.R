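# The eight seizure quality indices. Every index is attempted and returns
# either a value or a missing-reason code; callers never see exceptions
# for clinically expectable situations (no endpoint, short ictal or
# postictal phases, single-channel recordings).

# Segment grid of a record: start times aligned to t = 0, the same grid
# used by segment_record(). Returns start times and sample index ranges.
record_grid <- function(record, window_s = 1.28) {
  spw <- round(window_s * record$sampling_rate)
  n_seg <- floor(nrow(record$channels) / spw)
  list(start = (seq_len(n_seg) - 1) * window_s, spw = spw, n = n_seg)
}

grid_samples <- function(record, k, spw, channel = 1L) {
  record$channels[((k - 1) * spw + 1):(k * spw), channel]
}

# Indices of grid segments lying wholly inside [from, to).
segments_within <- function(grid, from, to, window_s) {
  eps <- 1e-9
  which(grid$start >= from - eps & grid$start + window_s <= to + eps)
}

missing_index <- function(reason) {
  structure(list(value = NA_real_, missing_reason = reason),
            class = "quality_index")
}

ok_index <- function(value) {
  structure(list(value = value, missing_reason = "ok"),
            class = "quality_index")
}

require_detected <- function(annotation) {
  if (!inherits(annotation, "seizure_annotation") ||
      annotation$status != "detected") missing_index("no_endpoint") else NULL
}

#' Seizure duration
#'
#' Elapsed time between seizure onset and conclusion.
#'
#' @param annotation a [seizure_annotation()].
#' @return A `quality_index`: `value` (seconds) and `missing_reason`.
#' @export
seizure_duration <- function(annotation) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  ok_index(annotation$endpoint_time - annotation$onset_time)
}

#' Average Seizure Energy Index (ASEI)
#'
#' Total ictal EEG power divided by the seizure duration, computed in the
#' time domain as the mean squared amplitude over the ictal interval
#' (units uV^2). A PSD-based variant is available for sensitivity
#' analysis via `spectral = TRUE` (sum of per-segment 0.7-25 Hz band
#' powers times the window length, divided by duration).
#'
#' @param record an [eeg_record].
#' @param annotation a [seizure_annotation()].
#' @param spectral use the PSD-sum variant instead of the time domain.
#' @param window_s segment length (s).
#' @return A `quality_index` in uV^2.
#' @export
asei <- function(record, annotation, spectral = FALSE, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  fs <- record$sampling_rate
  if (!spectral) {
    i0 <- floor(annotation$onset_time * fs + 1e-6) + 1
    i1 <- min(floor(annotation$endpoint_time * fs + 1e-6), nrow(record$channels))
    x <- record$channels[i0:i1, 1]
    return(ok_index(mean(x^2)))
  }
  grid <- record_grid(record, window_s)
  sel <- segments_within(grid, annotation$onset_time,
                         annotation$endpoint_time, window_s)
  if (!length(sel)) return(missing_index("ictal_too_short"))
  pw <- vapply(sel, function(k)
    band_power(grid_samples(record, k, grid$spw), fs), numeric(1))
  ok_index(sum(pw) * window_s / annotation$duration)
}

# Per-segment total PSD (sum of one-sided PSD bins over 0.7-25 Hz,
# uV^2/Hz) for the ictal segments of a record.
ictal_segment_psd <- function(record, annotation, window_s) {
  grid <- record_grid(record, window_s)
  sel <- segments_within(grid, annotation$onset_time,
                         annotation$endpoint_time, window_s)
  psd <- vapply(sel, function(k) {
    sp <- segment_psd(grid_samples(record, k, grid$spw), record$sampling_rate)
    sum(sp$psd[sp$freq >= 0.7 & sp$freq < 25])
  }, numeric(1))
  list(sel = sel, start = grid$start[sel], psd = psd, grid = grid)
}

#' Maximum Sustained Power (MSP)
#'
#' Peak cumulative power spectral density over any 8 consecutive ictal
#' segments (uV^2/Hz).
#'
#' @inheritParams asei
#' @param window_segments run length in segments.
#' @return A `quality_index` in uV^2/Hz.
#' @export
msp <- function(record, annotation, window_segments = 8L, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  ip <- ictal_segment_psd(record, annotation, window_s)
  if (length(ip$psd) < window_segments)
    return(missing_index("ictal_too_short"))
  sums <- stats::filter(ip$psd, rep(1, window_segments), sides = 1)
  ok_index(max(sums, na.rm = TRUE))
}

#' Time To Peak Power (TTPP)
#'
#' Latency from seizure onset to the start of the ictal segment with the
#' highest total power spectral density (ties resolve to the earliest).
#'
#' @inheritParams asei
#' @return A `quality_index` in seconds.
#' @export
ttpp <- function(record, annotation, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  ip <- ictal_segment_psd(record, annotation, window_s)
  if (!length(ip$psd)) return(missing_index("ictal_too_short"))
  ok_index(ip$start[which.max(ip$psd)] - annotation$onset_time)
}

#' Early-Ictal Amplitude (EIA)
#'
#' Mean absolute amplitude over the initial phase of the seizure, taken as
#' the first `early_segments` ictal segments (about 10.24 s at defaults,
#' matching the MIA window for comparability).
#'
#' @inheritParams asei
#' @param early_segments number of leading ictal segments.
#' @return A `quality_index` in uV.
#' @export
eia <- function(record, annotation, early_segments = 8L, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  grid <- record_grid(record, window_s)
  sel <- segments_within(grid, annotation$onset_time,
                         annotation$endpoint_time, window_s)
  if (length(sel) < early_segments) return(missing_index("ictal_too_short"))
  x <- unlist(lapply(sel[seq_len(early_segments)],
                     function(k) grid_samples(record, k, grid$spw)))
  ok_index(mean(abs(x)))
}

#' Mid-Ictal Amplitude (MIA)
#'
#' Maximum mean absolute amplitude over any `window_segments` sequential
#' ictal segments.
#'
#' @inheritParams msp
#' @return A `quality_index` in uV.
#' @export
mia <- function(record, annotation, window_segments = 8L, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  grid <- record_grid(record, window_s)
  sel <- segments_within(grid, annotation$onset_time,
                         annotation$endpoint_time, window_s)
  if (length(sel) < window_segments) return(missing_index("ictal_too_short"))
  maa <- vapply(sel, function(k)
    mean(abs(grid_samples(record, k, grid$spw))), numeric(1))
  sums <- stats::filter(maa, rep(1 / window_segments, window_segments),
                        sides = 1)
  ok_index(max(sums, na.rm = TRUE))
}

#' Postictal Suppression Index (PSI)
#'
#' Percent reduction of postictal versus late-ictal average absolute
#' amplitude, excluding a symmetric `exclusion_s` window on either side of
#' the seizure endpoint. The ictal reference is the last `n_segments`
#' segments wholly before `endpoint - exclusion_s`; the postictal sample
#' is the first `n_segments` segments wholly after
#' `endpoint + exclusion_s`. A postictal increase clips to 0%.
#'
#' @inheritParams asei
#' @param n_segments segments per side.
#' @param exclusion_s half-width of the excluded window around the
#'   endpoint.
#' @return A `quality_index` in percent (0-100).
#' @export
psi <- function(record, annotation, n_segments = 3L, exclusion_s = 4,
                window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  grid <- record_grid(record, window_s)
  dur <- record_duration(record)
  ict <- segments_within(grid, annotation$onset_time,
                         annotation$endpoint_time - exclusion_s, window_s)
  if (length(ict) < n_segments) return(missing_index("ictal_too_short"))
  post <- segments_within(grid, annotation$endpoint_time + exclusion_s,
                          dur, window_s)
  if (length(post) < n_segments) return(missing_index("postictal_too_short"))
  ict_ref <- utils::tail(ict, n_segments)
  post_ref <- utils::head(post, n_segments)
  maa <- function(ks) mean(abs(unlist(
    lapply(ks, function(k) grid_samples(record, k, grid$spw)))))
  i_amp <- maa(ict_ref)
  p_amp <- maa(post_ref)
  if (i_amp == 0) return(missing_index("ictal_too_short"))
  ok_index(max(0, 1 - p_amp / i_amp) * 100)
}

#' Maximum Sustained Coherence (COH)
#'
#' Highest mean interhemispheric magnitude-squared coherence over any
#' 10-s ictal interval. Coherence is estimated per sliding window (stride
#' one segment) by Welch's method with 256-sample Hanning sub-windows at
#' 50% overlap, averaged over 0.7-25 Hz, and the maximum across windows is
#' reported in percent.
#'
#' @inheritParams asei
#' @param coh_window_s coherence window length (s).
#' @return A `quality_index` in percent (0-100).
#' @export
coh <- function(record, annotation, coh_window_s = 10, window_s = 1.28) {
  bad <- require_detected(annotation)
  if (!is.null(bad)) return(bad)
  if (ncol(record$channels) < 2L) return(missing_index("single_channel"))
  fs <- record$sampling_rate
  grid <- record_grid(record, window_s)
  eps <- 1e-9
  starts <- grid$start[grid$start >= annotation$onset_time - eps &
                       grid$start + coh_window_s <= annotation$endpoint_time + eps]
  if (!length(starts)) return(missing_index("ictal_too_short"))
  nwin <- round(coh_window_s * fs)
  vals <- vapply(starts, function(t0) {
    i0 <- round(t0 * fs) + 1
    idx <- i0:(i0 + nwin - 1)
    welch_coherence(record$channels[idx, 1], record$channels[idx, 2], fs)
  }, numeric(1))
  ok_index(max(vals) * 100)
}

#' Compute all eight seizure quality indices
#'
#' Attempts every index; failures are recorded as missing-reason codes,
#' never exceptions.
#'
#' @param record an [eeg_record].
#' @param annotation a [seizure_annotation()].
#' @param ... per-index parameters passed through (`early_segments`,
#'   `window_segments`, `n_segments`, `exclusion_s`, `coh_window_s`).
#' @return A `quality_indices` data.frame with columns `index`, `value`,
#'   `missing_reason` (one row per index, in the order duration, psi,
#'   asei, msp, ttpp, eia, mia, coh).
#' @export
compute_indices <- function(record, annotation, ...) {
  args <- list(...)
  call_with <- function(f, names_ok) {
    do.call(f, c(list(record, annotation), args[names(args) %in% names_ok]))
  }
  res <- list(
    duration = seizure_duration(annotation),
    psi = call_with(psi, c("n_segments", "exclusion_s", "window_s")),
    asei = call_with(asei, c("spectral", "window_s")),
    msp = call_with(msp, c("window_segments", "window_s")),
    ttpp = call_with(ttpp, "window_s"),
    eia = call_with(eia, c("early_segments", "window_s")),
    mia = call_with(mia, c("window_segments", "window_s")),
    coh = call_with(coh, c("coh_window_s", "window_s")))
  out <- data.frame(
    index = names(res),
    value = vapply(res, function(r) r$value, numeric(1)),
    missing_reason = vapply(res, function(r) r$missing_reason, ""),
    row.names = NULL)
  class(out) <- c("quality_indices", "data.frame")
  out
}

#' Tabulate indices for a batch of annotated records
#'
#' @param records list of [eeg_record]s.
#' @param annotations matching list of [seizure_annotation()]s.
#' @param ... passed to [compute_indices()].
#' @return A long data.frame (`record_id`, `index`, `value`,
#'   `missing_reason`); the attribute `missing_counts` tabulates
#'   missing-reason codes per index.
#' @export
indices_table <- function(records, annotations, ...) {
  stopifnot(length(records) == length(annotations))
  rows <- lapply(seq_along(records), function(i) {
    qi <- compute_indices(records[[i]], annotations[[i]], ...)
    qi$record_id <- records[[i]]$record_id
    qi[, c("record_id", "index", "value", "missing_reason")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing_counts") <-
    table(out$index[out$missing_reason != "ok"],
          out$missing_reason[out$missing_reason != "ok"])
  out
}
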