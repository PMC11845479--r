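# Seizure onset/endpoint determination from a per-segment ictal
# probability trace.

#' Seizure annotation constructor
#'
#' @param onset_time,endpoint_time seconds from record start (NA unless
#'   status is "detected").
#' @param status one of `"detected"`, `"no_seizure"`,
#'   `"truncated_recording"`.
#' @param trace data.frame with columns `time` and `prob` (the per-segment
#'   probability trace the decision was based on), kept for audit.
#' @return A `seizure_annotation` list with `onset_time`, `endpoint_time`,
#'   `duration`, `status`, `trace`.
#' @export
seizure_annotation <- function(onset_time = NA_real_,
                               endpoint_time = NA_real_,
                               status = c("detected", "no_seizure",
                                          "truncated_recording"),
                               trace = NULL) {
  status <- match.arg(status)
  if (status == "detected") {
    stopifnot(is.finite(onset_time), is.finite(endpoint_time),
              onset_time < endpoint_time)
    duration <- endpoint_time - onset_time
  } else {
    onset_time <- endpoint_time <- duration <- NA_real_
  }
  structure(list(onset_time = onset_time, endpoint_time = endpoint_time,
                 duration = duration, status = status, trace = trace),
            class = "seizure_annotation")
}

#' @export
print.seizure_annotation <- function(x, ...) {
  if (x$status == "detected") {
    cat(sprintf("<seizure_annotation: onset %.2f s, endpoint %.2f s, duration %.2f s>\n",
                x$onset_time, x$endpoint_time, x$duration))
  } else {
    cat(sprintf("<seizure_annotation: %s>\n", x$status))
  }
  invisible(x)
}

#' Detect seizure onset and endpoint from an ictal probability trace
#'
#' Onset is the start of the first run of at least
#' `ceiling(onset_min_s / window)` consecutive segments with
#' `p > onset_threshold`, beginning at or after the end of stimulation
#' (with 1.28 s windows and an 8 s minimum this is 7 segments). The
#' endpoint is the start time of the first segment of the first subsequent
#' run of `end_run` consecutive segments with `p < end_threshold` ("the
#' first non-ictal epoch"). If the onset condition is met again by a run
#' starting within `recurrence_window_s` seconds after a candidate
#' endpoint, detection continues and the later endpoint is retained.
#' With no qualifying onset run the status is `"no_seizure"`; if the
#' record ends before an endpoint run completes, the status is
#' `"truncated_recording"`.
#'
#' Thresholds are strict: onset requires `p > onset_threshold`, the
#' endpoint `p < end_threshold`; boundary values do not qualify.
#'
#' @param prob per-segment ictal probabilities in time order.
#' @param time matching segment start times (seconds).
#' @param stimulus_end end of stimulation (seconds); segments starting
#'   earlier are ignored.
#' @param onset_threshold probability a segment must exceed to count
#'   towards onset.
#' @param onset_min_s minimum sustained supra-threshold time implying a
#'   seizure.
#' @param end_threshold probability a segment must stay under to count
#'   towards the endpoint.
#' @param end_run number of consecutive sub-threshold segments ending a
#'   seizure.
#' @param recurrence_window_s window after a candidate endpoint within
#'   which a new onset run keeps the seizure going.
#' @param window_s segment length (seconds), used to convert
#'   `onset_min_s` to a segment count.
#' @return A [seizure_annotation()].
#' @export
detect_seizure <- function(prob, time, stimulus_end = 0,
                           onset_threshold = 0.5, onset_min_s = 8,
                           end_threshold = 0.3, end_run = 3L,
                           recurrence_window_s = 4, window_s = 1.28) {
  stopifnot(length(prob) == length(time))
  trace <- data.frame(time = time, prob = prob)
  keep <- time >= stimulus_end - 1e-9
  p <- prob[keep]; t <- time[keep]
  m <- length(p)
  n_on <- max(1L, ceiling(onset_min_s / window_s - 1e-9))
  if (m == 0L) return(seizure_annotation(status = "no_seizure", trace = trace))

  # start indices of complete onset runs (>= n_on consecutive p > threshold)
  hi <- p > onset_threshold
  run_starts <- integer(0)
  if (m >= n_on) {
    csum <- cumsum(c(0, as.integer(hi)))
    cand <- which((csum[(n_on + 1):(m + 1)] - csum[1:(m - n_on + 1)]) == n_on)
    run_starts <- cand
  }
  if (!length(run_starts))
    return(seizure_annotation(status = "no_seizure", trace = trace))

  onset_idx <- run_starts[1]
  lo <- p < end_threshold
  lo_run_ok <- logical(m)
  if (m >= end_run) {
    csum_lo <- cumsum(c(0, as.integer(lo)))
    ok <- (csum_lo[(end_run + 1):(m + 1)] - csum_lo[1:(m - end_run + 1)]) == end_run
    lo_run_ok[seq_along(ok)] <- ok
  }

  pos <- onset_idx
  repeat {
    cand <- which(lo_run_ok & seq_len(m) > pos)
    if (!length(cand)) {
      return(seizure_annotation(status = "truncated_recording", trace = trace))
    }
    j <- cand[1]
    t_end <- t[j]
    # recurrence: a complete onset run starting within the post-ictal window
    re <- run_starts[run_starts > j & t[run_starts] <= t_end + recurrence_window_s + 1e-9]
    if (length(re)) {
      pos <- re[1]
    } else {
      return(seizure_annotation(onset_time = t[onset_idx],
                                endpoint_time = t_end,
                                status = "detected", trace = trace))
    }
  }
}

#' Detect a seizure in a record using a trained classifier
#'
#' Convenience wrapper: [predict_ictal_probability()] followed by
#' [detect_seizure()].
#'
#' @param model an `ect_model`.
#' @param record an [eeg_record].
#' @param ... passed to [detect_seizure()].
#' @return A [seizure_annotation()]; records excluded by the segmentation
#'   stage come back as `"no_seizure"` with the segmentation status in the
#'   `exclusion` field.
#' @export
annotate_record <- function(model, record, ...) {
  pr <- predict_ictal_probability(model, record)
  if (pr$status != "ok") {
    ann <- seizure_annotation(status = "no_seizure")
    ann$exclusion <- pr$status
    return(ann)
  }
  detect_seizure(pr$prob, pr$time, stimulus_end = pr$stimulus_end, ...)
}
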