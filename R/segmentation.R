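#' Partition a recording into fixed non-overlapping windows
#'
#' Cuts a record into contiguous non-overlapping segments of `window_s`
#' seconds (1.28 s at 200 Hz gives 256 samples and a spectral resolution of
#' about 0.78 Hz). A trailing partial window is dropped. Recordings longer
#' than `max_record_s` are not segmented; they come back with zero segments
#' and status `"excluded_too_long"` so batch runs can count exclusions
#' instead of aborting.
#'
#' @param record an [eeg_record].
#' @param window_s window length in seconds.
#' @param max_record_s records longer than this are excluded.
#' @return An object of class `eeg_segments`: a list with `status`
#'   (`"ok"`, `"excluded_too_long"` or `"too_short"`), `window_s`,
#'   `sampling_rate`, `record_id`, `stimulus_end`, `start_time` (numeric
#'   vector), `samples` (list of samples x channels matrices) and `label`
#'   (filled by [label_segments()], initially `"unlabelled"`).
#' @export
segment_record <- function(record, window_s = 1.28, max_record_s = 120) {
  dur <- record_duration(record)
  base <- structure(
    list(status = "ok", window_s = window_s,
         sampling_rate = record$sampling_rate,
         record_id = record$record_id, stimulus_end = record$stimulus_end,
         start_time = numeric(0), samples = list(), label = character(0)),
    class = "eeg_segments")
  if (dur > max_record_s) {
    base$status <- "excluded_too_long"
    return(base)
  }
  n_seg <- floor(dur / window_s + 1e-9)
  if (n_seg < 1L) {
    base$status <- "too_short"
    return(base)
  }
  spw <- round(window_s * record$sampling_rate)
  base$start_time <- (seq_len(n_seg) - 1) * window_s
  base$samples <- lapply(seq_len(n_seg), function(k) {
    record$channels[((k - 1) * spw + 1):(k * spw), , drop = FALSE]
  })
  base$label <- rep("unlabelled", n_seg)
  base
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf("<eeg_segments '%s': %d segments of %.2f s, status '%s'>\n",
              x$record_id, length(x$start_time), x$window_s, x$status))
  if (length(x$label)) print(table(x$label))
  invisible(x)
}

#' Assign reference ictal/non-ictal labels to segments
#'
#' Segments overlapping the stimulation interval `[0, stimulus_end)` are
#' `"omitted"`. Of the remaining segments, those starting before the
#' reference seizure endpoint are `"ictal"` and the rest `"non_ictal"`
#' (start-time rule for the window that straddles the endpoint). When no
#' reference endpoint exists (`reference_endpoint = NA`) all
#' post-stimulation segments stay `"unlabelled"` and are excluded from
#' training.
#'
#' @param segments an `eeg_segments` object from [segment_record()].
#' @param reference_endpoint reference seizure endpoint in seconds, or `NA`.
#' @param stimulus_end end of stimulation in seconds; defaults to the value
#'   carried by `segments`.
#' @return `segments` with the `label` field filled.
#' @export
label_segments <- function(segments, reference_endpoint,
                           stimulus_end = segments$stimulus_end) {
  n <- length(segments$start_time)
  if (n == 0L) return(segments)
  if (!is.na(reference_endpoint) && reference_endpoint <= stimulus_end)
    stop("label_segments: reference_endpoint must exceed stimulus_end")
  eps <- 1e-9
  start <- segments$start_time
  lab <- rep("unlabelled", n)
  overlaps_stim <- start < stimulus_end - eps
  if (is.na(reference_endpoint)) {
    lab[overlaps_stim] <- "omitted"
  } else {
    lab[!overlaps_stim & start < reference_endpoint - eps] <- "ictal"
    lab[!overlaps_stim & start >= reference_endpoint - eps] <- "non_ictal"
    lab[overlaps_stim] <- "omitted"
  }
  segments$label <- lab
  segments
}
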