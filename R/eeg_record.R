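#' EEG record container
#'
#' An `eeg_record` holds one ECT-EEG recording: one or two channels of
#' equal-length samples in microvolts, the sampling rate, and the time at
#' which electrical stimulation ended. All times are seconds from the first
#' sample (t = 0), and every window in the package is half-open
#' `[start, end)`.
#'
#' @param channels numeric matrix (samples x channels) or a numeric vector
#'   (one channel), amplitudes in microvolts.
#' @param sampling_rate sampling frequency in Hz.
#' @param stimulus_end end of stimulation, seconds from record start.
#' @param record_id opaque identifier string.
#' @return An object of class `eeg_record` with fields `channels` (matrix),
#'   `sampling_rate`, `stimulus_end`, `record_id`.
#' @export
eeg_record <- function(channels, sampling_rate = 200, stimulus_end = 0,
                       record_id = "record") {
  if (is.vector(channels)) channels <- matrix(channels, ncol = 1)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  rec <- structure(
    list(channels = channels,
         sampling_rate = as.numeric(sampling_rate),
         stimulus_end = as.numeric(stimulus_end),
         record_id = as.character(record_id)),
    class = "eeg_record")
  validate_eeg_record(rec)
  rec
}

validate_eeg_record <- function(rec) {
  if (nrow(rec$channels) < 1L)
    stop("eeg_record: channels must contain at least one sample")
  nch <- ncol(rec$channels)
  if (!nch %in% c(1L, 2L))
    stop("eeg_record: channel_count must be 1 or 2, got ", nch)
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("eeg_record: sampling_rate must be > 0")
  dur <- record_duration(rec)
  if (is.na(rec$stimulus_end))
    stop("eeg_record: stimulus_end is missing; supply it in the file ",
         "metadata or via the stimulus_end argument")
  if (rec$stimulus_end < 0 || rec$stimulus_end >= dur)
    stop("eeg_record: stimulus_end must lie in [0, duration); duration is ",
         dur, " s")
  invisible(rec)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s': %d channel(s), %.2f s at %g Hz, stim end %.2f s>\n",
              x$record_id, ncol(x$channels), record_duration(x),
              x$sampling_rate, x$stimulus_end))
  invisible(x)
}

#' @rdname eeg_record
#' @param record an `eeg_record`.
#' @export
record_duration <- function(record) nrow(record$channels) / record$sampling_rate

#' @rdname eeg_record
#' @export
channel_count <- function(record) ncol(record$channels)

#' Read an EEG recording from disk
#'
#' Supports two dialects: a plain CSV with a metadata comment line
#' `# sampling_rate_hz=<fs> stimulus_end_s=<t>` followed by a header
#' `time_s,ch1[,ch2]`, and EDF (16-bit European Data Format, one or two
#' EEG signals in microvolts, with the end of stimulation stored as an
#' annotation named `STIM_END`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param stimulus_end optional override (seconds) when the file carries no
#'   stimulation marker.
#' @param record_id optional identifier; defaults to the file name.
#' @return An [eeg_record].
#' @export
read_record <- function(path, format = c("auto", "csv", "edf"),
                        stimulus_end = NULL, record_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") read_record_csv(path, stimulus_end, record_id)
  else read_record_edf(path, stimulus_end, record_id)
}

read_record_csv <- function(path, stimulus_end, record_id) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[[1]], "#"))
    stop("CSV record: expected a '# sampling_rate_hz=... stimulus_end_s=...' ",
         "metadata line before the header")
  meta <- lines[[1]]
  fs <- csv_meta_value(meta, "sampling_rate_hz")
  if (is.na(fs)) stop("CSV record: metadata line lacks sampling_rate_hz")
  stim <- csv_meta_value(meta, "stimulus_end_s")
  if (!is.null(stimulus_end)) stim <- stimulus_end
  if (is.na(stim))
    stop("CSV record: no stimulus_end_s in metadata; pass stimulus_end ",
         "explicitly if the marker is known from elsewhere")
  df <- utils::read.csv(path, comment.char = "#")
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) == 0L)
    stop("CSV record: no ch1/ch2 sample columns found")
  eeg_record(as.matrix(df[ch_cols]), sampling_rate = fs,
             stimulus_end = stim, record_id = record_id)
}

csv_meta_value <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, "=([-0-9.eE+]+)"), line))[[1]]
  if (length(m) < 2L) NA_real_ else as.numeric(m[[2]])
}

read_record_edf <- function(path, stimulus_end, record_id) {
  edf <- read_edf(path)
  stim <- if (!is.null(stimulus_end)) stimulus_end else edf$stimulus_end
  if (is.null(stim) || is.na(stim))
    stop("EDF record: no STIM_END annotation found; pass stimulus_end ",
         "explicitly")
  eeg_record(edf$channels, sampling_rate = edf$sampling_rate,
             stimulus_end = stim, record_id = record_id)
}

#' Write an EEG recording to disk
#'
#' Inverse of [read_record()]; the CSV dialect round-trips samples exactly,
#' EDF quantizes to the 16-bit grid spanned by each channel's range.
#'
#' @param record an [eeg_record].
#' @param path destination path.
#' @param format `"auto"`, `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    n <- nrow(record$channels)
    df <- data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate)
    for (j in seq_len(ncol(record$channels)))
      df[[paste0("ch", j)]] <- record$channels[, j]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sampling_rate_hz=%g stimulus_end_s=%g",
                       record$sampling_rate, record$stimulus_end), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    write_edf(record, path)
  }
  invisible(path)
}

#' Filter a recording the way the acquisition device does
#'
#' Applies a 50 Hz notch and a 30 Hz lowpass, both as zero-phase
#' (forward-backward) Butterworth filters so that event timing is not
#' shifted by group delay. Exported recordings may already carry the device
#' filters, hence the `enabled` switch.
#'
#' @param record an [eeg_record].
#' @param notch_hz notch centre frequency (Hz); `NA` disables the notch.
#' @param lowpass_hz lowpass cutoff (Hz); `NA` disables the lowpass.
#' @param enabled if `FALSE` the record is returned untouched.
#' @return A filtered copy of `record`.
#' @export
preprocess <- function(record, notch_hz = 50, lowpass_hz = 30, enabled = TRUE) {
  if (!enabled) return(record)
  nyq <- record$sampling_rate / 2
  if (!is.na(notch_hz) && notch_hz >= nyq)
    stop("preprocess: notch_hz must be below the Nyquist frequency (", nyq, " Hz)")
  if (!is.na(lowpass_hz) && lowpass_hz >= nyq)
    stop("preprocess: lowpass_hz must be below the Nyquist frequency (", nyq, " Hz)")
  out <- record
  for (j in seq_len(ncol(out$channels))) {
    x <- out$channels[, j]
    if (!is.na(notch_hz)) {
      bw <- 2  # +/- 2 Hz stopband around the mains frequency
      bs <- signal::butter(2, c(notch_hz - bw, notch_hz + bw) / nyq, type = "stop")
      x <- signal::filtfilt(bs, x)
    }
    if (!is.na(lowpass_hz)) {
      lp <- signal::butter(4, lowpass_hz / nyq, type = "low")
      x <- signal::filtfilt(lp, x)
    }
    out$channels[, j] <- x
  }
  out
}
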