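# Minimal EDF(+C) support: enough of the 16-bit European Data Format to
# round-trip one or two EEG signals plus an annotations signal carrying the
# end-of-stimulation marker. The whole recording is stored as a single data
# record so samples round-trip without padding.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF field too wide: '", x, "'")
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

write_edf <- function(record, path) {
  ch <- record$channels
  n <- nrow(ch); nsig <- ncol(ch)
  fs <- record$sampling_rate
  dur <- n / fs

  # annotation payload: record onset TAL, then the stimulation marker;
  # TALs are NUL-terminated, so assemble raw bytes (R strings cannot
  # carry embedded NULs)
  ann_raw <- c(charToRaw("+0\x14\x14"), as.raw(0),
               charToRaw(sprintf("+%g\x14STIM_END\x14",
                                 record$stimulus_end)), as.raw(0))
  ann_len <- length(ann_raw) + (length(ann_raw) %% 2)  # even byte count
  ann_raw <- c(ann_raw, rep(as.raw(0), ann_len - length(ann_raw)))
  ann_samples <- ann_len / 2L

  ns_total <- nsig + 1L
  header_bytes <- 256L + 256L * ns_total

  # physical range per signal: round the amplitude ceiling UP to 4
  # significant digits so +/-pm both fit the 8-char header fields, nothing
  # clips, and the reader's parsed range matches the digitisation range
  pmin <- pmax <- numeric(nsig)
  for (j in seq_len(nsig)) {
    m <- max(abs(ch[, j]), 1e-6)
    f <- 10^(floor(log10(m)) - 3)
    m <- ceiling(m / f) * f
    pmax[j] <- m; pmin[j] <- -m
  }

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(edf_pad("0", 8))                               # version
  put(edf_pad(record$record_id, 80))                 # patient id field
  put(edf_pad("Startdate X X X X", 80))              # recording id field
  put(edf_pad("01.01.00", 8)); put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad("EDF+C", 44))
  put(edf_pad(1, 8))                                 # one data record
  put(edf_num(dur, 8))
  put(edf_pad(ns_total, 4))

  labels <- c(paste0("EEG ch", seq_len(nsig)), "EDF Annotations")
  for (lab in labels) put(edf_pad(lab, 16))
  for (i in seq_len(ns_total)) put(edf_pad("", 80))  # transducer
  for (i in seq_len(ns_total)) put(edf_pad(if (i <= nsig) "uV" else "", 8))
  for (i in seq_len(ns_total)) put(edf_num(if (i <= nsig) pmin[i] else -1, 8))
  for (i in seq_len(ns_total)) put(edf_num(if (i <= nsig) pmax[i] else 1, 8))
  for (i in seq_len(ns_total)) put(edf_pad(-32768, 8))
  for (i in seq_len(ns_total)) put(edf_pad(32767, 8))
  for (i in seq_len(ns_total)) put(edf_pad("", 80))  # prefiltering
  for (i in seq_len(ns_total)) put(edf_pad(if (i <= nsig) n else ann_samples, 8))
  for (i in seq_len(ns_total)) put(edf_pad("", 32))  # reserved

  for (j in seq_len(nsig)) {
    scale <- (pmax[j] - pmin[j]) / (32767 - (-32768))
    dig <- as.integer(round((ch[, j] - pmin[j]) / scale) - 32768)
    dig <- pmin(pmax(dig, -32768L), 32767L)
    writeBin(dig, con, size = 2, endian = "little")
  }
  writeBin(ann_raw, con)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- get(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  get(44)
  n_records <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))

  labels <- vapply(seq_len(ns), function(i) get(16), "")
  for (i in seq_len(ns)) get(80)
  dims <- vapply(seq_len(ns), function(i) get(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(32)

  is_ann <- grepl("Annotations", labels)
  sig_idx <- which(!is_ann)
  chans <- vector("list", length(sig_idx))
  names(chans) <- labels[sig_idx]
  for (j in seq_along(chans)) chans[[j]] <- vector("list", n_records)
  ann_text <- character(0)

  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        raw <- readBin(con, "raw", n = 2L * nsamp[i])
        ann_text <- c(ann_text, rawToChar(raw[raw != as.raw(0)]))
      } else {
        dig <- readBin(con, "integer", n = nsamp[i], size = 2,
                       endian = "little")
        j <- match(i, sig_idx)
        scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        chans[[j]][[r]] <- pmin[i] + (dig - dmin[i]) * scale
      }
    }
  }
  channels <- do.call(cbind, lapply(chans, function(l) unlist(l)))

  stim <- NA_real_
  all_ann <- paste(ann_text, collapse = "")
  m <- regmatches(all_ann,
                  regexec("\\+([-0-9.]+)(\\x15[-0-9.]+)?\\x14STIM_END", all_ann))[[1]]
  if (length(m) >= 2) stim <- as.numeric(m[[2]])

  fs <- nsamp[sig_idx[1]] / rec_dur
  list(channels = channels, sampling_rate = fs, stimulus_end = stim,
       labels = labels[sig_idx], dims = dims[sig_idx])
}
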