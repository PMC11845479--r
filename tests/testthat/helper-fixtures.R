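# Shared fixtures, all generated in code.

sine_record <- function(freq, amp = 1, dur = 10, fs = 200, nchan = 1,
                        stimulus_end = 0, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- amp * sin(2 * pi * freq * t + phase)
  ch <- matrix(rep(x, nchan), ncol = nchan)
  eeg_record(ch, sampling_rate = fs, stimulus_end = stimulus_end,
             record_id = "sine")
}

# annotation covering [onset, endpoint) without running detection
fixed_annotation <- function(onset, endpoint) {
  seizure_annotation(onset_time = onset, endpoint_time = endpoint,
                     status = "detected")
}

# small labelled feature table with separable classes (two Gaussian blobs)
separable_table <- function(n_per_class = 120, d = 6, sep = 8, seed = 5) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per_class * d), ncol = d)
  x2 <- matrix(rnorm(n_per_class * d), ncol = d)
  x2[, 1] <- x2[, 1] + sep
  m <- rbind(x1, x2)
  colnames(m) <- paste0("f", seq_len(d))
  df <- data.frame(record_id = "blob",
                   segment_index = seq_len(2 * n_per_class),
                   label = rep(c("non_ictal", "ictal"), each = n_per_class))
  df <- cbind(df, as.data.frame(m))
  ictal:::as_feature_table(df)
}

# expensive shared fixtures, computed once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shared_training_table <- function() {
  cached("training_table", generate_training_set(24, seed = 101))
}

shared_model <- function() {
  cached("model",
         train_classifier(shared_training_table(), "random_forest",
                          seed = 101))
}
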