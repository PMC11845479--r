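# Synthetic ECT-EEG simulator. Generates two-channel 200 Hz records with
# a mixed-frequency baseline, a saturating stimulation artifact, a
# spike-wave ictal phase with an amplitude envelope, and a suppressed
# postictal phase, together with the ground-truth seizure annotation.
# Amplitude parameters are calibrated in mean-absolute-amplitude terms
# (each phase's waveform is normalised to unit mean |x| before scaling),
# so the postictal/late-ictal amplitude ratio equals suppression_ratio by
# construction and PSI recovery can be checked quantitatively.

#' Simulator configuration
#'
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param sampling_rate Hz.
#' @param baseline_s,stimulus_s,ictal_s,postictal_s phase durations (s).
#' @param baseline_amp target mean absolute amplitude of the baseline (uV).
#' @param ictal_amp peak of the ictal mean-amplitude envelope (uV).
#' @param spike_freq spike-wave repetition rate (Hz), in the delta/theta
#'   range typical of ECT seizures.
#' @param suppression_ratio fraction of baseline amplitude retained
#'   postictally (0 = flat suppression, 1 = no suppression).
#' @param noise_sd additive Gaussian sensor noise SD (uV).
#' @param interhemispheric_coupling mixing weight of channel 1 into
#'   channel 2, in [0, 1].
#' @param peak_frac position of the envelope peak within the ictal phase.
#' @param onset_latency seizure onset delay after stimulation end (s).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = NULL, sampling_rate = 200,
                         baseline_s = 5, stimulus_s = 2, ictal_s = 30,
                         postictal_s = 20, baseline_amp = 20,
                         ictal_amp = 150, spike_freq = 3.5,
                         suppression_ratio = 0.2, noise_sd = 1,
                         interhemispheric_coupling = 0.9,
                         peak_frac = 0.3, onset_latency = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$baseline_s >= 0, cfg$stimulus_s >= 0, cfg$ictal_s >= 0,
            cfg$postictal_s >= 0, cfg$baseline_amp > 0, cfg$ictal_amp > 0,
            cfg$suppression_ratio >= 0, cfg$suppression_ratio <= 1,
            cfg$interhemispheric_coupling >= 0,
            cfg$interhemispheric_coupling <= 1)
  structure(cfg, class = "synth_config")
}

# Unit mean-|x| mixed-frequency background: alpha-dominant with theta and
# delta components, random phases.
synth_background <- function(t) {
  x <- 1.0 * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) +
       0.6 * sin(2 * pi * 6 * t + stats::runif(1, 0, 2 * pi)) +
       0.4 * sin(2 * pi * 2.2 * t + stats::runif(1, 0, 2 * pi))
  x / mean(abs(x))
}

# Unit mean-|x| spike-wave: slow wave at spike_freq plus a Gaussian-
# windowed fast transient repeating every cycle, with a random phase so
# repeated realisations differ.
synth_spikewave <- function(t, spike_freq) {
  t <- t + stats::runif(1, 0, 1 / spike_freq)
  period <- 1 / spike_freq
  phase <- (t %% period) / period
  slow <- sin(2 * pi * spike_freq * t)
  burst <- exp(-0.5 * ((phase - 0.25) / 0.07)^2) * sin(2 * pi * 15 * t)
  x <- slow + 1.5 * burst
  x / mean(abs(x))
}

# Ictal mean-amplitude envelope: linear rise from baseline_amp to
# ictal_amp at the peak, then a slow-then-fast (quadratic) decay back to
# baseline_amp, flat over the final `tail_s`. The flat tail spans the
# exclusion zone plus the late-ictal reference segments used by PSI, so
# the postictal/late-ictal amplitude ratio equals suppression_ratio.
synth_envelope <- function(t_rel, ictal_s, baseline_amp, ictal_amp,
                           peak_frac) {
  tail_s <- min(12, ictal_s / 2)
  t_flat <- ictal_s - tail_s
  t_peak <- peak_frac * t_flat
  env <- numeric(length(t_rel))
  up <- t_rel <= t_peak
  env[up] <- baseline_amp + (ictal_amp - baseline_amp) *
    (if (t_peak > 0) t_rel[up] / t_peak else 1)
  down <- t_rel > t_peak & t_rel <= t_flat
  frac <- (t_rel[down] - t_peak) / max(t_flat - t_peak, 1e-9)
  env[down] <- ictal_amp - (ictal_amp - baseline_amp) * frac^2
  env[t_rel > t_flat] <- baseline_amp
  env
}

synth_channel <- function(cfg, t, onset, endpoint) {
  n <- length(t)
  x <- numeric(n)
  bg <- synth_background(t)
  stim_start <- cfg$baseline_s
  stim_end <- cfg$baseline_s + cfg$stimulus_s
  pre <- t < stim_start
  x[pre] <- cfg$baseline_amp * bg[pre]
  stim <- t >= stim_start & t < stim_end
  x[stim] <- 5 * cfg$ictal_amp * sign(sin(2 * pi * 10 * t[stim]) + 1e-12)
  gap <- t >= stim_end & t < onset   # latency between stimulation and onset
  x[gap] <- cfg$baseline_amp * bg[gap]
  ict <- t >= onset & t < endpoint
  if (any(ict)) {
    env <- synth_envelope(t[ict] - onset, cfg$ictal_s, cfg$baseline_amp,
                          cfg$ictal_amp, cfg$peak_frac)
    x[ict] <- env * synth_spikewave(t[ict] - onset, cfg$spike_freq)
  }
  post <- t >= endpoint
  x[post] <- cfg$suppression_ratio * cfg$baseline_amp * bg[post]
  x
}

#' Generate one synthetic ECT-EEG record with ground truth
#'
#' @param config a [synth_config()].
#' @param record_id identifier for the generated record.
#' @return A list: `record` (two-channel [eeg_record]), `annotation`
#'   (ground-truth [seizure_annotation()], onset = stimulation end +
#'   latency, endpoint = onset + `ictal_s`), `config`.
#' @export
generate_record <- function(config = synth_config(), record_id = "synth") {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  total_s <- cfg$baseline_s + cfg$stimulus_s + cfg$onset_latency +
    cfg$ictal_s + cfg$postictal_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  onset <- cfg$baseline_s + cfg$stimulus_s + cfg$onset_latency
  endpoint <- onset + cfg$ictal_s

  ch1 <- synth_channel(cfg, t, onset, endpoint)
  ind <- synth_channel(cfg, t, onset, endpoint)  # independent realisation
  w <- cfg$interhemispheric_coupling
  ch2 <- w * ch1 + sqrt(max(0, 1 - w^2)) * ind
  ch1 <- ch1 + stats::rnorm(n, 0, cfg$noise_sd)
  ch2 <- ch2 + stats::rnorm(n, 0, cfg$noise_sd)

  record <- eeg_record(cbind(ch1, ch2), sampling_rate = fs,
                       stimulus_end = cfg$baseline_s + cfg$stimulus_s,
                       record_id = record_id)
  annotation <- seizure_annotation(onset_time = onset,
                                   endpoint_time = endpoint,
                                   status = "detected")
  list(record = record, annotation = annotation, config = cfg)
}

#' Default parameter ranges for simulated training sets
#'
#' @return Named list of `c(min, max)` ranges drawn per record.
#' @export
default_config_ranges <- function() {
  list(ictal_s = c(15, 40), suppression_ratio = c(0.05, 0.5),
       ictal_amp = c(100, 200), baseline_amp = c(15, 25),
       spike_freq = c(2.5, 5), postictal_s = c(12, 25))
}

#' Generate a labelled synthetic training table
#'
#' Draws per-record parameters uniformly from `config_ranges`, generates
#' each record, labels its segments from the ground-truth interval and
#' extracts features.
#'
#' @param n_records number of records.
#' @param config_ranges named list of `c(min, max)` ranges overriding
#'   [default_config_ranges()] entries.
#' @param seed integer master seed.
#' @param base_config baseline [synth_config()] providing all other
#'   fields.
#' @return A labelled `feature_table`; attributes `class_counts` and
#'   `records` (the generated records with ground truth, for reuse).
#' @export
generate_training_set <- function(n_records, config_ranges = list(),
                                  seed = 1L,
                                  base_config = synth_config()) {
  stopifnot(n_records >= 1L)
  ranges <- utils::modifyList(default_config_ranges(), config_ranges)
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_records)
  draws <- lapply(names(ranges), function(nm)
    stats::runif(n_records, ranges[[nm]][1], ranges[[nm]][2]))
  names(draws) <- names(ranges)

  sets <- vector("list", n_records)
  gen <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    cfg <- base_config
    for (nm in names(draws)) cfg[[nm]] <- draws[[nm]][i]
    cfg$seed <- seeds[i]
    g <- generate_record(cfg, record_id = sprintf("synth_%03d", i))
    segs <- segment_record(g$record)
    segs <- label_segments(segs, g$annotation$endpoint_time)
    gen[[i]] <- g
    sets[[i]] <- segs
  }
  tab <- build_feature_table(sets)
  attr(tab, "class_counts") <- table(tab$label)
  attr(tab, "records") <- gen
  tab
}
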