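# Synthetic scalp-EEG cohorts: 1/f background, sleep spindles, epileptiform
# spike/slow-wave complexes, and injected HFO bursts with configurable
# group x state x band energy factors. Everything is annotated so detection,
# energy and statistics stages can be tested against ground truth.

# deterministic substream: one seed per (group, subject, state) cell
substream_seed <- function(seed, counter) {
  (abs(as.integer(seed)) %% 1000003L) * 2000L + counter %% 2000L
}

#' Generate 1/f background EEG
#'
#' Gaussian noise spectrally shaped so power falls as 1/f above 1 Hz (flat
#' below), then rescaled so every channel has exactly the requested RMS.
#' Deterministic given `seed`.
#'
#' @param duration_s Record length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Channel labels.
#' @param amplitude_rms Per-channel RMS in microvolts (> 0).
#' @param seed Integer seed.
#' @return An `eeg_recording`.
#' @examples
#' bg <- generate_background(2, 500, c("C3", "C4"), 20, seed = 1)
#' @export
generate_background <- function(duration_s, fs, channels = channels_1020(),
                                amplitude_rms = 15, seed = 1) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.numeric(amplitude_rms) || amplitude_rms <= 0)
    stop("amplitude_rms must be > 0")
  n <- round(duration_s * fs)
  freqs <- seq(0, fs - fs / n, length.out = n)
  freqs <- pmin(freqs, fs - freqs)  # two-sided |f|
  shape <- 1 / sqrt(pmax(freqs, 1))
  shape[1] <- 0  # no DC
  set.seed(seed)
  data <- vapply(seq_along(channels), function(j) {
    w <- rnorm(n)
    x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
    x * amplitude_rms / sqrt(mean(x^2))
  }, numeric(n))
  eeg_recording(data, channels, fs)
}

#' Inject a Hann-windowed oscillatory burst
#'
#' Adds `n_cycles` cycles of a sinusoid at `freq_hz`, Hann-windowed with peak
#' amplitude `amplitude_uv`, to one channel, and annotates the recording.
#' The band label follows the analysis bands (gamma 40-80, ripple 80-200,
#' fast ripple 200-300 Hz); frequencies outside 40-300 Hz are still injected
#' but labelled `"out-of-band"`.
#'
#' @param recording An `eeg_recording`.
#' @param channel Target channel label.
#' @param t0 Burst onset in seconds.
#' @param freq_hz Oscillation frequency (< fs/2).
#' @param n_cycles Number of cycles (duration is `n_cycles / freq_hz`).
#' @param amplitude_uv Peak amplitude in microvolts.
#' @return List with the modified `recording` and the injected `event`
#'   (one-row data.frame: channel, band, onset, offset, freq, n_cycles,
#'   peak_amp).
#' @export
inject_burst <- function(recording, channel, t0, freq_hz, n_cycles,
                         amplitude_uv) {
  fs <- recording$fs
  if (freq_hz >= fs / 2) stop("freq_hz must be below Nyquist (fs/2)")
  dur <- n_cycles / freq_hz
  if (t0 < 0 || t0 + dur > recording_duration(recording) + 1e-9)
    stop("burst [", t0, ", ", t0 + dur, "] s exceeds the record")
  j <- match(channel, recording$channel_names)
  if (is.na(j)) stop("no such channel: ", channel)
  i0 <- round(t0 * fs) + 1L
  m <- max(2L, round(dur * fs))
  tt <- (seq_len(m) - 1) / fs
  hann <- 0.5 * (1 - cos(2 * pi * tt / dur))
  s <- amplitude_uv * hann * sin(2 * pi * freq_hz * tt)
  idx <- i0:(i0 + m - 1L)
  recording$data[idx, j] <- recording$data[idx, j] + s
  band <- band_of_freq(freq_hz)
  recording <- annotate(recording, paste0("hfo_", band), t0, dur, channel)
  event <- data.frame(channel = channel, band = band, onset = t0,
                      offset = t0 + dur, freq = freq_hz, n_cycles = n_cycles,
                      peak_amp = amplitude_uv, stringsAsFactors = FALSE)
  list(recording = recording, event = event)
}

#' Inject epileptiform spike/slow-wave complexes
#'
#' Adds biphasic spikes (20-70 ms) each followed by a high-amplitude slow
#' half-wave (200-500 ms) at Poisson-distributed times, on the given
#' channels. Every complex is annotated. Deterministic given `seed`.
#'
#' @param recording An `eeg_recording`.
#' @param channels Channels carrying the discharges.
#' @param rate_per_s Poisson rate of complexes per second (>= 0).
#' @param spike_amp_uv,slow_amp_uv Peak amplitudes in microvolts (>= 0).
#' @param seed Integer seed.
#' @return List with the modified `recording` and `annotations` data.frame
#'   (onset, duration, channels).
#' @export
inject_discharges <- function(recording, channels, rate_per_s,
                              spike_amp_uv = 150, slow_amp_uv = 250,
                              seed = 1) {
  stopifnot(rate_per_s >= 0, spike_amp_uv >= 0, slow_amp_uv >= 0)
  dur_total <- recording_duration(recording)
  fs <- recording$fs
  set.seed(seed)
  n_ev <- rpois(1, rate_per_s * dur_total)
  ann <- data.frame(onset = numeric(), duration = numeric(),
                    channels = character(), stringsAsFactors = FALSE)
  if (n_ev == 0) return(list(recording = recording, annotations = ann))
  onsets <- sort(runif(n_ev, 0, dur_total))
  jdx <- match(channels, recording$channel_names)
  if (anyNA(jdx)) stop("unknown channel(s) in 'channels'")
  for (t0 in onsets) {
    sp_d <- runif(1, 0.02, 0.07)
    sw_d <- runif(1, 0.2, 0.5)
    if (t0 + sp_d + sw_d > dur_total) next
    i0 <- round(t0 * fs) + 1L
    m_sp <- max(2L, round(sp_d * fs))
    m_sw <- max(2L, round(sw_d * fs))
    tt_sp <- (seq_len(m_sp) - 1) / (m_sp - 1)
    tt_sw <- (seq_len(m_sw) - 1) / (m_sw - 1)
    wave <- c(spike_amp_uv * sin(2 * pi * tt_sp),
              slow_amp_uv * sin(pi * tt_sw))
    idx <- i0:(i0 + length(wave) - 1L)
    for (j in jdx) recording$data[idx, j] <- recording$data[idx, j] + wave
    d <- sp_d + sw_d
    recording <- annotate(recording, "discharge", t0, d,
                          paste(channels, collapse = ","))
    ann <- rbind(ann, data.frame(onset = t0, duration = d,
                                 channels = paste(channels, collapse = ","),
                                 stringsAsFactors = FALSE))
  }
  list(recording = recording, annotations = ann)
}

#' Cohort design configuration
#'
#' Captures the simulated study design: an IS (infantile spasms) group with
#' interictal wake/sleep and 2-s pre-spasm/spasm/post-spasm states, and a
#' normal-control (NC) group with wake/sleep only. `band_effects` holds one
#' multiplicative average-energy factor per (group, state, band) cell;
#' injected burst amplitudes are scaled by `sqrt(factor)` since energy is
#' quadratic in amplitude.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param groups Group labels (default `c("IS", "NC")`).
#' @param states Named list of state labels per group.
#' @param fs Sampling rate, Hz; must be at least twice the highest injected
#'   frequency.
#' @param segment_duration Named vector of seconds per state (interictal 300,
#'   spasm stages 2 by default).
#' @param channels Electrode labels.
#' @param band_effects data.frame with columns `group`, `state`, `band`,
#'   `factor` (all factors > 0); missing cells default to 1.
#' @param event_rate Injected HFO events per channel per 5 minutes, split
#'   evenly across the three bands (deterministic per-segment counts).
#' @param background_amplitude Background RMS, microvolts.
#' @param burst_amplitude Baseline burst peak amplitude, microvolts
#'   (scaled by `sqrt(factor)`).
#' @param spindle_amplitude,spindle_rate_per_min Sleep-spindle (11-14 Hz)
#'   burst parameters for sleep segments.
#' @param discharge_rate_per_s,discharge_spike_amp,discharge_slow_amp
#'   Spike/slow-wave complex parameters for IS sleep segments.
#' @param channel_weights Optional named sampling weights biasing which
#'   channels receive bursts (default uniform).
#' @param seed Integer master seed; per-(group, subject, state) substreams
#'   are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_group = 10,
                          groups = c("IS", "NC"),
                          states = list(
                            IS = c("wake", "sleep", "Pre-S", "S", "Post-S"),
                            NC = c("wake", "sleep")),
                          fs = 1000,
                          segment_duration = c(wake = 300, sleep = 300,
                                               "Pre-S" = 2, "S" = 2,
                                               "Post-S" = 2),
                          channels = channels_1020(),
                          band_effects = NULL,
                          event_rate = 12,
                          background_amplitude = 15,
                          burst_amplitude = 60,
                          spindle_amplitude = 30,
                          spindle_rate_per_min = 3,
                          discharge_rate_per_s = 0.3,
                          discharge_spike_amp = 150,
                          discharge_slow_amp = 250,
                          channel_weights = NULL,
                          seed = 1) {
  stopifnot(n_subjects_per_group >= 0, event_rate >= 0,
            background_amplitude > 0, all(segment_duration > 0))
  if (fs < 2 * 300)
    stop("fs must satisfy Nyquist for the 300 Hz analysis ceiling (fs >= 600)")
  missing_states <- setdiff(groups, names(states))
  if (length(missing_states))
    stop("states not defined for group(s): ",
         paste(missing_states, collapse = ", "))
  for (g in groups) {
    nodur <- setdiff(states[[g]], names(segment_duration))
    if (length(nodur))
      stop("segment_duration missing for state(s): ",
           paste(nodur, collapse = ", "))
  }
  if (!is.null(band_effects)) {
    stopifnot(all(c("group", "state", "band", "factor") %in%
                    names(band_effects)))
    if (any(band_effects$factor <= 0)) stop("all band_effects factors must be > 0")
  }
  structure(list(
    n_subjects_per_group = n_subjects_per_group, groups = groups,
    states = states, fs = fs, segment_duration = segment_duration,
    channels = channels, band_effects = band_effects, event_rate = event_rate,
    background_amplitude = background_amplitude,
    burst_amplitude = burst_amplitude,
    spindle_amplitude = spindle_amplitude,
    spindle_rate_per_min = spindle_rate_per_min,
    discharge_rate_per_s = discharge_rate_per_s,
    discharge_spike_amp = discharge_spike_amp,
    discharge_slow_amp = discharge_slow_amp,
    channel_weights = channel_weights, seed = seed),
    class = "cohort_config")
}

effect_factor <- function(config, group, state, band) {
  be <- config$band_effects
  if (is.null(be)) return(1)
  hit <- be$group == group & be$state == state & be$band == band
  if (any(hit)) be$factor[which(hit)[1]] else 1
}

#' Generate an annotated synthetic cohort
#'
#' Builds one state-labelled segment per subject x state. Each segment is 1/f
#' background plus injected HFO bursts whose amplitudes carry the configured
#' `sqrt(band_effects)` scaling; sleep segments additionally carry 11-14 Hz
#' spindles and, in the IS group, spike/slow-wave discharge complexes.
#' Bit-identical for identical config (including seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `hfo_cohort`:
#'   `segments` (list of `eeg_segment`), and `ground_truth` with
#'   `events` (all injected bursts with subject/group/state), `factors`
#'   (the realised (subject, state, band) energy factors) and `discharges`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  bands <- names(hfo_bands())
  segments <- list()
  events <- list()
  factors <- list()
  discharges <- list()
  counter <- 0L
  for (g in config$groups) {
    for (i in seq_len(config$n_subjects_per_group)) {
      subj <- sprintf("%s%02d", g, i)
      for (st in config$states[[g]]) {
        counter <- counter + 1L
        sseed <- substream_seed(config$seed, counter)
        dur <- unname(config$segment_duration[st])
        rec <- generate_background(dur, config$fs, config$channels,
                                   config$background_amplitude, seed = sseed)
        set.seed(sseed + 1L)
        if (st %in% c("sleep", "SED", "SNED")) {
          rec <- add_spindles(rec, config)
          if (g == "IS" && config$discharge_rate_per_s > 0) {
            dd <- inject_discharges(rec, config$channels,
                                    config$discharge_rate_per_s,
                                    config$discharge_spike_amp,
                                    config$discharge_slow_amp,
                                    seed = sseed + 2L)
            rec <- dd$recording
            if (nrow(dd$annotations))
              discharges[[length(discharges) + 1L]] <-
                cbind(subject = subj, group = g, state = st, dd$annotations)
          }
        }
        set.seed(sseed + 3L)
        for (b in bands) {
          fac <- effect_factor(config, g, st, b)
          factors[[length(factors) + 1L]] <- data.frame(
            subject = subj, group = g, state = st, band = b, factor = fac,
            stringsAsFactors = FALSE)
          n_ev <- round(config$event_rate / 3 * length(config$channels) *
                          dur / 300)
          if (n_ev < 1) next
          bd <- hfo_band(b)
          margin <- 0.1 * (bd$high - bd$low)
          w <- config$channel_weights
          prob <- if (is.null(w)) NULL else w[config$channels]
          chs <- sample(config$channels, n_ev, replace = TRUE, prob = prob)
          for (k in seq_len(n_ev)) {
            fr <- runif(1, bd$low + margin, bd$high - margin)
            nc <- sample(6:12, 1)
            t0 <- runif(1, 0.25, dur - 0.25 - nc / fr)
            ib <- inject_burst(rec, chs[k], t0, fr, nc,
                               config$burst_amplitude * sqrt(fac))
            rec <- ib$recording
            events[[length(events) + 1L]] <-
              cbind(subject = subj, group = g, state = st, ib$event)
          }
        }
        seg <- eeg_segment(rec$data, rec$channel_names, rec$fs,
                           rec$annotations, state = st, subject = subj,
                           group = g)
        segments[[paste(subj, st, sep = ".")]] <- seg
      }
    }
  }
  bindrows <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  structure(list(
    segments = segments,
    ground_truth = list(
      events = bindrows(events, data.frame()),
      factors = bindrows(factors, data.frame()),
      discharges = bindrows(discharges, data.frame())),
    config = config), class = "hfo_cohort")
}

add_spindles <- function(rec, config) {
  dur <- recording_duration(rec)
  n_sp <- rpois(1, config$spindle_rate_per_min * dur / 60)
  if (n_sp == 0) return(rec)
  targets <- intersect(c("Fz", "Cz", "C3", "C4"), rec$channel_names)
  if (!length(targets)) targets <- rec$channel_names
  for (k in seq_len(n_sp)) {
    f <- runif(1, 11, 14)
    nc <- round(runif(1, 0.6, 1.2) * f)  # 0.6-1.2 s of spindle
    t0 <- runif(1, 0.2, max(0.21, dur - 0.2 - nc / f))
    ch <- sample(targets, 1)
    if (t0 + nc / f > dur) next
    rec <- inject_burst(rec, ch, t0, f, nc,
                        config$spindle_amplitude)$recording
  }
  rec
}

#' Write a cohort to disk
#'
#' One EDF file (plus annotation sidecar) per segment, and a ground-truth
#' JSON file.
#'
#' @param cohort An `hfo_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$segments)) {
    write_edf(cohort$segments[[nm]], file.path(dir, paste0(nm, ".edf")))
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
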