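# Envelope-threshold HFO detector. The clinical marking definition (at least
# four consecutive, regular oscillations standing out from the background) is
# operationalised as: band-pass, analytic envelope, background level
# mean + amp_factor * SD with one re-estimation pass excluding candidates,
# candidate excursions above the level extended by a lower boundary
# threshold, and a cycle-count / inter-peak-interval regularity rule.

#' Detector parameters
#'
#' @param amp_factor Detection threshold in background-envelope SDs above the
#'   envelope mean (default 3).
#' @param regularity_max Maximum allowed ratio of longest to shortest
#'   inter-peak interval within an event (default 1.5).
#' @param merge_gap Events closer than this gap in seconds are merged
#'   (default 0.01).
#' @param min_rate Minimum events per 5 minutes for the rate rule
#'   (default 2; set 0 for 2-s ictal segments).
#' @param boundary_sd Boundary (extension) threshold in SDs above the
#'   envelope mean: a candidate excursion is widened to the surrounding
#'   region where the envelope stays above `mean + boundary_sd * SD`
#'   (default 0.5; see the methods vignette for the calibration behind the
#'   default).
#' @param min_high_cycles Minimum duration of the above-threshold excursion,
#'   in periods of the band *width* (`min_high_cycles / (band$high -
#'   band$low)` seconds, i.e. multiples of the band's coherence time).
#'   Background envelope excursions above the detection threshold last about
#'   one coherence time at most in every band, whereas a genuine multi-cycle
#'   burst stays above it for longer; the floor (default 1.5) rejects the
#'   former (see the methods vignette for the calibration).
#' @return A `detector_params` list.
#' @export
detector_params <- function(amp_factor = 3, regularity_max = 1.5,
                            merge_gap = 0.01, min_rate = 2,
                            boundary_sd = 0.5, min_high_cycles = 1.5) {
  stopifnot(amp_factor > 0, regularity_max >= 1, merge_gap >= 0,
            min_rate >= 0, min_high_cycles >= 0)
  structure(list(amp_factor = amp_factor, regularity_max = regularity_max,
                 merge_gap = merge_gap, min_rate = min_rate,
                 boundary_sd = boundary_sd,
                 min_high_cycles = min_high_cycles),
            class = "detector_params")
}

#' Background envelope thresholds with candidate re-estimation
#'
#' Computes the detection threshold `t_high = mean + amp_factor * SD` and the
#' boundary threshold `t_ext = mean + boundary_sd * SD` of an envelope. The
#' statistics are estimated, candidate regions (above the provisional
#' `t_high`, widened to the provisional `t_ext`) are excluded, and the
#' thresholds are re-estimated once from the remaining background samples.
#'
#' @param env Envelope vector.
#' @param amp_factor,boundary_sd See [detector_params()].
#' @return List with `t_high`, `t_ext`, `mean`, `sd`.
#' @export
detector_thresholds <- function(env, amp_factor = 3, boundary_sd = 0) {
  pass <- function(m, s) {
    list(t_high = m + amp_factor * s, t_ext = m + boundary_sd * s)
  }
  m1 <- mean(env); s1 <- sd(env)
  if (!is.finite(s1) || s1 == 0)
    return(list(t_high = Inf, t_ext = Inf, mean = m1, sd = 0))
  th1 <- pass(m1, s1)
  excl <- extend_mask(env > th1$t_high, env > th1$t_ext)
  keep <- env[!excl]
  if (length(keep) < 10) keep <- env
  m2 <- mean(keep); s2 <- sd(keep)
  if (!is.finite(s2) || s2 == 0) { m2 <- m1; s2 <- s1 }
  th2 <- pass(m2, s2)
  list(t_high = th2$t_high, t_ext = th2$t_ext, mean = m2, sd = s2)
}

# widen every TRUE run of `core` to the enclosing TRUE run of `loose`
extend_mask <- function(core, loose) {
  if (!any(core)) return(core)
  r <- rle(loose)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- logical(length(core))
  for (k in which(r$values)) {
    if (any(core[starts[k]:ends[k]])) out[starts[k]:ends[k]] <- TRUE
  }
  out
}

# positive strict local maxima of a signal
positive_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(y[i] > y[i - 1] & y[i] > y[i + 1] & y[i] > 0) + 1L
}

# sub-sample peak times by parabolic interpolation (seconds); essential for
# the fast-ripple band where a cycle spans only 3-5 samples
peak_times <- function(y, pk, fs) {
  if (!length(pk)) return(numeric(0))
  num <- y[pk - 1] - y[pk + 1]
  den <- 2 * (y[pk - 1] - 2 * y[pk] + y[pk + 1])
  shift <- ifelse(den != 0, num / den, 0)
  (pk - 1 + shift) / fs
}

# longest run of consecutive in-range inter-peak intervals; returns
# list(npk, intervals) for the best run (npk = peaks in the run)
best_peak_run <- function(pk_times, lo, hi) {
  if (length(pk_times) < 2)
    return(list(npk = length(pk_times), intervals = numeric(0)))
  d <- diff(pk_times)
  ok <- d >= lo & d <= hi
  best_len <- 0L; best_start <- 1L
  cur_len <- 0L
  for (i in seq_along(ok)) {
    if (ok[i]) {
      cur_len <- cur_len + 1L
      if (cur_len > best_len) { best_len <- cur_len; best_start <- i - cur_len + 1L }
    } else cur_len <- 0L
  }
  if (best_len == 0L) return(list(npk = 1L, intervals = numeric(0)))
  list(npk = best_len + 1L, intervals = d[best_start:(best_start + best_len - 1L)])
}

empty_events <- function() {
  data.frame(channel = character(), band = character(), onset = numeric(),
             offset = numeric(), n_cycles = integer(), peak_amp = numeric(),
             regularity = numeric(), stringsAsFactors = FALSE)
}

detect_events_channel <- function(x, fs, band, params, channel = "ch") {
  y <- bandpass(x, band, fs)
  env <- envelope(y)
  th <- detector_thresholds(env, params$amp_factor, params$boundary_sd)
  if (!is.finite(th$t_high)) return(empty_events())
  core <- env > th$t_high
  min_len <- ceiling(params$min_high_cycles / (band$high - band$low) * fs)
  if (min_len > 1 && any(core)) {
    r0 <- rle(core)
    r0$values[r0$values & r0$lengths < min_len] <- FALSE
    core <- inverse.rle(r0)
  }
  mask <- extend_mask(core, env > th$t_ext)
  if (!any(mask)) return(empty_events())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(starts[r$values], ends[r$values])
  pk <- positive_peaks(y)
  pk_t <- peak_times(y, pk, fs)
  lo <- 1 / band$high
  hi <- 1 / band$low
  ev <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    run <- best_peak_run(pk_t[pk >= a & pk <= b], lo, hi)
    if (run$npk < 4) next
    reg <- max(run$intervals) / min(run$intervals)
    if (reg > params$regularity_max) next
    ev[[length(ev) + 1L]] <- data.frame(
      channel = channel, band = band$name, onset = (a - 1) / fs,
      offset = (b - 1) / fs, n_cycles = run$npk,
      peak_amp = max(abs(y[a:b])), regularity = reg,
      stringsAsFactors = FALSE)
  }
  if (!length(ev)) return(empty_events())
  out <- do.call(rbind, ev)
  merge_events(out, params$merge_gap)
}

merge_events <- function(events, merge_gap) {
  if (nrow(events) < 2) return(events)
  events <- events[order(events$onset), , drop = FALSE]
  keep <- events[1, , drop = FALSE]
  for (i in 2:nrow(events)) {
    last <- nrow(keep)
    if (events$onset[i] - keep$offset[last] < merge_gap) {
      keep$offset[last] <- max(keep$offset[last], events$offset[i])
      keep$n_cycles[last] <- keep$n_cycles[last] + events$n_cycles[i]
      keep$peak_amp[last] <- max(keep$peak_amp[last], events$peak_amp[i])
      keep$regularity[last] <- max(keep$regularity[last], events$regularity[i])
    } else keep <- rbind(keep, events[i, , drop = FALSE])
  }
  rownames(keep) <- NULL
  keep
}

#' Detect HFO events in a segment
#'
#' Runs the envelope-threshold detector on every channel of a segment for one
#' analysis band. Returned events are sorted by onset within channel and are
#' non-overlapping per channel.
#'
#' @param segment An `eeg_segment`/`eeg_recording`, or a numeric vector (then
#'   `fs` must be given).
#' @param band An [hfo_band()] or band name.
#' @param params A [detector_params()].
#' @param fs Sampling rate, only for vector input.
#' @return data.frame of events: `channel`, `band`, `onset`, `offset` (s),
#'   `n_cycles`, `peak_amp` (microvolts), `regularity`.
#' @export
detect_events <- function(segment, band, params = detector_params(),
                          fs = NULL) {
  if (is.character(band)) band <- hfo_band(band)
  if (is.numeric(segment)) {
    if (is.null(fs)) stop("fs required for vector input")
    if (length(segment) / fs < 8 / band$low)
      stop("segment shorter than 8 / band.low = ", 8 / band$low, " s")
    return(detect_events_channel(segment, fs, band, params))
  }
  fs <- segment$fs
  if (nrow(segment$data) / fs < 8 / band$low)
    stop("segment shorter than 8 / band.low = ", 8 / band$low, " s")
  out <- lapply(segment$channel_names, function(ch)
    detect_events_channel(segment$data[, ch], fs, band, params, channel = ch))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply the minimum-rate rule
#'
#' HFOs must appear at least `min_rate` times per 5 minutes in a channel to
#' be retained; otherwise all its events are dropped. Applied as a rate so a
#' shorter segment is scaled to the 5-minute window (2 events in 120 s is a
#' rate of 5 per 5 min and is kept).
#'
#' @param events Events from one channel and band.
#' @param segment_duration_s Duration of the analysed segment in seconds.
#' @param min_rate Minimum events per 5 minutes (default 2).
#' @return The events unchanged, or an empty event table.
#' @export
apply_rate_rule <- function(events, segment_duration_s, min_rate = 2) {
  if (nrow(events) == 0) return(events)
  if (length(unique(events$channel)) > 1 || length(unique(events$band)) > 1)
    stop("apply_rate_rule expects events from a single channel and band")
  rate <- nrow(events) / (segment_duration_s / 300)
  if (rate >= min_rate) events else events[0, , drop = FALSE]
}
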