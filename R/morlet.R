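# Morlet-wavelet time-frequency energy. Complex Morlet atoms with omega0
# cycles (default 6); the response at each analysis frequency is calibrated
# so a sinusoid of amplitude a yields its mean-square power a^2/2 at its own
# frequency, independent of frequency. Power units are therefore uV^2.

sigma_t_of <- function(freq, omega0) omega0 / (2 * pi * freq)

# frequency grids per band: 2 Hz steps in gamma, 5 Hz in ripple/fast ripple
band_freq_grid <- function(band, step = NULL) {
  if (is.character(band)) band <- hfo_band(band)
  if (is.null(step)) step <- if (band$name == "gamma") 2 else 5
  seq(band$low, band$high - step / 2, by = step)
}

# mean power per frequency (time-averaged, per-frequency edge exclusion of
# one half wavelet = 3 sigma_t); single FFT of the reflect-padded signal
morlet_power_means <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  pad <- ceiling(3 * sigma_t_of(min(freqs), omega0) * fs)
  pad <- min(pad, n - 1)
  ext <- c(x[seq(pad + 1, 2)], x, x[seq(n - 1, n - pad)])
  ne <- length(ext)
  X <- fft(ext)
  nu <- seq(0, ne - 1) * fs / ne
  nu <- ifelse(nu > fs / 2, nu - fs, nu)
  vapply(freqs, function(f) {
    st <- sigma_t_of(f, omega0)
    H <- exp(-2 * pi^2 * st^2 * (nu - f)^2)
    w <- fft(X * H, inverse = TRUE) / ne
    p <- 2 * Mod(w[(pad + 1):(pad + n)])^2
    excl <- min(ceiling(3 * st * fs), floor((n - 1) / 2))
    mean(p[(excl + 1):(n - excl)])
  }, numeric(1))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves the signal with L2-area-calibrated complex Morlet wavelets
#' (`omega0` cycles) at each requested frequency. The returned power is
#' `2 |W(f,t)|^2`, calibrated so an infinite unit-amplitude sinusoid at `f`
#' yields power 1/2 (its mean square) at `f`, independent of frequency.
#'
#' @param x Numeric signal (microvolts).
#' @param fs Sampling rate (Hz).
#' @param freqs Analysis frequencies (all below `fs/2`).
#' @param omega0 Wavelet width in cycles (>= 5, default 6).
#' @return A `tf_map`: list with `freqs`, `times`, `power` (frequency x time
#'   matrix, microvolts squared), `fs`, `omega0`.
#' @export
morlet_tfr <- function(x, fs, freqs, omega0 = 6) {
  stopifnot(omega0 >= 5, length(freqs) >= 1)
  if (max(freqs) >= fs / 2)
    stop("analysis frequency at or above Nyquist (fs/2 = ", fs / 2, ")")
  if (is.unsorted(freqs, strictly = TRUE)) freqs <- sort(unique(freqs))
  n <- length(x)
  pad <- ceiling(3 * sigma_t_of(min(freqs), omega0) * fs)
  pad <- min(pad, n - 1)
  ext <- c(x[seq(pad + 1, 2)], x, x[seq(n - 1, n - pad)])
  ne <- length(ext)
  X <- fft(ext)
  nu <- seq(0, ne - 1) * fs / ne
  nu <- ifelse(nu > fs / 2, nu - fs, nu)
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    st <- sigma_t_of(freqs[i], omega0)
    H <- exp(-2 * pi^2 * st^2 * (nu - freqs[i])^2)
    w <- fft(X * H, inverse = TRUE) / ne
    power[i, ] <- 2 * Mod(w[(pad + 1):(pad + n)])^2
  }
  structure(list(freqs = freqs, times = (seq_len(n) - 1) / fs, power = power,
                 fs = fs, omega0 = omega0), class = "tf_map")
}

#' Average band energy of a time-frequency map
#'
#' Mean power over all grid points with frequency in `[band$low, band$high)`
#' and time inside `time_window`, excluding samples within one wavelet
#' half-length (3 sigma_t at each frequency) of the segment boundaries.
#'
#' @param tfmap A [morlet_tfr()] result.
#' @param band An [hfo_band()] or band name.
#' @param time_window Optional `c(t0, t1)` in seconds.
#' @return Average energy in microvolts squared.
#' @export
average_band_energy <- function(tfmap, band, time_window = NULL) {
  if (is.character(band)) band <- hfo_band(band)
  fsel <- which(tfmap$freqs >= band$low & tfmap$freqs < band$high)
  if (!length(fsel))
    stop("no analysis frequencies inside band '", band$name, "'")
  n <- length(tfmap$times)
  total <- 0; count <- 0
  for (i in fsel) {
    st <- sigma_t_of(tfmap$freqs[i], tfmap$omega0)
    excl <- min(ceiling(3 * st * tfmap$fs), floor((n - 1) / 2))
    tsel <- (excl + 1):(n - excl)
    if (!is.null(time_window))
      tsel <- tsel[tfmap$times[tsel] >= time_window[1] &
                     tfmap$times[tsel] <= time_window[2]]
    if (!length(tsel)) next
    total <- total + sum(tfmap$power[i, tsel])
    count <- count + length(tsel)
  }
  if (count == 0) stop("empty time selection for band '", band$name, "'")
  total / count
}

#' Per-channel average band energies of a cohort
#'
#' Computes, for every segment and channel, the Morlet average energy in each
#' analysis band, on average-referenced signals (the montage used for the
#' high-frequency analysis). One row per subject x channel x state x band.
#'
#' @param segments List of `eeg_segment`s carrying `subject`, `group`,
#'   `state` metadata (e.g. from [generate_cohort()]).
#' @param bands List of bands (default all three).
#' @param freq_step Optional named vector overriding the per-band frequency
#'   grid step (Hz), e.g. `c(gamma = 4, ripple = 10, fast_ripple = 10)` for a
#'   coarser, faster grid.
#' @param omega0 Wavelet cycles (default 6).
#' @param average_reference Apply the average montage first (default TRUE).
#' @return data.frame: `subject`, `group`, `channel`, `state`, `band`,
#'   `avg_energy`.
#' @export
channel_band_energies <- function(segments, bands = hfo_bands(),
                                  freq_step = NULL, omega0 = 6,
                                  average_reference = TRUE) {
  if (!length(segments)) {
    return(data.frame(subject = character(), group = character(),
                      channel = character(), state = character(),
                      band = character(), avg_energy = numeric(),
                      stringsAsFactors = FALSE))
  }
  grids <- lapply(bands, function(b)
    band_freq_grid(b, step = if (!is.null(freq_step)) freq_step[[b$name]]
                   else NULL))
  out <- vector("list", length(segments))
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    if (is.null(seg$subject) || is.na(seg$subject) || is.null(seg$state) ||
        is.na(seg$state))
      stop("segment ", k, " lacks subject/state metadata")
    work <- if (average_reference && ncol(seg$data) > 1)
      apply_montage(seg, "average_reference") else seg
    rows <- list()
    for (ch in work$channel_names) {
      x <- work$data[, ch]
      for (bi in seq_along(bands)) {
        pm <- morlet_power_means(x, seg$fs, grids[[bi]], omega0)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = seg$subject, group = seg$group, channel = ch,
          state = seg$state, band = bands[[bi]]$name,
          avg_energy = mean(pm), stringsAsFactors = FALSE)
      }
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Responsible leads and lobe summary
#'
#' The channel with the largest average HFO energy for a subject is its
#' responsible lead. Channels are ranked per subject on energy pooled (mean)
#' over the requested states and bands; ties are broken by canonical 10-20
#' channel order and flagged.
#'
#' @param table A [channel_band_energies()] table.
#' @param top_k Number of leads to return per subject (>= 1).
#' @param states,bands Optional filters before pooling.
#' @return A `lead_summary`: list with `leads` (subject, rank, channel, lobe,
#'   energy, tie) and `lobe_counts` (lobe counts over all returned leads).
#' @export
responsible_leads <- function(table, top_k = 1, states = NULL, bands = NULL) {
  if (!is.numeric(top_k) || top_k < 1) stop("top_k must be >= 1")
  if (!nrow(table)) stop("empty energy table")
  if (!is.null(states)) table <- table[table$state %in% states, , drop = FALSE]
  if (!is.null(bands)) table <- table[table$band %in% bands, , drop = FALSE]
  if (!nrow(table)) stop("no rows left after state/band filtering")
  canon <- function(ch) {
    i <- match(ch, CHANNELS_1020)
    ifelse(is.na(i), length(CHANNELS_1020) + rank(ch), i)
  }
  leads <- list()
  for (subj in unique(table$subject)) {
    sub <- table[table$subject == subj, , drop = FALSE]
    agg <- tapply(sub$avg_energy, sub$channel, mean)
    ch <- names(agg); en <- as.numeric(agg)
    ord <- order(-en, canon(ch))
    k <- min(top_k, length(ch))
    sel <- ord[seq_len(k)]
    tie <- duplicated(en[ord]) | rev(duplicated(rev(en[ord])))
    leads[[subj]] <- data.frame(
      subject = subj, rank = seq_len(k), channel = ch[sel],
      lobe = lobe_of(ch[sel]), energy = en[sel], tie = tie[seq_len(k)],
      stringsAsFactors = FALSE)
  }
  leads <- do.call(rbind, leads)
  rownames(leads) <- NULL
  counts <- table(factor(leads$lobe, levels = c("frontal", "temporal",
                                                "central", "parietal",
                                                "occipital")))
  structure(list(leads = leads, lobe_counts = counts),
            class = "lead_summary")
}

#' Energy table restricted to each subject's responsible lead
#'
#' The study's summary ambiguity (per-channel averages versus the responsible
#' lead only) is resolved by computing both: [channel_band_energies()] is the
#' per-channel table, and this helper restricts it to each subject's
#' top-ranked lead so the two summaries can be reported side by side.
#'
#' @param table A [channel_band_energies()] table.
#' @param leads Optional [responsible_leads()] result (computed from `table`
#'   by default).
#' @return The rows of `table` belonging to each subject's rank-1 lead, with
#'   a `lead` column attached.
#' @export
lead_restricted_energies <- function(table, leads = responsible_leads(table)) {
  top <- leads$leads[leads$leads$rank == 1, c("subject", "channel")]
  out <- merge(table, top, by = c("subject", "channel"))
  out$lead <- out$channel
  out[order(out$subject, out$state, out$band), ]
}
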