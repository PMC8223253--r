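# Brute-force event scanner: an independent, loop-based implementation of the
# detection rules (amplitude excursion, duration floor, boundary extension,
# >= 4 regular cycles, merging). Shares only the signal primitives (bandpass,
# envelope, threshold estimation) with the production detector; all event
# logic is re-derived sample by sample.

oracle_detect <- function(x, fs, band, params = detector_params(),
                          channel = "ch") {
  if (is.character(band)) band <- hfo_band(band)
  y <- bandpass(x, band, fs)
  env <- envelope(y)
  th <- detector_thresholds(env, params$amp_factor, params$boundary_sd)
  empty <- data.frame(channel = character(), band = character(),
                      onset = numeric(), offset = numeric(),
                      n_cycles = integer(), peak_amp = numeric(),
                      regularity = numeric(), stringsAsFactors = FALSE)
  if (!is.finite(th$t_high)) return(empty)
  n <- length(y)
  min_len <- ceiling(params$min_high_cycles / (band$high - band$low) * fs)
  # scan for qualifying excursions, extend each to the boundary threshold
  extents <- list()
  i <- 1L
  while (i <= n) {
    if (env[i] > th$t_high) {
      j <- i
      while (j < n && env[j + 1] > th$t_high) j <- j + 1L
      if (j - i + 1L >= min_len) {
        a <- i; while (a > 1L && env[a - 1] > th$t_ext) a <- a - 1L
        b <- j; while (b < n && env[b + 1] > th$t_ext) b <- b + 1L
        extents[[length(extents) + 1L]] <- c(a, b)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(extents)) return(empty)
  # distinct extents only (two excursions inside one boundary region share it)
  extents <- unique(do.call(rbind, extents))
  # peaks by explicit comparison, sub-sample refined
  pk <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1] && y[i] > 0) pk <- c(pk, i)
  }
  pk_t <- numeric(length(pk))
  for (q in seq_along(pk)) {
    i <- pk[q]
    den <- 2 * (y[i - 1] - 2 * y[i] + y[i + 1])
    sh <- if (den != 0) (y[i - 1] - y[i + 1]) / den else 0
    pk_t[q] <- (i - 1 + sh) / fs
  }
  lo <- 1 / band$high; hi <- 1 / band$low
  accepted <- empty
  for (r in seq_len(nrow(extents))) {
    a <- extents[r, 1]; b <- extents[r, 2]
    tt <- pk_t[pk >= a & pk <= b]
    # try every contiguous window of peaks; keep the longest valid run,
    # earliest wins ties
    best <- NULL; best_len <- 0L
    for (i in seq_along(tt)) {
      for (j in seq_along(tt)) {
        if (j <= i) next
        d <- diff(tt[i:j])
        if (all(d >= lo & d <= hi)) {
          if (j - i + 1L > best_len) { best_len <- j - i + 1L; best <- d }
        }
      }
    }
    npk <- if (best_len > 0L) best_len else min(1L, length(tt))
    if (npk < 4L) next
    reg <- max(best) / min(best)
    if (reg > params$regularity_max) next
    accepted <- rbind(accepted, data.frame(
      channel = channel, band = band$name, onset = (a - 1) / fs,
      offset = (b - 1) / fs, n_cycles = npk,
      peak_amp = max(abs(y[a:b])), regularity = reg,
      stringsAsFactors = FALSE))
  }
  if (nrow(accepted) < 2) { rownames(accepted) <- NULL; return(accepted) }
  # merge by explicit walk
  accepted <- accepted[order(accepted$onset), , drop = FALSE]
  out <- accepted[1, , drop = FALSE]
  for (i in 2:nrow(accepted)) {
    k <- nrow(out)
    if (accepted$onset[i] - out$offset[k] < params$merge_gap) {
      out$offset[k] <- max(out$offset[k], accepted$offset[i])
      out$n_cycles[k] <- out$n_cycles[k] + accepted$n_cycles[i]
      out$peak_amp[k] <- max(out$peak_amp[k], accepted$peak_amp[i])
      out$regularity[k] <- max(out$regularity[k], accepted$regularity[i])
    } else out <- rbind(out, accepted[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# Holm step-down oracle: literal definition, loop over sorted order
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, min(1, (m - j + 1) * p[o[j]]))
    adj[o[j]] <- running
  }
  adj
}

# shorthand used across detection tests: amplitude reference = SD of the
# broadband background envelope
broadband_env_sd <- function(x) sd(envelope(x))
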