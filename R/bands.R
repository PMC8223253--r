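#' HFO frequency bands
#'
#' The three analysis bands used throughout: gamma (40-80 Hz), ripple
#' (80-200 Hz) and fast ripple (200-300 Hz). Band membership of a frequency f
#' is half-open, `low <= f < high`, except the fast-ripple band which is
#' closed at 300 Hz (the upper analysis filter limit).
#'
#' @param name One of `"gamma"`, `"ripple"`, `"fast_ripple"`.
#' @return `hfo_band(name)` returns a list with elements `name`, `low`, `high`
#'   (Hz); `hfo_bands()` returns a named list of all three.
#' @examples
#' hfo_band("ripple")$low
#' @export
hfo_band <- function(name) {
  name <- match.arg(name, c("gamma", "ripple", "fast_ripple"))
  lims <- switch(name,
    gamma = c(40, 80),
    ripple = c(80, 200),
    fast_ripple = c(200, 300))
  structure(list(name = name, low = lims[1], high = lims[2]),
            class = "hfo_band")
}

#' @rdname hfo_band
#' @export
hfo_bands <- function() {
  nm <- c("gamma", "ripple", "fast_ripple")
  setNames(lapply(nm, hfo_band), nm)
}

#' Band label of an oscillation frequency
#'
#' @param freq_hz Frequency in Hz.
#' @return `"gamma"`, `"ripple"`, `"fast_ripple"`, or `"out-of-band"` for
#'   frequencies outside 40-300 Hz.
#' @export
band_of_freq <- function(freq_hz) {
  stopifnot(is.numeric(freq_hz), length(freq_hz) == 1L, is.finite(freq_hz))
  if (freq_hz >= 40 && freq_hz < 80) "gamma"
  else if (freq_hz >= 80 && freq_hz < 200) "ripple"
  else if (freq_hz >= 200 && freq_hz <= 300) "fast_ripple"
  else "out-of-band"
}

#' Lobe attribution of a 10-20 electrode
#'
#' F7/F8 are assigned to the temporal lobe (anterior temporal convention);
#' this choice moves electrodes between the frontal and temporal counts and
#' is therefore part of the documented configuration.
#'
#' @param channel A 10-20 electrode label (vectorised).
#' @return Character vector of lobes: `"frontal"`, `"temporal"`, `"central"`,
#'   `"parietal"` or `"occipital"`.
#' @examples
#' lobe_of(c("T5", "Fp2"))
#' @export
lobe_of <- function(channel) {
  map <- c(Fp1 = "frontal", Fp2 = "frontal", F3 = "frontal", F4 = "frontal",
           Fz = "frontal",
           F7 = "temporal", F8 = "temporal", T3 = "temporal", T4 = "temporal",
           T5 = "temporal", T6 = "temporal",
           C3 = "central", C4 = "central", Cz = "central",
           P3 = "parietal", P4 = "parietal", Pz = "parietal",
           O1 = "occipital", O2 = "occipital")
  bad <- setdiff(channel, names(map))
  if (length(bad))
    stop("unknown 10-20 channel label(s): ", paste(bad, collapse = ", "))
  unname(map[channel])
}
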