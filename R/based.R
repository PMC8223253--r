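# BASED (Burden of Amplitudes and Epileptiform Discharges) severity scoring
# for infantile spasms, and the treatment-efficacy classification. Scoring
# operates on annotated inputs (discharge annotations from a reader or the
# simulator) over the worst 5 minutes of longitudinal-bipolar EEG; spike
# detection itself is deliberately not re-invented here.

#' Discharge density over 1-s windows
#'
#' Fraction of the 300 non-overlapping 1-s windows of a 5-min segment that
#' contain at least one annotated discharge. A discharge spanning a window
#' boundary counts in every window it touches (conservative toward higher
#' density).
#'
#' @param annotations data.frame with `onset` and `duration` columns
#'   (seconds, relative to segment start).
#' @param segment_duration_s Must be 300 (the scale is defined on the most
#'   severe 5 minutes).
#' @return Fraction in `[0, 1]`.
#' @export
discharge_density <- function(annotations, segment_duration_s = 300) {
  if (abs(segment_duration_s - 300) > 1e-9)
    stop("BASED discharge density is defined on a 300-s segment")
  n_win <- 300L
  if (is.null(annotations) || !nrow(annotations)) return(0)
  hit <- logical(n_win)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations$onset[i]
    b <- a + annotations$duration[i]
    w0 <- max(0L, floor(a))
    w1 <- min(n_win - 1L, if (b > floor(b)) floor(b) else floor(b) - 1L)
    if (w1 >= w0) hit[(w0:w1) + 1L] <- TRUE
  }
  sum(hit) / n_win
}

#' Slow-wave amplitude per bipolar derivation
#'
#' Peak-to-peak amplitude of the 0.5-3 Hz filtered trace for each derivation
#' of a longitudinal-bipolar segment.
#'
#' @param segment An `eeg_segment` already in bipolar montage (or any
#'   recording; each column is treated as one derivation).
#' @return Named numeric vector, microvolts peak-to-peak.
#' @export
slow_wave_amplitude <- function(segment) {
  fs <- segment$fs
  coef <- butter_bandpass(0.5, 3, fs, order = 2)
  vapply(seq_len(ncol(segment$data)), function(j) {
    y <- filtfilt(coef$b, coef$a, segment$data[, j],
                  padlen = min(nrow(segment$data) - 1, round(2 * fs)))
    diff(range(y))
  }, numeric(1)) |> setNames(segment$channel_names)
}

#' Assemble a BASED scoring input
#'
#' @param density Discharge density from [discharge_density()] (fraction of
#'   1-s windows).
#' @param slow_amp_uv Slow-wave peak-to-peak amplitudes per bipolar
#'   derivation (microvolts); a scalar is accepted.
#' @param n_foci Number of distinct spike foci (0 = no spikes, 1 = focal,
#'   >= 2 = multifocal).
#' @return A `based_input` list.
#' @export
based_input <- function(density, slow_amp_uv, n_foci) {
  stopifnot(density >= 0, density <= 1, all(slow_amp_uv >= 0), n_foci >= 0)
  structure(list(density = density, slow_amp_uv = slow_amp_uv,
                 n_foci = n_foci), class = "based_input")
}

#' BASED score (2-5)
#'
#' Decision ladder over the quantitative criteria:
#' 5 if discharge density > 50% of 1-s windows, or slow-wave amplitude
#' exceeds 300 uV on more than half the derivations (widespread);
#' 4 if density <= 50% and slow-wave amplitude reaches 200 uV
#' (exactly 200 uV scores 4 and is flagged via a warning, the captions
#' leave the boundary open);
#' 3 for multifocal spikes with slow waves below 200 uV;
#' 2 for a single spike focus. Scores 0-1 (no epileptiform activity) are not
#' applicable to this scale and raise an error.
#'
#' @param input A [based_input()].
#' @return Integer score in 2..5.
#' @export
based_score <- function(input) {
  stopifnot(inherits(input, "based_input"))
  amp <- input$slow_amp_uv
  widespread_300 <- mean(amp > 300) > 0.5
  max_amp <- max(amp)
  if (input$density > 0.5 || widespread_300) return(5L)
  if (max_amp >= 200) {
    if (abs(max_amp - 200) < 1e-9)
      warning("slow-wave amplitude exactly 200 uV: boundary case scored 4")
    return(4L)
  }
  if (input$n_foci >= 2) return(3L)
  if (input$n_foci == 1) return(2L)
  stop("no epileptiform activity: BASED scores 0-1 are not applicable")
}

#' Classify treatment efficacy
#'
#' Effective requires both a clinical response (`controlled` or `improved`)
#' and a post-treatment BASED score of 3 or less; a score of 4 or more is
#' ineffective regardless of clinical class.
#'
#' @param clinical_class `"controlled"`, `"improved"` or `"ineffective"`.
#' @param based_after Post-treatment BASED score (2-5).
#' @return List: `clinical_class`, `based_score`, `final_label`
#'   (`"effective"` / `"ineffective"`).
#' @export
classify_efficacy <- function(clinical_class, based_after) {
  clinical_class <- match.arg(clinical_class,
                              c("controlled", "improved", "ineffective"))
  if (!is.numeric(based_after) || based_after < 2 || based_after > 5)
    stop("based_after must be in 2..5")
  eff <- clinical_class %in% c("controlled", "improved") && based_after <= 3
  list(clinical_class = clinical_class, based_score = as.integer(based_after),
       final_label = if (eff) "effective" else "ineffective")
}

#' Treatment efficiency
#'
#' `efficiency = (controlled + improved) / total * 100%`.
#'
#' @param n_controlled,n_improved,n_total Case counts.
#' @return Percentage.
#' @examples
#' efficiency(10, 6, 30)  # 53.33...
#' @export
efficiency <- function(n_controlled, n_improved, n_total) {
  stopifnot(n_controlled >= 0, n_improved >= 0)
  if (n_total <= 0) stop("n_total must be positive")
  if (n_controlled + n_improved > n_total)
    stop("controlled + improved exceeds total")
  (n_controlled + n_improved) / n_total * 100
}
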