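# Referencing schemes. The average montage subtracts the all-channel mean at
# every sample (all 19 scalp electrodes, midline included); the longitudinal
# bipolar ("double banana") montage chains adjacent electrodes.

LONGITUDINAL_BIPOLAR <- list(
  c("Fp1", "F7"), c("F7", "T3"), c("T3", "T5"), c("T5", "O1"),
  c("Fp1", "F3"), c("F3", "C3"), c("C3", "P3"), c("P3", "O1"),
  c("Fp2", "F4"), c("F4", "C4"), c("C4", "P4"), c("P4", "O2"),
  c("Fp2", "F8"), c("F8", "T4"), c("T4", "T6"), c("T6", "O2"),
  c("Fz", "Cz"), c("Cz", "Pz"))

#' Montage definition
#'
#' @param kind `"average_reference"` or `"longitudinal_bipolar"`.
#' @return A `montage` object. For the bipolar kind the derivation list is the
#'   standard double-banana chain (e.g. Fp1-F7, F7-T3, ...).
#' @export
montage <- function(kind = c("average_reference", "longitudinal_bipolar")) {
  kind <- match.arg(kind)
  derivations <- if (kind == "longitudinal_bipolar") LONGITUDINAL_BIPOLAR
    else NULL
  structure(list(kind = kind, derivations = derivations), class = "montage")
}

#' Apply a referencing montage
#'
#' `average_reference` subtracts the mean of all channels from each channel at
#' every sample (output channels sum to zero). `longitudinal_bipolar` returns
#' the chained pairwise differences with labels like `"Fp1-F7"`.
#'
#' @param recording An `eeg_recording` or `eeg_segment`.
#' @param m A [montage()] object or montage kind string.
#' @return A recording of the same class with re-referenced data.
#' @export
apply_montage <- function(recording, m = montage("average_reference")) {
  if (is.character(m)) m <- montage(m)
  x <- recording$data
  if (m$kind == "average_reference") {
    recording$data <- x - rowMeans(x)
    return(recording)
  }
  need <- unique(unlist(m$derivations))
  missing <- setdiff(need, recording$channel_names)
  if (length(missing))
    stop("montage requires missing channel(s): ",
         paste(missing, collapse = ", "))
  out <- vapply(m$derivations,
                function(d) x[, d[1]] - x[, d[2]], numeric(nrow(x)))
  labels <- vapply(m$derivations, function(d) paste(d, collapse = "-"),
                   character(1))
  colnames(out) <- labels
  recording$data <- out
  recording$channel_names <- labels
  recording
}
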