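#' Multichannel EEG recording
#'
#' Container for a multichannel scalp EEG record: a samples x channels
#' matrix in microvolts, a sampling rate, and an annotation table
#' (label, onset_s, duration_s, channel; channel `"all"` marks whole-head
#' annotations such as state labels).
#'
#' @param data Numeric matrix, samples in rows, one column per channel.
#' @param channel_names Unique channel labels, one per column.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional data.frame with columns `label`, `onset_s`,
#'   `duration_s`, `channel`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, fs, annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (ncol(data) != length(channel_names))
    stop("channel_names length (", length(channel_names),
         ") does not match number of columns (", ncol(data), ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel labels: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (is.null(annotations)) annotations <- empty_annotations()
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("label", "onset_s", "duration_s", "channel") %in%
                  names(annotations)))
  dur <- nrow(data) / fs
  if (nrow(annotations) &&
      any(annotations$onset_s < 0 |
          annotations$onset_s + annotations$duration_s > dur + 1e-9))
    stop("annotation window outside the record [0, ", dur, "] s")
  colnames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names, fs = fs,
                 annotations = annotations),
            class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(label = character(), onset_s = numeric(),
             duration_s = numeric(), channel = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x$data), " ch x ",
      sprintf("%.3f", nrow(x$data) / x$fs), " s @ ", x$fs, " Hz, ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An `eeg_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(recording) {
  nrow(recording$data) / recording$fs
}

annotate <- function(recording, label, onset_s, duration_s, channel = "all") {
  recording$annotations <- rbind(
    recording$annotations,
    data.frame(label = label, onset_s = onset_s, duration_s = duration_s,
               channel = channel, stringsAsFactors = FALSE))
  recording
}

#' Extract a state-labelled segment from a recording
#'
#' Returns the first annotated window carrying `state_label` that is at least
#' `duration_s` long, trimmed to exactly `duration_s`. Segment times are
#' seconds from record start, half-open `[onset, onset + duration)`.
#'
#' @param recording An `eeg_recording` whose annotations include state labels
#'   (channel `"all"`).
#' @param state_label State name, e.g. `"SED"`, `"WED"`, `"SNED"`, `"WNED"`,
#'   `"Pre-S"`, `"S"`, `"Post-S"`, `"wake"`, `"sleep"`.
#' @param duration_s Requested duration in seconds.
#' @param subject,group Optional metadata attached to the segment.
#' @return An `eeg_segment`: an `eeg_recording` restricted to the window, with
#'   `state`, `onset` (s), `subject` and `group` fields; annotations are
#'   re-expressed relative to the segment start.
#' @export
extract_segment <- function(recording, state_label, duration_s,
                            subject = NA_character_, group = NA_character_) {
  ann <- recording$annotations
  hit <- ann[ann$label == state_label &
               ann$duration_s >= duration_s - 1e-9, , drop = FALSE]
  if (!nrow(hit)) {
    avail <- unique(ann$label[ann$channel == "all"])
    stop("no annotated window with label '", state_label, "' of at least ",
         duration_s, " s; available labels: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  onset <- hit$onset_s[1]
  fs <- recording$fs
  i0 <- round(onset * fs) + 1L
  i1 <- i0 + round(duration_s * fs) - 1L
  seg_data <- recording$data[i0:i1, , drop = FALSE]
  inside <- ann$onset_s >= onset - 1e-9 &
    ann$onset_s + ann$duration_s <= onset + duration_s + 1e-9 &
    ann$label != state_label
  seg_ann <- ann[inside, , drop = FALSE]
  seg_ann$onset_s <- seg_ann$onset_s - onset
  seg <- eeg_recording(seg_data, recording$channel_names, fs, seg_ann)
  seg$state <- state_label
  seg$onset <- onset
  seg$subject <- subject
  seg$group <- group
  class(seg) <- c("eeg_segment", class(seg))
  seg
}

#' Build a segment directly from data
#'
#' Convenience constructor used by the cohort generator: wraps a matrix as an
#' `eeg_segment` with state/subject/group metadata.
#'
#' @inheritParams eeg_recording
#' @param state,subject,group Metadata labels.
#' @return An `eeg_segment`.
#' @export
eeg_segment <- function(data, channel_names, fs, annotations = NULL,
                        state = NA_character_, subject = NA_character_,
                        group = NA_character_) {
  seg <- eeg_recording(data, channel_names, fs, annotations)
  seg$state <- state
  seg$onset <- 0
  seg$subject <- subject
  seg$group <- group
  class(seg) <- c("eeg_segment", class(seg))
  seg
}
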