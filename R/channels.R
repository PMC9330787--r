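#' Standard electrode montage
#'
#' The pipeline records 27 scalp EEG channels over fronto-central-parietal
#' cortex (10-10 system) plus 4 bipolar EOG channels (horizontal right/left,
#' vertical up/down) used as artifact references.
#'
#' @format Character vectors of channel labels.
#' @name montage
NULL

#' @rdname montage
#' @export
eeg_channel_names <- function() {
  c("F3", "FZ", "FC1", "FCZ", "C1", "CZ", "CP1", "CPZ",
    "FC5", "FC3", "C5", "C3", "CP5", "CP3", "P3", "PZ",
    "F4", "FC2", "FC4", "FC6", "C2", "C4", "CP2", "CP4",
    "C6", "CP6", "P4")
}

#' @rdname montage
#' @export
eog_channel_names <- function() {
  c("HR", "HL", "VU", "VD")
}

#' Construct a channel set
#'
#' @param eeg_labels 27 unique EEG channel names from the 10-10 montage.
#' @param eog_labels 4 bipolar EOG channel names.
#' @param reference,ground Free-text descriptors of reference/ground placement.
#' @return A `channel_set` object.
#' @export
channel_set <- function(eeg_labels = eeg_channel_names(),
                        eog_labels = eog_channel_names(),
                        reference = "right earlobe",
                        ground = "left earlobe") {
  eeg_labels <- as.character(eeg_labels)
  eog_labels <- as.character(eog_labels)
  if (length(eeg_labels) != 27L || anyDuplicated(eeg_labels))
    abort("`eeg_labels` must hold exactly 27 unique channel names.")
  if (!all(eeg_labels %in% eeg_channel_names()))
    abort("`eeg_labels` must be drawn from the standard 10-10 montage.")
  if (length(eog_labels) != 4L)
    abort("`eog_labels` must hold exactly 4 names (HR, HL, VU, VD).")
  structure(
    list(eeg_labels = eeg_labels, eog_labels = eog_labels,
         reference = reference, ground = ground),
    class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> 27 EEG + 4 EOG\n")
  cat("  EEG:", paste(x$eeg_labels, collapse = " "), "\n")
  cat("  EOG:", paste(x$eog_labels, collapse = " "), "\n")
  invisible(x)
}

# Split a labelled multichannel matrix into EEG and EOG blocks in canonical
# channel order; errors if any montage channel is missing.
split_eeg_eog <- function(samples, labels, channels = channel_set()) {
  labels <- as.character(labels)
  miss <- setdiff(c(channels$eeg_labels, channels$eog_labels), labels)
  if (length(miss))
    abort(paste0("Missing channels: ", paste(miss, collapse = ", ")),
          class = "turnintent_channel_error")
  list(eeg = samples[, match(channels$eeg_labels, labels), drop = FALSE],
       eog = samples[, match(channels$eog_labels, labels), drop = FALSE])
}
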