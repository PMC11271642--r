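#' Construct a continuous EEG recording
#'
#' A light container for continuous multichannel EEG: a channels x time
#' matrix in microvolts, the sampling rate, and an event table (a tibble with
#' columns `time` (s), `kind` and `side`).
#'
#' @param data Numeric matrix, channels x time, in microvolts.
#' @param channels Character vector of unique channel names (rows of `data`).
#' @param rate Sampling rate in Hz.
#' @param events Event tibble with columns `time`, `kind`, `side` (may have
#'   zero rows).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channels, rate,
                          events = empty_events()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x time matrix", call. = FALSE)
  }
  if (nrow(data) != length(channels)) {
    stop("`channels` length must match nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  duration <- ncol(data) / rate
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0) {
    if (is.unsorted(events$time)) {
      events <- dplyr::arrange(events, .data$time)
    }
    if (any(events$time < 0 | events$time > duration)) {
      stop("event times must lie within [0, duration]", call. = FALSE)
    }
  }
  rownames(data) <- channels
  structure(
    list(data = data, channels = channels, rate = rate,
         events = events, duration = duration),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
              length(x$channels), ncol(x$data), x$rate, x$duration,
              nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  tibble::tibble(time = numeric(), kind = character(), side = character())
}

event_kinds <- c("switch_press", "switch_release", "button_press",
                 "invalid_trial", "movement_onset")

#' Write / read an EEG recording as tab-separated text
#'
#' The sample matrix is written as one column per channel plus a leading
#' `time` column; events go to a companion `<stem>_events.tsv`.
#'
#' @param recording An [eeg_recording()].
#' @param stem File path stem; `<stem>_eeg.tsv` and `<stem>_events.tsv` are
#'   written.
#' @return `write_recording_tsv()` returns the paths invisibly;
#'   `read_recording_tsv()` returns an [eeg_recording()].
#' @export
write_recording_tsv <- function(recording, stem) {
  eeg_path <- paste0(stem, "_eeg.tsv")
  ev_path <- paste0(stem, "_events.tsv")
  df <- tibble::as_tibble(t(recording$data))
  df <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(ncol(recording$data)) - 1) / recording$rate),
    df
  )
  readr::write_tsv(df, eeg_path)
  readr::write_tsv(recording$events, ev_path)
  invisible(c(eeg = eeg_path, events = ev_path))
}

#' @rdname write_recording_tsv
#' @param rate Sampling rate in Hz of the stored data.
#' @export
read_recording_tsv <- function(stem, rate) {
  df <- readr::read_tsv(paste0(stem, "_eeg.tsv"), show_col_types = FALSE)
  ev_path <- paste0(stem, "_events.tsv")
  events <- if (file.exists(ev_path)) {
    readr::read_tsv(ev_path, show_col_types = FALSE)
  } else {
    empty_events()
  }
  chans <- setdiff(names(df), "time")
  eeg_recording(t(as.matrix(df[chans])), chans, rate, events)
}
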