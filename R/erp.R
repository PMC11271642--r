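# ERP analysis: band-pass, epoch [-1.5, 0] s around movement onset,
# baseline-correct on [-1.5, -1] s, average within and across subjects.

# zero-phase band-pass as a cascade of 4th-order Butterworth high- and
# low-pass stages (a direct band-pass design of this order is numerically
# unstable at a 0.1 Hz edge on a 500 Hz grid)
bandpass_continuous <- function(x, rate, band = c(0.1, 4)) {
  hp <- signal::butter(4, band[1] / (rate / 2), type = "high")
  lp <- signal::butter(4, band[2] / (rate / 2), type = "low")
  x <- x - rowMeans(x) # remove DC first: shrinks high-pass edge transients
  t(apply(x, 1, function(ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch))))
}

#' Cut baseline-corrected epochs around movement onsets
#'
#' Band-pass filters the continuous recording (zero-phase, 0.1-4 Hz),
#' cuts epochs spanning `[-1.5, 0]` s relative to each onset, and subtracts
#' the per-channel mean over the `[-1.5, -1]` s baseline window. Onsets
#' without the full epoch history are skipped. An optional peak-to-peak
#' amplitude rejection discards artifact-contaminated epochs.
#'
#' @param recording An [eeg_recording()].
#' @param onsets Onset times in seconds (absolute recording time).
#' @param band Pass band in Hz (default `c(0.1, 4)`).
#' @param span Epoch span relative to onset (default `c(-1.5, 0)`).
#' @param baseline Baseline window relative to onset (default
#'   `c(-1.5, -1)`).
#' @param reject_peak_to_peak Optional microvolt threshold; epochs whose
#'   peak-to-peak amplitude exceeds it on any channel are dropped
#'   (default `NULL`, off: synthetic data carry no blink artifacts).
#' @return An `eeg_epochs` object: list with `data` (channels x time x
#'   epoch array), `channels`, `rate`, `span`, `n_epochs`, `n_skipped`.
#' @export
epoch_baseline <- function(recording, onsets, band = c(0.1, 4),
                           span = c(-1.5, 0), baseline = c(-1.5, -1),
                           reject_peak_to_peak = NULL) {
  fs <- recording$rate
  filtered <- bandpass_continuous(recording$data, fs, band)
  n_ep <- round((span[2] - span[1]) * fs)
  b_idx <- seq_len(round((baseline[2] - baseline[1]) * fs))
  epochs <- list()
  skipped <- 0
  for (on in onsets) {
    i0 <- round((on + span[1]) * fs) + 1
    i1 <- i0 + n_ep - 1
    if (i0 < 1 || i1 > ncol(filtered)) {
      skipped <- skipped + 1
      next
    }
    ep <- filtered[, i0:i1, drop = FALSE]
    ep <- ep - rowMeans(ep[, b_idx, drop = FALSE])
    if (!is.null(reject_peak_to_peak)) {
      ptp <- apply(ep, 1, function(ch) diff(range(ch)))
      if (max(ptp) > reject_peak_to_peak) {
        skipped <- skipped + 1
        next
      }
    }
    epochs[[length(epochs) + 1]] <- ep
  }
  if (skipped > 0) {
    message(skipped, " epoch(s) skipped")
  }
  data <- if (length(epochs) > 0) {
    array(unlist(epochs),
          dim = c(nrow(filtered), n_ep, length(epochs)),
          dimnames = list(recording$channels, NULL, NULL))
  } else {
    array(0, dim = c(nrow(filtered), n_ep, 0),
          dimnames = list(recording$channels, NULL, NULL))
  }
  structure(
    list(data = data, channels = recording$channels, rate = fs,
         span = span, n_epochs = length(epochs), n_skipped = skipped),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epoch(s) x %d ch x %d samples @ %g Hz\n",
              x$n_epochs, length(x$channels), dim(x$data)[2], x$rate))
  invisible(x)
}

#' Grand average of epochs
#'
#' Arithmetic mean over all epochs (optionally pooled across several epoch
#' sets, e.g. one per subject), with the pooled epoch count reported.
#'
#' @param epochs An `eeg_epochs` object or a list of them (pooled by
#'   weighted mean over their epoch counts).
#' @return A `grand_average`: list with `mean` (channels x time), `time`
#'   (seconds relative to onset), `channels`, `rate`, `n_epochs`.
#' @export
grand_average <- function(epochs) {
  if (inherits(epochs, "eeg_epochs")) {
    epochs <- list(epochs)
  }
  epochs <- purrr::keep(epochs, function(e) e$n_epochs > 0)
  if (length(epochs) == 0) {
    stop("no epochs to average", call. = FALSE)
  }
  first <- epochs[[1]]
  sums <- Reduce(`+`, purrr::map(epochs, function(e)
    rowSums(e$data, dims = 2)))
  n <- sum(purrr::map_int(epochs, function(e) e$n_epochs))
  avg <- sums / n
  time <- first$span[1] + (seq_len(ncol(avg)) - 1) / first$rate
  structure(
    list(mean = avg, time = time, channels = first$channels,
         rate = first$rate, n_epochs = n),
    class = "grand_average"
  )
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("<grand_average> %d epoch(s), %d ch, [%.2f, %.2f] s\n",
              x$n_epochs, length(x$channels), min(x$time), max(x$time)))
  invisible(x)
}

#' Tidy a grand average into long format
#' @param x A `grand_average`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `channel`, `amplitude`.
#' @export
tidy.grand_average <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, times = length(x$channels)),
    channel = rep(x$channels, each = length(x$time)),
    amplitude = as.vector(t(x$mean))
  )
}

#' Write a grand average as a time x channels TSV
#' @param x A `grand_average`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grand_average_tsv <- function(x, path) {
  df <- dplyr::bind_cols(tibble::tibble(time = x$time),
                         tibble::as_tibble(t(x$mean)))
  readr::write_tsv(df, path)
  invisible(path)
}
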