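# Channel montages: custom left-hemisphere selections centred on C1 and
# standard extended 10-20 constellations.

montage_cache <- new.env(parent = emptyenv())

load_montage_config <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "montages.yaml", package = "lrpdetect")
  }
  key <- normalizePath(file, mustWork = TRUE)
  if (is.null(montage_cache[[key]])) {
    montage_cache[[key]] <- yaml::read_yaml(file)
  }
  montage_cache[[key]]
}

#' Retrieve a channel montage
#'
#' Custom montages (`4`, `8`, `16`, `21`, `32` channels) are
#' left-hemisphere/midline selections nested concentrically around C1, the
#' focus of right-arm movement-planning activity. Standard montages (`16`,
#' `21`, `32`) are extended 10-20 constellations. Definitions live in an
#' editable YAML configuration; the shipped defaults can be overridden with
#' `file`.
#'
#' @param scheme `"custom"` or `"standard"`. A compact `"custom:8"` spec is
#'   also accepted, in which case `n_channels` is ignored.
#' @param n_channels Montage size: one of 32, 21, 16, 8, 4 (custom) or 32,
#'   21, 16 (standard).
#' @param file Optional YAML file overriding the shipped montage
#'   definitions.
#' @return A `montage` object: list with `scheme`, `n_channels`,
#'   `channel_names`.
#' @export
#' @examples
#' get_montage("custom", 8)
#' get_montage("standard:16")
get_montage <- function(scheme, n_channels = NULL, file = NULL) {
  if (grepl(":", scheme, fixed = TRUE)) {
    parts <- strsplit(scheme, ":", fixed = TRUE)[[1]]
    scheme <- parts[1]
    n_channels <- as.integer(parts[2])
  }
  if (!scheme %in% c("custom", "standard")) {
    stop("unsupported montage scheme: ", scheme, call. = FALSE)
  }
  defs <- load_montage_config(file)
  key <- as.character(n_channels)
  if (is.null(defs[[scheme]][[key]])) {
    stop(sprintf("unsupported montage size: %s with %s channels",
                 scheme, key), call. = FALSE)
  }
  channels <- as.character(defs[[scheme]][[key]])
  if (length(channels) != n_channels) {
    stop("montage definition length does not match its size", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("montage definition contains duplicate channels", call. = FALSE)
  }
  if (scheme == "custom") {
    if (!"C1" %in% channels) {
      stop("custom montages must contain C1", call. = FALSE)
    }
    if (any(is_right_hemisphere(channels))) {
      stop("custom montages must not contain right-hemisphere channels",
           call. = FALSE)
    }
  }
  structure(
    list(scheme = scheme, n_channels = as.integer(n_channels),
         channel_names = channels),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %s:%d\n  %s\n", x$scheme, x$n_channels,
              paste(x$channel_names, collapse = " ")))
  invisible(x)
}

#' Restrict a recording to a montage
#'
#' Returns the recording with only the montage channels, in montage order;
#' samples and events are otherwise unchanged. Applying the same montage
#' again is the identity.
#'
#' @param recording An [eeg_recording()].
#' @param montage A [get_montage()] result (or a `"scheme:n"` string).
#' @return The restricted [eeg_recording()].
#' @export
apply_montage <- function(recording, montage) {
  if (is.character(montage)) {
    montage <- get_montage(montage)
  }
  missing <- setdiff(montage$channel_names, recording$channels)
  if (length(missing) > 0) {
    stop("montage channel(s) missing from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eeg_recording(
    recording$data[montage$channel_names, , drop = FALSE],
    montage$channel_names, recording$rate, recording$events
  )
}
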