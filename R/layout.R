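#' 64-channel actiCap electrode layout
#'
#' Channel names of the 64-electrode active-cap layout used by the study
#' design, in cap order (two banks of 32). Labels follow the extended 10-20
#' system; the reference electrode FCz is not a data channel and is therefore
#' not part of the layout.
#'
#' @return Character vector of 64 unique channel labels.
#' @export
#' @examples
#' head(acticap64_layout())
acticap64_layout <- function() {
  c(
    # first bank of 32
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10",
    # second bank of 32
    "AF7", "AF3", "AF4", "AF8",
    "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6",
    "PO7", "PO3", "POz", "PO4", "PO8"
  )
}

#' Idealized planar coordinates of 10-20 electrode labels
#'
#' Maps extended 10-20 labels onto a schematic 2-D head plane: `x` grows to
#' the right (odd indices negative/left, even positive/right, `z` labels on
#' the midline), `y` grows to the front. Units are electrode-grid steps, not
#' centimetres; the coordinates serve to define spatial falloff of simulated
#' scalp patterns and concentric montage growth, not exact head geometry.
#'
#' @param channels Character vector of 10-20 labels (default: full 64-channel
#'   layout).
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' channel_positions(c("C1", "C2", "Cz"))
channel_positions <- function(channels = acticap64_layout()) {
  row_y <- c(
    Fp = 4, AF = 3, F = 2, FT = 1, FC = 1,
    T = 0, C = 0, TP = -1, CP = -1, P = -2, PO = -3, O = -4
  )
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) != 3) {
      stop("cannot parse 10-20 label: ", lab, call. = FALSE)
    }
    prefix <- sub("p$", "p", m[2])
    if (!prefix %in% names(row_y)) {
      stop("unknown 10-20 row prefix in label: ", lab, call. = FALSE)
    }
    idx <- m[3]
    x <- if (identical(idx, "z")) {
      0
    } else {
      d <- as.numeric(idx)
      if (d %% 2 == 1) -(d + 1) / 2 else d / 2
    }
    c(x = x, y = unname(row_y[prefix]))
  }
  xy <- t(vapply(channels, parse_one, c(x = 0, y = 0)))
  tibble::tibble(channel = channels, x = xy[, "x"], y = xy[, "y"])
}

# left-hemisphere test: even 10-20 digit index => right hemisphere
is_right_hemisphere <- function(channels) {
  idx <- sub("^[A-Za-z]+?", "", channels)
  suppressWarnings(num <- as.numeric(idx))
  !is.na(num) & num %% 2 == 0
}
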