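# Sliding-window feature pipeline: 81-window grid per trial; per window
# channel-wise standardization -> anti-aliased decimation 500 -> 20 Hz ->
# FFT band-pass 0.1-4 Hz -> xDAWN spatial filtering to 4 pseudo-channels ->
# last 4 samples as features -> Gaussian feature normalization.

#' The canonical sliding-window grid
#'
#' 1 s windows stepped by 0.05 s spanning `[-5, 0]` s relative to the
#' movement onset: 81 windows from `[-5.00, -4.00]` to `[-1.00, 0.00]`.
#'
#' @param window_length Window length in seconds (default 1).
#' @param step Step between window starts in seconds (default 0.05).
#' @param span Start of the first and end of the last window, relative to
#'   onset (default `c(-5, 0)`).
#' @return A tibble with columns `window`, `start`, `end` (seconds relative
#'   to onset).
#' @export
#' @examples
#' nrow(window_grid()) # 81
window_grid <- function(window_length = 1, step = 0.05, span = c(-5, 0)) {
  starts <- seq(span[1], span[2] - window_length, by = step)
  starts <- round(starts / step) * step # exact grid, no fp drift
  tibble::tibble(window = seq_along(starts), start = starts,
                 end = starts + window_length)
}

#' Cut the sliding windows of one trial
#'
#' Extracts each grid window's samples from the recording using half-open
#' ranges `[start, start + length)` on the sampling grid. Trials without the
#' full 5 s of pre-onset data are skipped with a warning.
#'
#' @param recording An [eeg_recording()].
#' @param onset Movement onset in seconds (absolute recording time).
#' @param grid A [window_grid()].
#' @return A `sliding_windows` tibble (`window`, `start`, `end`, `data`
#'   list-column of channels x samples matrices) with attribute
#'   `stage = "raw"`, or `NULL` if the trial was skipped.
#' @export
cut_windows <- function(recording, onset, grid = window_grid()) {
  fs <- recording$rate
  wl <- round((grid$end[1] - grid$start[1]) * fs)
  first_sample <- round((onset + grid$start[1]) * fs) + 1
  last_sample <- round((onset + grid$start[nrow(grid)]) * fs) + wl
  if (first_sample < 1 || last_sample > ncol(recording$data)) {
    warning(sprintf(
      "trial at onset %.2f s skipped: needs %g s of pre-onset data",
      onset, -grid$start[1]), call. = FALSE)
    return(NULL)
  }
  data <- purrr::map(grid$start, function(st) {
    i0 <- round((onset + st) * fs) + 1
    recording$data[, i0:(i0 + wl - 1), drop = FALSE]
  })
  out <- dplyr::mutate(grid, data = data)
  attr(out, "stage") <- "raw"
  attr(out, "rate") <- fs
  class(out) <- c("sliding_windows", class(out))
  out
}

## ---- preprocessing operator -------------------------------------------

operator_cache <- new.env(parent = emptyenv())

# anti-aliased decimation matrix via DFT-domain spectral resampling: the
# window's spectrum is truncated at the target Nyquist and re-evaluated on
# the coarse grid. On a finite window this is the exact brick-wall
# anti-alias decimator, with no IIR edge transients; tones at resolvable
# (integer-bin) stop-band frequencies are annihilated.
decimation_operator <- function(n_in, factor) {
  key <- sprintf("dec_%d_%d", n_in, factor)
  if (is.null(operator_cache[[key]])) {
    n_out <- n_in / factor
    half <- n_out / 2
    cols <- vapply(seq_len(n_in), function(j) {
      e <- numeric(n_in)
      e[j] <- 1
      X <- stats::fft(e)
      Y <- complex(n_out)
      Y[1:half] <- X[1:half] # bins 0 .. half-1
      Y[half + 1] <- (X[half + 1] + X[n_in - half + 1]) / 2 # Nyquist bin
      Y[(half + 2):n_out] <- X[(n_in - half + 2):n_in] # negative bins
      Re(stats::fft(Y, inverse = TRUE)) / n_in
    }, numeric(n_out))
    operator_cache[[key]] <- cols
  }
  operator_cache[[key]]
}

# FFT band-pass matrix on an n-sample window at `rate` Hz: bins whose
# centre frequency f satisfies band[1] <= f <= band[2] are kept (DC removed)
fft_bandpass_operator <- function(n, rate, band = c(0.1, 4)) {
  key <- sprintf("bp_%d_%g_%g_%g", n, rate, band[1], band[2])
  if (is.null(operator_cache[[key]])) {
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * rate / n
    mask <- as.numeric(f >= band[1] & f <= band[2])
    cols <- vapply(seq_len(n), function(j) {
      e <- numeric(n)
      e[j] <- 1
      Re(stats::fft(stats::fft(e) * mask, inverse = TRUE)) / n
    }, numeric(n))
    operator_cache[[key]] <- cols
  }
  operator_cache[[key]]
}

preprocess_operator <- function(n_in = 500, factor = 25, rate_out = 20,
                                band = c(0.1, 4)) {
  key <- sprintf("pre_%d_%d_%g", n_in, factor, rate_out)
  if (is.null(operator_cache[[key]])) {
    operator_cache[[key]] <-
      fft_bandpass_operator(n_in / factor, rate_out, band) %*%
      decimation_operator(n_in, factor)
  }
  operator_cache[[key]]
}

standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  sd[sd == 0] <- Inf # zero-variance channel -> all-zero output
  (x - mu) / sd
}

#' Preprocess a raw sliding window
#'
#' Channel-wise standardization with the window's own statistics (zero
#' mean, unit SD; zero-variance channels map to all-zeros), anti-aliased
#' decimation from 500 Hz to 20 Hz, and an FFT band-pass keeping bins with
#' centre frequencies in `[0.1, 4]` Hz (DC removed).
#'
#' @param x A channels x samples matrix at the raw rate, or a
#'   `sliding_windows` tibble from [cut_windows()] (each window is then
#'   preprocessed).
#' @param rate Input sampling rate in Hz (default 500).
#' @param rate_out Output rate in Hz (default 20).
#' @param band Pass band in Hz (default `c(0.1, 4)`).
#' @return Matrix input: the preprocessed channels x 20 matrix. Tibble
#'   input: the tibble with preprocessed `data` and `stage = "preprocessed"`.
#' @export
preprocess_window <- function(x, rate = 500, rate_out = 20,
                              band = c(0.1, 4)) {
  if (inherits(x, "sliding_windows")) {
    rate <- attr(x, "rate") %||% rate
    out <- dplyr::mutate(
      x, data = purrr::map(data, preprocess_window,
                           rate = rate, rate_out = rate_out, band = band))
    attr(out, "stage") <- "preprocessed"
    attr(out, "rate") <- rate_out
    class(out) <- unique(c("sliding_windows", class(out)))
    return(out)
  }
  factor <- round(rate / rate_out)
  P <- preprocess_operator(ncol(x), factor, rate_out, band)
  standardize_rows(x) %*% t(P)
}

## ---- xDAWN -------------------------------------------------------------

#' Fit xDAWN spatial filters
#'
#' Two-class epoch formulation: the filters solve the generalized symmetric
#' eigenproblem maximizing the energy of the LRP-class evoked (average)
#' response against the pooled energy of all training windows. The top
#' `n_filters` generalized eigenvectors, ordered by decreasing eigenvalue,
#' become the spatial filters producing "pseudo-channels". Rank-deficient
#' pooled covariances are ridge-regularized (`1e-8 * trace / dim`).
#'
#' @param windows Preprocessed windows: a list of channels x time matrices,
#'   or a tibble with a `data` list-column.
#' @param labels Character/factor labels per window, `"LRP"` or `"NoLRP"`;
#'   both classes must be present.
#' @param n_filters Number of retained filters (default 4).
#' @return An `xdawn_filter`: list with `weights` (channels x n_filters),
#'   `eigenvalues`, `channels`, `classes`, `fitted`.
#' @export
fit_xdawn <- function(windows, labels = NULL, n_filters = 4) {
  if (is.data.frame(windows)) {
    if (is.null(labels)) labels <- windows$label
    windows <- windows$data
  }
  labels <- as.character(labels)
  if (length(windows) != length(labels)) {
    stop("`labels` must match the number of windows", call. = FALSE)
  }
  if (!all(c("LRP", "NoLRP") %in% labels)) {
    stop("both classes (LRP, NoLRP) must be present", call. = FALSE)
  }
  nc <- nrow(windows[[1]])
  if (nc < n_filters) {
    stop("need at least `n_filters` channels", call. = FALSE)
  }
  nt <- ncol(windows[[1]])
  evoked <- Reduce(`+`, windows[labels == "LRP"]) / sum(labels == "LRP")
  sigma_e <- tcrossprod(evoked) / nt
  sigma_t <- Reduce(`+`, purrr::map(windows, tcrossprod)) /
    (length(windows) * nt)
  R <- tryCatch(chol(sigma_t), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-8 * sum(diag(sigma_t)) / nc
    sigma_t <- sigma_t + diag(ridge, nc)
    R <- chol(sigma_t)
  }
  Rinv <- backsolve(R, diag(nc))
  M <- crossprod(Rinv, sigma_e) %*% Rinv
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Rinv %*% eig$vectors[, seq_len(n_filters), drop = FALSE]
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] * sign(W[which.max(abs(W[, j])), j])
  }
  channels <- rownames(windows[[1]])
  if (!is.null(channels)) rownames(W) <- channels
  structure(
    list(weights = W, eigenvalues = eig$values[seq_len(n_filters)],
         channels = channels, classes = c("LRP", "NoLRP"), fitted = TRUE),
    class = "xdawn_filter"
  )
}

#' @export
print.xdawn_filter <- function(x, ...) {
  cat(sprintf("<xdawn_filter> %d channel(s) -> %d pseudo-channel(s)\n",
              nrow(x$weights), ncol(x$weights)))
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Apply xDAWN spatial filters
#'
#' Linear, stateless projection of a preprocessed window onto the fitted
#' pseudo-channels: `t(weights) %*% samples`.
#'
#' @param x A preprocessed channels x time matrix, or a `sliding_windows`
#'   tibble.
#' @param filter A fitted [fit_xdawn()] object.
#' @return Matrix input: the pseudo-channels x time matrix. Tibble input:
#'   the tibble with projected `data` and `stage = "pseudo"`.
#' @export
apply_xdawn <- function(x, filter) {
  if (inherits(x, "sliding_windows")) {
    out <- dplyr::mutate(x, data = purrr::map(data, apply_xdawn, filter))
    attr(out, "stage") <- "pseudo"
    class(out) <- unique(c("sliding_windows", class(out)))
    return(out)
  }
  if (nrow(x) != nrow(filter$weights)) {
    stop("window channel count does not match the xDAWN filter",
         call. = FALSE)
  }
  crossprod(filter$weights, x)
}

## ---- features ----------------------------------------------------------

#' Extract time-domain features from a pseudo-channel window
#'
#' Takes the last 4 samples (the final 0.2 s at 20 Hz) of each of the 4
#' pseudo-channels, flattened channel-major (pseudo-channel 1's four
#' samples first): 16 features per window. If a normalizer is given, each
#' feature is z-scored with the training statistics.
#'
#' @param x A pseudo-channels x time matrix, or a `sliding_windows` tibble
#'   at the pseudo stage.
#' @param normalizer Optional [fit_feature_normalizer()] result.
#' @param n_last Number of trailing samples per pseudo-channel (default 4).
#' @return Matrix input: numeric feature vector (length 16). Tibble input:
#'   a tibble with provenance columns `window`, `start`, `end` and feature
#'   columns `f01` ... `f16`.
#' @export
extract_features <- function(x, normalizer = NULL, n_last = 4) {
  if (inherits(x, "sliding_windows")) {
    feats <- t(vapply(x$data, extract_features,
                      numeric(nrow(x$data[[1]]) * n_last),
                      normalizer = normalizer, n_last = n_last))
    colnames(feats) <- sprintf("f%02d", seq_len(ncol(feats)))
    return(dplyr::bind_cols(x[c("window", "start", "end")],
                            tibble::as_tibble(feats)))
  }
  nt <- ncol(x)
  v <- as.vector(t(x[, (nt - n_last + 1):nt, drop = FALSE]))
  if (!is.null(normalizer)) {
    v <- (v - normalizer$mean) / normalizer$sd
  }
  v
}

#' Fit a Gaussian feature normalizer
#'
#' Per-feature mean and SD estimated on training feature vectors; features
#' with zero SD are mapped with SD 1 and flagged.
#'
#' @param features Numeric matrix (instances x features) or a tibble with
#'   `f..` feature columns.
#' @return A `feature_normalizer`: list with `mean`, `sd`,
#'   `zero_sd_features`.
#' @export
fit_feature_normalizer <- function(features) {
  features <- feature_matrix(features)
  mu <- colMeans(features)
  sd <- apply(features, 2, stats::sd)
  zero <- which(sd == 0)
  sd[zero] <- 1
  structure(list(mean = mu, sd = sd, zero_sd_features = zero),
            class = "feature_normalizer")
}

# pull the numeric feature matrix out of tibbles produced by
# extract_features() (f01..f16 columns) or pass matrices through
feature_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  cols <- grep("^f[0-9]+$", names(x), value = TRUE)
  if (length(cols) == 0) {
    stop("no feature columns (f01...) found", call. = FALSE)
  }
  as.matrix(x[cols])
}

apply_normalizer <- function(features, normalizer) {
  m <- feature_matrix(features)
  scale(m, center = normalizer$mean, scale = normalizer$sd)[, , drop = FALSE]
}
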