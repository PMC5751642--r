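# Sliding-window gait feature extraction: per-window mean, population
# standard deviation, pairwise inter-axis Pearson correlation, and FFT
# energy, averaged across windows into one 24-dimensional descriptor per
# recording (12 per signal: acceleration and attitude).

#' Sliding-window specification
#'
#' @param window_length Window size in samples (default 128).
#' @param step Hop between window starts in samples; default 64
#'   (50% overlap).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_length = 128L, step = 64L) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 2L) stop("'window_length' must be >= 2", call. = FALSE)
  if (step < 1L || step > window_length) {
    stop("'step' must lie in [1, window_length]", call. = FALSE)
  }
  structure(list(window_length = window_length, step = step),
            class = "window_spec")
}

#' Slice a series into sliding windows
#'
#' Windows start at offsets 0, `step`, `2 * step`, ...; a trailing partial
#' window is discarded, giving `floor((n - window_length) / step) + 1`
#' windows.
#'
#' @param series Numeric vector, length at least `window_length`.
#' @param spec A [window_spec()].
#' @return A matrix with one window per row.
#' @export
sliding_windows <- function(series, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n <- length(series)
  w <- spec$window_length
  if (n < w) {
    stop(sprintf("series too short: %d samples < window length %d", n, w),
         call. = FALSE)
  }
  starts <- seq.int(1L, n - w + 1L, by = spec$step)
  out <- matrix(0, nrow = length(starts), ncol = w)
  for (i in seq_along(starts)) {
    out[i, ] <- series[starts[i]:(starts[i] + w - 1L)]
  }
  out
}

#' Frequency-domain energy of a window
#'
#' The sum of squared discrete Fourier transform coefficient magnitudes
#' (DC included), divided by the window length for normalization:
#' \deqn{E = \frac{1}{|w|}\sum_k |X_k|^2.}
#' By Parseval's theorem this equals the time-domain sum of squared samples
#' \eqn{\sum_n x_n^2}.
#'
#' @param window Nonempty numeric vector.
#' @return Scalar energy (>= 0).
#' @export
window_energy <- function(window) {
  if (length(window) == 0L) stop("empty window", call. = FALSE)
  sum(Mod(stats::fft(window))^2) / length(window)
}

#' Window mean
#' @param window Numeric vector.
#' @return Arithmetic mean.
#' @export
window_mean <- function(window) mean(window)

#' Window standard deviation (population convention)
#'
#' Divides by the window length \eqn{|w|}, not \eqn{|w| - 1}, so a
#' constant window has SD exactly 0 and windowed SDs compose consistently
#' with the energy normalization.
#'
#' @param window Numeric vector of length >= 2.
#' @return Population standard deviation.
#' @export
window_sd <- function(window) {
  if (length(window) < 2L) stop("window too short for sd", call. = FALSE)
  sqrt(mean((window - mean(window))^2))
}

#' Pairwise Pearson correlation between two windows
#'
#' Returns 0 when either window has zero variance (degenerate windows carry
#' no translation information), avoiding NaN propagation.
#'
#' @param window_a,window_b Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
window_corr <- function(window_a, window_b) {
  if (length(window_a) != length(window_b)) {
    stop("windows must have equal length", call. = FALSE)
  }
  if (length(window_a) < 2L) stop("windows too short", call. = FALSE)
  sa <- stats::sd(window_a)
  sb <- stats::sd(window_b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(window_a, window_b)
}

# canonical feature-name order for one signal
signal_feature_names <- function(signal) {
  paste(signal,
        c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z",
          "corr_xy", "corr_xz", "corr_yz",
          "energy_x", "energy_y", "energy_z"),
        sep = "_")
}

#' Names of the 24 gait features, in canonical order
#' @return Character vector of length 24.
#' @export
gait_feature_names <- function() {
  c(signal_feature_names("accel"), signal_feature_names("attitude"))
}

# 12 features for one tri-axial signal (matrix with 3 columns)
signal_features <- function(xyz, spec) {
  wins <- lapply(1:3, function(j) sliding_windows(xyz[, j], spec))
  nw <- nrow(wins[[1]])
  means <- vapply(wins, function(w) mean(apply(w, 1, window_mean)), 0)
  sds <- vapply(wins, function(w) mean(apply(w, 1, window_sd)), 0)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  corrs <- vapply(pairs, function(p) {
    mean(vapply(seq_len(nw), function(i) {
      window_corr(wins[[p[1]]][i, ], wins[[p[2]]][i, ])
    }, 0))
  }, 0)
  energies <- vapply(wins, function(w) mean(apply(w, 1, window_energy)), 0)
  c(means, sds, corrs, energies)
}

#' Extract the 24-dimensional gait feature vector
#'
#' For each signal (acceleration, attitude) and each axis, computes
#' per-window mean, population SD and FFT energy, plus per-window pairwise
#' inter-axis correlations, then averages every feature across windows.
#' This gives 12 features per signal and 24 in total, in the fixed order of
#' [gait_feature_names()].
#'
#' @param recording A [gait_recording()].
#' @param spec A [window_spec()].
#' @return Named numeric vector of length 24.
#' @export
extract_features <- function(recording, spec = window_spec()) {
  stopifnot(inherits(recording, "gait_recording"))
  out <- c(signal_features(recording$acceleration, spec),
           signal_features(recording$attitude, spec))
  stats::setNames(out, gait_feature_names())
}

#' Build a feature table for a simulated dataset
#'
#' Applies [extract_features()] to every recording and binds the results to
#' the dataset's identifying keys and eBAC labels.
#'
#' @param dataset Result of [simulate_dataset()], or a list with elements
#'   `recordings` and `meta`.
#' @param spec A [window_spec()].
#' @return A data frame: `subject_id`, `evening_id`, `hour_index`, 24
#'   feature columns, and `ebac`.
#' @export
feature_table <- function(dataset, spec = window_spec()) {
  feats <- t(vapply(dataset$recordings, extract_features,
                    numeric(24L), spec = spec))
  cbind(dataset$meta[c("subject_id", "evening_id", "hour_index")],
        as.data.frame(feats), ebac = dataset$meta$ebac)
}

#' Write/read a feature table CSV
#'
#' @param features Data frame from [feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
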