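# Preprocessing: baseline-wander removal with a wide moving-average filter
# and Savitzky-Golay least-squares smoothing that preserves pulse shape.

#' Filter configuration
#'
#' @param ma_half_window Half-window N of the smoothing moving average
#'   (samples; the filter averages 2N+1 points).
#' @param baseline_half_window Half-window of the baseline estimator
#'   (samples). Default `NULL` resolves to `round(1.5 * fs)` at use time,
#'   i.e. at least 1.5 beat periods at resting heart rates.
#' @param sg_window Savitzky-Golay window length (odd, >= 3).
#' @param sg_polyorder Savitzky-Golay polynomial degree (< `sg_window`).
#' @param window_size Optional analysis window size bookkeeping field.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(ma_half_window = 2, baseline_half_window = NULL,
                          sg_window = 11, sg_polyorder = 3,
                          window_size = NULL) {
  if (sg_window < 3 || sg_window %% 2 == 0) {
    stop_input("`sg_window` must be odd and >= 3")
  }
  if (sg_polyorder < 0 || sg_polyorder >= sg_window) {
    stop_input("`sg_polyorder` must satisfy 0 <= polyorder < sg_window")
  }
  if (ma_half_window < 0) stop_input("`ma_half_window` must be >= 0")
  if (!is.null(baseline_half_window) &&
      baseline_half_window <= ma_half_window) {
    stop_input("`baseline_half_window` must exceed `ma_half_window`")
  }
  structure(list(ma_half_window = as.integer(ma_half_window),
                 baseline_half_window = baseline_half_window,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 window_size = window_size),
            class = "filter_config")
}

#' Moving-average filter
#'
#' Output sample i is the mean of the input over the symmetric window
#' \[i - N, i + N\]. Near the edges the window shrinks symmetrically
#' (half-width `min(N, i - 1, length - i)`) so the output keeps the input
#' length without phase shift.
#'
#' @param signal Non-empty numeric vector.
#' @param half_window Half-window N in samples (>= 0).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(signal, half_window) {
  if (length(signal) == 0L) stop_input("`signal` must be non-empty")
  if (half_window < 0 || half_window != floor(half_window)) {
    stop_input("`half_window` must be a non-negative integer")
  }
  n <- length(signal)
  N <- as.integer(half_window)
  if (N == 0L) return(as.numeric(signal))
  out <- numeric(n)
  cs <- cumsum(c(0, signal))
  k <- pmin(N, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  out <- (cs[hi + 1L] - cs[lo]) / (2 * k + 1)
  out
}

#' Remove baseline wander
#'
#' Subtracts a wide moving-average estimate of the baseline from the
#' signal. The window should span at least ~1.5 beat periods so the pulse
#' train itself is not attenuated.
#'
#' @param signal Non-empty numeric vector.
#' @param baseline_half_window Half-window of the baseline estimator
#'   (samples).
#' @return Detrended vector of the same length.
#' @export
remove_baseline <- function(signal, baseline_half_window) {
  signal - moving_average(signal, baseline_half_window)
}

#' Savitzky-Golay smoothing filter
#'
#' Least-squares polynomial smoothing: each output point is the centre
#' value of a degree-`polyorder` polynomial fitted to the surrounding
#' window. Edge samples are produced by the fitted polynomials of the first
#' and last complete windows, so polynomials of degree <= `polyorder` are
#' reproduced exactly at every sample.
#'
#' @param signal Numeric vector, length >= `window`.
#' @param window Odd window length >= 3.
#' @param polyorder Polynomial degree, `0 <= polyorder < window`.
#' @return Filtered vector of the same length.
#' @export
savitzky_golay <- function(signal, window, polyorder) {
  if (window < 3 || window %% 2 == 0) stop_input("`window` must be odd >= 3")
  if (polyorder < 0 || polyorder >= window) {
    stop_input("`polyorder` must satisfy 0 <= polyorder < window")
  }
  if (length(signal) < window) {
    stop_input("`signal` must be at least `window` samples long")
  }
  as.numeric(signal::sgolayfilt(as.numeric(signal), p = polyorder,
                                n = window))
}

#' Preprocess a PPG segment
#'
#' Pipeline order: baseline removal (wide moving average subtracted), then
#' Savitzky-Golay smoothing. Length, sampling rate and glucose metadata are
#' preserved; the returned segment is flagged `preprocessed`.
#'
#' @param segment A raw [ppg_segment()].
#' @param config A [filter_config()].
#' @return The filtered `ppg_segment` with `preprocessed = TRUE`.
#' @export
preprocess_segment <- function(segment, config = filter_config()) {
  stopifnot(inherits(segment, "ppg_segment"))
  if (isTRUE(segment$preprocessed)) {
    stop_input("segment is already preprocessed")
  }
  bw <- config$baseline_half_window
  if (is.null(bw)) bw <- round(1.5 * segment$fs)
  x <- remove_baseline(segment$samples, bw)
  x <- savitzky_golay(x, config$sg_window, config$sg_polyorder)
  out <- segment
  out$samples <- x
  out$preprocessed <- TRUE
  out
}
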