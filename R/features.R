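# Feature extraction: the eight-family, 36-element feature vector combining
# frequency-domain (AR spectrum, spectral entropy) and time-domain
# (Teager-Kaiser energy, heart-rate, log-energy, pulse timing/amplitude)
# descriptors of a preprocessed PPG segment.

#' Framing configuration
#'
#' @param frame_len Frame length in samples.
#' @param hop Hop between frame starts in samples (`0 < hop <= frame_len`).
#' @param n_fft FFT length for per-frame spectra (`>= frame_len`).
#' @param window_len Optional global analysis window bookkeeping field.
#' @return An object of class `framing_config`.
#' @export
framing_config <- function(frame_len = 256, hop = 128, n_fft = 256,
                           window_len = NULL) {
  if (!is_count(frame_len)) stop_input("`frame_len` must be a positive count")
  if (!is_count(hop) || hop > frame_len) {
    stop_input("`hop` must satisfy 0 < hop <= frame_len")
  }
  if (n_fft < frame_len) stop_input("`n_fft` must be >= frame_len")
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 n_fft = as.integer(n_fft), window_len = window_len),
            class = "framing_config")
}

#' Split a signal into frames
#'
#' Frames start at hop spacing; a trailing partial frame is dropped, so the
#' frame count is `floor((length - frame_len) / hop) + 1`.
#'
#' @param signal Numeric vector at least one frame long.
#' @param config A [framing_config()].
#' @return Matrix of dimension `frame_len x n_frames`.
#' @export
frame_signal <- function(signal, config = framing_config()) {
  n <- length(signal)
  if (n < config$frame_len) {
    stop_input("signal shorter than one frame")
  }
  nf <- (n - config$frame_len) %/% config$hop + 1L
  starts <- (seq_len(nf) - 1L) * config$hop
  idx <- outer(seq_len(config$frame_len), starts, `+`)
  matrix(signal[idx], nrow = config$frame_len, ncol = nf)
}

#' Yule-Walker autoregressive coefficients
#'
#' Fits an AR model of the given order by solving the Yule-Walker system
#' built from biased sample autocovariances (Levinson recursion). The
#' coefficients follow the convention `sum_k c_k * gamma(l - k) =
#' -gamma(l)`, i.e. they are the negated one-step-prediction weights, so a
#' white-noise input yields coefficients near zero.
#'
#' @param signal Numeric vector, longer than `order`, with non-zero
#'   variance.
#' @param order AR model order (default 5).
#' @return Numeric vector of `order` coefficients, with the innovation
#'   variance in attribute `"var_pred"`.
#' @export
ar_coefficients <- function(signal, order = 5) {
  if (length(signal) <= order) {
    stop_input("signal must be longer than the AR order")
  }
  v <- stats::var(signal)
  if (!is.finite(v) || v == 0) {
    stop_input("degenerate input: signal has zero variance")
  }
  fit <- stats::ar.yw(as.numeric(signal), aic = FALSE, order.max = order,
                      demean = TRUE)
  ck <- -as.numeric(fit$ar)
  attr(ck, "var_pred") <- fit$var.pred
  ck
}

#' Implied AR power spectrum
#'
#' Power spectral density of the fitted AR model at the requested
#' frequencies: `PS(f) = var_pred * dt / |1 + sum_k c_k exp(-i 2 pi f k
#' dt)|^2` with `dt = 1/fs`.
#'
#' @param coef Coefficient vector from [ar_coefficients()].
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies (Hz) at which to evaluate; default a grid up to
#'   the Nyquist frequency.
#' @param var_pred Innovation variance; default taken from `coef`'s
#'   attribute.
#' @return Data frame with columns `freq` and `power`.
#' @export
ar_power_spectrum <- function(coef, fs, freqs = NULL, var_pred = NULL) {
  if (is.null(var_pred)) var_pred <- attr(coef, "var_pred") %||% 1
  if (is.null(freqs)) freqs <- seq(0, fs / 2, length.out = 256)
  dt <- 1 / fs
  k <- seq_along(coef)
  denom <- vapply(freqs, function(f) {
    Mod(1 + sum(coef * exp(-2i * pi * f * k * dt)))^2
  }, numeric(1))
  data.frame(freq = freqs, power = var_pred * dt / denom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Teager-Kaiser energy operator
#'
#' `KTE(t) = a(t)^2 - a(t+1) * a(t-1)` evaluated at the interior points, so
#' the output is two samples shorter than the input. Constants map to zero,
#' integer ramps to one, and a sinusoid `A sin(w n)` to the constant
#' `A^2 sin(w)^2`.
#'
#' @param signal Numeric vector of length >= 3.
#' @return Numeric vector of length `length(signal) - 2`.
#' @export
teager_energy <- function(signal) {
  n <- length(signal)
  if (n < 3L) stop_input("`signal` must have at least 3 samples")
  i <- 2:(n - 1L)
  signal[i]^2 - signal[i + 1L] * signal[i - 1L]
}

#' Summary statistics of a per-frame series
#'
#' Mean, unbiased variance, interquartile range (linear-interpolation
#' quantiles) and adjusted Fisher-Pearson skewness, used uniformly for the
#' KTE / HRS / HS / PTT / PPI / PA feature blocks. A zero-variance series
#' has skewness 0 by convention.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Named numeric vector `c(mean, variance, iqr, skewness)`.
#' @export
frame_statistics <- function(values) {
  if (length(values) < 2L) {
    stop_input("insufficient data: need at least 2 values")
  }
  if (!all(is.finite(values))) stop_input("`values` must be finite")
  v <- stats::var(values)
  sk <- if (v == 0) 0 else e1071::skewness(values, type = 2)
  c(mean = mean(values), variance = v,
    iqr = unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7))),
    skewness = sk)
}

#' Detect systolic peaks and pulse onsets
#'
#' Systolic peaks are local maxima separated by at least `fs * 60 / 180`
#' samples (a 180 bpm ceiling) with prominence at least 0.3x the median
#' peak prominence; the onset of each pulse is the signal minimum between
#' the preceding peak (or segment start) and the peak. Intended for
#' baseline-removed signals. Deterministic; a signal with no qualifying
#' maxima yields an empty peak set rather than an error.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param prominence_frac Fraction of the median prominence required
#'   (default 0.3).
#' @return An object of class `peak_set` with `peak_indices`,
#'   `onset_indices` and `fs`.
#' @export
detect_pulses <- function(signal, fs, prominence_frac = 0.3) {
  n <- length(signal)
  empty <- structure(list(peak_indices = integer(0),
                          onset_indices = integer(0), fs = fs),
                     class = "peak_set")
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  cand <- i[signal[i] > signal[i - 1L] & signal[i] >= signal[i + 1L]]
  if (length(cand) == 0L) return(empty)
  prom <- peak_prominence(signal, cand)
  # enforce the minimum separation, keeping the taller peak of any clash
  minsep <- floor(fs * 60 / 180)
  ord <- cand[order(signal[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= minsep)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  kp <- prom[match(kept, cand)]
  kept <- kept[kp >= prominence_frac * stats::median(kp)]
  if (length(kept) == 0L) return(empty)
  onsets <- integer(length(kept))
  prev <- 1L
  for (j in seq_along(kept)) {
    lo <- prev
    hi <- kept[j] - 1L
    if (hi < lo) hi <- lo
    onsets[j] <- lo + which.min(signal[lo:hi]) - 1L
    prev <- kept[j] + 1L
  }
  # a leading pulse whose "onset" is the boundary sample was cut mid-rise
  # by the recording window; its amplitude is unverifiable, so drop it
  if (length(kept) > 1L && onsets[1] == 1L) {
    kept <- kept[-1]
    onsets <- onsets[-1]
  }
  structure(list(peak_indices = kept, onset_indices = onsets, fs = fs),
            class = "peak_set")
}

# frame_statistics with the single-value convention: a length-1 series has
# zero spread by definition.
series_stats <- function(values) {
  if (length(values) == 1L) {
    c(mean = values, variance = 0, iqr = 0, skewness = 0)
  } else {
    frame_statistics(values)
  }
}

# Topographic prominence of candidate maxima: height above the higher of
# the two minima reached before a taller sample (or the edge) on each side.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    j <- p - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- p + 1L
    while (j <= length(x) && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Heart-rate statistics from detected peaks
#'
#' Beat-to-beat heart rate `hr_j = 60 * fs / (peak_{j+1} - peak_j)` in bpm,
#' summarised by [frame_statistics()].
#'
#' @param peaks A `peak_set` with at least 3 peaks.
#' @return Named statistics vector.
#' @export
heart_rate_features <- function(peaks) {
  if (length(peaks$peak_indices) < 3L) {
    stop_input("insufficient data: need at least 3 peaks")
  }
  hr <- 60 * peaks$fs / diff(peaks$peak_indices)
  frame_statistics(hr)
}

#' Spectral entropy of a frame
#'
#' Shannon entropy of the normalised power spectrum: the frame is
#' zero-padded to `n_fft`, `p_k = |A_k|^2 / sum |A|^2`, and
#' `H = -sum p_k log p_k` (natural log, `0 log 0 := 0`). A single occupied
#' FFT bin gives `H = 0`; a unit impulse (flat spectrum) gives
#' `H = log(n_fft)`.
#'
#' @param frame Numeric (or complex) vector, non-empty, not all zero.
#' @param n_fft FFT length `>= length(frame)`.
#' @return List with `entropy` (nats) and `normalized`
#'   (`entropy / log(n_fft)`).
#' @export
spectral_entropy <- function(frame, n_fft = length(frame)) {
  if (length(frame) == 0L) stop_input("`frame` must be non-empty")
  if (n_fft < length(frame)) stop_input("`n_fft` must be >= frame length")
  padded <- c(frame, rep(0, n_fft - length(frame)))
  p <- Mod(stats::fft(padded))^2
  tot <- sum(p)
  if (tot == 0) stop_input("degenerate input: all-zero frame")
  p <- p / tot
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  list(entropy = h, normalized = h / log(n_fft))
}

#' Frame log energy
#'
#' Natural log of the frame's sum of squares with a small floor:
#' `log(sum(x^2) + 1e-12)`, so a zero frame maps to `log(1e-12)` and
#' scaling the frame by 2 adds exactly `log 4`.
#'
#' @param frame Non-empty numeric vector.
#' @return Scalar log energy.
#' @export
log_energy <- function(frame) {
  if (length(frame) == 0L) stop_input("`frame` must be non-empty")
  log(sum(frame^2) + 1e-12)
}

#' Pulse transit times
#'
#' Onset-to-onset intervals within the single PPG channel:
#' `PTT_j = (onset_{j+1} - onset_j) / fs` seconds, with summary statistics.
#'
#' @param peaks A `peak_set` with at least 2 onsets.
#' @return List with `ptt` (seconds) and `stats` from
#'   [frame_statistics()].
#' @export
pulse_transit_times <- function(peaks) {
  if (length(peaks$onset_indices) < 2L) {
    stop_input("insufficient data: need at least 2 onsets")
  }
  ptt <- diff(peaks$onset_indices) / peaks$fs
  list(ptt = ptt, stats = series_stats(ptt))
}

#' Peak-to-peak intervals
#'
#' Intervals between consecutive systolic maxima,
#' `PPI_j = (peak_{j+1} - peak_j) / fs` seconds, a PPG proxy for the
#' cardiac R-R interval, with summary statistics.
#'
#' @param peaks A `peak_set` with at least 2 peaks.
#' @return List with `ppi` (seconds) and `stats`.
#' @export
peak_to_peak_intervals <- function(peaks) {
  if (length(peaks$peak_indices) < 2L) {
    stop_input("insufficient data: need at least 2 peaks")
  }
  ppi <- diff(peaks$peak_indices) / peaks$fs
  list(ppi = ppi, stats = series_stats(ppi))
}

#' Pulse amplitudes
#'
#' Per-beat systolic rise `PA_j = signal[peak_j] - signal[onset_j]`
#' (offset-invariant on baseline-removed signals), with summary statistics.
#' Set `mode = "raw"` for the raw peak height instead.
#'
#' @param signal Numeric vector the peaks were detected on.
#' @param peaks A non-empty `peak_set`.
#' @param mode `"rise"` (default) or `"raw"`.
#' @return List with `pa` (a.u.) and `stats`.
#' @export
pulse_amplitudes <- function(signal, peaks, mode = c("rise", "raw")) {
  mode <- match.arg(mode)
  if (length(peaks$peak_indices) == 0L) {
    stop_input("insufficient data: empty peak set")
  }
  pa <- if (mode == "rise") {
    signal[peaks$peak_indices] - signal[peaks$onset_indices]
  } else {
    signal[peaks$peak_indices]
  }
  list(pa = pa, stats = series_stats(pa))
}

#' Names of the 36 feature columns
#'
#' Block order: AR coefficients (5), Teager energy stats (4), heart-rate
#' stats (4), spectral-entropy stats (4), log-energy AR + spread (7), pulse
#' transit time stats (4), peak-to-peak interval stats (4), pulse amplitude
#' stats (4).
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  st <- c("mean", "var", "iqr", "sk")
  c(paste0("far_", 1:5),
    paste0("kte_", st), paste0("hrs_", st), paste0("hs_", st),
    c(paste0("logep_ar", 1:5), "logep_var", "logep_iqr"),
    paste0("ptt_", st), paste0("ppi_", st), paste0("pa_", st))
}

#' Extract the full feature vector of a segment
#'
#' Assembles the eight feature blocks, in order, into a length-36 vector:
#' AR(5) of the whole segment; statistics of the per-frame mean Teager
#' energy; beat-to-beat heart-rate statistics; statistics of per-frame
#' spectral entropy; AR(5) plus variance and IQR of the per-frame
#' log-energy series; and statistics of the pulse transit time,
#' peak-to-peak interval and pulse amplitude series. Blocks whose
#' sub-computation reports insufficient data are imputed with zeros and
#' recorded in the `"imputed_blocks"` attribute.
#'
#' @param segment A preprocessed [ppg_segment()].
#' @param framing A [framing_config()].
#' @return Named numeric vector of length 36 with attribute
#'   `"imputed_blocks"`.
#' @export
extract_feature_vector <- function(segment, framing = framing_config()) {
  stopifnot(inherits(segment, "ppg_segment"))
  if (!isTRUE(segment$preprocessed)) {
    stop_input("segment must be preprocessed before feature extraction")
  }
  x <- segment$samples
  fs <- segment$fs
  imputed <- character(0)
  grab <- function(name, k, fun) {
    tryCatch(fun(), error = function(e) {
      imputed <<- c(imputed, name)
      rep(0, k)
    })
  }
  far <- grab("far", 5L, function() as.numeric(ar_coefficients(x, 5)))
  frames <- tryCatch(frame_signal(x, framing), error = function(e) NULL)
  kte <- grab("kte", 4L, function() {
    if (is.null(frames)) stop_input("no frames")
    frame_statistics(apply(frames, 2, function(f) mean(teager_energy(f))))
  })
  peaks <- detect_pulses(x, fs)
  hrs <- grab("hrs", 4L, function() heart_rate_features(peaks))
  hs <- grab("hs", 4L, function() {
    if (is.null(frames)) stop_input("no frames")
    frame_statistics(apply(frames, 2, function(f)
      spectral_entropy(f, framing$n_fft)$entropy))
  })
  logep <- grab("logep", 7L, function() {
    if (is.null(frames)) stop_input("no frames")
    le <- apply(frames, 2, log_energy)
    ar <- as.numeric(ar_coefficients(le, 5))
    c(ar, stats::var(le),
      unname(diff(stats::quantile(le, c(0.25, 0.75), type = 7))))
  })
  ptt <- grab("ptt", 4L, function() pulse_transit_times(peaks)$stats)
  ppi <- grab("ppi", 4L, function() peak_to_peak_intervals(peaks)$stats)
  pa <- grab("pa", 4L, function() pulse_amplitudes(x, peaks)$stats)
  fv <- c(far, kte, hrs, hs, logep, ptt, ppi, pa)
  names(fv) <- feature_names()
  fv[!is.finite(fv)] <- 0
  attr(fv, "imputed_blocks") <- imputed
  fv
}

#' Extract features for a whole cohort
#'
#' Preprocesses (if needed) and featurises every segment, returning one row
#' per segment with metadata, the 36 feature columns and an
#' `imputed_blocks` bookkeeping column.
#'
#' @param cohort Cohort list from [generate_cohort()] (or a bare list of
#'   segments).
#' @param framing A [framing_config()].
#' @param filters A [filter_config()] applied to raw segments.
#' @return A data.frame with `subject_id`, `segment_idx`, `reference_bgl`,
#'   `fasting`, 36 feature columns and `imputed_blocks`.
#' @export
extract_feature_matrix <- function(cohort, framing = framing_config(),
                                   filters = filter_config()) {
  segs <- if (!is.null(cohort$segments)) cohort$segments else cohort
  rows <- lapply(segs, function(s) {
    if (!isTRUE(s$preprocessed)) s <- preprocess_segment(s, filters)
    fv <- extract_feature_vector(s, framing)
    df <- data.frame(subject_id = s$subject_id, segment_idx = s$segment_idx,
                     reference_bgl = s$reference_bgl, fasting = s$fasting)
    df[names(fv)] <- as.list(unname(fv))
    df$imputed_blocks <- paste(attr(fv, "imputed_blocks"), collapse = ";")
    df
  })
  do.call(rbind, rows)
}
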