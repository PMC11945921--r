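# Synthetic PPG cohort generation.
#
# Each beat is modelled as a systolic Gaussian plus a delayed, scaled
# diastolic Gaussian; segments add baseline wander (slow sinusoid), white
# Gaussian noise and powerline interference. A documented monotone coupling
# ties the reference blood glucose level (BGL, mmol/L) to pulse morphology
# so that the regression target is recoverable downstream.

#' Construct a PPG segment
#'
#' Container for one subject's pulse waveform with its sampling rate and
#' reference glucose annotation.
#'
#' @param samples Numeric vector of waveform samples (arbitrary units).
#' @param fs Sampling frequency in Hz.
#' @param subject_id Integer subject identifier.
#' @param reference_bgl Reference blood glucose in mmol/L.
#' @param fasting Logical; `TRUE` for the fasting condition.
#' @param preprocessed Logical; `TRUE` once filtered by
#'   [preprocess_segment()].
#' @param segment_idx Integer segment index within the subject.
#' @return An object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs = 115.2, subject_id = NA_integer_,
                        reference_bgl = NA_real_, fasting = NA,
                        preprocessed = FALSE, segment_idx = 1L) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_input("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop_input("`samples` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_input("`fs` must be a positive scalar")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.integer(subject_id),
         reference_bgl = reference_bgl, fasting = fasting,
         preprocessed = isTRUE(preprocessed),
         segment_idx = as.integer(segment_idx)),
    class = "ppg_segment"
  )
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment> n=%d fs=%.1f Hz subject=%s bgl=%s mmol/L %s\n",
              length(x$samples), x$fs, x$subject_id,
              format(x$reference_bgl, digits = 3),
              if (x$preprocessed) "(preprocessed)" else "(raw)"))
  invisible(x)
}

#' Default BGL-to-morphology coupling coefficients
#'
#' The generator couples glucose to pulse shape through two strictly
#' monotone affine maps: systolic amplitude decreases with BGL and the
#' diastolic-to-systolic ratio increases with BGL. Per-subject jitter with
#' the stated standard deviations is added on top, so coupling strength is
#' tunable by editing this list.
#'
#' @param amp_intercept,amp_slope Affine map for systolic amplitude (a.u.):
#'   `amplitude = amp_intercept + amp_slope * bgl` (slope negative).
#' @param amp_jitter_sd Subject-level SD of the amplitude jitter (a.u.).
#' @param dia_intercept,dia_slope Affine map for the diastolic ratio
#'   (dimensionless, slope positive).
#' @param dia_jitter_sd Subject-level SD of the ratio jitter.
#' @return Named list of coupling coefficients.
#' @export
coupling_config <- function(amp_intercept = 1.5, amp_slope = -0.08,
                            amp_jitter_sd = 0.03,
                            dia_intercept = 0.2, dia_slope = 0.02,
                            dia_jitter_sd = 0.02) {
  if (amp_slope >= 0) stop_input("`amp_slope` must be negative")
  if (dia_slope <= 0) stop_input("`dia_slope` must be positive")
  list(amp_intercept = amp_intercept, amp_slope = amp_slope,
       amp_jitter_sd = amp_jitter_sd,
       dia_intercept = dia_intercept, dia_slope = dia_slope,
       dia_jitter_sd = dia_jitter_sd)
}

#' Pulse model parameters
#'
#' @param heart_rate Beats per minute, in \[40, 180\].
#' @param systolic_amplitude Systolic Gaussian peak height (a.u., > 0).
#' @param systolic_width Systolic Gaussian SD in seconds.
#' @param diastolic_ratio Diastolic amplitude as a fraction of the systolic
#'   amplitude, in \[0, 1).
#' @param diastolic_delay Delay of the diastolic component after the
#'   systolic peak, seconds.
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude
#'   (a.u.) and frequency (Hz).
#' @param noise_sd White-noise SD (a.u., >= 0).
#' @param powerline_amp,powerline_freq Powerline interference amplitude
#'   (a.u.) and frequency (Hz, default 50).
#' @return An object of class `pulse_model_params`.
#' @export
pulse_model_params <- function(heart_rate = 75, systolic_amplitude = 1.0,
                               systolic_width = 0.09, diastolic_ratio = 0.35,
                               diastolic_delay = 0.30, baseline_amp = 0.1,
                               baseline_freq = 0.12, noise_sd = 0.02,
                               powerline_amp = 0.01, powerline_freq = 50) {
  if (heart_rate < 40 || heart_rate > 180) {
    stop_input("`heart_rate` must lie in [40, 180] bpm")
  }
  if (systolic_amplitude <= 0) stop_input("`systolic_amplitude` must be > 0")
  if (diastolic_ratio < 0 || diastolic_ratio >= 1) {
    stop_input("`diastolic_ratio` must lie in [0, 1)")
  }
  beat <- 60 / heart_rate
  if (systolic_width <= 0 || systolic_width >= beat ||
      diastolic_delay <= 0 || diastolic_delay >= beat) {
    stop_input("widths and delays must be positive and shorter than one beat")
  }
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(
    list(heart_rate = heart_rate, systolic_amplitude = systolic_amplitude,
         systolic_width = systolic_width, diastolic_ratio = diastolic_ratio,
         diastolic_delay = diastolic_delay, baseline_amp = baseline_amp,
         baseline_freq = baseline_freq, noise_sd = noise_sd,
         powerline_amp = powerline_amp, powerline_freq = powerline_freq),
    class = "pulse_model_params"
  )
}

#' Sample one subject profile
#'
#' Draws demographics and fasting / non-fasting reference glucose for one
#' synthetic subject. Fasting BGL comes from a three-component normal
#' mixture spanning the normal, prediabetic and diabetic bands; the
#' non-fasting reading adds a postprandial increment bounded below by
#' -1 mmol/L. Deterministic for a fixed seed.
#'
#' @param seed Non-negative integer seed.
#' @param subject_id Integer identifier stored on the profile (default the
#'   seed itself).
#' @return An object of class `subject_profile` with fields `subject_id`,
#'   `gender`, `age` (years), `weight` (kg), `bgl_fasting` and
#'   `bgl_nonfasting` (mmol/L).
#' @export
sample_subject <- function(seed, subject_id = seed) {
  with_local_seed(seed, {
    gender <- sample(c("male", "female"), 1L)
    age <- sample(18:85, 1L)
    weight <- round(runif(1, 40, 120), 1)
    band <- sample.int(3L, 1L, prob = c(0.5, 0.25, 0.25))
    fast <- switch(band,
                   rnorm(1, 5.2, 0.55),
                   rnorm(1, 7.0, 0.45),
                   rnorm(1, 9.2, 0.90))
    fast <- clamp(fast, 3.2, 14.0)
    delta <- max(rnorm(1, 0.9, 0.5), -0.9)
    nonfast <- clamp(fast + delta, 2.5, 15.0)
    profile <- structure(
      list(subject_id = as.integer(subject_id), gender = gender,
           age = age, weight = weight,
           bgl_fasting = round(fast, 2), bgl_nonfasting = round(nonfast, 2)),
      class = "subject_profile"
    )
    validate_subject(profile)
    profile
  })
}

validate_subject <- function(p) {
  stopifnot(p$age > 0, p$weight > 0)
  for (b in c(p$bgl_fasting, p$bgl_nonfasting)) {
    if (b < 2.0 || b > 25.0) stop_input("BGL outside the [2, 25] mmol/L range")
  }
  if (p$bgl_nonfasting < p$bgl_fasting - 1.0) {
    stop_input("non-fasting BGL below fasting BGL - 1.0")
  }
  invisible(p)
}

#' Map glucose to pulse-model parameters
#'
#' Applies the monotone BGL-to-morphology coupling: systolic amplitude
#' decreases affinely with glucose while the diastolic ratio increases
#' affinely, each with seeded subject-level jitter. With both jitter SDs set
#' to zero the mapping is exactly affine. The subject's heart rate is drawn
#' once per seed, so the two conditions of one subject share physiology.
#'
#' @param bgl Reference glucose in mmol/L; must lie in \[2, 25\].
#' @param subject A `subject_profile` (only used for its identity; kept in
#'   the signature so coupling can be made demographics-aware).
#' @param seed Non-negative integer seed (use one seed per subject so the
#'   jitter is a subject effect, not a segment effect).
#' @param coupling Coupling coefficients from [coupling_config()].
#' @return A `pulse_model_params` object.
#' @export
glucose_to_pulse_params <- function(bgl, subject, seed,
                                    coupling = coupling_config()) {
  if (!is.numeric(bgl) || length(bgl) != 1L || !is.finite(bgl) ||
      bgl < 2.0 || bgl > 25.0) {
    stop_input("`bgl` must be a single value in [2, 25] mmol/L")
  }
  with_local_seed(seed, {
    hr <- clamp(rnorm(1, 75, 6), 55, 100)
    amp <- coupling$amp_intercept + coupling$amp_slope * bgl +
      rnorm(1, 0, coupling$amp_jitter_sd)
    amp <- max(amp, 0.05)
    dia <- coupling$dia_intercept + coupling$dia_slope * bgl +
      rnorm(1, 0, coupling$dia_jitter_sd)
    dia <- clamp(dia, 0, 0.9)
    pulse_model_params(heart_rate = hr, systolic_amplitude = amp,
                       diastolic_ratio = dia)
  })
}

#' Synthesize one PPG segment
#'
#' Beat onsets are spaced at the heart-rate period; each beat contributes a
#' systolic Gaussian (peak 1.8 systolic widths after onset) and a delayed
#' diastolic Gaussian of width 1.6x the systolic width. Baseline sinusoid,
#' white noise and powerline interference are added. Fully deterministic
#' per seed.
#'
#' @param params A `pulse_model_params` object.
#' @param bgl Reference glucose stored on the segment (mmol/L).
#' @param n_samples Number of samples (default 1700).
#' @param fs Sampling rate in Hz (default 115.2).
#' @param seed Non-negative integer seed.
#' @param subject_id,fasting,segment_idx Metadata stored on the segment.
#' @return A raw (`preprocessed = FALSE`) [ppg_segment()].
#' @export
synthesize_segment <- function(params, bgl, n_samples = 1700, fs = 115.2,
                               seed = 0, subject_id = NA_integer_,
                               fasting = NA, segment_idx = 1L) {
  if (!is_count(n_samples)) stop_input("`n_samples` must be a positive count")
  if (!is.numeric(fs) || fs <= 0) stop_input("`fs` must be > 0")
  stopifnot(inherits(params, "pulse_model_params"))
  t <- (seq_len(n_samples) - 1) / fs
  period <- 60 / params$heart_rate
  sw <- params$systolic_width
  dw <- 1.6 * sw
  x <- numeric(n_samples)
  beats <- seq(-3L, ceiling(t[n_samples] / period) + 3L)
  for (k in beats) {
    cs <- k * period + 1.8 * sw                   # systolic peak time
    cd <- cs + params$diastolic_delay             # diastolic peak time
    x <- x + params$systolic_amplitude *
      (exp(-((t - cs)^2) / (2 * sw^2)) +
         params$diastolic_ratio * exp(-((t - cd)^2) / (2 * dw^2)))
  }
  with_local_seed(seed, {
    ph_b <- runif(1, 0, 2 * pi)
    ph_p <- runif(1, 0, 2 * pi)
    x <- x +
      params$baseline_amp * sin(2 * pi * params$baseline_freq * t + ph_b) +
      params$powerline_amp * sin(2 * pi * params$powerline_freq * t + ph_p)
    if (params$noise_sd > 0) x <- x + rnorm(n_samples, 0, params$noise_sd)
  })
  ppg_segment(x, fs = fs, subject_id = subject_id, reference_bgl = bgl,
              fasting = fasting, preprocessed = FALSE,
              segment_idx = segment_idx)
}

#' Generate a synthetic cohort
#'
#' Per subject, fasting and non-fasting conditions alternate across
#' segments (odd segment indices fasting), each segment labelled with the
#' matching reference BGL. Subject profiles, pulse parameters and segment
#' noise are all derived deterministically from the single cohort seed.
#'
#' @param n_subjects Number of subjects (> 0).
#' @param segments_per_subject Segments per subject (default 2).
#' @param seed Non-negative integer cohort seed.
#' @param n_samples,fs Segment length and sampling rate.
#' @param coupling Coupling coefficients from [coupling_config()].
#' @return A list with `subjects` (data.frame mirroring the demographic
#'   table) and `segments` (list of [ppg_segment()]).
#' @export
generate_cohort <- function(n_subjects, segments_per_subject = 2, seed = 0,
                            n_samples = 1700, fs = 115.2,
                            coupling = coupling_config()) {
  if (!is_count(n_subjects) || !is_count(segments_per_subject)) {
    stop_input("subject and segment counts must be positive integers")
  }
  subjects <- vector("list", n_subjects)
  segments <- vector("list", n_subjects * segments_per_subject)
  si <- 0L
  for (i in seq_len(n_subjects)) {
    prof <- sample_subject(derive_seed(seed, i, 0L), subject_id = i)
    subjects[[i]] <- data.frame(
      subject_id = prof$subject_id, gender = prof$gender, age = prof$age,
      weight = prof$weight, bgl_fasting = prof$bgl_fasting,
      bgl_nonfasting = prof$bgl_nonfasting, stringsAsFactors = FALSE
    )
    par_seed <- derive_seed(seed, i, 1L)
    for (j in seq_len(segments_per_subject)) {
      fasting <- (j %% 2L) == 1L
      bgl <- if (fasting) prof$bgl_fasting else prof$bgl_nonfasting
      params <- glucose_to_pulse_params(bgl, prof, par_seed, coupling)
      si <- si + 1L
      segments[[si]] <- synthesize_segment(
        params, bgl, n_samples = n_samples, fs = fs,
        seed = derive_seed(seed, i, 1L + j), subject_id = i,
        fasting = fasting, segment_idx = j
      )
    }
  }
  list(subjects = do.call(rbind, subjects), segments = segments,
       config = list(n_subjects = n_subjects,
                     segments_per_subject = segments_per_subject,
                     seed = seed, n_samples = n_samples, fs = fs,
                     coupling = coupling,
                     pulse_defaults = unclass(pulse_model_params())))
}

#' Write / read a cohort as plain CSV
#'
#' `write_cohort()` stores three files under `dir`: `signals.csv` (one row
#' per sample: subject_id, segment_idx, t_s, amplitude), `segments.csv`
#' (per-segment metadata incl. reference BGL and condition) and
#' `subjects.csv` (demographics). `read_cohort()` reconstructs the cohort
#' list from the same layout.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segs <- cohort$segments
  meta <- data.table::rbindlist(lapply(segs, function(s) {
    data.table::data.table(subject_id = s$subject_id,
                           segment_idx = s$segment_idx, fs = s$fs,
                           reference_bgl = s$reference_bgl,
                           fasting = s$fasting, preprocessed = s$preprocessed,
                           n = length(s$samples))
  }))
  sig <- data.table::rbindlist(lapply(segs, function(s) {
    data.table::data.table(subject_id = s$subject_id,
                           segment_idx = s$segment_idx,
                           t_s = (seq_along(s$samples) - 1) / s$fs,
                           amplitude = s$samples)
  }))
  data.table::fwrite(sig, file.path(dir, "signals.csv"))
  data.table::fwrite(meta, file.path(dir, "segments.csv"))
  data.table::fwrite(data.table::as.data.table(cohort$subjects),
                     file.path(dir, "subjects.csv"))
  if (!is.null(cohort$config)) {
    jsonlite::write_json(cohort$config,
                         file.path(dir, "generator_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sig <- data.table::fread(file.path(dir, "signals.csv"))
  meta <- data.table::fread(file.path(dir, "segments.csv"))
  subjects <- as.data.frame(data.table::fread(file.path(dir, "subjects.csv")))
  segments <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- as.list(meta[i, ])
    sel <- sig$subject_id == m$subject_id & sig$segment_idx == m$segment_idx
    rows <- sig[sel, ]
    segments[[i]] <- ppg_segment(rows$amplitude, fs = m$fs,
                                 subject_id = m$subject_id,
                                 reference_bgl = m$reference_bgl,
                                 fasting = m$fasting,
                                 preprocessed = m$preprocessed,
                                 segment_idx = m$segment_idx)
  }
  list(subjects = subjects, segments = segments)
}
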