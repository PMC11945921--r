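# Shared fixtures, all generated in code.

# Noise-free pulse parameters for closed-form checks.
clean_params <- function(heart_rate = 72, amplitude = 1,
                         diastolic_ratio = 0.35) {
  pulse_model_params(heart_rate = heart_rate,
                     systolic_amplitude = amplitude,
                     diastolic_ratio = diastolic_ratio,
                     baseline_amp = 0, noise_sd = 0, powerline_amp = 0)
}

# A small preprocessed cohort reused across feature / model tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(12, 2, seed = 101)
      clean <- lapply(coh$segments, preprocess_segment)
      cache <<- list(cohort = coh, clean = clean,
                     features = extract_feature_matrix(clean))
    }
    cache
  }
})

# Tiny segment set for fast network tests: short windows cut from synthetic
# segments so convolutions stay cheap.
tiny_model_data <- function(n_subjects = 12, len = 256, seed = 7) {
  coh <- generate_cohort(n_subjects, 2, seed = seed, n_samples = len)
  clean <- lapply(coh$segments, preprocess_segment)
  fm <- extract_feature_matrix(clean)
  list(x = segments_to_array(clean),
       fv = t(as.matrix(fm[, feature_names()])),
       y = fm$reference_bgl,
       subject_id = fm$subject_id)
}

tiny_config <- function(...) {
  model_config(conv_channels = 8, primary_maps = 2, dense_width = 16,
               num_filters = c(4, 4, 8, 8), dropout_rate = 0, ...)
}
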