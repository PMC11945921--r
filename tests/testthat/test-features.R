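test_that("framing produces hop-spaced frames and drops the tail", {
  x <- rnorm(1700)
  fr <- frame_signal(x, framing_config(frame_len = 256, hop = 128))
  expect_equal(ncol(fr), 12)           # floor((1700 - 256) / 128) + 1
  expect_equal(fr[, 2], x[129:384])

  fr1 <- frame_signal(x[1:300], framing_config(frame_len = 300, hop = 300,
                                               n_fft = 300))
  expect_equal(ncol(fr1), 1)
  expect_equal(fr1[, 1], x[1:300])

  expect_error(frame_signal(x[1:100], framing_config(frame_len = 256)),
               "shorter")
})

test_that("Yule-Walker coefficients match a direct Toeplitz solve", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), n = 4000))
  ck <- ar_coefficients(x, order = 5)
  # independent oracle: biased autocovariances + explicit linear solve
  xc <- x - mean(x)
  g <- vapply(0:5, function(l)
    sum(xc[1:(length(x) - l)] * xc[(1 + l):length(x)]) / length(x),
    numeric(1))
  phi <- solve(toeplitz(g[1:5]), g[2:6])
  expect_equal(as.numeric(ck), -as.numeric(phi), tolerance = 1e-8)
})

test_that("AR estimation handles white noise and degenerate inputs", {
  set.seed(6)
  ck <- ar_coefficients(rnorm(1e5), order = 5)
  expect_true(all(abs(ck) < 0.02))
  expect_error(ar_coefficients(rep(2, 100)), "zero variance")
  expect_error(ar_coefficients(rnorm(4), order = 5), "longer")
  ps <- ar_power_spectrum(ck, fs = 100)
  expect_true(all(ps$power > 0))
})

test_that("AR coefficient bias shrinks with sample size", {
  phi <- c(0.5, -0.3, 0.2, -0.1, 0.05)
  err_at <- function(n, seed) {
    set.seed(seed)
    x <- as.numeric(arima.sim(list(ar = phi), n = n))
    max(abs(-ar_coefficients(x, 5) - phi))
  }
  e_small <- mean(vapply(1:5, function(s) err_at(1e3, s), numeric(1)))
  e_large <- mean(vapply(1:5, function(s) err_at(1e5, s), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("Teager energy obeys its closed forms", {
  expect_equal(teager_energy(rep(4, 10)), rep(0, 8))
  expect_equal(teager_energy(1:20), rep(1, 18))
  A <- 2.5
  w <- 0.3
  x <- A * sin(w * (0:499))
  expect_equal(teager_energy(x), rep(A^2 * sin(w)^2, 498),
               tolerance = 1e-9)
  expect_error(teager_energy(c(1, 2)), "at least 3")
})

test_that("frame statistics use the stated estimators", {
  st <- frame_statistics(c(1, 2, 3, 4))
  expect_equal(unname(st["mean"]), 2.5)
  expect_equal(unname(st["variance"]), 5 / 3)
  expect_equal(unname(st["iqr"]), 1.5)

  same <- frame_statistics(rep(2, 6))
  expect_equal(unname(same[c("variance", "iqr", "skewness")]), c(0, 0, 0))

  sym <- frame_statistics(c(-3, -1, 0, 1, 3))
  expect_lt(abs(unname(sym["skewness"])), 1e-12)

  expect_error(frame_statistics(1), "at least 2")
})

test_that("pulse detection finds systolic peaks with correct spacing", {
  seg <- synthesize_segment(clean_params(heart_rate = 72), bgl = 5,
                            seed = 0)
  pk <- detect_pulses(seg$samples, seg$fs)
  expect_true(length(pk$peak_indices) %in% c(17, 18))
  gap <- round(seg$fs * 60 / 72)
  expect_true(all(abs(diff(pk$peak_indices) - gap) <= 1))
  expect_true(all(pk$onset_indices < pk$peak_indices))
  expect_true(all(diff(pk$onset_indices) > 0))

  empty <- detect_pulses(rep(1, 500), 115.2)
  expect_length(empty$peak_indices, 0)
})

test_that("heart-rate statistics summarise beat-to-beat rate", {
  fs <- 115.2
  gap <- round(fs * 60 / 72)
  pk <- structure(list(peak_indices = seq(10, by = gap, length.out = 15),
                       onset_indices = seq(5, by = gap, length.out = 15),
                       fs = fs), class = "peak_set")
  st <- heart_rate_features(pk)
  expect_equal(unname(st["mean"]), 60 * fs / gap, tolerance = 1e-9)
  expect_lt(unname(st["variance"]), 1e-12)

  # alternating long/short intervals: IQR equals the two-class difference
  gaps <- rep(c(80, 120), 4)
  pk2 <- structure(list(peak_indices = cumsum(c(10, gaps)),
                        onset_indices = cumsum(c(5, gaps)), fs = fs),
                   class = "peak_set")
  st2 <- heart_rate_features(pk2)
  expect_equal(unname(st2["iqr"]), 60 * fs / 80 - 60 * fs / 120,
               tolerance = 1e-9)

  pk3 <- structure(list(peak_indices = c(10, 100), onset_indices = c(5, 95),
                        fs = fs), class = "peak_set")
  expect_error(heart_rate_features(pk3), "at least 3")
})

test_that("spectral entropy hits its analytic extremes", {
  n <- 64
  tone <- exp(2i * pi * 5 * (0:(n - 1)) / n)     # one occupied FFT bin
  expect_equal(spectral_entropy(tone, n)$entropy, 0, tolerance = 1e-9)

  imp <- c(1, rep(0, n - 1))
  se <- spectral_entropy(imp, n)
  expect_equal(se$entropy, log(n), tolerance = 1e-9)
  expect_equal(se$normalized, 1, tolerance = 1e-9)

  two <- cos(2 * pi * 7 * (0:(n - 1)) / n)       # two equal bins
  expect_equal(spectral_entropy(two, n)$entropy, log(2), tolerance = 1e-9)

  expect_error(spectral_entropy(rep(0, 8)), "all-zero")
  set.seed(8)
  for (i in 1:10) {
    h <- spectral_entropy(rnorm(50), 64)$entropy
    expect_true(h >= 0 && h <= log(64) + 1e-12)
  }
})

test_that("log energy matches hand computation and scales by log 4", {
  expect_equal(log_energy(rep(0, 10)), log(1e-12))
  expect_equal(log_energy(c(3, 4)), log(25 + 1e-12))
  x <- rnorm(100)
  expect_equal(log_energy(2 * x) - log_energy(x), log(4), tolerance = 1e-9)
})

test_that("pulse timing features follow index arithmetic", {
  fs <- 115.2
  pk <- structure(list(peak_indices = c(150, 265),
                       onset_indices = c(100, 215), fs = fs),
                  class = "peak_set")
  expect_equal(pulse_transit_times(pk)$ptt, 115 / 115.2, tolerance = 1e-12)

  seg <- synthesize_segment(clean_params(heart_rate = 72), bgl = 5,
                            seed = 0)
  pks <- detect_pulses(seg$samples, seg$fs)
  ptt <- pulse_transit_times(pks)
  ppi <- peak_to_peak_intervals(pks)
  expect_true(all(abs(ptt$ptt - 60 / 72) <= 1.5 / fs))
  expect_lt(abs(mean(ptt$ptt) - mean(ppi$ppi)), 1 / fs)
  expect_lt(unname(ppi$stats["variance"]), 1e-6)

  one <- structure(list(peak_indices = 10L, onset_indices = 5L, fs = fs),
                   class = "peak_set")
  expect_error(pulse_transit_times(one), "at least 2")
  expect_error(peak_to_peak_intervals(one), "at least 2")
})

test_that("pulse amplitudes recover the generator ground truth", {
  A <- 1.7
  seg <- synthesize_segment(clean_params(amplitude = A,
                                         diastolic_ratio = 0),
                            bgl = 5, seed = 0)
  pk <- detect_pulses(seg$samples, seg$fs)
  pa <- pulse_amplitudes(seg$samples, pk)
  expect_true(all(abs(pa$pa - A) / A < 0.02))

  pa2 <- pulse_amplitudes(2 * seg$samples, pk)
  expect_equal(pa2$pa, 2 * pa$pa, tolerance = 1e-12)

  # interval features are amplitude-invariant
  pk2 <- detect_pulses(3 * seg$samples, seg$fs)
  expect_identical(pk2$peak_indices, pk$peak_indices)

  empty <- detect_pulses(rep(0.5, 100), 100)
  expect_error(pulse_amplitudes(rep(0.5, 100), empty), "empty")
})

test_that("the assembled feature vector has 36 finite named entries", {
  cc <- small_cohort()
  seg <- cc$clean[[1]]
  fv <- extract_feature_vector(seg)
  expect_length(fv, 36)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(attr(fv, "imputed_blocks"), character(0))

  fv2 <- extract_feature_vector(cc$clean[[1]])
  expect_identical(fv, fv2)

  raw <- cc$cohort$segments[[1]]
  expect_error(extract_feature_vector(raw), "preprocessed")
})

test_that("degenerate segments are imputed and flagged, not fatal", {
  flat <- ppg_segment(rep(0, 1700), fs = 115.2, preprocessed = TRUE)
  fv <- extract_feature_vector(flat)
  expect_length(fv, 36)
  expect_true(all(is.finite(fv)))
  expect_true(length(attr(fv, "imputed_blocks")) > 0)
})

test_that("pulse amplitude features recover the glucose coupling", {
  coh <- generate_cohort(100, 2, seed = 7)
  fm <- extract_feature_matrix(lapply(coh$segments, preprocess_segment))
  expect_gte(abs(cor(fm$pa_mean, fm$reference_bgl)), 0.7)
  expect_equal(nrow(fm), 200)
  expect_true(all(is.finite(as.matrix(fm[, feature_names()]))))
})
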