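test_that("Hjorth parameters match sinusoid and white-noise oracles", {
  s <- tone(10, 10)
  h <- hjorth_parameters(s, 500)
  expect_equal(h$mobility, 2 * pi * 10, tolerance = 0.02)
  expect_equal(h$complexity, 1, tolerance = 0.02)
  set.seed(1)
  hw <- hjorth_parameters(rnorm(50000), 500)
  expect_equal(hw$activity, 1, tolerance = 0.05)
  hc <- hjorth_parameters(rep(2, 100), 500)
  expect_equal(hc$activity, 0)
  expect_true(is.na(hc$mobility))
})

test_that("Barlow parameters match analytic sinusoid values", {
  b <- barlow_parameters(2 * tone(10, 10), 500)
  expect_equal(b$mean_frequency, 10, tolerance = 0.01 * 10)
  expect_equal(b$spectral_purity, 1, tolerance = 0.01)
  expect_equal(b$mean_amplitude, 2 * 2 / pi, tolerance = 0.01)
  b2 <- barlow_parameters(0.5 * tone(6, 10), 500)
  expect_equal(b2$mean_amplitude, 0.5 * 2 / pi, tolerance = 0.01)
  # broadband noise: purity well below 1 (flat spectrum over [0, pi] gives
  # purity (1/3)^2/(1/5) = 5/9 for ideal continuous white noise)
  set.seed(2)
  bw <- barlow_parameters(rnorm(50000), 500)
  expect_lt(bw$spectral_purity, 0.7)
  expect_gt(bw$spectral_purity, 0.4)
})

test_that("Wackermann descriptors behave at the rank-1 and isotropic limits", {
  s <- tone(10, 10)
  rec1 <- eeg_recording(rbind(s, 0.8 * s, 1.2 * s), 500, c("C3", "Cz", "C4"))
  w1 <- wackermann_parameters(rec1)
  expect_equal(w1$spatial_complexity, 1, tolerance = 0.01)
  expect_equal(w1$global_frequency, 10, tolerance = 0.05)
  rec2 <- noise_recording(n_ch = 4, duration = 40, fs = 250, seed = 3,
                          labels = c("C3", "Cz", "C4", "Pz"))
  w2 <- wackermann_parameters(rec2)
  expect_gt(w2$spatial_complexity, 3.7)   # -> n within sampling error
  single <- eeg_recording(matrix(s, 1), 500, "Cz")
  expect_true(is.na(wackermann_parameters(single)$spatial_complexity))
})

test_that("DFA matches its white-noise and Brownian limits", {
  set.seed(5)
  w <- median(vapply(1:5, function(i)
    dfa_exponent(rnorm(2^14), 100, window_range = c(0.1, 16)), numeric(1)))
  expect_lt(abs(w - 0.5), 0.1)
  b <- median(vapply(1:5, function(i)
    dfa_exponent(cumsum(rnorm(2^14)), 100, window_range = c(0.1, 16)),
    numeric(1)))
  expect_lt(abs(b - 1.5), 0.1)
  expect_true(is.na(dfa_exponent(rep(1, 1000), 100)))
  expect_true(is.na(dfa_exponent(rnorm(50), 100)))
})

test_that("MFDFA width separates monofractal from multifractal series", {
  set.seed(6)
  mono <- vapply(1:3, function(i)
    mfdfa_width(rnorm(2^14), 100, window_range = c(0.16, 16)), numeric(1))
  expect_lt(max(mono), 0.15)
  cascade <- function(n_levels, p = 0.7) {
    x <- 1
    for (i in seq_len(n_levels)) {
      m <- ifelse(runif(length(x)) < 0.5, p, 1 - p)
      x <- as.vector(rbind(x * m, x * (1 - m)))
    }
    x
  }
  multi <- vapply(1:3, function(i)
    mfdfa_width(cascade(14), 100, window_range = c(0.16, 16)), numeric(1))
  expect_gt(min(multi), 0.3)
  # q = {2} only: a single h(q), zero width by construction
  expect_equal(mfdfa_width(rnorm(2^13), 100, q_range = 2,
                           window_range = c(0.16, 8)), 0)
  expect_true(is.na(mfdfa_width(rep(1, 4000), 100)))
})

test_that("burst statistics equal the brute-force run-length oracle", {
  fs <- 100
  # deterministic square-wave envelope: 2 s high, 2 s low
  env_sq <- rep(c(rep(2, 2 * fs), rep(0.5, 2 * fs)), 25)
  ob <- oscillation_bursts(env_sq, fs)
  expect_equal(ob$duration_p95, 2)
  # random envelopes against the oracle, exactly
  for (seed in 1:10) {
    set.seed(seed)
    env <- abs(rnorm(60 * fs)) + 0.01
    got <- oscillation_bursts(env, fs)
    want <- brute_force_bursts(env, fs)
    expect_equal(got$duration_p95, want$duration_p95)
    expect_equal(got$size_p95, want$size_p95)
    expect_equal(got$n_bursts, want$n)
  }
  # constant envelope: nothing crosses the median -> flagged undefined
  const <- oscillation_bursts(rep(1, 40 * fs), fs)
  expect_false(const$defined)
  expect_true(is.na(const$duration_p95))
})

test_that("phase bursts match constructed slip times and the brute-force oracle", {
  fs <- 500
  # pure sinusoid: no slips, single flagged period
  ap <- analytic_envelope_phase(tone(10, 10))
  pb0 <- phase_bursts(ap$phase, fs)
  expect_false(pb0$defined)
  expect_equal(pb0$n_bursts, 1L)
  expect_equal(pb0$duration_p95, 10, tolerance = 1e-6)

  # phase resets injected every 1 s -> stable periods of ~1 s
  ph <- cumsum(rep(2 * pi * 10 / fs, 40 * fs))
  reset_at <- seq(fs, 40 * fs - 1, by = fs)
  for (i in reset_at) ph[i] <- ph[i] - 1   # backward phase step
  pb1 <- phase_bursts(ph, fs)
  expect_true(pb1$defined)
  expect_equal(pb1$duration_p95, 1, tolerance = 0.01)

  # alpha-filtered noise: percentiles equal the brute-force oracle
  for (seed in 1:5) {
    set.seed(seed)
    xb <- bandpass_filter(rnorm(60 * fs), canonical_bands()$alpha, fs)
    phase <- analytic_envelope_phase(xb)$phase
    got <- phase_bursts(phase, fs)
    want <- brute_force_phase_bursts(phase, fs)
    expect_equal(got$duration_p95, want$duration_p95)
    expect_equal(got$n_bursts, want$n)
  }
})

test_that("envelope statistics match closed-form distribution oracles", {
  st <- envelope_statistics(rep(3, 200))
  expect_equal(st$median, 3)
  expect_equal(st$variance, 0)
  expect_equal(st$range, 0)
  # Rayleigh envelope (narrowband Gaussian limit): skewness 0.6311
  set.seed(7)
  ray <- sqrt(rnorm(2e5)^2 + rnorm(2e5)^2)
  expect_equal(envelope_statistics(ray)$skewness,
               2 * sqrt(pi) * (pi - 3) / (4 - pi)^1.5, tolerance = 0.05 /
                 0.631)
  two <- envelope_statistics(rep(c(1, 3), 100))
  expect_equal(two$median, 2)
  expect_equal(two$range, 2)
})

test_that("envelope correlations have Spearman structure and Cz extraction", {
  s <- tone(10, 20) * (1 + 0.5 * sin(2 * pi * 0.2 * seq_len(10000) / 500))
  rec_same <- eeg_recording(rbind(s, s), 500, c("C3", "Cz"))
  C <- envelope_correlation(rec_same, canonical_bands()$alpha)
  expect_equal(C["C3", "Cz"], 1, tolerance = 1e-6)
  # independent sources: near-zero off-diagonals (envelope autocorrelation
  # limits the effective sample size, hence the sampling tolerance)
  rec_ind <- noise_recording(n_ch = 3, duration = 120, fs = 250, seed = 9)
  Ci <- envelope_correlation(rec_ind, canonical_bands()$alpha)
  expect_lt(max(abs(Ci[upper.tri(Ci)])), 0.08)
  expect_equal(diag(Ci), c(C3 = 1, Cz = 1, C4 = 1))
  cz <- envelope_correlation_cz(rec_ind, canonical_bands()$alpha)
  expect_true(is.na(cz["Cz"]))
  expect_equal(unname(cz["C3"]), Ci["C3", "Cz"])
  no_cz <- eeg_recording(rec_ind$data[1:2, ], 250, c("C3", "C4"))
  expect_warning(cz2 <- envelope_correlation_cz(no_cz, canonical_bands()$alpha),
                 "Cz not present")
  expect_true(all(is.na(cz2)))
})

test_that("frequency stability separates stationary from alternating tones", {
  fs <- 250
  stat_tone <- tone(10, 60, fs)
  st <- frequency_stability(stat_tone, fs, canonical_bands()$alpha)
  expect_lt(st$sd_central_freq, 0.25)
  expect_equal(st$cycles_median, 50)   # 10 Hz x 5 s windows

  # alternate 9/11 Hz between consecutive 5 s windows: sd ~ 1 Hz
  segs <- lapply(1:12, function(i) tone(if (i %% 2) 9 else 11, 5, fs))
  alt <- unlist(segs)
  sa <- frequency_stability(alt, fs, canonical_bands()$alpha)
  expect_equal(sa$sd_central_freq, 1, tolerance = 0.15)
  expect_equal(sa$sd_max_wavelet_freq, 1, tolerance = 0.15)
  expect_error(frequency_stability(tone(10, 20, fs), fs,
                                   canonical_bands()$alpha), "10 windows")
})
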