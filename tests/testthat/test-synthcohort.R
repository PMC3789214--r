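test_that("background spectra have the requested log-log slope", {
  slope_of <- function(chi, seed) {
    x <- generate_background(60, 500, chi, seed)
    ps <- welch_psd(x, 500)
    keep <- ps$frequencies >= 1 & ps$frequencies <= 45
    unname(coef(lm(log10(ps$power[keep]) ~ log10(ps$frequencies[keep])))[2])
  }
  expect_lt(abs(slope_of(0, 1)), 0.1)
  expect_lt(abs(slope_of(1, 2) - (-1)), 0.15)
  expect_lt(abs(slope_of(2, 3) - (-2)), 0.15)
  x1 <- generate_background(60, 500, 1, 42)
  x2 <- generate_background(60, 500, 1, 42)
  expect_identical(x1, x2)
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_error(generate_background(-1, 500, 1, 1), "positive")
  expect_error(generate_background(60, 500, 3, 1), "\\[0, 2\\]")
})

test_that("oscillations are narrowband with the requested peak location", {
  sp <- oscillation_spec(19.6, 1, relative_amplitude = 1)
  x <- generate_oscillation(sp, 300, 500, seed = 4)
  pk <- fit_spectral_peak(welch_psd(x, 500), canonical_bands()$beta,
                          baseline_fit_range = c(14, 45),
                          baseline_exclude = c(16, 24))
  expect_true(pk$present)
  expect_lt(abs(pk$center - 19.6), 0.3)
  ps <- welch_psd(x, 500)
  inb <- band_power(ps, band_definition("p", 19.6 - 3, 19.6 + 3))
  expect_gt(inb / (sum(ps$power) * ps$df), 0.8)
  expect_identical(generate_oscillation(sp, 60, 500, seed = 9),
                   generate_oscillation(sp, 60, 500, seed = 9))
})

test_that("zero relative amplitude yields silence; Nyquist is enforced", {
  sp0 <- oscillation_spec(19.6, 1, relative_amplitude = 0)
  expect_equal(generate_oscillation(sp0, 60, 500, 1), numeric(30000))
  spbad <- oscillation_spec(60, 3, 1)
  expect_error(generate_oscillation(spbad, 60, 128, 1), "Nyquist")
})

test_that("envelope memory exponent is imposed on the oscillation envelope", {
  # fit above ~10x the burst timescale, where the memory scaling lives
  for (target in c(0.5, 0.75)) {
    d <- median(vapply(1:5, function(s) {
      sp <- oscillation_spec(19.6, 2, 1, envelope_memory_exponent = target)
      x <- generate_oscillation(sp, 300, 500, seed = 100 + s)
      dfa_exponent(analytic_envelope_phase(x)$envelope, 500,
                   window_range = c(5, 30))
    }, numeric(1)))
    expect_lt(abs(d - target), 0.1)
  }
})

test_that("envelope autocorrelation decays on the burst timescale", {
  sp_fast <- oscillation_spec(19.6, 2, 1, burst_timescale = 0.2)
  sp_slow <- oscillation_spec(19.6, 2, 1, burst_timescale = 2)
  acf_at <- function(sp, lag_s) {
    x <- generate_oscillation(sp, 120, 500, seed = 5)
    env <- analytic_envelope_phase(x)$envelope
    acf(env, lag.max = lag_s * 500, plot = FALSE)$acf[lag_s * 500 + 1]
  }
  expect_gt(acf_at(sp_slow, 1), acf_at(sp_fast, 1))
})

test_that("mixing controls inter-channel envelope correlation", {
  spec <- fast_cohort_spec(n_per_group = 1)
  g_ind <- spec$groups[[1]]; g_ind$mixing_coef <- 0
  g_ind$inter_channel_mixing <- diag(4)
  r_ind <- generate_recording(g_ind, spec, "s", 1, 7)
  C_ind <- envelope_correlation(r_ind, canonical_bands()$alpha)
  expect_lt(max(abs(C_ind[upper.tri(C_ind)])), 0.15)

  g_r1 <- spec$groups[[1]]
  g_r1$inter_channel_mixing <- matrix(1, 4, 4)  # same source everywhere
  r_r1 <- generate_recording(g_r1, spec, "s", 1, 7)
  C_r1 <- envelope_correlation(r_r1, canonical_bands()$alpha)
  expect_gt(min(C_r1[upper.tri(C_r1)]), 0.9)

  r_a <- generate_recording(spec$groups[[1]], spec, "s", 1, 11)
  r_b <- generate_recording(spec$groups[[1]], spec, "s", 1, 11)
  expect_identical(r_a$data, r_b$data)
})

test_that("mixing conserves channel power (normalized rows, independent sources)", {
  # with L2-normalized mixing rows and i.i.d.-constructed sources, the
  # expected channel variance is the mean source variance plus the 1%
  # sensor-noise power, whatever the mixing topology; compare identity vs
  # rank-1 mixing of the same cohort
  spec <- fast_cohort_spec(n_per_group = 1, duration = 120)
  # with the same seed the source realizations are identical, so an
  # orthonormal re-mixing must conserve the total channel power exactly
  # (up to the 1% sensor noise drawn per channel)
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  g_id <- spec$groups[[1]]; g_id$inter_channel_mixing <- diag(4)
  g_q <- spec$groups[[1]]; g_q$inter_channel_mixing <- Q
  tot_id <- sum(apply(generate_recording(g_id, spec, "s", 1, 3)$data, 1, var))
  tot_q <- sum(apply(generate_recording(g_q, spec, "s", 1, 3)$data, 1, var))
  expect_lt(abs(tot_id / tot_q - 1), 0.05)
  expect_error(
    generate_recording(
      within_g <- { g <- spec$groups[[1]]; g$inter_channel_mixing <- diag(3); g },
      spec, "s", 1, 1),
    "mixing matrix")
})

test_that("cohort structure: visits, missingness and determinism", {
  spec <- fast_cohort_spec(n_per_group = 5, frac_missing = 2 / 5)
  out <- generate_cohort(spec)
  expect_equal(nrow(out$subjects), 10)
  expect_equal(sum(!out$subjects$has_visit2), 4)   # 2 per group
  v1 <- grepl("-v1$", names(out$recordings))
  expect_equal(sum(v1), 10)                        # everyone has visit 1
  expect_equal(length(out$recordings), 10 + 6)
  out2 <- generate_cohort(spec)
  expect_identical(out$recordings[["MCI-001-v1"]]$data,
                   out2$recordings[["MCI-001-v1"]]$data)

  spec0 <- fast_cohort_spec(n_per_group = 3, frac_missing = 0)
  out0 <- generate_cohort(spec0)
  expect_true(all(out0$subjects$has_visit2))
})

test_that("default cohort mirrors the study's n-structure", {
  spec <- default_cohort_spec()
  ns <- vapply(spec$groups, function(g) g$n_subjects, integer(1))
  expect_equal(ns, c(39L, 25L))
  miss <- vapply(spec$groups, function(g)
    round(g$fraction_without_second_visit * g$n_subjects), numeric(1))
  expect_equal(miss, c(22, 8))   # 17 + 17 remain for training
  expect_equal(length(spec$channel_labels), 21)
  expect_true("Cz" %in% spec$channel_labels)
})

test_that("cohort recordings recover the injected beta peak frequency", {
  # group-level spectral fidelity: median fitted center within 0.3 Hz
  spec <- default_cohort_spec(n_channels = 4, sampling_rate = 250,
                              duration = 300, master_seed = 77)
  g <- spec$groups[[2]]   # AD-converter, beta at 19.6 Hz visit 1
  centers <- vapply(1:20, function(si) {
    r <- generate_recording(g, spec, sprintf("s%d", si), 1,
                            derive_seed(77, 2, si, 1))
    pk <- fit_spectral_peak(welch_psd(r$data[1, ], 250),
                            canonical_bands()$beta)
    if (pk$present) pk$center else NA_real_
  }, numeric(1))
  expect_lt(abs(median(centers, na.rm = TRUE) - 19.6), 0.3)
})

test_that("write_cohort writes a readable subject table and recordings", {
  dir <- tempfile()
  out <- generate_cohort(fast_cohort_spec(n_per_group = 2, frac_missing = 0.5,
                                          duration = 60))
  write_cohort(out, dir)
  tab <- read.delim(file.path(dir, "subjects.tsv"))
  expect_equal(names(tab), c("subject_id", "group", "visit1_file", "visit2_file"))
  expect_equal(nrow(tab), 4)
  back <- read_recording(file.path(dir, tab$visit1_file[1]))
  expect_identical(back$data, out$recordings[[paste0(tab$subject_id[1], "-v1")]]$data)
})
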