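#' Hjorth parameters
#'
#' Activity (signal variance), mobility (RMS angular frequency, rad/s, via
#' the ratio-of-derivatives estimate with the discrete difference scaled by
#' the sampling rate) and complexity (mobility of the derivative over the
#' mobility of the signal; 1 for a pure sinusoid).
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @return list: `activity`, `mobility` (rad/s), `complexity`.
#' @export
hjorth_parameters <- function(x, sampling_rate) {
  if (length(x) < 3) stop("need at least 3 samples")
  v0 <- stats::var(x)
  if (v0 == 0)
    return(list(activity = 0, mobility = NA_real_, complexity = NA_real_))
  d1 <- diff(x) * sampling_rate
  d2 <- diff(d1) * sampling_rate
  mob <- sqrt(stats::var(d1) / v0)
  list(activity = v0, mobility = mob,
       complexity = sqrt(stats::var(d2) / stats::var(d1)) / mob)
}

#' Barlow time-domain parameters
#'
#' Mean amplitude (time-averaged rectified signal; a sinusoid of amplitude A
#' yields 2A/pi), mean frequency (ratio-of-derivatives estimate, Hz) and
#' spectral purity index in \[0, 1\] (1 for a pure sinusoid), computed from
#' the second spectral moments of the signal and its first two derivatives.
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @return list: `mean_amplitude`, `mean_frequency` (Hz), `spectral_purity`.
#' @export
barlow_parameters <- function(x, sampling_rate) {
  if (length(x) < sampling_rate) stop("need at least 1 s of signal")
  v0 <- stats::var(x)
  if (v0 == 0)
    return(list(mean_amplitude = mean(abs(x)), mean_frequency = NA_real_,
                spectral_purity = NA_real_))
  d1 <- diff(x) * sampling_rate
  d2 <- diff(d1) * sampling_rate
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  list(mean_amplitude = mean(abs(x)),
       mean_frequency = sqrt(v1 / v0) / (2 * pi),
       spectral_purity = v1^2 / (v0 * v2))
}

#' Wackermann global descriptors of multichannel EEG
#'
#' On average-referenced data: global field strength (RMS over channels and
#' time), global frequency (ratio-of-derivatives estimate pooled over
#' channels, Hz) and spatial complexity Omega (exponential of the entropy of
#' the normalized eigenvalues of the channel covariance; 1 = rank-1
#' topography, n = isotropic noise).
#'
#' @param rec an [eeg_recording()].
#' @param band optional [band_definition()]; data are band-filtered first
#'   (default 1-45 Hz broadband).
#' @return list: `global_field_strength`, `global_frequency`,
#'   `spatial_complexity`.
#' @export
wackermann_parameters <- function(rec, band = canonical_bands()$broadband) {
  if (n_channels(rec) < 2)
    return(list(global_field_strength = NA_real_, global_frequency = NA_real_,
                spatial_complexity = NA_real_))
  X <- t(apply(rec$data, 1L, bandpass_filter, band = band,
               sampling_rate = rec$sampling_rate))
  # field strength on average-referenced data; frequency and spatial
  # complexity on the raw field (re-referencing would remove one rank and
  # distort the eigenstructure of near-rank-1 topographies)
  Xr <- sweep(X, 2L, colMeans(X))
  D <- t(diff(t(X))) * rec$sampling_rate
  lam <- eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0); lam <- lam / sum(lam)
  lam <- lam[lam > 1e-12]
  list(global_field_strength = sqrt(mean(Xr^2)),
       global_frequency = sqrt(sum(D^2) / sum(X^2)) / (2 * pi),
       spatial_complexity = exp(-sum(lam * log(lam))))
}

# linearly detrended RMS of consecutive columns of a segment matrix
.segment_rms <- function(Y, s, starts) {
  t_ <- seq_len(s)
  B <- cbind(1, t_ - mean(t_))
  Q <- qr.Q(qr(B))
  M <- vapply(starts, function(i) Y[i:(i + s - 1L)], numeric(s))
  R <- M - Q %*% crossprod(Q, M)
  colMeans(R^2)                           # per-window mean squared residual
}

.dfa_scales <- function(n, sampling_rate, window_range, n_scales) {
  s_min <- max(4L, round(window_range[1] * sampling_rate))
  s_max <- min(n %/% 4L, round(window_range[2] * sampling_rate))
  if (s_max <= s_min) return(NULL)
  unique(round(exp(seq(log(s_min), log(s_max), length.out = n_scales))))
}

#' Detrended fluctuation analysis exponent
#'
#' Computes the DFA scaling exponent of a series (typically an amplitude
#' envelope): the least-squares slope of log fluctuation versus log window
#' size, with linear detrending per window and 50%-overlapping windows
#' logarithmically spaced over `window_range`.
#'
#' @param x numeric series.
#' @param sampling_rate samples per second of `x`.
#' @param window_range fit range in seconds; default 1 s to one tenth of the
#'   series length.
#' @param overlap window overlap fraction (default 0.5).
#' @param n_scales number of log-spaced scales (default 12).
#' @return the exponent, or `NA` when the series is too short or constant.
#' @export
dfa_exponent <- function(x, sampling_rate,
                         window_range = c(1, length(x) / sampling_rate / 10),
                         overlap = 0.5, n_scales = 12) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  scales <- .dfa_scales(n, sampling_rate, window_range, n_scales)
  if (is.null(scales) || length(scales) < 4) return(NA_real_)
  Y <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    starts <- unique(round(seq(1L, n - s + 1L, by = max(1, s * (1 - overlap)))))
    sqrt(mean(.segment_rms(Y, s, starts)))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(Fs) ~ log(scales)))[2L])
}

#' Multifractal DFA spectral width
#'
#' Generalized Hurst exponents h(q) are estimated as slopes of the
#' q-th-order fluctuation function over log-spaced scales; the multifractal
#' width is `max h(q) - min h(q)` over the q grid. A monofractal series has
#' width near 0 (finite-size scatter aside).
#'
#' @param x numeric series (typically an amplitude envelope).
#' @param sampling_rate samples per second.
#' @param q_range moment orders; default -5..-1, 1..5 (q = 0 excluded, the
#'   log-average limit is not needed for the width).
#' @param window_range,n_scales as in [dfa_exponent()].
#' @return the width (>= 0), or `NA` for degenerate input.
#' @export
mfdfa_width <- function(x, sampling_rate, q_range = c(-5:-1, 1:5),
                        window_range = c(1, length(x) / sampling_rate / 10),
                        n_scales = 12) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  q_range <- q_range[q_range != 0]
  scales <- .dfa_scales(n, sampling_rate, window_range, n_scales)
  if (is.null(scales) || length(scales) < 4) return(NA_real_)
  Y <- cumsum(x - mean(x))
  # non-overlapping windows from both ends (standard MFDFA segmentation)
  Fq <- vapply(scales, function(s) {
    starts <- c(seq(1L, n - s + 1L, by = s),
                rev(seq(n - s + 1L, 1L, by = -s)))
    f2 <- pmax(.segment_rms(Y, s, unique(starts)), .Machine$double.xmin)
    vapply(q_range, function(q) mean(f2^(q / 2))^(1 / q), numeric(1))
  }, numeric(length(q_range)))
  Fq <- matrix(Fq, nrow = length(q_range))
  hq <- apply(log(Fq), 1L, function(lf)
    stats::coef(stats::lm(lf ~ log(scales)))[2L])
  max(hq) - min(hq)
}

#' Oscillation-burst statistics of an amplitude envelope
#'
#' Bursts are maximal runs where the envelope exceeds its median. Duration
#' is the run length in seconds; size is the area of the envelope above the
#' threshold over the run. The 95th percentiles of both are returned;
#' fewer than 20 bursts flags the statistics undefined.
#'
#' @param envelope non-negative numeric envelope.
#' @param sampling_rate samples per second.
#' @param threshold burst threshold; default the envelope median.
#' @return list: `duration_p95` (s), `size_p95`, `n_bursts`, `defined`.
#' @export
oscillation_bursts <- function(envelope, sampling_rate,
                               threshold = stats::median(envelope)) {
  if (length(envelope) < 30 * sampling_rate)
    stop("need at least 30 s of envelope")
  above <- envelope > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (sum(keep) < 20)
    return(list(duration_p95 = NA_real_, size_p95 = NA_real_,
                n_bursts = sum(keep), defined = FALSE))
  durations <- r$lengths[keep] / sampling_rate
  sizes <- mapply(function(s, e) sum(envelope[s:e] - threshold),
                  starts[keep], ends[keep]) / sampling_rate
  list(duration_p95 = unname(stats::quantile(durations, 0.95)),
       size_p95 = unname(stats::quantile(sizes, 0.95)),
       n_bursts = sum(keep), defined = TRUE)
}

#' Stable-phase-burst statistics
#'
#' A phase slip is a sample where the discrete derivative of the unwrapped
#' instantaneous phase is negative (backward phase motion); consecutive slip
#' samples merge into one slip event. Stable phase bursts are the periods
#' between consecutive slips; duration is the period length in seconds and
#' size the phase advance (radians) over the period. 95th percentiles are
#' returned; fewer than 20 bursts (e.g., a pure sinusoid with no slips at
#' all) flags the statistics undefined.
#'
#' @param phase unwrapped instantaneous phase (radians), e.g. from
#'   [analytic_envelope_phase()].
#' @param sampling_rate samples per second.
#' @return list: `duration_p95` (s), `size_p95` (rad), `n_bursts`, `defined`.
#' @export
phase_bursts <- function(phase, sampling_rate) {
  dphi <- diff(phase)
  slip <- dphi < 0
  r <- rle(slip)
  # slip-event start indices (into the phase vector)
  ends <- cumsum(r$lengths)
  ev <- (ends - r$lengths + 1L)[r$values]
  if (length(ev) < 1)
    return(list(duration_p95 = length(phase) / sampling_rate,
                size_p95 = phase[length(phase)] - phase[1L],
                n_bursts = 1L, defined = FALSE))
  bounds <- c(1L, ev, length(phase))
  durations <- diff(bounds) / sampling_rate
  sizes <- phase[bounds[-1L]] - phase[bounds[-length(bounds)]]
  defined <- length(durations) >= 20
  list(duration_p95 = unname(stats::quantile(durations, 0.95)),
       size_p95 = unname(stats::quantile(sizes, 0.95)),
       n_bursts = length(durations), defined = defined)
}

#' Distribution statistics of an amplitude envelope
#'
#' Excess kurtosis (Gaussian = 0), skewness, interquartile range, median,
#' range (max - min) and variance of the envelope sample distribution.
#'
#' @param envelope numeric envelope (>= 100 samples).
#' @return named list of the six statistics.
#' @export
envelope_statistics <- function(envelope) {
  if (length(envelope) < 100) stop("need at least 100 samples")
  m <- mean(envelope)
  d <- envelope - m
  m2 <- mean(d^2)
  list(kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else NA_real_,
       skewness = if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_,
       iqr = stats::IQR(envelope),
       median = stats::median(envelope),
       range = diff(range(envelope)),
       variance = stats::var(envelope))
}

#' Spearman correlation matrix of band amplitude envelopes across channels
#'
#' @param rec an [eeg_recording()] with >= 2 channels.
#' @param band a [band_definition()].
#' @return channel x channel Spearman correlation matrix of in-band
#'   amplitude envelopes (symmetric, unit diagonal).
#' @export
envelope_correlation <- function(rec, band) {
  if (n_channels(rec) < 2) stop("need at least 2 channels")
  env <- apply(rec$data, 1L, function(ch)
    analytic_envelope_phase(
      bandpass_filter(ch, band, rec$sampling_rate))$envelope)
  C <- stats::cor(env, method = "spearman")
  dimnames(C) <- list(rec$channel_labels, rec$channel_labels)
  C
}

#' Per-channel envelope correlation with Cz
#'
#' @param rec an [eeg_recording()].
#' @param band a [band_definition()].
#' @return named numeric vector (one value per channel; Cz itself is `NA`);
#'   all-`NA` with a warning when Cz is absent.
#' @export
envelope_correlation_cz <- function(rec, band) {
  out <- stats::setNames(rep(NA_real_, n_channels(rec)), rec$channel_labels)
  if (!"Cz" %in% rec$channel_labels) {
    warning("Cz not present; with-Cz envelope correlations undefined")
    return(out)
  }
  C <- envelope_correlation(rec, band)
  out[] <- C[, "Cz"]
  out["Cz"] <- NA_real_
  out
}

# mean Morlet wavelet power per (frequency, window); freqs x windows matrix
.morlet_window_power <- function(x, sampling_rate, freqs, win_samples,
                                 n_cycles = 6) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f_axis <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  n_win <- n %/% win_samples
  idx <- rep(seq_len(n_win), each = win_samples)
  P <- vapply(freqs, function(f0) {
    sig_f <- f0 / n_cycles
    H <- exp(-(f_axis - f0)^2 / (2 * sig_f^2))   # analytic Morlet in freq
    z <- stats::fft(X * H, inverse = TRUE) / n
    pw <- Mod(z)^2
    as.numeric(tapply(pw[seq_len(n_win * win_samples)], idx, mean))
  }, numeric(n_win))
  t(P)                                           # freqs x windows
}

#' Frequency-stability biomarkers
#'
#' Splits the in-band signal into non-overlapping windows (default 5 s) and
#' summarizes, across windows, the dispersion of (a) the spectral central
#' frequency and (b) the frequency of maximum Morlet wavelet power, plus the
#' distribution parameters (median, IQR) of the positive instantaneous
#' phase values and of the number of oscillation cycle peaks per window.
#'
#' @param x numeric signal (raw; filtered internally).
#' @param sampling_rate Hz.
#' @param band a [band_definition()].
#' @param window_length window length in seconds (default 5).
#' @return named list: `sd_central_freq`, `iqr_central_freq`,
#'   `sd_max_wavelet_freq`, `iqr_max_wavelet_freq`, `phase_pos_median`,
#'   `phase_pos_iqr`, `cycles_median`, `cycles_iqr`.
#' @export
frequency_stability <- function(x, sampling_rate, band, window_length = 5) {
  ws <- round(window_length * sampling_rate)
  n_win <- length(x) %/% ws
  if (n_win < 10) stop("need at least 10 windows")
  xb <- bandpass_filter(x, band, sampling_rate)
  idx <- rep(seq_len(n_win), each = ws)
  used <- seq_len(n_win * ws)

  # central frequency per window from the window periodogram
  cf <- vapply(seq_len(n_win), function(w) {
    seg <- xb[((w - 1L) * ws + 1L):(w * ws)]
    P <- Mod(stats::fft(seg - mean(seg)))^2
    nf <- ws %/% 2 + 1L
    fr <- (seq_len(nf) - 1L) * sampling_rate / ws
    keep <- fr >= band$low_edge & fr < band$high_edge
    p <- P[seq_len(nf)][keep]
    if (sum(p) == 0) return(NA_real_)
    sum(fr[keep] * p) / sum(p)
  }, numeric(1))

  freqs <- seq(band$low_edge, band$high_edge, by = 0.5)
  WP <- .morlet_window_power(x, sampling_rate, freqs, ws)
  max_wf <- freqs[apply(WP, 2L, which.max)]

  ap <- analytic_envelope_phase(xb)
  wrapped <- Arg(exp(1i * ap$phase))
  pos <- wrapped[wrapped > 0]

  peaks <- which(diff(sign(diff(xb))) == -2) + 1L
  cyc <- tabulate(idx[peaks[peaks <= max(used)]], nbins = n_win)

  list(sd_central_freq = stats::sd(cf, na.rm = TRUE),
       iqr_central_freq = stats::IQR(cf, na.rm = TRUE),
       sd_max_wavelet_freq = stats::sd(max_wf),
       iqr_max_wavelet_freq = stats::IQR(max_wf),
       phase_pos_median = if (length(pos)) stats::median(pos) else NA_real_,
       phase_pos_iqr = if (length(pos)) stats::IQR(pos) else NA_real_,
       cycles_median = stats::median(cyc),
       cycles_iqr = stats::IQR(cyc))
}
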