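#' Frequency band definition
#'
#' @param name band name.
#' @param low_edge,high_edge band edges in Hz; `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low_edge, high_edge) {
  if (!(low_edge > 0 && high_edge > low_edge))
    stop("band edges must satisfy 0 < low_edge < high_edge")
  structure(list(name = as.character(name), low_edge = as.numeric(low_edge),
                 high_edge = as.numeric(high_edge)),
            class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-13, beta 13-30, gamma 30-45 Hz, plus the
#' 1-45 Hz broadband used for power normalization. Band edges are treated as
#' half-open `[low, high)` on spectral grids so the shared 13 Hz alpha/beta
#' edge is not double counted.
#'
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function() {
  list(delta     = band_definition("delta", 1, 3),
       theta     = band_definition("theta", 4, 7),
       alpha     = band_definition("alpha", 8, 13),
       beta      = band_definition("beta", 13, 30),
       gamma     = band_definition("gamma", 30, 45),
       broadband = band_definition("broadband", 1, 45))
}

#' Individualized frequency bands anchored at the alpha peak frequency
#'
#' Given the individual alpha peak frequency (APF), returns
#' alpha1 = \[APF-4, APF-2\], alpha2 = \[APF-2, APF\], alpha3 = \[APF, APF+2\]
#' and an individualized beta band \[APF+2, 30\] Hz.
#'
#' @param apf individual alpha peak frequency in Hz; sane range 6-14.
#' @return list with `apf` and the four bands; if `apf` is missing or out of
#'   the sanity range, canonical stand-ins are returned with
#'   `fallback = TRUE` and a warning.
#' @export
individualized_bands <- function(apf) {
  fallback <- function(why) {
    warning("individualized_bands: ", why, "; falling back to canonical anchors")
    list(apf = NA_real_, fallback = TRUE,
         alpha1 = band_definition("alpha1", 6, 8),
         alpha2 = band_definition("alpha2", 8, 10),
         alpha3 = band_definition("alpha3", 10, 12),
         beta_ind = band_definition("beta_ind", 12, 30))
  }
  if (!is.finite(apf)) return(fallback("APF undefined"))
  if (apf < 6 || apf > 14) return(fallback(sprintf("APF %.1f outside [6, 14]", apf)))
  list(apf = apf, fallback = FALSE,
       alpha1 = band_definition("alpha1", apf - 4, apf - 2),
       alpha2 = band_definition("alpha2", apf - 2, apf),
       alpha3 = band_definition("alpha3", apf, apf + 2),
       beta_ind = band_definition("beta_ind", apf + 2, 30))
}

#' Zero-phase band-pass filter
#'
#' Filters in the frequency domain with a real transfer function: unit gain
#' inside the band, zero far outside, raised-cosine transitions of width
#' `transition` Hz. A real, even transfer function has exactly zero phase, so
#' phase-based biomarkers are undistorted; attenuation one octave outside the
#' band is effectively complete (>> 20 dB).
#'
#' @param x numeric signal vector.
#' @param band a [band_definition()].
#' @param sampling_rate Hz.
#' @param transition transition-band width in Hz (default: quarter of the
#'   band's low edge, capped at 1 Hz).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, band, sampling_rate,
                            transition = min(1, band$low_edge / 4)) {
  nyq <- sampling_rate / 2
  if (band$high_edge > nyq) stop("band exceeds the Nyquist frequency")
  n <- length(x)
  if (n < 3 * sampling_rate / band$low_edge)
    stop("signal too short for this band (need >= 3 cycles of the low edge)")
  xm <- mean(x)
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate - f)       # two-sided frequency axis
  h <- raised_cosine_gain(f, band$low_edge, band$high_edge, transition)
  Re(stats::fft(stats::fft(x - xm) * h, inverse = TRUE)) / n
}

# gain 0 outside [lo - tw, hi + tw], 1 inside [lo, hi], cosine edges
raised_cosine_gain <- function(f, lo, hi, tw) {
  g <- numeric(length(f))
  g[f >= lo & f <= hi] <- 1
  rise <- f > (lo - tw) & f < lo
  g[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / tw))
  fall <- f > hi & f < (hi + tw)
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / tw))
  g
}

#' Analytic amplitude envelope and instantaneous phase
#'
#' Computes the analytic signal by the Fourier method (one-sided spectrum
#' doubling) and returns the amplitude envelope and the unwrapped
#' instantaneous phase. Intended for band-limited input.
#'
#' @param x band-limited numeric signal.
#' @param sampling_rate Hz (used only for the `instantaneous_frequency`
#'   helper attribute; may be omitted).
#' @return list with `envelope` (>= 0), `phase` (unwrapped radians) and
#'   `defined` (FALSE for an all-zero input, whose phase is meaningless).
#' @export
analytic_envelope_phase <- function(x, sampling_rate = NULL) {
  n <- length(x)
  if (all(x == 0)) {
    return(list(envelope = numeric(n), phase = rep(NA_real_, n),
                defined = FALSE))
  }
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  list(envelope = Mod(z), phase = signal::unwrap(Arg(z)), defined = TRUE)
}

#' Mean instantaneous frequency from an unwrapped phase
#' @param phase unwrapped phase in radians.
#' @param sampling_rate Hz.
#' @return Hz.
#' @export
instantaneous_frequency <- function(phase, sampling_rate) {
  mean(diff(phase)) * sampling_rate / (2 * pi)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with per-segment demeaning, normalized
#' so that the PSD integrates to the signal variance (Parseval-consistent,
#' one-sided).
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @param window_length segment length in seconds (default 4 s -> 0.25 Hz
#'   resolution).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return An `eeg_spectrum`: list with `frequencies`, `power` (uV^2/Hz),
#'   `df`, `window_length`, `overlap`.
#' @export
welch_psd <- function(x, sampling_rate, window_length = 4, overlap = 0.5) {
  nper <- round(window_length * sampling_rate)
  n <- length(x)
  if (nper > n) stop("window longer than the signal")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper))  # Hann
  U <- sum(w^2)
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (U * sampling_rate)
    half <- P[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nper even)
    if (nper %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  freqs <- (seq_len(nf) - 1L) * sampling_rate / nper
  structure(list(frequencies = freqs, power = acc / length(starts),
                 df = sampling_rate / nper,
                 window_length = window_length, overlap = overlap),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d bins, %g-%g Hz, df = %g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$df))
  invisible(x)
}

# indices of spectrum bins inside [low, high) of a band
band_bins <- function(spectrum, band) {
  which(spectrum$frequencies >= band$low_edge &
        spectrum$frequencies < band$high_edge)
}

# integrated band power (uV^2), half-open band convention
band_power <- function(spectrum, band) {
  sum(spectrum$power[band_bins(spectrum, band)]) * spectrum$df
}
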