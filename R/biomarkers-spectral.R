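#' Spectral features of a frequency band
#'
#' From a Welch spectrum: absolute band power (integral of the PSD over the
#' half-open band), relative power (absolute power over broadband 1-45 Hz
#' power), power-weighted central frequency, PSD at the grid bin nearest the
#' central frequency, power-weighted bandwidth (SD around the central
#' frequency) and the 90% spectral edge frequency.
#'
#' @param spectrum an `eeg_spectrum` from [welch_psd()].
#' @param band a [band_definition()].
#' @param broadband normalization band (default 1-45 Hz).
#' @return named list of the six features; all `NA` when in-band power is 0.
#' @export
spectral_band_features <- function(spectrum, band,
                                   broadband = canonical_bands()$broadband) {
  bins <- band_bins(spectrum, band)
  if (!length(bins)) stop("band outside the spectrum range")
  f <- spectrum$frequencies[bins]
  p <- spectrum$power[bins]
  tot <- sum(p)
  if (tot == 0) {
    na <- NA_real_
    return(list(absolute_power = 0, relative_power = na,
                central_frequency = na, power_at_central_frequency = na,
                bandwidth = na, spectral_edge = na))
  }
  cf <- sum(f * p) / tot
  cdf <- cumsum(p) / tot
  list(absolute_power = tot * spectrum$df,
       relative_power = tot * spectrum$df / band_power(spectrum, broadband),
       central_frequency = cf,
       power_at_central_frequency = p[which.min(abs(f - cf))],
       bandwidth = sqrt(sum((f - cf)^2 * p) / tot),
       spectral_edge = f[which(cdf >= 0.9)[1L]])
}

#' Band power ratio
#'
#' @param spectrum an `eeg_spectrum`.
#' @param band_a,band_b numerator and denominator [band_definition()]s.
#' @return absolute power in `band_a` over absolute power in `band_b`;
#'   `NA` when the denominator power is zero.
#' @export
power_ratio <- function(spectrum, band_a, band_b) {
  pb <- band_power(spectrum, band_b)
  if (pb == 0) return(NA_real_)
  band_power(spectrum, band_a) / pb
}

# robust log-log linear 1/f baseline; returns function(f) -> PSD and the
# robust residual scale (linear power units) over the given bins
.fit_one_over_f <- function(spectrum, fit_range = c(1, 45),
                            exclude = c(6, 14)) {
  f <- spectrum$frequencies
  keep <- f >= fit_range[1] & f <= fit_range[2] &
    !(f >= exclude[1] & f <= exclude[2]) & spectrum$power > 0
  if (sum(keep) < 8) stop("too few bins for the 1/f baseline fit")
  lf <- log10(f[keep]); lp <- log10(spectrum$power[keep])
  fit <- tryCatch(MASS::rlm(lp ~ lf, maxit = 50),
                  error = function(e) stats::lm(lp ~ lf))
  co <- stats::coef(fit)
  list(baseline = function(fr) 10^(co[1L] + co[2L] * log10(pmax(fr, 1e-6))),
       slope = unname(co[2L]))
}

# fit one Gaussian to residual power; minimum width 2 grid steps keeps the
# fit from latching onto single-bin noise; returns NULL on failure
.fit_gaussian <- function(f, resid, df) {
  i0 <- which.max(resid)
  start <- list(A = max(resid[i0], df), mu = f[i0], sig = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-(fr - mu)^2 / (2 * sig^2)),
                      data = data.frame(r = resid, fr = f),
                      start = start,
                      lower = c(A = 0, mu = min(f), sig = 2 * df),
                      upper = c(A = Inf, mu = max(f), sig = diff(range(f))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(stats::coef(fit))
}

#' Fit a 1/f-corrected spectral peak
#'
#' Fits a robust straight line to log power versus log frequency over
#' `baseline_fit_range` (excluding the alpha region, which would bias the
#' aperiodic fit), then fits a Gaussian to the baseline-subtracted power
#' inside `search_band`. The peak is declared present only when its fitted
#' amplitude reaches one robust standard deviation of the baseline
#' residuals inside the search band. A second Gaussian is attempted on the
#' residual after subtracting the first and reported when it independently
#' passes the same criterion.
#'
#' @param spectrum an `eeg_spectrum`.
#' @param search_band [band_definition()] in which to look for the peak.
#' @param baseline_fit_range frequency range (Hz) of the 1/f fit.
#' @param baseline_exclude frequency range excluded from the 1/f fit.
#' @return A `spectral_peak`: list with `present`, `center` (Hz), `width`
#'   (Gaussian FWHM, Hz), `corrected_power` (PSD above baseline at the
#'   center), `uncorrected_power` (total PSD at the center),
#'   `baseline_slope`, and `second_peak` (same fields or NULL).
#' @export
fit_spectral_peak <- function(spectrum, search_band,
                              baseline_fit_range = c(1, 45),
                              baseline_exclude = c(6, 14)) {
  bins <- band_bins(spectrum, search_band)
  if (length(bins) < 8) stop("spectrum too coarse for this search band")
  bl <- .fit_one_over_f(spectrum, baseline_fit_range, baseline_exclude)
  f <- spectrum$frequencies[bins]
  resid <- spectrum$power[bins] - bl$baseline(f)
  absent <- list(present = FALSE, center = NA_real_, width = NA_real_,
                 corrected_power = NA_real_, uncorrected_power = NA_real_,
                 baseline_slope = bl$slope, second_peak = NULL)
  g1 <- .fit_gaussian(f, resid, spectrum$df)
  # presence: amplitude >= 1 SD of the baseline residuals outside the
  # fitted peak, with a tiny relative floor catching the degenerate
  # noise-free baseline (residuals at machine precision)
  passes <- function(g, r) {
    if (is.null(g)) return(FALSE)
    outside <- abs(f - g$mu) > 2 * sqrt(2 * log(2)) * g$sig
    resid_sd <- if (sum(outside) >= 4) stats::sd(r[outside])
                else stats::mad(r)
    g$A >= max(resid_sd, 1e-3 * bl$baseline(g$mu))
  }
  if (!passes(g1, resid)) return(structure(absent, class = "spectral_peak"))
  peak <- function(g) list(
    center = g$mu, width = 2 * sqrt(2 * log(2)) * g$sig,
    corrected_power = g$A,
    uncorrected_power = g$A + bl$baseline(g$mu))
  out <- c(list(present = TRUE), peak(g1),
           list(baseline_slope = bl$slope, second_peak = NULL))
  resid2 <- resid - g1$A * exp(-(f - g1$mu)^2 / (2 * g1$sig^2))
  g2 <- .fit_gaussian(f, resid2, spectrum$df)
  if (!is.null(g2) && passes(g2, resid2) && abs(g2$mu - g1$mu) > out$width / 2)
    out$second_peak <- c(list(present = TRUE), peak(g2))
  structure(out, class = "spectral_peak")
}

#' @export
print.spectral_peak <- function(x, ...) {
  if (!x$present) cat("<spectral_peak> absent\n")
  else cat(sprintf("<spectral_peak> center %.2f Hz, FWHM %.2f Hz, corrected power %.3g%s\n",
                   x$center, x$width, x$corrected_power,
                   if (!is.null(x$second_peak)) " (+ second peak)" else ""))
  invisible(x)
}

#' Alpha-theta transition frequency
#'
#' The frequency of minimum power between the theta range and the alpha
#' peak (grid argmin of the PSD over \[4, APF\] Hz). When the minimum falls
#' on the search boundary the spectrum is monotone there and the value is
#' flagged degenerate.
#'
#' @param spectrum an `eeg_spectrum`.
#' @param apf individual alpha peak frequency (Hz); `NA` when no alpha peak
#'   was found.
#' @return list: `frequency` (Hz or NA), `defined`, `degenerate`.
#' @export
alpha_theta_transition <- function(spectrum, apf) {
  if (!is.finite(apf))
    return(list(frequency = NA_real_, defined = FALSE, degenerate = FALSE))
  keep <- which(spectrum$frequencies >= 4 & spectrum$frequencies <= apf)
  if (length(keep) < 3)
    return(list(frequency = NA_real_, defined = FALSE, degenerate = FALSE))
  i <- keep[which.min(spectrum$power[keep])]
  list(frequency = spectrum$frequencies[i], defined = TRUE,
       degenerate = i %in% range(keep))
}
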