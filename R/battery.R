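#' Default biomarker registry
#'
#' Enumerates the per-channel biomarker battery as a data frame with one row
#' per biomarker: spectral features for the five canonical and four
#' individualized bands, theta/alpha and gamma/delta power ratios, the
#' amplitude-envelope family (distribution statistics, DFA, multifractal
#' width, oscillation bursts, stable phase bursts, with-Cz envelope
#' correlation) per canonical band, broadband time-domain parameters
#' (Hjorth, Barlow, Wackermann), 1/f-corrected alpha and beta peak
#' parameters and the alpha-theta transition, and frequency-stability
#' statistics per canonical band. The default composition has
#' `nrow(default_registry())` rows; the composition (not the count) is the
#' contract, and subsets can be selected by family for faster runs.
#'
#' @param families character subset of
#'   `c("spectral", "ratios", "envelope", "broadband", "peaks", "stability")`.
#' @param envelope_bands,stability_bands canonical band names for the
#'   envelope and stability families.
#' @return data.frame with columns `name`, `family`, `band`, `feature`.
#' @export
default_registry <- function(families = c("spectral", "ratios", "envelope",
                                          "broadband", "peaks", "stability"),
                             envelope_bands = c("delta", "theta", "alpha",
                                                "beta", "gamma"),
                             stability_bands = c("delta", "theta", "alpha",
                                                 "beta", "gamma")) {
  families <- match.arg(families, several.ok = TRUE)
  rows <- list()
  add <- function(family, band, feature)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste(feature, band, sep = "_"), family = family,
      band = band, feature = feature, stringsAsFactors = FALSE)
  spectral_feats <- c("absolute_power", "relative_power", "central_frequency",
                      "power_at_central_frequency", "bandwidth",
                      "spectral_edge")
  if ("spectral" %in% families)
    for (b in c("delta", "theta", "alpha", "beta", "gamma",
                "alpha1", "alpha2", "alpha3", "beta_ind"))
      for (ft in spectral_feats) add("spectral", b, ft)
  if ("ratios" %in% families) {
    add("ratios", "theta_alpha", "power_ratio")
    add("ratios", "gamma_delta", "power_ratio")
  }
  env_feats <- c("env_kurtosis", "env_skewness", "env_iqr", "env_median",
                 "env_range", "env_variance", "env_dfa", "env_mfdfa_width",
                 "burst_duration_p95", "burst_size_p95",
                 "phase_burst_duration_p95", "phase_burst_size_p95",
                 "env_corr_cz")
  if ("envelope" %in% families)
    for (b in envelope_bands) for (ft in env_feats) add("envelope", b, ft)
  if ("broadband" %in% families)
    for (ft in c("hjorth_activity", "hjorth_mobility", "hjorth_complexity",
                 "barlow_amplitude", "barlow_frequency",
                 "barlow_spectral_purity", "global_field_strength",
                 "global_frequency", "spatial_complexity"))
      add("broadband", "broadband", ft)
  if ("peaks" %in% families) {
    for (ft in c("center", "width", "corrected_power"))
      add("peaks", "alpha", paste0("alpha_peak_", ft))
    for (ft in c("center", "width", "corrected_power"))
      add("peaks", "alpha", paste0("alpha_peak2_", ft))
    add("peaks", "alpha", "alpha_theta_transition")
    for (ft in c("center", "width", "corrected_power", "uncorrected_power"))
      add("peaks", "beta", paste0("beta_peak_", ft))
    for (ft in c("center", "width", "corrected_power"))
      add("peaks", "beta", paste0("beta_peak2_", ft))
  }
  stab_feats <- c("sd_central_freq", "iqr_central_freq",
                  "sd_max_wavelet_freq", "iqr_max_wavelet_freq",
                  "phase_pos_median", "phase_pos_iqr",
                  "cycles_median", "cycles_iqr")
  if ("stability" %in% families)
    for (b in stability_bands) for (ft in stab_feats)
      add("stability", b, paste0("stab_", ft))
  reg <- do.call(rbind, rows)
  if (anyDuplicated(reg$name)) stop("registry names must be unique")
  reg
}

#' Extract the biomarker battery from one recording
#'
#' Computes every biomarker listed in the registry for every channel,
#' returning a biomarker x channel matrix. Channel-independent biomarkers
#' (Wackermann's three) are replicated across channels. Undefined values
#' (flagged peaks, too few bursts, missing Cz, ...) are stored as `NA`,
#' never silently zero. The extraction is deterministic.
#'
#' @param rec an [eeg_recording()].
#' @param registry a registry data frame from [default_registry()].
#' @param psd_window_length Welch window length in seconds.
#' @return A `biomarker_tensor`: list with `values` (matrix), `registry`,
#'   `subject_id`, `visit`, `group`, `channel_labels`.
#' @export
extract_battery <- function(rec, registry = default_registry(),
                            psd_window_length = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(c("name", "family", "band", "feature") %in% names(registry)))
    stop("registry must have columns name, family, band, feature")
  known <- c("spectral", "ratios", "envelope", "broadband", "peaks",
             "stability")
  if (!all(registry$family %in% known))
    stop("registry references unknown operation family: ",
         paste(setdiff(registry$family, known), collapse = ", "))
  fs <- rec$sampling_rate
  nch <- n_channels(rec)
  bands <- canonical_bands()
  V <- matrix(NA_real_, nrow(registry), nch,
              dimnames = list(registry$name, rec$channel_labels))

  spectra <- lapply(seq_len(nch), function(i)
    welch_psd(rec$data[i, ], fs, window_length = psd_window_length))
  alpha_search <- band_definition("alpha_search", 6, 14)
  beta_search <- bands$beta
  alpha_peaks <- lapply(spectra, fit_spectral_peak, search_band = alpha_search)
  apf <- vapply(alpha_peaks, function(p)
    if (p$present) p$center else NA_real_, numeric(1))

  # lazily cached per-(band, channel) filtered signal / envelope / phase
  cache <- new.env(parent = emptyenv())
  get_band <- function(bname, ch) {
    key <- paste0(bname, ".", ch)
    if (is.null(cache[[key]])) {
      xb <- bandpass_filter(rec$data[ch, ], bands[[bname]], fs)
      ap <- analytic_envelope_phase(xb)
      cache[[key]] <- list(filtered = xb, envelope = ap$envelope,
                           phase = ap$phase)
    }
    cache[[key]]
  }
  cz_corr <- function(bname) {
    key <- paste0("czcorr.", bname)
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressWarnings(
        envelope_correlation_cz(rec, bands[[bname]]))
    cache[[key]]
  }

  band_def_for <- function(bname, ch) {
    if (bname %in% names(bands)) return(bands[[bname]])
    ib <- suppressWarnings(individualized_bands(apf[ch]))
    ib[[bname]]
  }

  for (r in seq_len(nrow(registry))) {
    fam <- registry$family[r]; bnm <- registry$band[r]
    ft <- registry$feature[r]; nm <- registry$name[r]
    if (fam == "spectral") {
      for (ch in seq_len(nch)) {
        bd <- band_def_for(bnm, ch)
        V[nm, ch] <- spectral_band_features(spectra[[ch]], bd)[[ft]]
      }
    } else if (fam == "ratios") {
      pair <- strsplit(bnm, "_", fixed = TRUE)[[1L]]
      for (ch in seq_len(nch))
        V[nm, ch] <- power_ratio(spectra[[ch]], bands[[pair[1L]]],
                                 bands[[pair[2L]]])
    } else if (fam == "envelope") {
      if (ft == "env_corr_cz") {
        V[nm, ] <- cz_corr(bnm)
      } else for (ch in seq_len(nch)) {
        bc <- get_band(bnm, ch)
        V[nm, ch] <- switch(
          ft,
          env_kurtosis = envelope_statistics(bc$envelope)$kurtosis,
          env_skewness = envelope_statistics(bc$envelope)$skewness,
          env_iqr = envelope_statistics(bc$envelope)$iqr,
          env_median = envelope_statistics(bc$envelope)$median,
          env_range = envelope_statistics(bc$envelope)$range,
          env_variance = envelope_statistics(bc$envelope)$variance,
          env_dfa = dfa_exponent(bc$envelope, fs),
          env_mfdfa_width = mfdfa_width(bc$envelope, fs),
          burst_duration_p95 = {
            b <- oscillation_bursts(bc$envelope, fs)
            if (b$defined) b$duration_p95 else NA_real_
          },
          burst_size_p95 = {
            b <- oscillation_bursts(bc$envelope, fs)
            if (b$defined) b$size_p95 else NA_real_
          },
          phase_burst_duration_p95 = {
            b <- phase_bursts(bc$phase, fs)
            if (b$defined) b$duration_p95 else NA_real_
          },
          phase_burst_size_p95 = {
            b <- phase_bursts(bc$phase, fs)
            if (b$defined) b$size_p95 else NA_real_
          },
          stop("unknown envelope feature: ", ft))
      }
    } else if (fam == "broadband") {
      if (ft %in% c("global_field_strength", "global_frequency",
                    "spatial_complexity")) {
        if (is.null(cache[["wack"]]))
          cache[["wack"]] <- wackermann_parameters(rec)
        V[nm, ] <- cache[["wack"]][[ft]]
      } else for (ch in seq_len(nch)) {
        bc <- get_band("broadband", ch)
        V[nm, ch] <- switch(
          ft,
          hjorth_activity = hjorth_parameters(bc$filtered, fs)$activity,
          hjorth_mobility = hjorth_parameters(bc$filtered, fs)$mobility,
          hjorth_complexity = hjorth_parameters(bc$filtered, fs)$complexity,
          barlow_amplitude = barlow_parameters(bc$filtered, fs)$mean_amplitude,
          barlow_frequency = barlow_parameters(bc$filtered, fs)$mean_frequency,
          barlow_spectral_purity =
            barlow_parameters(bc$filtered, fs)$spectral_purity)
      }
    } else if (fam == "peaks") {
      for (ch in seq_len(nch)) {
        if (startsWith(ft, "alpha_peak2_")) {
          p <- alpha_peaks[[ch]]$second_peak
          V[nm, ch] <- if (!is.null(p)) p[[sub("alpha_peak2_", "", ft)]]
                       else NA_real_
        } else if (startsWith(ft, "alpha_peak_")) {
          p <- alpha_peaks[[ch]]
          V[nm, ch] <- if (p$present) p[[sub("alpha_peak_", "", ft)]]
                       else NA_real_
        } else if (ft == "alpha_theta_transition") {
          tr <- alpha_theta_transition(spectra[[ch]], apf[ch])
          V[nm, ch] <- if (tr$defined && !tr$degenerate) tr$frequency
                       else NA_real_
        } else {
          key <- paste0("betapeak.", ch)
          if (is.null(cache[[key]]))
            cache[[key]] <- fit_spectral_peak(spectra[[ch]], beta_search)
          p <- cache[[key]]
          if (startsWith(ft, "beta_peak2_")) {
            sp <- p$second_peak
            V[nm, ch] <- if (!is.null(sp)) sp[[sub("beta_peak2_", "", ft)]]
                         else NA_real_
          } else {
            V[nm, ch] <- if (p$present) p[[sub("beta_peak_", "", ft)]]
                         else NA_real_
          }
        }
      }
    } else if (fam == "stability") {
      key <- paste0("stab.", bnm)
      if (is.null(cache[[key]]))
        cache[[key]] <- lapply(seq_len(nch), function(ch)
          tryCatch(frequency_stability(rec$data[ch, ], fs, bands[[bnm]]),
                   error = function(e) NULL))
      st <- cache[[key]]
      fkey <- sub("^stab_", "", ft)
      V[nm, ] <- vapply(st, function(s)
        if (is.null(s)) NA_real_ else s[[fkey]], numeric(1))
    }
  }
  structure(list(values = V, registry = registry,
                 subject_id = rec$subject_id, visit = rec$visit,
                 group = rec$group, channel_labels = rec$channel_labels),
            class = "biomarker_tensor")
}

#' @export
print.biomarker_tensor <- function(x, ...) {
  cat(sprintf("<biomarker_tensor> %d biomarkers x %d channels (subject %s, visit %d, %s)\n",
              nrow(x$values), ncol(x$values), x$subject_id, x$visit, x$group))
  cat(sprintf("  %d of %d values missing/flagged\n",
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Write a biomarker tensor as TSV (biomarkers x channels)
#' @param tensor a `biomarker_tensor`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tensor <- function(tensor, path) {
  utils::write.table(
    data.frame(biomarker = rownames(tensor$values), tensor$values,
               check.names = FALSE),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
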