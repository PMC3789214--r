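#' Oscillation specification for the synthetic EEG generator
#'
#' Describes one narrowband oscillatory component: where its spectral peak
#' sits, how wide it is, how strong it is relative to the 1/f background,
#' and the temporal structure of its amplitude envelope (burst timescale and
#' long-range temporal correlation target).
#'
#' @param center_frequency peak center in Hz.
#' @param peak_width spectral width (FWHM of the Gaussian peak) in Hz.
#' @param relative_amplitude oscillation RMS relative to the background RMS
#'   inside `center +/- 3 * peak_width`; 0 yields a silent component.
#' @param burst_timescale mean envelope modulation correlation time, seconds.
#' @param envelope_memory_exponent target detrended-fluctuation exponent of
#'   the amplitude envelope; 0.5 = memoryless bursts, > 0.5 persistent.
#' @return An `oscillation_spec`.
#' @export
oscillation_spec <- function(center_frequency, peak_width,
                             relative_amplitude = 1,
                             burst_timescale = 0.3,
                             envelope_memory_exponent = 0.7) {
  stopifnot(center_frequency > 0, peak_width > 0, relative_amplitude >= 0,
            burst_timescale > 0, envelope_memory_exponent > 0)
  structure(list(center_frequency = center_frequency, peak_width = peak_width,
                 relative_amplitude = relative_amplitude,
                 burst_timescale = burst_timescale,
                 envelope_memory_exponent = envelope_memory_exponent),
            class = "oscillation_spec")
}

#' Group specification for a synthetic cohort
#'
#' @param label `"MCI-stable"` or `"AD-converter"`.
#' @param n_subjects number of subjects in the group.
#' @param alpha,beta per-visit [oscillation_spec()]s: either a single spec
#'   (used for both visits) or `list(v1 = , v2 = )`.
#' @param background_exponent chi of the 1/f^chi background, in \[0, 2\].
#' @param theta_alpha_power_ratio ratio of injected theta-oscillation band
#'   power to injected alpha-oscillation band power.
#' @param mixing_coef scalar in \[0, 1): weight of a shared source mixed
#'   into every channel (drives inter-channel envelope correlations); used
#'   to build the default mixing matrix when `inter_channel_mixing` is NULL.
#' @param inter_channel_mixing optional channels x sources mixing matrix;
#'   rows are L2-normalized on use so channel variance is conserved.
#' @param fraction_without_second_visit optional per-group override of the
#'   cohort-level fraction.
#' @return A `group_spec`.
#' @export
group_spec <- function(label, n_subjects, alpha, beta,
                       background_exponent = 1,
                       theta_alpha_power_ratio = 0.4,
                       mixing_coef = 0.35,
                       inter_channel_mixing = NULL,
                       fraction_without_second_visit = NULL) {
  label <- match.arg(label, c("MCI-stable", "AD-converter"))
  stopifnot(n_subjects >= 1,
            background_exponent >= 0, background_exponent <= 2,
            theta_alpha_power_ratio >= 0,
            mixing_coef >= 0, mixing_coef < 1)
  per_visit <- function(s) {
    if (inherits(s, "oscillation_spec")) list(v1 = s, v2 = s)
    else { stopifnot(all(c("v1", "v2") %in% names(s))); s }
  }
  if (!is.null(inter_channel_mixing)) {
    m <- as.matrix(inter_channel_mixing)
    if (!all(is.finite(m)) || any(rowSums(m != 0) == 0))
      stop("mixing matrix rows must be finite with at least one nonzero entry")
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 alpha = per_visit(alpha), beta = per_visit(beta),
                 background_exponent = background_exponent,
                 theta_alpha_power_ratio = theta_alpha_power_ratio,
                 mixing_coef = mixing_coef,
                 inter_channel_mixing = inter_channel_mixing,
                 fraction_without_second_visit = fraction_without_second_visit),
            class = "group_spec")
}

#' Cohort specification
#'
#' @param groups list of [group_spec()]s.
#' @param n_channels number of channels.
#' @param channel_labels unique 10-20 electrode names.
#' @param sampling_rate Hz; must exceed twice the 45 Hz top band edge.
#' @param duration recording length in seconds (>= 60).
#' @param fraction_without_second_visit fraction of subjects per group whose
#'   second visit is missing (held-out subjects), unless overridden per group.
#' @param master_seed integer seed from which all per-subject, per-visit
#'   seeds are derived.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_channels = length(channel_labels),
                        channel_labels = montage_1020(n_channels),
                        sampling_rate = 500, duration = 300,
                        fraction_without_second_visit = 0,
                        master_seed = 1L) {
  stopifnot(length(groups) >= 1, sampling_rate > 90, duration >= 60,
            fraction_without_second_visit >= 0,
            fraction_without_second_visit <= 1)
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (length(channel_labels) != n_channels)
    stop("channel_labels length must equal n_channels")
  structure(list(groups = groups, n_channels = as.integer(n_channels),
                 channel_labels = channel_labels,
                 sampling_rate = sampling_rate, duration = duration,
                 fraction_without_second_visit = fraction_without_second_visit,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Standard 10-20 montage labels
#'
#' The 21-channel clinical montage (A1/A2 ear electrodes excluded); ask for
#' fewer channels and a prefix is returned.
#'
#' @param n number of channels (<= 21).
#' @return character vector of labels.
#' @export
montage_1020 <- function(n = 21L) {
  labs <- c("Fp2", "Fp1", "FT9", "FT10", "F8", "F7", "F4", "F3", "T4", "T3",
            "C4", "C3", "T6", "T5", "P4", "P3", "O2", "O1", "Fz", "Cz", "Pz")
  if (n > length(labs)) stop("montage supports at most ", length(labs), " channels")
  # keep the midline electrodes (incl. Cz) present even in small montages
  if (n >= 4 && n < length(labs))
    c(utils::head(setdiff(labs, c("Fz", "Cz", "Pz")), n - 3L), "Fz", "Cz", "Pz")
  else labs[seq_len(n)]
}

#' Derive a deterministic sub-seed from a master seed
#'
#' The cohort generator's stated counter scheme: a fixed linear mix of the
#' master seed with group/subject/visit/component counters, reduced modulo
#' 2^31 - 1 (never 0), so every recording is a pure function of the master
#' seed and its indices.
#'
#' @param master master seed (integer).
#' @param group_idx,subject_idx,visit,component non-negative counters.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, group_idx = 0L, subject_idx = 0L,
                        visit = 0L, component = 0L) {
  s <- (as.double(master) * 1000003 + group_idx * 290011 +
        subject_idx * 13007 + visit * 1009 + component * 97) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

# Gaussian noise with spectral amplitude shape amp_fun(f); unit variance
shaped_noise <- function(n, sampling_rate, amp_fun) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate - f)
  a <- amp_fun(f)
  a[1L] <- 0                       # remove DC
  x <- Re(stats::fft(W * a, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a 1/f^chi background signal
#'
#' Spectrally shaped Gaussian noise whose power spectrum is log-log linear
#' with slope `-exponent` across the analysis range; zero mean, unit
#' variance.
#'
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param exponent chi in \[0, 2\].
#' @param seed integer seed.
#' @return numeric signal of `duration * sampling_rate` samples.
#' @export
generate_background <- function(duration, sampling_rate, exponent, seed) {
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be positive")
  if (exponent < 0 || exponent > 2) stop("exponent must lie in [0, 2]")
  n <- round(duration * sampling_rate)
  if (n < 2^12) stop("need at least 2^12 samples")
  set.seed(seed)
  f_floor <- 0.5   # flatten below 0.5 Hz to keep variance finite
  shaped_noise(n, sampling_rate,
               function(f) pmax(f, f_floor)^(-exponent / 2))
}

#' Generate a bursty narrowband oscillation
#'
#' Narrowband-filtered Gaussian noise (Gaussian spectral peak of FWHM
#' `peak_width` at `center_frequency`) multiplied by a positive, log-normal
#' modulator whose log has a power-law spectrum, giving a controllable
#' envelope correlation time (`burst_timescale`) and long-range temporal
#' correlation (`envelope_memory_exponent`). Output RMS equals
#' `relative_amplitude * reference_rms`.
#'
#' @param spec an [oscillation_spec()].
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param seed integer seed.
#' @param reference_rms RMS scale the relative amplitude refers to
#'   (background in-band RMS when embedded in a recording; 1 standalone).
#' @return numeric signal.
#' @export
generate_oscillation <- function(spec, duration, sampling_rate, seed,
                                 reference_rms = 1) {
  stopifnot(inherits(spec, "oscillation_spec"))
  nyq <- sampling_rate / 2
  if (spec$center_frequency + 3 * spec$peak_width >= nyq)
    stop("center_frequency + 3 * peak_width must stay below Nyquist")
  n <- round(duration * sampling_rate)
  if (spec$relative_amplitude == 0) return(numeric(n))
  set.seed(seed)
  sig_f <- spec$peak_width / (2 * sqrt(2 * log(2)))   # FWHM -> Gaussian sigma
  carrier <- shaped_noise(n, sampling_rate, function(f)
    exp(-(f - spec$center_frequency)^2 / (4 * sig_f^2)))
  # log-modulator: power-law spectrum f^(-beta/2) in amplitude, rolled off
  # above the burst cutoff 1/(2*pi*timescale). The measured envelope DFA
  # exponent of the modulated carrier responds affinely to the nominal
  # exponent (the carrier's short-memory envelope dilutes the modulator's
  # long-range correlations), so the nominal exponent is pre-compensated by
  # the inverse affine map, calibrated once by simulation at the default
  # burst timescale; beta = 2*alpha - 1 then maps the DFA target to the
  # spectral exponent.
  alpha_nom <- (spec$envelope_memory_exponent - 0.2315) / 0.655
  beta <- min(max(2 * alpha_nom - 1, -0.5), 2.5)
  fc <- 1 / (2 * pi * spec$burst_timescale)
  f_lo <- max(1 / duration, 1 / 120)   # flatten below ~2 min periods
  g <- shaped_noise(n, sampling_rate, function(f) {
    fb <- pmax(f, f_lo)
    a <- fb^(-beta / 2)
    ifelse(f > fc, a * (fc / f)^2, a)
  })
  x <- carrier * exp(0.6 * g)
  x <- x - mean(x)
  x * (spec$relative_amplitude * reference_rms) / sqrt(mean(x^2))
}

# expected fraction of unit-variance 1/f^chi background power in [lo, hi]
background_band_fraction <- function(n, sampling_rate, exponent,
                                     lo, hi, f_floor = 0.5) {
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate - f)
  p <- pmax(f, f_floor)^(-exponent)
  p[1L] <- 0
  sum(p[f >= lo & f <= hi]) / sum(p)
}

#' Generate one synthetic EEG recording
#'
#' Builds `n_channels` independent composite sources (1/f background plus
#' theta, alpha and beta oscillations per the group's per-visit specs),
#' mixes them through the group's mixing matrix (default:
#' `(1 - m) I + m * shared-source`, rows L2-normalized), and adds white
#' sensor noise at 20 dB SNR per channel.
#'
#' @param group a [group_spec()].
#' @param cohort a [cohort_spec()].
#' @param subject_id subject identifier string.
#' @param visit 1 or 2.
#' @param seed integer seed.
#' @return an [eeg_recording()].
#' @export
generate_recording <- function(group, cohort, subject_id, visit, seed) {
  nch <- cohort$n_channels
  n <- round(cohort$duration * cohort$sampling_rate)
  fs <- cohort$sampling_rate
  vkey <- if (visit == 1L) "v1" else "v2"
  alpha <- group$alpha[[vkey]]
  beta <- group$beta[[vkey]]
  theta <- oscillation_spec(
    center_frequency = 6, peak_width = 2,
    relative_amplitude = sqrt(group$theta_alpha_power_ratio),
    burst_timescale = alpha$burst_timescale,
    envelope_memory_exponent = alpha$envelope_memory_exponent)

  W <- group$inter_channel_mixing
  if (is.null(W)) {
    m <- group$mixing_coef
    W <- diag(1 - m, nch, nch + 1L)
    W[, nch + 1L] <- m
  }
  if (ncol(W) < nch) stop("mixing matrix needs at least n_channels sources")
  if (nrow(W) != nch)
    stop("mixing matrix rows must match the number of channels")
  W <- W / sqrt(rowSums(W^2))            # conserve channel variance
  n_src <- ncol(W)

  inband_rms <- function(spec) sqrt(background_band_fraction(
    n, fs, group$background_exponent,
    spec$center_frequency - 3 * spec$peak_width,
    spec$center_frequency + 3 * spec$peak_width))

  make_source <- function(k) {
    bg <- generate_background(cohort$duration, fs, group$background_exponent,
                              derive_seed(seed, component = 10L + k))
    osc <- function(spec, comp) {
      if (spec$relative_amplitude == 0) return(0)
      generate_oscillation(spec, cohort$duration, fs,
                           derive_seed(seed, component = comp * 1000L + k),
                           reference_rms = inband_rms(spec))
    }
    # theta amplitude: sqrt(ratio) x the alpha oscillation's injected RMS
    th <- theta
    th$relative_amplitude <- sqrt(group$theta_alpha_power_ratio) *
      alpha$relative_amplitude * inband_rms(alpha) /
      max(inband_rms(theta), .Machine$double.eps)
    bg + osc(alpha, 2L) + osc(beta, 3L) + osc(th, 4L)
  }
  S <- vapply(seq_len(n_src), make_source, numeric(n))   # n x n_src
  X <- tcrossprod(W, S)                                  # nch x n
  set.seed(derive_seed(seed, component = 5L))
  noise_sd <- sqrt(rowMeans(X^2) / 100)                  # 20 dB SNR
  X <- X + matrix(stats::rnorm(length(X)), nch) * noise_sd
  eeg_recording(X, fs, cohort$channel_labels, subject_id = subject_id,
                visit = visit, group = group$label)
}

#' Generate a full synthetic cohort
#'
#' Every subject gets a visit-1 recording; per group, the last
#' `round(fraction_without_second_visit * n_subjects)` subjects lack the
#' second visit (these are the held-out prediction subjects). All seeds
#' derive deterministically from `master_seed`, so the cohort is a pure
#' function of its [cohort_spec()].
#'
#' @param cohort a [cohort_spec()].
#' @return list with `recordings` (list of [eeg_recording()]) and
#'   `subjects` (data.frame: subject_id, group, has_visit2).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  recordings <- list()
  subjects <- NULL
  for (gi in seq_along(cohort$groups)) {
    g <- cohort$groups[[gi]]
    frac <- if (!is.null(g$fraction_without_second_visit))
      g$fraction_without_second_visit else cohort$fraction_without_second_visit
    n_missing <- round(frac * g$n_subjects)
    for (si in seq_len(g$n_subjects)) {
      sid <- sprintf("%s-%03d", if (g$label == "MCI-stable") "MCI" else "AD", si)
      has_v2 <- si <= g$n_subjects - n_missing
      for (v in if (has_v2) c(1L, 2L) else 1L) {
        seed <- derive_seed(cohort$master_seed, gi, si, v)
        recordings[[paste0(sid, "-v", v)]] <-
          generate_recording(g, cohort, sid, v, seed)
      }
      subjects <- rbind(subjects, data.frame(
        subject_id = sid, group = g$label, has_visit2 = has_v2,
        stringsAsFactors = FALSE))
    }
  }
  list(recordings = recordings, subjects = subjects)
}

#' Default synthetic cohort mirroring the clinical study structure
#'
#' 39 MCI-stable and 25 AD-converter subjects; the second visit is available
#' for 17 subjects in each group (22 and 8 held out, respectively). Group
#' contrasts: the AD-converter group has a higher and wider beta peak
#' (centers 19.6/19.3 Hz vs 17.6/16.9 Hz across visits), higher theta/alpha
#' power ratio, lower alpha relative amplitude and weaker inter-channel
#' mixing (lower envelope correlations with Cz).
#'
#' @param n_channels,sampling_rate,duration,master_seed see [cohort_spec()].
#' @param null_effects if TRUE, both groups share the MCI-stable parameters
#'   (a null cohort for calibration studies).
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n_channels = 21L, sampling_rate = 500,
                                duration = 300, master_seed = 1L,
                                null_effects = FALSE) {
  osc <- function(center, width, amp)
    oscillation_spec(center, width, amp,
                     burst_timescale = 0.3, envelope_memory_exponent = 0.7)
  mci <- group_spec(
    "MCI-stable", 39,
    alpha = osc(10, 1.5, 3.0),
    beta = list(v1 = osc(17.6, 2.0, 1.6), v2 = osc(16.9, 2.0, 1.6)),
    background_exponent = 1, theta_alpha_power_ratio = 0.35,
    mixing_coef = 0.45, fraction_without_second_visit = 22 / 39)
  ad <- if (null_effects) {
    g <- mci; g$label <- "AD-converter"; g$n_subjects <- 25L
    g$fraction_without_second_visit <- 8 / 25
    g
  } else group_spec(
    "AD-converter", 25,
    alpha = osc(10, 1.5, 2.5),
    beta = list(v1 = osc(19.6, 2.6, 1.6), v2 = osc(19.3, 2.6, 1.6)),
    background_exponent = 1, theta_alpha_power_ratio = 0.55,
    mixing_coef = 0.25, fraction_without_second_visit = 8 / 25)
  cohort_spec(list(mci, ad), n_channels = n_channels,
              sampling_rate = sampling_rate, duration = duration,
              master_seed = master_seed)
}

#' Write a cohort subject table as TSV
#' @param cohort_result output of [generate_cohort()].
#' @param dir output directory; recordings are written alongside.
#' @return path of the subject table, invisibly.
#' @export
write_cohort <- function(cohort_result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort_result$subjects
  tab$visit1_file <- paste0(tab$subject_id, "-v1.eegdx")
  tab$visit2_file <- ifelse(tab$has_visit2,
                            paste0(tab$subject_id, "-v2.eegdx"), "")
  for (nm in names(cohort_result$recordings))
    write_recording(cohort_result$recordings[[nm]],
                    file.path(dir, paste0(nm, ".eegdx")))
  path <- file.path(dir, "subjects.tsv")
  utils::write.table(tab[, c("subject_id", "group", "visit1_file", "visit2_file")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
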