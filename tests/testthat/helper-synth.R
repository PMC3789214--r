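# shared fixtures: everything is generated in code at test time

tone <- function(freq, duration = 10, fs = 500, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * seq_len(duration * fs) / fs + phase)
}

# tiny multichannel recording of independent white noise
noise_recording <- function(n_ch = 3, duration = 20, fs = 250, seed = 1,
                            labels = c("C3", "Cz", "C4", "Pz", "Fz")[seq_len(n_ch)]) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * duration * fs), n_ch), fs, labels)
}

# independent brute-force oracle for supra-threshold run statistics
brute_force_bursts <- function(env, fs, thr = median(env)) {
  dur <- c(); siz <- c()
  run <- 0; area <- 0
  for (v in env) {
    if (v > thr) { run <- run + 1; area <- area + (v - thr) }
    else if (run > 0) { dur <- c(dur, run); siz <- c(siz, area); run <- 0; area <- 0 }
  }
  if (run > 0) { dur <- c(dur, run); siz <- c(siz, area) }
  list(duration_p95 = unname(quantile(dur / fs, 0.95)),
       size_p95 = unname(quantile(siz / fs, 0.95)), n = length(dur))
}

# independent brute-force oracle for stable periods between phase slips
brute_force_phase_bursts <- function(phase, fs) {
  d <- diff(phase)
  slips <- integer(0)
  in_slip <- FALSE
  for (i in seq_along(d)) {
    if (d[i] < 0 && !in_slip) { slips <- c(slips, i); in_slip <- TRUE }
    if (d[i] >= 0) in_slip <- FALSE
  }
  if (!length(slips)) return(NULL)
  bounds <- c(1L, slips, length(phase))
  list(duration_p95 = unname(quantile(diff(bounds) / fs, 0.95)),
       n = length(bounds) - 1L)
}

# a tiny fast cohort for end-to-end tests: few channels, 60 s, 128 Hz
fast_cohort_spec <- function(n_per_group = 10, frac_missing = 0.4,
                             master_seed = 1, null_effects = FALSE,
                             duration = 60) {
  spec <- default_cohort_spec(n_channels = 4, sampling_rate = 128,
                              duration = duration, master_seed = master_seed,
                              null_effects = null_effects)
  for (i in seq_along(spec$groups)) {
    spec$groups[[i]]$n_subjects <- as.integer(n_per_group)
    spec$groups[[i]]$fraction_without_second_visit <- frac_missing
  }
  spec
}

fast_registry <- function()
  default_registry(families = c("spectral", "ratios"))
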