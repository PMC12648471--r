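# Shared fixtures, all built in code at test time.

ZERO_BANDS <- c(theta = 0, alpha = 0, beta = 0, gamma_low = 0, gamma_high = 0)

# generator config producing clean dose-response data: evoked template plus
# background noise only (band oscillations and ISI component off), so the
# measured RMS follows the configured log-linear law
clean_dose_cfg <- function(seed, n_trials = 15L,
                           energy_grid = c(0.25, 0.5, 1, 2, 3, 4),
                           isi_grid = c(5, 50), ...) {
  generator_config(seed = seed, n_trials = n_trials,
                   energy_grid_mJ = energy_grid, isi_grid_ms = isi_grid,
                   band_gains = ZERO_BANDS, isi_gain_uV = 0, ...)
}

# tiny trial set for I/O and plumbing tests
tiny_trialset <- function(seed = 1, n_trials = 2L, rate = 200) {
  cfg <- generator_config(seed = seed, n_trials = n_trials,
                          energy_grid_mJ = c(1, 3), isi_grid_ms = 5,
                          rate_hz = rate, electrodes = c("e1", "e2"),
                          n_animals = 1L)
  gen_spike_trains(cfg, gen_lfp_trialset(cfg))
}

# unit sine at the analysis rate
sine_series <- function(f_hz, n = 1526, rate = 1526, amp = 1, phase = 0) {
  amp * sin(2 * pi * f_hz * (0:(n - 1)) / rate + phase)
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  s / choose(n, 2)
}
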