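# Synthetic trial-set generation with known ground truth.
#
# The generator states a world matching the study design it emulates: 5-pulse
# laser trains, energies 0-4.5 mJ, ISIs 0.2-100 ms, 1 s trials with a 200 ms
# prestimulus baseline, 30-60 trials per energy condition, and LFP N1-P2 RMS
# following a log-linear dose-response law. All generators are pure functions
# of (config, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic trial-set generator
#'
#' Dose-response defaults are the population-level estimates the generator is
#' meant to emulate: `ln(RMS) = beta0 + beta_E ln(E) + beta_ISI ln(ISI) +
#' beta_ExISI ln(E) ln(ISI) + N(0, sigma)` with `beta_E = 0.087`,
#' `beta_ISI = 0.065`, `beta_ExISI = -0.0038` and residual SD `sigma = 0.51`.
#'
#' @param seed integer seed; the generator is a pure function of (cfg, seed).
#' @param n_trials trials per (energy, ISI) condition (study range 30-60).
#' @param energy_grid_mJ energies per pulse, mJ.
#' @param isi_grid_ms interpulse intervals, ms.
#' @param n_pulses,pulse_width_ms,prestim_s,trial_length_s trial geometry.
#' @param rate_hz sampling rate of generated LFPs (analysis rate).
#' @param beta0,beta_E,beta_ISI,beta_ExISI,sigma log-linear dose-response law
#'   for N1-P2 RMS (uV scale via `exp(beta0)`).
#' @param n1_latency_s,p2_latency_s evoked template lobe peak latencies after
#'   stimulus onset (defaults 25 and 70 ms keep the complex inside the 150 ms
#'   search window).
#' @param band_gains named oscillation amplitude gains (uV per sqrt(mJ)) for
#'   theta/alpha/beta/gamma_low/gamma_high; band power grows log-linearly in E
#'   with unit slope (power proportional to E).
#' @param isi_gain_uV ISI-locked sinusoid amplitude per mJ at frequency
#'   `1000/(pulse_width_ms + isi_ms)` Hz, present during the train.
#' @param noise_amp_uV standard deviation of the 1/f background noise.
#' @param noise_exponent spectral exponent of the background (1 = pink).
#' @param spike_rate_hz baseline (spontaneous) firing rate.
#' @param spike_gain_hz_per_mJ evoked rate increase per mJ in the onset window.
#' @param kappa von Mises concentration of spike phase locking (0 = none).
#' @param lock_band LFP band whose phase the spikes lock to.
#' @param electrodes electrode ids (one recording site each); at least 3 are
#'   needed downstream for hierarchical slopes.
#' @param n_animals number of synthetic subjects (electrodes are assigned
#'   round-robin).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_trials = 30L,
                             energy_grid_mJ = c(0.5, 1, 2, 3, 4),
                             isi_grid_ms = c(5, 50),
                             n_pulses = 5L,
                             pulse_width_ms = 10,
                             prestim_s = 0.2,
                             trial_length_s = 1,
                             rate_hz = 1526,
                             beta0 = 3,
                             beta_E = 0.087,
                             beta_ISI = 0.065,
                             beta_ExISI = -0.0038,
                             sigma = 0.51,
                             n1_latency_s = 0.025,
                             p2_latency_s = 0.070,
                             band_gains = c(theta = 0.4, alpha = 0.6,
                                            beta = 1.5, gamma_low = 2,
                                            gamma_high = 1.2),
                             isi_gain_uV = 4,
                             noise_amp_uV = 3,
                             noise_exponent = 1,
                             spike_rate_hz = 5,
                             spike_gain_hz_per_mJ = 15,
                             kappa = 0,
                             lock_band = "gamma_low",
                             electrodes = c("e1", "e2", "e3", "e4"),
                             n_animals = 2L) {
  stopifnot(n_trials >= 1, sigma >= 0, kappa >= 0, noise_amp_uV >= 0,
            spike_rate_hz >= 0, spike_gain_hz_per_mJ >= 0,
            all(energy_grid_mJ >= 0), all(energy_grid_mJ <= 4.5),
            all(isi_grid_ms >= 0.2), all(isi_grid_ms <= 100))
  structure(as.list(environment()), class = "generator_config")
}

one_over_f_noise <- function(n, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))           # avoid DC blowup; DC zeroed below
  f <- pmin(f, n - f + 1)             # fold to two-sided frequency magnitude
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x * sd_target / stats::sd(x)
}

band_edges_hz <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       gamma_low = c(30, 80), gamma_high = c(80, 200))
}

evoked_template <- function(n_samples, rate, onset_i, n1_lat, p2_lat) {
  # difference of two gamma-shaped lobes: negative N1 then positive P2
  t <- (seq_len(n_samples) - onset_i) / rate   # s after stimulus onset
  t[t < 0] <- NA
  lobe <- function(peak_s, width_s) {
    k <- (peak_s / width_s)^2            # gamma shape with mode at peak_s
    th <- width_s^2 / peak_s
    y <- ifelse(is.na(t), 0, stats::dgamma(t, shape = k + 1, scale = th))
    y / max(y)
  }
  tmpl <- -lobe(n1_lat, 0.010) + 0.8 * lobe(p2_lat, 0.022)
  p2_i <- which.max(ifelse(is.na(t) | t < n1_lat, -Inf, tmpl))
  list(shape = tmpl, p2_sample = p2_i)
}

#' Generate a synthetic LFP trial set
#'
#' Each trial is the sum of (a) an N1-P2 evoked template whose RMS from
#' stimulus onset through the P2 sample follows the configured log-linear
#' dose-response law (amplitude 0 at E = 0), (b) stimulus-gated band-limited
#' oscillations with power growing log-linearly in energy, (c) an ISI-rate
#' sinusoid at `1/(pulse_width + isi)` during the pulse train, and (d) 1/f
#' background noise. Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param electrodes character vector of electrode ids (defaults to the
#'   config's); electrodes are assigned round-robin to animals.
#' @param n_animals number of synthetic subjects (defaults to the config's).
#' @return a [trial_set()] whose manifest records the generator settings.
#' @export
gen_lfp_trialset <- function(cfg, electrodes = cfg$electrodes,
                             n_animals = cfg$n_animals) {
  stopifnot(inherits(cfg, "generator_config"))
  rate <- cfg$rate_hz
  n_samp <- round(cfg$trial_length_s * rate)
  animals <- paste0("a", rep_len(seq_len(n_animals), length(electrodes)))
  bands <- band_edges_hz()
  gains <- cfg$band_gains
  with_seed(cfg$seed, {
    trials <- list()
    for (ei in seq_along(electrodes)) {
      # mild per-electrode gain heterogeneity (hierarchical structure)
      el_fac <- exp(stats::rnorm(1, 0, 0.05))
      trial_no <- 0L
      for (E in cfg$energy_grid_mJ) for (isi in cfg$isi_grid_ms) {
        stim <- stimulus_train(E, isi, cfg$n_pulses, cfg$pulse_width_ms,
                               cfg$prestim_s, cfg$trial_length_s)
        win <- compute_windows(stim)
        onset_i <- window_samples(win$onset, rate, n_samp)
        train_i <- window_samples(
          c(stim$prestim_s, stim$prestim_s + stim$train_duration_s),
          rate, n_samp)
        tmpl <- evoked_template(n_samp, rate, onset_i[1], cfg$n1_latency_s,
                                cfg$p2_latency_s)
        rms_span <- onset_i[1]:tmpl$p2_sample
        unit_rms <- sqrt(mean(tmpl$shape[rms_span]^2))
        t_s <- (seq_len(n_samp) - 1) / rate
        for (k in seq_len(cfg$n_trials)) {
          trial_no <- trial_no + 1L
          x <- numeric(n_samp)
          if (E > 0) {
            target <- el_fac * exp(cfg$beta0 + cfg$beta_E * log(E) +
                                     cfg$beta_ISI * log(isi) +
                                     cfg$beta_ExISI * log(E) * log(isi) +
                                     stats::rnorm(1, 0, cfg$sigma))
            x <- x + tmpl$shape * (target / unit_rms)
            for (b in names(bands)) {
              amp <- gains[[b]] * sqrt(E)
              if (amp > 0) {
                f0 <- stats::runif(1, bands[[b]][1], bands[[b]][2])
                ph <- stats::runif(1, 0, 2 * pi)
                osc <- numeric(n_samp)
                osc[onset_i] <- amp * sin(2 * pi * f0 * t_s[onset_i] + ph)
                x <- x + osc
              }
            }
            f_train <- 1000 / (cfg$pulse_width_ms + isi)
            if (f_train < rate / 2 && cfg$isi_gain_uV > 0) {
              # stimulus-locked (evoked) component: phase tied to train onset
              x[train_i] <- x[train_i] + cfg$isi_gain_uV * E *
                sin(2 * pi * f_train * (t_s[train_i] - stim$prestim_s))
            }
          }
          x <- x + one_over_f_noise(n_samp, cfg$noise_exponent,
                                    cfg$noise_amp_uV)
          trials[[length(trials) + 1L]] <- trial_recording(
            lfp = x, rate = rate, spikes = list(), stimulus = stim,
            animal = animals[ei], electrode = electrodes[ei], trial = trial_no)
        }
      }
    }
    trial_set(trials, manifest = list(seed = cfg$seed, generator = "gen_lfp_trialset"))
  })
}

#' Attach synthetic spike trains to a trial set
#'
#' Spikes are an inhomogeneous Bernoulli process on the LFP sample grid with
#' rate `lambda0 + gain * E` inside the onset window (`lambda0` elsewhere),
#' modulated by a von Mises factor `exp(kappa * cos(phase))/I0(kappa)` on the
#' instantaneous phase of the configured LFP band; `kappa = 0` gives spiking
#' independent of the LFP.
#'
#' @param cfg a [generator_config()].
#' @param ts a [trial_set()] with LFPs (from [gen_lfp_trialset()]).
#' @param unit name for the generated unit.
#' @return the trial set with spikes filled in; deterministic given
#'   `cfg$seed + 1`.
#' @export
gen_spike_trains <- function(cfg, ts, unit = "u1") {
  stopifnot(inherits(cfg, "generator_config"), inherits(ts, "trial_set"))
  band <- band_edges_hz()[[cfg$lock_band]]
  i0k <- besselI(cfg$kappa, 0)
  with_seed(cfg$seed + 1L, {
    for (i in seq_along(ts$trials)) {
      tr <- ts$trials[[i]]
      n <- length(tr$lfp)
      dt <- 1 / tr$rate
      win <- compute_windows(tr$stimulus)
      onset_i <- window_samples(win$onset, tr$rate, n)
      lam <- rep(cfg$spike_rate_hz, n)
      lam[onset_i] <- cfg$spike_rate_hz +
        cfg$spike_gain_hz_per_mJ * tr$stimulus$energy_mJ
      if (cfg$kappa > 0) {
        ph <- band_phase(tr$lfp, tr$rate, band)
        lam <- lam * exp(cfg$kappa * cos(ph)) / i0k
      }
      p <- pmin(lam * dt, 1)
      hit <- which(stats::runif(n) < p)
      ts$trials[[i]]$spikes <- stats::setNames(
        list((hit - 1) / tr$rate), unit)
    }
    ts
  })
}

band_phase <- function(x, rate, band) {
  # Gaussian FFT band-pass then analytic-signal phase
  n <- length(x)
  f <- (0:(n - 1)) / n * rate
  f[f > rate / 2] <- f[f > rate / 2] - rate
  fc <- mean(band); bw <- diff(band) / 2
  g <- exp(-((abs(f) - fc)^2) / (2 * (bw / 2)^2))
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
  Arg(hilbert_analytic(y))
}

#' Generate calibration time series for the dynamics tests
#'
#' @param kind `"sine"` (unit amplitude), `"logistic"` (x_{k+1} = r x_k (1 -
#'   x_k), 1000 burn-in samples discarded), `"ar1"` (Gaussian AR(1)), or
#'   `"constant"`.
#' @param n number of samples (>= 100).
#' @param params named list: sine `f_hz` (default 5) and `rate_hz` (1526);
#'   logistic `r` (4) and `x0` (0.2); ar1 `phi` (0.5) and `sd` (1); constant
#'   `level` (0).
#' @param seed RNG seed (used by `ar1` only).
#' @return numeric vector of length `n`.
#' @export
gen_dynamics_series <- function(kind = c("sine", "logistic", "ar1", "constant"),
                                n, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 100)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  switch(kind,
    sine = sin(2 * pi * p("f_hz", 5) * (0:(n - 1)) / p("rate_hz", 1526)),
    logistic = {
      r <- p("r", 4); x <- p("x0", 0.2)
      if (x <= 0 || x >= 1) stop("logistic map requires x0 in (0, 1)")
      for (i in seq_len(1000)) x <- r * x * (1 - x)
      out <- numeric(n)
      for (i in seq_len(n)) { x <- r * x * (1 - x); out[i] <- x }
      out
    },
    ar1 = with_seed(seed, {
      phi <- p("phi", 0.5); s <- p("sd", 1)
      e <- stats::rnorm(n + 100, 0, s)
      x <- numeric(n + 100)
      for (i in 2:(n + 100)) x[i] <- phi * x[i - 1] + e[i]
      x[(length(x) - n + 1):length(x)]
    }),
    constant = rep(p("level", 0), n)
  )
}

#' Generate synthetic chaos-versus-MI regime features
#'
#' Emulates the two-regime structure of chaos/information scatter: a cluster of
#' low-information responses (MI < 0.4 bits) that are uniformly highly chaotic
#' (K near 1), and a cluster of informative responses (MI > 0.4 bits) whose K
#' statistic is bimodal (mixed low- and high-chaos responses).
#'
#' @param n_points number of (MI, K) pairs (>= 50).
#' @param seed RNG seed.
#' @param prop_low proportion of points in the low-MI regime.
#' @param separation multiplier on the MI gap between regimes (1 = default
#'   world; values near 0 collapse the two regimes into one).
#' @return data.frame with columns `mi` (bits), `k`, and ground-truth `label`
#'   (1 = low-MI chaotic regime, 2 = informative mixed regime).
#' @export
gen_regime_features <- function(n_points = 300L, seed = 7L, prop_low = 0.4,
                                separation = 1) {
  stopifnot(n_points >= 50)
  with_seed(seed, {
    n1 <- round(n_points * prop_low)
    n2 <- n_points - n1
    mi1 <- pmax(0.01, stats::rnorm(n1, 0.15, 0.08))
    mi1 <- pmin(mi1, 0.38)
    k1 <- pmin(pmax(stats::rnorm(n1, 0.9, 0.06), 0), 1)
    mi2 <- 0.4 + separation * stats::runif(n2, 0.1, 1.1)
    # bimodal but overlapping K modes: informative responses mix lower- and
    # higher-chaos dynamics without forming two separable sub-clusters
    hi <- stats::runif(n2) < 0.5
    k2 <- ifelse(hi, stats::rnorm(n2, 0.62, 0.13), stats::rnorm(n2, 0.32, 0.13))
    k2 <- pmin(pmax(k2, 0), 1)
    data.frame(mi = c(mi1, mi2), k = c(k1, k2),
               label = rep(1:2, c(n1, n2)))
  })
}
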