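test_that("generators are pure functions of (cfg, seed)", {
  cfg <- generator_config(seed = 5, n_trials = 3, energy_grid_mJ = c(1, 3),
                          isi_grid_ms = 5, electrodes = "e1", n_animals = 1)
  ts1 <- gen_spike_trains(cfg, gen_lfp_trialset(cfg))
  ts2 <- gen_spike_trains(cfg, gen_lfp_trialset(cfg))
  for (i in seq_along(ts1$trials)) {
    expect_identical(ts1$trials[[i]]$lfp, ts2$trials[[i]]$lfp)
    expect_identical(ts1$trials[[i]]$spikes, ts2$trials[[i]]$spikes)
  }
})

test_that("sigma = 0 with a single condition gives identical trials", {
  cfg <- generator_config(seed = 2, n_trials = 4, energy_grid_mJ = 2,
                          isi_grid_ms = 5, sigma = 0, noise_amp_uV = 0,
                          band_gains = ZERO_BANDS, isi_gain_uV = 0,
                          electrodes = "e1", n_animals = 1)
  ts <- gen_lfp_trialset(cfg)
  for (i in 2:4) expect_identical(ts$trials[[i]]$lfp, ts$trials[[1]]$lfp)
})

test_that("E = 0 conditions contain noise only", {
  cfg <- generator_config(seed = 3, n_trials = 2, energy_grid_mJ = c(0, 2),
                          isi_grid_ms = 5, noise_amp_uV = 0,
                          electrodes = "e1", n_animals = 1)
  ts <- gen_lfp_trialset(cfg)
  tt <- trial_table(ts)
  zero_rows <- tt$row[tt$energy_mJ == 0]
  for (i in zero_rows) expect_identical(unique(ts$trials[[i]]$lfp), 0)
  expect_gt(max(abs(ts$trials[[tt$row[tt$energy_mJ == 2][1]]]$lfp)), 0)
})

test_that("noiseless dose-response obeys its log-linear law exactly", {
  cfg <- clean_dose_cfg(seed = 4, n_trials = 2,
                        energy_grid = c(0.5, 1, 2, 4), isi_grid = c(5, 50),
                        sigma = 0, noise_amp_uV = 0)
  cfg$electrodes <- "e1"; cfg$n_animals <- 1L
  ts <- gen_lfp_trialset(cfg)
  tt <- trial_table(ts)
  rms <- vapply(seq_len(nrow(tt)), function(i) {
    tr <- ts$trials[[tt$row[i]]]
    w <- compute_windows(tr$stimulus)
    si <- window_samples(w$n1p2_search, tr$rate, length(tr$lfp))
    p2 <- si[which.max(tr$lfp[si])]
    on <- window_samples(w$onset, tr$rate, length(tr$lfp))[1]
    sqrt(mean(tr$lfp[on:p2]^2))
  }, numeric(1))
  fit <- stats::lm(log(rms) ~ log(tt$energy_mJ) * log(tt$isi_ms))
  cf <- coef(fit)
  # electrode gain factor folds into the intercept; slopes recovered to
  # >= 6 significant digits (float32 LFP storage limits further precision)
  expect_equal(unname(cf[2]), 0.087, tolerance = 1e-6)
  expect_equal(unname(cf[3]), 0.065, tolerance = 1e-6)
  expect_equal(unname(cf[4]), -0.0038, tolerance = 1e-6)
})

test_that("gen_dynamics_series produces the stated dynamics", {
  x <- gen_dynamics_series("logistic", 5000)
  expect_true(all(x > 0 & x < 1))
  # aperiodicity: no lag < 50 with near-perfect autocorrelation
  ac <- stats::acf(x, lag.max = 50, plot = FALSE)$acf[-1]
  expect_lt(max(abs(ac)), 0.9)
  expect_error(gen_dynamics_series("logistic", 500, params = list(x0 = 1.2)),
               "x0")

  s <- gen_dynamics_series("sine", 5000, params = list(f_hz = 5, rate_hz = 1526))
  expect_equal(max(abs(s)), 1, tolerance = 1e-4)
  per <- 1526 / 5  # non-integer period; check via exact sinusoid
  expect_equal(s, sin(2 * pi * 5 * (0:4999) / 1526), tolerance = 1e-12)

  a <- gen_dynamics_series("ar1", 5000, params = list(phi = 0.5), seed = 2)
  r1 <- stats::acf(a, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.5, tolerance = 0.05)

  expect_identical(gen_dynamics_series("constant", 100,
                                       params = list(level = 2)), rep(2, 100))
})

test_that("regime feature generator produces a recoverable 2-regime world", {
  pts <- gen_regime_features(300, seed = 7)
  expect_equal(nrow(pts), 300)
  expect_true(all(pts$mi[pts$label == 1] < 0.4))
  expect_true(all(pts$mi[pts$label == 2] > 0.4))
  expect_gt(mean(pts$k[pts$label == 1]), 0.8)
  cl <- cluster_chaos_mi(pts[, c("mi", "k")], seed = 7)
  expect_equal(cl$k, 2)
  expect_gt(rand_index(pts$label, cl$labels), 0.9)

  # a single-regime configuration is flagged as weak structure
  p1 <- gen_regime_features(300, seed = 7, prop_low = 1)
  c1 <- cluster_chaos_mi(p1[, c("mi", "k")], seed = 7)
  expect_true(c1$weak_structure)

  expect_identical(gen_regime_features(120, seed = 3),
                   gen_regime_features(120, seed = 3))
})

test_that("kappa = 0 spike trains are independent of the LFP", {
  cfg <- generator_config(seed = 8, n_trials = 30, energy_grid_mJ = 3,
                          isi_grid_ms = 5, kappa = 0,
                          spike_gain_hz_per_mJ = 30,
                          electrodes = "e1", n_animals = 1)
  ts <- gen_spike_trains(cfg, gen_lfp_trialset(cfg))
  st <- sfc_table(ts)
  # small-sample bias level at 30 trials is well below strong locking
  expect_lt(st$sfc[st$band == "gamma_low"], 0.5)
  # more trials -> lower bias floor
  cfg2 <- cfg; cfg2$n_trials <- 10L
  ts2 <- gen_spike_trains(cfg2, gen_lfp_trialset(cfg2))
  st2 <- sfc_table(ts2)
  expect_lt(st$sfc[st$band == "gamma_high"],
            st2$sfc[st2$band == "gamma_high"] + 0.2)
  # lambda0 = 0 and gain = 0 gives empty spike lists
  cfg0 <- generator_config(seed = 9, n_trials = 2, energy_grid_mJ = 2,
                           isi_grid_ms = 5, spike_rate_hz = 0,
                           spike_gain_hz_per_mJ = 0,
                           electrodes = "e1", n_animals = 1)
  ts0 <- gen_spike_trains(cfg0, gen_lfp_trialset(cfg0))
  expect_true(all(vapply(ts0$trials,
                         function(tr) length(tr$spikes$u1) == 0, logical(1))))
})
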