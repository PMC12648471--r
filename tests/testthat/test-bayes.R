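fast_settings <- function(seed = 1) sampler_settings(2L, 1000L, 500L, seed)

test_that("posterior summaries match closed forms", {
  set.seed(71)
  z <- matrix(rnorm(20000), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_posterior(z)
  expect_lt(abs(s$map), 0.05)
  expect_equal(s$hdi_lo, -1.96, tolerance = 0.1)
  expect_equal(s$hdi_hi, 1.96, tolerance = 0.1)
  expect_false(s$significant)

  pm <- matrix(rep(2.5, 1200), ncol = 1, dimnames = list(NULL, "c"))
  sp <- summarize_posterior(pm)
  expect_equal(sp$map, 2.5)
  expect_equal(sp$hdi_hi - sp$hdi_lo, 0)
  expect_true(sp$significant)

  ex <- matrix(rexp(20000), ncol = 1, dimnames = list(NULL, "e"))
  se <- summarize_posterior(ex)
  expect_equal(se$hdi_lo, 0, tolerance = 0.05)
  expect_equal(se$hdi_hi, stats::qexp(0.95), tolerance = 0.1)
})

test_that("the HDI is never wider than the equal-tailed interval", {
  set.seed(72)
  for (x in list(rnorm(5000), rexp(5000), rbeta(5000, 2, 8),
                 c(rnorm(2500), rnorm(2500, 4)))) {
    h <- hdi(x)
    et <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    expect_lte(h[2] - h[1], et[2] - et[1] + 1e-12)
    # MAP inside HDI
    s <- summarize_posterior(matrix(x, ncol = 1))
    expect_gte(s$map, s$hdi_lo)
    expect_lte(s$map, s$hdi_hi)
  }
})

test_that("significance follows the HDI-excludes-zero convention", {
  pos <- matrix(rnorm(2000, 5, 0.5), ncol = 1, dimnames = list(NULL, "b"))
  expect_true(summarize_posterior(pos)$significant)
  straddle <- matrix(rnorm(2000, 0.1, 1), ncol = 1, dimnames = list(NULL, "b"))
  expect_false(summarize_posterior(straddle)$significant)
})

test_that("simple Bayesian regression recovers known coefficients", {
  set.seed(73)
  n <- 300
  x <- runif(n, -2, 2)
  y <- 1.5 + 0.8 * x + rnorm(n, 0, 0.4)
  f <- fit_blr(y, cbind(intercept = 1, b_x = x), fast_settings(2))
  s <- f$summary
  expect_lt(abs(s$map[s$term == "intercept"] - 1.5), 0.15)
  expect_lt(abs(s$map[s$term == "b_x"] - 0.8), 0.1)
  expect_gt(f$ppc_p, 0.05); expect_lt(f$ppc_p, 0.95)
  # near-noiseless data pins the MAP
  y0 <- 1.5 + 0.8 * x + rnorm(n, 0, 1e-4)
  f0 <- fit_blr(y0, cbind(intercept = 1, b_x = x), fast_settings(3))
  expect_lt(abs(f0$summary$map[2] - 0.8), 1e-3)
})

test_that("hierarchical fit recovers slopes and handles the null", {
  cfg <- clean_dose_cfg(seed = 74, n_trials = 10)
  ts <- gen_lfp_trialset(cfg)
  dose <- dose_response_table(ts)
  fh <- fit_hlr(dose, settings = fast_settings(4))
  s <- fh$summary
  expect_true(s$hdi_lo[s$term == "b_E"] <= 0.087 &
                s$hdi_hi[s$term == "b_E"] >= 0.087)
  expect_true(all(s$rhat < 1.05, na.rm = TRUE))
  # pure-noise response: slope HDIs contain 0
  set.seed(75)
  null_tab <- dose
  null_tab$rms <- exp(rnorm(nrow(null_tab)))
  fn <- fit_hlr(null_tab, settings = fast_settings(5))
  sn <- fn$summary
  for (term in c("b_E", "b_ISI", "b_ExISI")) {
    expect_false(sn$significant[sn$term == term])
  }
  expect_error(fit_hlr(dose[dose$electrode == "e1", ],
                       settings = fast_settings(1)), "3 groups")
})

test_that("shrinking the group-scale prior reduces the fit to pooled", {
  cfg <- clean_dose_cfg(seed = 76, n_trials = 8)
  ts <- gen_lfp_trialset(cfg)
  dose <- dose_response_table(ts)
  fh <- fit_hlr(dose, settings = fast_settings(6), prior_scale_tau = 1e-6)
  d <- dose[dose$valid & dose$energy_mJ > 0 & dose$rms > 0, ]
  pooled <- stats::lm(log(rms) ~ log(energy_mJ) * log(isi_ms), d)
  s <- fh$summary
  expect_lt(abs(s$map[s$term == "b_E"] - coef(pooled)[2]), 0.02)
  expect_lt(abs(s$map[s$term == "b_ISI"] - coef(pooled)[3]), 0.02)
})

test_that("spike-rate regression recovers construction and rejects nulls", {
  set.seed(77)
  n <- 300
  rate <- exp(runif(n, 0, 3))
  isi <- sample(c(1, 5, 50), n, replace = TRUE)
  rms <- exp(0.5 + 1.8 * log(rate) - 0.047 * log(isi) + rnorm(n, 0, 0.3))
  tab <- data.frame(rms = rms, spike_rate = rate, isi_ms = isi)
  f <- fit_spike_lfp_lr(tab, fast_settings(7))
  s <- f$summary
  expect_gt(s$hdi_lo[s$term == "b_spikerate"], 0)   # positive rate slope
  expect_lt(s$hdi_hi[s$term == "b_ISI"], 0)         # negative ISI slope
  expect_lt(abs(s$map[s$term == "b_spikerate"] - 1.8), 0.1)
  # shuffled rates: slope HDI contains 0
  tab2 <- tab; tab2$spike_rate <- sample(tab$spike_rate)
  f2 <- fit_spike_lfp_lr(tab2, fast_settings(8))
  s2 <- f2$summary
  expect_false(s2$significant[s2$term == "b_spikerate"])
  expect_error(fit_spike_lfp_lr(data.frame(rms = 1, spike_rate = 0,
                                           isi_ms = 5)), "positive")
})

test_that("stimulus spike rates use the train + 50 ms window", {
  st <- stimulus_train(2, 5)  # train 0.2-0.27 s; window 0.2-0.32 s
  tr <- trial_recording(rep(0, 1526), 1526,
                        spikes = list(u1 = c(0.1, 0.21, 0.25, 0.31, 0.5)),
                        stimulus = st)
  r <- stimulus_spike_rates(trial_set(list(tr)))
  expect_equal(r$spike_rate, 3 / 0.12, tolerance = 1e-9)
})

test_that("knot detection finds constructed breaks and skips linear data", {
  e <- exp(seq(log(0.05), log(4.5), length.out = 24))
  piece <- function(e, knot, s_lo, s_hi, a = 0.2) {
    ifelse(e < knot, a + s_lo * log(e / knot), a + s_hi * log(e / knot))
  }
  for (kn in c(0.15, 0.125)) {
    k <- find_knot(e, piece(e, kn, 0, 0.15))
    expect_true(k$has_knot)
    i_true <- which.min(abs(e - kn))
    i_got <- which.min(abs(e - k$knot_mJ))
    expect_lte(abs(i_got - i_true), 1)
  }
  expect_false(find_knot(e, 0.1 + 0.2 * log(e))$has_knot)
  expect_error(find_knot(e[1:5], e[1:5]), "8 energy")
})

test_that("piecewise spline fits recover per-segment slopes", {
  set.seed(78)
  e <- rep(exp(seq(log(0.05), log(4.5), length.out = 24)), each = 6)
  sfc <- ifelse(e < 0.15, 0.2, 0.2 + 0.15 * log(e / 0.15)) +
    rnorm(length(e), 0, 0.02)
  f <- fit_spline_sfc(e, sfc, 0.15, fast_settings(9))
  s <- f$summary
  expect_false(s$significant[s$term == "b_below"])
  expect_true(s$significant[s$term == "b_above"])
  expect_lt(abs(s$map[s$term == "b_above"] - 0.15), 0.02)
  # globally flat data: both segments contain 0
  flat <- 0.2 + rnorm(length(e), 0, 0.02)
  sf <- fit_spline_sfc(e, flat, 0.15, fast_settings(10))$summary
  expect_false(sf$significant[sf$term == "b_below"])
  expect_false(sf$significant[sf$term == "b_above"])
  # near-noiseless two-segment data pins the MAPs
  exact <- ifelse(e < 0.15, 0.2, 0.2 + 0.15 * log(e / 0.15)) +
    rnorm(length(e), 0, 1e-4)
  s0 <- fit_spline_sfc(e, exact, 0.15, fast_settings(11))$summary
  expect_lt(abs(s0$map[s0$term == "b_below"] - 0), 1e-2)
  expect_lt(abs(s0$map[s0$term == "b_above"] - 0.15), 1e-2)
  # sparse segment flag
  fsp <- fit_spline_sfc(e[e > 0.14], sfc[e > 0.14], 0.15, fast_settings(12))
  expect_match(fsp$flags, "below-knot")
})
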