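test_that("downsampling decimates with anti-aliasing", {
  rate0 <- 24414.0625
  st <- stimulus_train(2, 5, trial_length_s = 0.5)
  t <- (0:(round(0.5 * rate0) - 1)) / rate0
  tr <- trial_recording(sin(2 * pi * 100 * t), rate0, stimulus = st)
  out <- downsample_lfp(tr, 1526)
  expect_equal(out$rate, 1526)
  expect_equal(length(out$lfp), round(0.5 * 1526))
  # 100 Hz sine survives with amplitude within 1% (mid-section, away from edges)
  mid <- 200:500
  t2 <- (seq_along(out$lfp) - 1) / (rate0 / 16)
  fit <- stats::lm(out$lfp[mid] ~ sin(2 * pi * 100 * t2[mid]) +
                     cos(2 * pi * 100 * t2[mid]))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 1, tolerance = 0.01)
})

test_that("downsampling edge cases behave", {
  st <- stimulus_train(2, 5, trial_length_s = 0.5)
  tr <- trial_recording(rnorm(round(0.5 * 1526)), 1526, stimulus = st)
  expect_identical(downsample_lfp(tr, 1526), tr)
  expect_error(downsample_lfp(tr, 3052), "upsample")
})

test_that("two-stage 4x4 decimation matches single-stage 16x", {
  rate0 <- 24416  # exact 16x for a clean comparison
  st <- stimulus_train(2, 5, trial_length_s = 0.5)
  n0 <- round(0.5 * rate0)
  t <- (0:(n0 - 1)) / rate0
  # band-limited input well under the final Nyquist
  set.seed(11)
  x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 200 * t + 1)
  tr <- trial_recording(x, rate0, stimulus = st)
  one <- downsample_lfp(tr, rate0 / 16)
  two <- downsample_lfp(downsample_lfp(tr, rate0 / 4), rate0 / 16)
  mid <- 100:650
  rel <- sqrt(mean((one$lfp[mid] - two$lfp[mid])^2)) /
    sqrt(mean(one$lfp[mid]^2))
  expect_lt(rel, 0.001)
})

test_that("the drift filter rejects DC and drift, passes the band", {
  st <- stimulus_train(2, 5)
  n <- 1526
  const <- trial_recording(rep(3.3, n), 1526, stimulus = st)
  expect_lt(max(abs(highpass_drift(const)$lfp)), 1e-6 * 3.3)

  hp <- cheby2_design(4, 40, 10 / 763, "high")
  # analytic frequency response oracle (single pass; filtfilt applies it twice)
  g50 <- 20 * log10(Mod(freq_response(hp, 50, 1526)))
  g1 <- 20 * log10(Mod(freq_response(hp, 1, 1526)))
  expect_gte(g50, -1)
  expect_lte(g1, -40)
  # measured attenuation agrees with the squared response
  tr50 <- trial_recording(sine_series(50), 1526, stimulus = st)
  y <- highpass_drift(tr50)$lfp
  expect_equal(max(abs(y[400:1100])), Mod(freq_response(hp, 50, 1526))^2,
               tolerance = 0.01)
})

test_that("filtering is linear", {
  st <- stimulus_train(2, 5)
  set.seed(12)
  x <- rnorm(1526); y <- rnorm(1526)
  f <- function(v) highpass_drift(trial_recording(v, 1526, stimulus = st))$lfp
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("PSTH arithmetic is exact", {
  st <- stimulus_train(2, 5)
  mk <- function(sp, i) trial_recording(rep(0, 1526), 1526,
                                        spikes = list(u1 = sp),
                                        stimulus = st, trial = i)
  # 10 trials, 1 spike per trial inside one 10 ms bin -> 100 Hz there
  ts <- trial_set(lapply(1:10, function(i) mk(0.255, i)))
  p <- build_psth(ts, "u1", 0.01)
  bin <- findInterval(0.255, p$edges)
  expect_equal(p$rate[bin], 100)
  expect_equal(sum(p$rate[-bin]), 0)

  # empty spike lists -> all-zero PSTH, spontaneous SD 0
  ts0 <- trial_set(lapply(1:5, function(i) mk(numeric(0), i)))
  p0 <- build_psth(ts0, "u1", 0.01)
  expect_true(all(p0$rate == 0))
  expect_equal(p0$spont_sd, 0)
  expect_error(build_psth(trial_set(list())), NULL)
})

test_that("homogeneous Poisson spiking recovers its baseline rate", {
  st <- stimulus_train(2, 5)
  set.seed(13)
  lam <- 20
  trials <- lapply(1:60, function(i) {
    k <- rpois(1, lam * 1)
    trial_recording(rep(0, 1526), 1526,
                    spikes = list(u1 = sort(runif(k, 0, 1))),
                    stimulus = st, trial = i)
  })
  p <- build_psth(trial_set(trials), "u1", 0.01)
  se <- sqrt(lam / (60 * 0.2))  # SE of the baseline-window mean rate
  expect_lt(abs(p$spont_mean - lam), 3 * se)
})

test_that("responsiveness uses the inclusive z >= 3.92 rule", {
  mk_psth <- function(rates, spont_mean, spont_sd) {
    structure(list(edges = seq(0, 1, 0.01), rate = rates,
                   spont_mean = spont_mean, spont_sd = spont_sd,
                   n_trials = 10,
                   windows = compute_windows(stimulus_train(2, 5))),
              class = "psth")
  }
  base <- rep(10, 100)
  onset_bin <- 25  # 0.245 s, inside the onset window
  r <- base; r[onset_bin] <- 10 + 5 * 2    # z = 5
  expect_true(classify_responsive(mk_psth(r, 10, 2))$responsive)
  expect_equal(classify_responsive(mk_psth(r, 10, 2))$max_z, 5)
  expect_false(classify_responsive(mk_psth(base, 10, 2))$responsive)
  r392 <- base; r392[onset_bin] <- 10 + 3.92 * 2   # z exactly at threshold
  expect_true(classify_responsive(mk_psth(r392, 10, 2))$responsive)
  r391 <- base; r391[onset_bin] <- 10 + 3.91 * 2
  expect_false(classify_responsive(mk_psth(r391, 10, 2))$responsive)
  # zero spontaneous SD with evoked spikes -> explicit verdict, no exception
  rz <- rep(0, 100); rz[onset_bin] <- 5
  out <- classify_responsive(mk_psth(rz, 0, 0))
  expect_true(out$responsive)
  expect_match(out$note, "undefined z")
})
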