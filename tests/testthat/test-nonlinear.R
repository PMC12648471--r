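test_that("the FFT displacement path matches the literal definition", {
  x <- gen_dynamics_series("logistic", 2000)
  p <- cumsum(x * cos(1.1 * seq_along(x)))
  q <- cumsum(x * sin(1.1 * seq_along(x)))
  md <- insdyn:::msd_direct(p, q, 200)
  mf <- insdyn:::msd_fft(p, q, 200)
  expect_equal(mf, md, tolerance = 1e-10)
})

test_that("the 0-1 test separates periodic from chaotic dynamics", {
  ks <- chaos01(gen_dynamics_series("sine", 5000), chaos_config(seed = 1))
  expect_lte(ks$kc, 0.2)
  kl <- chaos01(gen_dynamics_series("logistic", 5000), chaos_config(seed = 1))
  expect_gte(kl$kc, 0.9)
  expect_true(all(ks$kc >= 0 & ks$kc <= 1))
  # determinism under a fixed seed
  k2 <- chaos01(gen_dynamics_series("sine", 5000), chaos_config(seed = 1))
  expect_identical(ks$kc, k2$kc)
  # degenerate input
  kd <- chaos01(rep(1, 1000))
  expect_identical(kd$verdict, "degenerate")
  expect_true(is.na(kd$kc))
  expect_error(chaos01(rnorm(100)), "500")
})

test_that("Kc is stable under amplitude rescaling (sigma rescaled with M)", {
  x <- gen_dynamics_series("logistic", 3000)
  k1 <- chaos01(x, chaos_config(seed = 3))$kc
  # M_disp scales as k^2 under x -> k x, so sigma scales the same way
  k <- 5
  k2 <- chaos01(k * x, chaos_config(sigma = 0.5 * k^2, seed = 3))$kc
  expect_equal(k1, k2, tolerance = 0.05)
})

test_that("Kc(sine) < Kc(logistic) across seeds", {
  kc_s <- kc_l <- numeric(10)
  xs <- gen_dynamics_series("sine", 3000)
  xl <- gen_dynamics_series("logistic", 3000)
  for (s in 1:10) {
    kc_s[s] <- chaos01(xs, chaos_config(seed = s))$kc
    kc_l[s] <- chaos01(xl, chaos_config(seed = s))$kc
  }
  expect_true(all(kc_s < kc_l))
})

test_that("the permutation-entropy gate classifies canonical series", {
  set.seed(51)
  expect_identical(stochasticity_gate(rnorm(5000))$verdict, "stochastic")
  expect_identical(
    stochasticity_gate(gen_dynamics_series("logistic", 5000))$verdict,
    "deterministic")
  expect_identical(
    stochasticity_gate(gen_dynamics_series("sine", 5000))$verdict,
    "deterministic")
  expect_identical(stochasticity_gate(rep(2, 600))$verdict, "degenerate")
  # entropy itself: white noise near 1, strong structure well below
  expect_gt(permutation_entropy(rnorm(5000)), 0.95)
  expect_lt(permutation_entropy(gen_dynamics_series("sine", 5000)), 0.3)
  expect_warning(permutation_entropy(rnorm(600), m = 5), "coarse")
})

test_that("quadratic bias extrapolation solves the constructed law exactly", {
  ns <- c(100, 50, 25)
  i_est <- 1 + 10 / ns + 100 / ns^2
  sol <- mi_bias_solve(i_est, ns)
  expect_equal(sol$i_true, 1, tolerance = 1e-10)
  expect_equal(sol$a, 10, tolerance = 1e-9)
  expect_equal(sol$b, 100, tolerance = 1e-8)
})

test_that("MI estimation is calibrated on null and high-information channels", {
  set.seed(52)
  null_mi <- replicate(20, {
    estimate_mi(rnorm(200), rep(1:4, each = 50),
                seed = sample.int(1e6, 1))$i_corrected
  })
  expect_lt(abs(mean(null_mi)), 0.05)

  four <- replicate(5, {
    l <- rep(1:4, each = 50)
    r <- rnorm(200, mean = c(0, 10, 20, 30)[l], sd = 0.5)
    estimate_mi(r, l, seed = sample.int(1e6, 1))$i_corrected
  })
  expect_lt(max(abs(four - 2)), 0.1)
})

test_that("MI estimator respects its contracts", {
  set.seed(53)
  r <- rnorm(120); l <- rep(1:3, each = 40)
  e1 <- estimate_mi(r, l, seed = 9)
  expect_gte(e1$i_raw, 0)
  # permutation invariance to trial order
  o <- sample(120)
  e2 <- estimate_mi(r[o], l[o], seed = 9)
  expect_equal(e1$i_raw, e2$i_raw, tolerance = 1e-12)
  # small classes dropped with a warning; single class errors
  expect_warning(estimate_mi(c(r, 1), c(l, 4), seed = 1), "dropping")
  expect_error(suppressWarnings(
    estimate_mi(rnorm(8), c(rep(1, 5), rep(2, 3)))), "2 stimulus classes")
  # Doane bin count behaves sensibly
  expect_gte(doane_bins(rnorm(200)), 8)
  expect_lte(doane_bins(rnorm(10)), 8)
})

test_that("K-means + silhouette selects the constructed cluster count", {
  set.seed(54)
  two <- rbind(cbind(rnorm(60, 0, 0.03), rnorm(60, 0, 0.03)),
               cbind(rnorm(60, 1, 0.03), rnorm(60, 1, 0.03)))
  c2 <- cluster_chaos_mi(data.frame(mi = two[, 1], k = two[, 2]), seed = 2)
  expect_equal(c2$k, 2)
  expect_equal(rand_index(rep(1:2, each = 60), c2$labels), 1)

  three <- rbind(cbind(rnorm(50, 0, 0.04), rnorm(50, 0, 0.04)),
                 cbind(rnorm(50, 1, 0.04), rnorm(50, 0, 0.04)),
                 cbind(rnorm(50, 0.5, 0.04), rnorm(50, 1, 0.04)))
  c3 <- cluster_chaos_mi(data.frame(mi = three[, 1], k = three[, 2]), seed = 2)
  expect_equal(c3$k, 3)

  expect_error(cluster_chaos_mi(data.frame(mi = rnorm(5), k = rnorm(5))),
               "points")
})

test_that("the MI bifurcation readout lands between regime centers", {
  pts <- gen_regime_features(300, seed = 7)
  cl <- cluster_chaos_mi(pts[, c("mi", "k")], seed = 7)
  bp <- mi_bifurcation_point(pts$mi, cl$centers[, "mi"])
  expect_gt(bp, 0.2)
  expect_lt(bp, 0.8)
})
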