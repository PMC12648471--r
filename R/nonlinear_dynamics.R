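# Nonlinear dynamics: modified 0-1 test for chaos, permutation-entropy
# stochasticity gate, bias-corrected stimulus-response mutual information, and
# chaos-versus-MI regime clustering.
#
# The 0-1 test maps a series phi(n) onto translation variables
#   p(n+1) = p(n) + phi(n) cos(c n),  q(n+1) = q(n) + phi(n) sin(c n)
# for random c ~ Uniform(pi/5, 4pi/5) (the restricted support avoids
# resonance overestimation). Bounded (regular) dynamics keep (p, q) bounded;
# chaotic dynamics diffuse, so the time-averaged mean squared displacement
# M(n) grows linearly in n. The reported statistic is
#   Kc = median_c corr(M(n) + sigma*rho_n, n),  n <= N0 = N/10,
# with uniform noise rho_n in (-1/2, 1/2) of amplitude sigma = 0.5 suppressing
# spurious correlation of small bounded oscillations; Kc ~ 0 for periodic and
# ~ 1 for chaotic dynamics.

#' Configuration for the modified 0-1 chaos test
#'
#' @param n_c number of random draws of the mapping frequency c.
#' @param c_support support of c, a sub-interval of (0, pi).
#' @param sigma amplitude of the uniform noise perturbation added to the mean
#'   squared displacement.
#' @param n0_fraction fraction of the series length used as the displacement
#'   horizon N0 (must be well below 1).
#' @param seed RNG seed.
#' @return list of class `chaos_config`.
#' @export
chaos_config <- function(n_c = 100L, c_support = c(pi / 5, 4 * pi / 5),
                         sigma = 0.5, n0_fraction = 0.1, seed = 1L) {
  stopifnot(n_c >= 1, sigma >= 0, n0_fraction > 0, n0_fraction <= 0.25,
            c_support[1] > 0, c_support[2] < pi, c_support[1] < c_support[2])
  structure(list(n_c = as.integer(n_c), c_support = c_support, sigma = sigma,
                 n0_fraction = n0_fraction, seed = as.integer(seed)),
            class = "chaos_config")
}

msd_direct <- function(p, q, n0) {
  # reference implementation: literal time-averaged mean squared displacement
  N <- length(p)
  vapply(seq_len(n0), function(n) {
    dp <- p[(1 + n):N] - p[1:(N - n)]
    dq <- q[(1 + n):N] - q[1:(N - n)]
    mean(dp^2 + dq^2)
  }, numeric(1))
}

msd_fft <- function(p, q, n0) {
  # O(N log N) displacement via FFT autocorrelation:
  # sum_i (p_{i+n} - p_i)^2 = S2(n) - 2 r_p(n), with
  # S2(n) = sum_{i>n} p_i^2 + sum_{i<=N-n} p_i^2 and r_p(n) = sum p_i p_{i+n}
  N <- length(p)
  acf_fft <- function(x) {
    m <- 2^ceiling(log2(2 * N))
    X <- stats::fft(c(x, rep(0, m - N)))
    Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(n0 + 1)] / m
  }
  csum_p <- cumsum(p^2); csum_q <- cumsum(q^2)
  tp <- csum_p[N]; tq <- csum_q[N]
  rp <- acf_fft(p); rq <- acf_fft(q)
  n <- seq_len(n0)
  s2p <- (tp - csum_p[n]) + csum_p[N - n]
  s2q <- (tq - csum_q[n]) + csum_q[N - n]
  (s2p - 2 * rp[n + 1] + s2q - 2 * rq[n + 1]) / (N - n)
}

#' Modified 0-1 test for chaos
#'
#' @param x numeric series (>= 500 finite samples).
#' @param cfg a [chaos_config()].
#' @return object of class `chaos_result`: `kc` (median per-c correlation,
#'   clipped to \[0, 1\]), `kc_raw` (unclipped), `k_per_c`, `c_values`,
#'   `k_logratio` (diagnostic log M / log n growth rate at N0), and `verdict`
#'   (`"degenerate"` for constant input, otherwise `"ok"`; stochasticity is
#'   assessed separately by [stochasticity_gate()]).
#' @export
chaos01 <- function(x, cfg = chaos_config()) {
  stopifnot(inherits(cfg, "chaos_config"))
  if (length(x) < 500) stop("0-1 test requires at least 500 samples")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  if (stats::sd(x) == 0) {
    return(structure(list(kc = NA_real_, kc_raw = NA_real_,
                          k_per_c = numeric(0), c_values = numeric(0),
                          k_logratio = NA_real_, verdict = "degenerate"),
                     class = "chaos_result"))
  }
  N <- length(x)
  n0 <- floor(N * cfg$n0_fraction)
  nseq <- seq_len(n0)
  with_seed(cfg$seed, {
    cs <- stats::runif(cfg$n_c, cfg$c_support[1], cfg$c_support[2])
    ks <- numeric(cfg$n_c)
    klr <- numeric(cfg$n_c)
    for (j in seq_len(cfg$n_c)) {
      ang <- cs[j] * seq_len(N)
      p <- cumsum(x * cos(ang))
      q <- cumsum(x * sin(ang))
      M <- msd_fft(p, q, n0) + cfg$sigma * stats::runif(n0, -0.5, 0.5)
      ks[j] <- stats::cov(M, nseq) / sqrt(stats::var(M) * stats::var(nseq))
      klr[j] <- log(abs(M[n0])) / log(n0)
    }
    kc_raw <- stats::median(ks, na.rm = TRUE)
    structure(list(kc = min(max(kc_raw, 0), 1), kc_raw = kc_raw,
                   k_per_c = ks, c_values = cs,
                   k_logratio = stats::median(klr, na.rm = TRUE),
                   verdict = "ok"),
              class = "chaos_result")
  })
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution at embedding dimension
#' `m` and lag `tau`, normalized by `log2(m!)` to \[0, 1\].
#'
#' @param x numeric series.
#' @param m embedding dimension.
#' @param tau embedding lag.
#' @return normalized entropy in \[0, 1\].
#' @export
permutation_entropy <- function(x, m = 5L, tau = 1L) {
  n <- length(x) - (m - 1L) * tau
  if (n < 1) stop("series too short for the requested embedding")
  if (length(x) < factorial(m + 1)) {
    warning("series shorter than (m+1)! samples; entropy estimate is coarse")
  }
  # Lehmer-style pattern code from pairwise comparisons (ties broken by
  # position, matching rank(ties.method = "first"))
  code <- integer(n)
  base <- 1L
  for (j in seq_len(m)) {
    xj <- x[seq.int((j - 1L) * tau + 1L, length.out = n)]
    rj <- integer(n)
    for (k in seq_len(m)) {
      if (k == j) next
      xk <- x[seq.int((k - 1L) * tau + 1L, length.out = n)]
      rj <- rj + if (k < j) as.integer(xk <= xj) else as.integer(xk < xj)
    }
    code <- code + rj * base
    base <- base * m
  }
  tab <- tabulate(code + 1L, nbins = base)
  pr <- tab[tab > 0] / n
  -sum(pr * log2(pr)) / log2(factorial(m))
}

#' Permutation-entropy gate for stochastic dynamics
#'
#' Only strongly non-stochastic series should be forwarded to chaos reporting.
#' A series is called deterministic when its normalized permutation entropy
#' falls below 0.95 times the 5th percentile of the entropy of shuffled
#' surrogates (which destroy all temporal structure); otherwise stochastic.
#' Constant series are degenerate.
#'
#' @param x numeric series (>= 500 samples).
#' @param m,tau embedding dimension and lag.
#' @param n_surrogates number of shuffled surrogates.
#' @param threshold_factor multiplier on the surrogate 5th percentile.
#' @param seed RNG seed.
#' @return list: `verdict` in `{"stochastic","deterministic","degenerate"}`,
#'   `h_pe`, `h_null_q05`.
#' @export
stochasticity_gate <- function(x, m = 5L, tau = 1L, n_surrogates = 100L,
                               threshold_factor = 0.95, seed = 1L) {
  if (length(x) < 500) stop("gate requires at least 500 samples")
  if (stats::sd(x) == 0) {
    return(list(verdict = "degenerate", h_pe = NA_real_,
                h_null_q05 = NA_real_))
  }
  h <- permutation_entropy(x, m, tau)
  with_seed(seed, {
    hs <- vapply(seq_len(n_surrogates), function(i)
      permutation_entropy(sample(x), m, tau), numeric(1))
    q05 <- stats::quantile(hs, 0.05, names = FALSE)
    list(verdict = if (h < threshold_factor * q05) "deterministic"
         else "stochastic",
         h_pe = h, h_null_q05 = q05)
  })
}

#' Doane histogram bin count
#'
#' `1 + log2(n) + log2(1 + |g1| / sigma_g1)` with `g1` the sample skewness;
#' robust for non-normal response distributions.
#'
#' @param x numeric sample.
#' @return integer bin count.
#' @export
doane_bins <- function(x) {
  n <- length(x)
  if (n < 3) return(1L)
  g1 <- mean((x - mean(x))^3) / stats::sd(x)^3
  sg1 <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  as.integer(ceiling(1 + log2(n) + log2(1 + abs(g1) / sg1)))
}

mi_discrete <- function(responses, labels, n_bins, grid = NULL, bw = NULL) {
  # kernel-smoothed histogram MI on a common grid:
  # I = sum_s p(s) sum_i p(r_i|s) log2(p(r_i|s) / p(r_i)), p(r) the mixture
  labels <- as.factor(labels)
  if (is.null(grid)) {
    rg <- range(responses)
    pad <- 0.05 * diff(rg) + 1e-12
    grid <- seq(rg[1] - pad, rg[2] + pad, length.out = n_bins)
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(responses)
  cond <- vapply(levels(labels), function(s) {
    r <- responses[labels == s]
    # per-class bandwidth: conditional densities keep class-level resolution
    bws <- if (length(r) >= 5 && stats::sd(r) > 0) stats::bw.nrd0(r) else bw
    d <- rowMeans(outer(grid, r, function(g, x) stats::dnorm(g - x, sd = bws)))
    d / sum(d)
  }, numeric(length(grid)))
  ps <- as.numeric(table(labels)) / length(labels)
  pr <- as.numeric(cond %*% ps)
  terms <- 0
  for (s in seq_along(ps)) {
    nz <- cond[, s] > 0
    terms <- terms + ps[s] *
      sum(cond[nz, s] * log2(cond[nz, s] / pr[nz]))
  }
  terms
}

#' Bias-corrected stimulus-response mutual information
#'
#' MI (bits) between stimulus class and a scalar response, with conditional
#' and marginal densities estimated by Gaussian-kernel-smoothed histograms on
#' a common grid of `n_bins` bins (default the fixed 21; set
#' `n_bins = "doane"` for the data-driven Doane count). Estimation bias is
#' removed by the quadratic extrapolation `I_est(N) = I_true + a/N + b/N^2`,
#' solved exactly through mean estimates at subsample fractions 1, 0.5, and
#' 0.25 (stratified within class, `n_rep` seeded draws per fraction).
#'
#' @param responses numeric response vector.
#' @param labels stimulus class per response (>= 2 classes; classes with
#'   fewer than 5 responses are dropped with a warning).
#' @param n_bins bin count, or `"doane"`.
#' @param n_rep subsample draws per fraction.
#' @param seed RNG seed.
#' @return object of class `mi_estimate`: `i_raw` (full-N estimate), `i_half`,
#'   `i_quarter`, `a`, `b`, `i_corrected`, `n_bins`, `n`.
#' @export
estimate_mi <- function(responses, labels, n_bins = 21L, n_rep = 10L,
                        seed = 1L) {
  labels <- as.factor(as.character(labels))
  counts <- table(labels)
  bad <- names(counts)[counts < 5]
  if (length(bad)) {
    warning("dropping classes with < 5 responses: ", paste(bad, collapse = ", "))
    keep <- !(labels %in% bad)
    responses <- responses[keep]
    labels <- droplevels(labels[keep])
  }
  if (nlevels(labels) < 2) stop("need at least 2 stimulus classes")
  if (identical(n_bins, "doane")) n_bins <- doane_bins(responses)
  n_bins <- as.integer(n_bins)
  N <- length(responses)
  i_full <- mi_discrete(responses, labels, n_bins)
  sub_mi <- function(frac) {
    mean(vapply(seq_len(n_rep), function(r) {
      idx <- unlist(lapply(levels(labels), function(s) {
        pool <- which(labels == s)
        sample(pool, max(2, round(length(pool) * frac)))
      }))
      mi_discrete(responses[idx], labels[idx], n_bins)
    }, numeric(1)))
  }
  with_seed(seed, {
    i_half <- sub_mi(0.5)
    i_quarter <- sub_mi(0.25)
    ns <- c(N, round(N * 0.5), round(N * 0.25))
    A <- cbind(1, 1 / ns, 1 / ns^2)
    sol <- solve(A, c(i_full, i_half, i_quarter))
    structure(list(i_raw = i_full, i_half = i_half, i_quarter = i_quarter,
                   a = sol[2], b = sol[3], i_corrected = sol[1],
                   n_bins = n_bins, n = N),
              class = "mi_estimate")
  })
}

#' Exact quadratic bias-law solve
#'
#' Given MI estimates at three sample sizes, solves
#' `I_est = I_true + a/N + b/N^2` exactly.
#'
#' @param i_est estimates at the three sizes.
#' @param n_sizes the three sample sizes.
#' @return list `i_true`, `a`, `b`.
#' @export
mi_bias_solve <- function(i_est, n_sizes) {
  stopifnot(length(i_est) == 3, length(n_sizes) == 3)
  A <- cbind(1, 1 / n_sizes, 1 / n_sizes^2)
  sol <- solve(A, i_est)
  list(i_true = sol[1], a = sol[2], b = sol[3])
}

#' Silhouette-selected K-means clustering of (MI, K) features
#'
#' Standardizes the two features, runs K-means (multiple restarts) for each k
#' in `k_range`, and selects the k maximizing the mean silhouette width.
#'
#' @param points data.frame or matrix with columns `mi` and `k` (or two
#'   numeric columns).
#' @param k_range candidate cluster counts.
#' @param n_start K-means restarts per k.
#' @param seed RNG seed.
#' @return list: `k` (selected), `labels`, `silhouette` (named mean widths per
#'   candidate k), `weak_structure` (TRUE when the best mean silhouette is
#'   below 0.5, flagging data without clear cluster structure), `centers`
#'   (on the original scale).
#' @export
cluster_chaos_mi <- function(points, k_range = 2:6, n_start = 10L, seed = 1L) {
  X <- as.matrix(as.data.frame(points)[, 1:2])
  if (nrow(X) < 2 * max(k_range)) stop("need at least 2*max(k_range) points")
  Z <- scale(X)
  with_seed(seed, {
    sil <- stats::setNames(numeric(length(k_range)), k_range)
    fits <- list()
    d <- stats::dist(Z)
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      km <- stats::kmeans(Z, centers = k, nstart = n_start, iter.max = 50)
      sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      fits[[i]] <- km
    }
    best <- which.max(sil)
    km <- fits[[best]]
    centers <- km$centers * rep(attr(Z, "scaled:scale"), each = nrow(km$centers)) +
      rep(attr(Z, "scaled:center"), each = nrow(km$centers))
    list(k = k_range[best], labels = km$cluster, silhouette = sil,
         weak_structure = max(sil) < 0.5, centers = centers)
  })
}

#' Locate the MI bifurcation point between two regimes
#'
#' Descriptive readout: the minimum of a kernel density estimate of the MI
#' marginal between the two cluster centers.
#'
#' @param mi MI values (bits).
#' @param centers_mi MI coordinates of the two cluster centers.
#' @return MI value (bits) of the density minimum between the centers.
#' @export
mi_bifurcation_point <- function(mi, centers_mi) {
  stopifnot(length(centers_mi) >= 2)
  lo <- min(centers_mi); hi <- max(centers_mi)
  d <- stats::density(mi)
  sel <- d$x >= lo & d$x <= hi
  if (!any(sel)) return(mean(c(lo, hi)))
  d$x[sel][which.min(d$y[sel])]
}
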