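# Bayesian regression machinery: hierarchical linear models with group-level
# slope deviations, simple linear models, and piecewise (knotted) spline
# models, all with MAP + 95% highest-density-interval reporting.
#
# Model: y = X beta + Z u + eps, eps ~ N(0, sigma^2), beta_j ~ N(0, 10^2),
# u_{block b, group g} ~ N(0, tau_b^2), sigma and tau_b ~ half-Normal(10).
# Sampling is blocked Gibbs: all coefficients are drawn jointly from their
# conditional multivariate normal; sigma and each tau move by adaptive
# random-walk Metropolis on the log scale. For this linear-Gaussian family the
# blocked conditional draw mixes essentially perfectly, so modest chain
# lengths give stable MAP/HDI summaries. A parameter is "significant" iff its
# 95% HDI excludes 0 (Bayesian convention used throughout).

#' MCMC sampler settings
#'
#' @param chains number of chains.
#' @param draws post-warmup draws per chain.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed RNG seed.
#' @return list of class `sampler_settings`.
#' @export
sampler_settings <- function(chains = 4L, draws = 2000L, warmup = 1000L,
                             seed = 1L) {
  stopifnot(chains >= 1, draws >= 100, warmup >= 100)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "sampler_settings")
}

rw_update <- function(cur_log, logpost, step) {
  prop <- cur_log + stats::rnorm(1, 0, step)
  if (log(stats::runif(1)) < logpost(prop) - logpost(cur_log)) prop else cur_log
}

gibbs_lm <- function(y, X, Z = NULL, blocks = NULL,
                     prior_sd_beta = 10, prior_scale_sigma = 10,
                     prior_scale_tau = 10, settings = sampler_settings()) {
  # blocks: integer vector over columns of Z assigning each column to a
  # variance block (one tau per block)
  n <- length(y)
  W <- if (is.null(Z)) X else cbind(X, Z)
  p_fix <- ncol(X)
  p_all <- ncol(W)
  n_blocks <- if (is.null(Z)) 0L else max(blocks)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  total <- settings$warmup + settings$draws
  out <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + 1000L * ch)
    sigma <- stats::sd(y); if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    tau <- rep(1, n_blocks)
    step_s <- 0.3; step_t <- rep(0.5, n_blocks)
    theta <- rep(0, p_all)
    keep <- matrix(NA_real_, settings$draws, p_all + 1 + n_blocks)
    for (it in seq_len(total)) {
      # 1. joint conditional normal draw of all coefficients
      prior_prec <- c(rep(1 / prior_sd_beta^2, p_fix),
                      if (n_blocks) 1 / tau[blocks]^2)
      P <- WtW / sigma^2 + diag(prior_prec, p_all)
      U <- chol(P)
      mu <- backsolve(U, forwardsolve(t(U), Wty / sigma^2))
      theta <- drop(mu + backsolve(U, stats::rnorm(p_all)))
      resid <- y - drop(W %*% theta)
      rss <- sum(resid^2)
      # 2. adaptive RW-Metropolis on log sigma (half-normal prior)
      lp_sigma <- function(ls) {
        s <- exp(ls)
        -n * ls - rss / (2 * s^2) - s^2 / (2 * prior_scale_sigma^2) + ls
      }
      new_ls <- rw_update(log(sigma), lp_sigma, step_s)
      acc <- new_ls != log(sigma)
      sigma <- exp(new_ls)
      if (it <= settings$warmup) {
        step_s <- step_s * exp(0.05 * ((if (acc) 1 else 0) - 0.44))
        step_s <- min(max(step_s, 1e-3), 5)
      }
      # 3. tau per block
      if (n_blocks) for (b in seq_len(n_blocks)) {
        ub <- theta[p_fix + which(blocks == b)]
        gb <- length(ub); ss <- sum(ub^2)
        lp_tau <- function(lt) {
          t0 <- exp(lt)
          -gb * lt - ss / (2 * t0^2) - t0^2 / (2 * prior_scale_tau^2) + lt
        }
        new_lt <- rw_update(log(tau[b]), lp_tau, step_t[b])
        acc <- new_lt != log(tau[b])
        tau[b] <- exp(new_lt)
        if (it <= settings$warmup) {
          step_t[b] <- step_t[b] * exp(0.05 * ((if (acc) 1 else 0) - 0.44))
          step_t[b] <- min(max(step_t[b], 1e-3), 5)
        }
      }
      if (it > settings$warmup) {
        keep[it - settings$warmup, ] <- c(theta, sigma, tau)
      }
    }
    out[[ch]] <- keep
  }
  nm <- c(colnames(W),
          "sigma",
          if (n_blocks) paste0("tau_", seq_len(n_blocks)))
  for (ch in seq_along(out)) colnames(out[[ch]]) <- nm
  list(chains = out, W = W, y = y, p_fix = p_fix, names = nm)
}

split_rhat <- function(chains, col) {
  # split-chain potential scale reduction factor
  halves <- list()
  for (m in chains) {
    n2 <- floor(nrow(m) / 2)
    halves[[length(halves) + 1L]] <- m[1:n2, col]
    halves[[length(halves) + 1L]] <- m[(n2 + 1):(2 * n2), col]
  }
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  n2 <- length(halves[[1]])
  B <- n2 * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n2 - 1) / n2 * Wv + B / n2) / Wv)
}

#' Highest-density interval of a sample
#'
#' The narrowest interval containing `prob` posterior mass (narrower than or
#' equal to the equal-tailed interval for any sample).
#'
#' @param x numeric draws.
#' @param prob mass to cover.
#' @return `c(lo, hi)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- 1:(n - m)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

map_estimate <- function(x) {
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Summarize posterior draws: MAP, 95% HDI, significance
#'
#' MAP is the mode of a kernel-smoothed marginal (clamped into the HDI so the
#' invariant `lo <= MAP <= hi` holds even for skewed small samples); a
#' parameter is significant iff its 95% HDI excludes 0. Multimodal marginals
#' (secondary density peak above 60% of the main peak, well-separated) are
#' flagged.
#'
#' @param samples matrix of draws (columns = parameters) or a `gibbs_lm`
#'   result.
#' @param prob HDI mass.
#' @return data.frame of class `posterior_summary`: `term, map, hdi_lo,
#'   hdi_hi, significant, rhat` (rhat `NA` for plain matrices); attribute
#'   `flags` lists multimodal/non-converged parameters.
#' @export
summarize_posterior <- function(samples, prob = 0.95) {
  fit <- NULL
  if (is.list(samples) && !is.null(samples$chains)) {
    fit <- samples
    draws <- do.call(rbind, fit$chains)
  } else {
    draws <- as.matrix(samples)
    if (is.null(colnames(draws)))
      colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  }
  if (nrow(draws) < 1000) warning("fewer than 1000 post-warmup draws")
  flags <- character(0)
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    h <- hdi(x, prob)
    m <- min(max(map_estimate(x), h[1]), h[2])
    if (stats::sd(x) > 0) {
      d <- stats::density(x)
      pk <- which(diff(sign(diff(d$y))) < 0) + 1
      pk <- pk[order(d$y[pk], decreasing = TRUE)]
      if (length(pk) >= 2 && d$y[pk[2]] > 0.6 * d$y[pk[1]] &&
          abs(d$x[pk[1]] - d$x[pk[2]]) > 2 * d$bw * 3) {
        flags <<- c(flags, paste0(nm, ": multimodal marginal"))
      }
    }
    rh <- if (!is.null(fit) && length(fit$chains) > 1)
      split_rhat(fit$chains, nm) else NA_real_
    if (is.finite(rh) && rh > 1.05) {
      flags <<- c(flags, paste0(nm, ": R-hat ", round(rh, 3), " > 1.05"))
    }
    data.frame(term = nm, map = m, hdi_lo = h[1], hdi_hi = h[2],
               significant = h[1] > 0 | h[2] < 0, rhat = rh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "flags") <- flags
  class(out) <- c("posterior_summary", class(out))
  out
}

ppc_pvalue <- function(fit, n_rep = 200L) {
  # posterior-predictive Bayesian p-value for the chi^2-type discrepancy
  draws <- do.call(rbind, fit$chains)
  idx <- round(seq(1, nrow(draws), length.out = min(n_rep, nrow(draws))))
  p_fix_all <- ncol(fit$W)
  hits <- 0
  for (i in idx) {
    th <- draws[i, seq_len(p_fix_all)]
    sg <- draws[i, "sigma"]
    mu <- drop(fit$W %*% th)
    t_obs <- sum((fit$y - mu)^2) / sg^2
    y_rep <- mu + stats::rnorm(length(mu), 0, sg)
    t_rep <- sum((y_rep - mu)^2) / sg^2
    if (t_rep >= t_obs) hits <- hits + 1
  }
  hits / length(idx)
}

#' Bayesian hierarchical linear dose-response regression
#'
#' Fits `ln(response) = b0 + b_E ln(E) + b_ISI ln(ISI) + b_ExISI ln(E) ln(ISI)`
#' with group-level (electrode-within-animal) deviations on the three slopes,
#' each slope block with its own half-normal-scaled SD. Rows with `E = 0` are
#' excluded (log-transform; set `log_offset` to instead use `ln(E + offset)`).
#'
#' @param table data.frame with columns `energy_mJ`, `isi_ms`, the response,
#'   and group keys `animal`, `electrode`.
#' @param response response column name (default `"rms"`).
#' @param log_response take `ln` of the response (default TRUE; set FALSE for
#'   already-log-scale statistics such as dB changes).
#' @param log_offset optional epsilon added to E before the log transform
#'   instead of dropping E = 0 rows.
#' @param settings a [sampler_settings()].
#' @param prior_sd_beta,prior_scale_sigma,prior_scale_tau prior scales.
#' @return list of class `hlr_fit`: `summary` (a [summarize_posterior()] table
#'   for the population-level terms), `full_summary`, `ppc_p`, `n`, `groups`,
#'   `fit` (raw draws).
#' @export
fit_hlr <- function(table, response = "rms", log_response = TRUE,
                    log_offset = NULL, settings = sampler_settings(),
                    prior_sd_beta = 10, prior_scale_sigma = 10,
                    prior_scale_tau = 10) {
  df <- table
  if ("valid" %in% names(df)) df <- df[df$valid %in% TRUE, ]
  if (is.null(log_offset)) {
    df <- df[df$energy_mJ > 0, ]
    lE <- log(df$energy_mJ)
  } else {
    lE <- log(df$energy_mJ + log_offset)
  }
  y <- df[[response]]
  if (log_response) {
    keep <- y > 0
    df <- df[keep, ]; lE <- lE[keep]
    y <- log(y[keep])
  }
  lI <- log(df$isi_ms)
  grp <- factor(paste(df$animal, df$electrode, sep = ":"))
  if (nlevels(grp) < 3) stop("hierarchical slopes need at least 3 groups")
  X <- cbind(intercept = 1, b_E = lE, b_ISI = lI, b_ExISI = lE * lI)
  G <- stats::model.matrix(~ grp - 1)
  Z <- cbind(G * lE, G * lI, G * (lE * lI))
  colnames(Z) <- c(paste0("u_E.", levels(grp)), paste0("u_ISI.", levels(grp)),
                   paste0("u_ExISI.", levels(grp)))
  blocks <- rep(1:3, each = nlevels(grp))
  fit <- gibbs_lm(y, X, Z, blocks, prior_sd_beta, prior_scale_sigma,
                  prior_scale_tau, settings)
  full <- summarize_posterior(fit)
  structure(list(
    summary = full[full$term %in% c("intercept", "b_E", "b_ISI", "b_ExISI",
                                    "sigma"), ],
    full_summary = full, ppc_p = ppc_pvalue(fit), n = length(y),
    groups = levels(grp), fit = fit), class = "hlr_fit")
}

#' Simple Bayesian linear regression
#'
#' @param y response vector.
#' @param X design matrix (include the intercept column).
#' @param settings a [sampler_settings()].
#' @param prior_sd_beta,prior_scale_sigma prior scales.
#' @return list of class `blr_fit` with `summary`, `ppc_p`, `fit`.
#' @export
fit_blr <- function(y, X, settings = sampler_settings(), prior_sd_beta = 10,
                    prior_scale_sigma = 10) {
  fit <- gibbs_lm(y, X, settings = settings, prior_sd_beta = prior_sd_beta,
                  prior_scale_sigma = prior_scale_sigma)
  structure(list(summary = summarize_posterior(fit), ppc_p = ppc_pvalue(fit),
                 fit = fit), class = "blr_fit")
}

#' Spike-rate / N1-P2 RMS Bayesian regression
#'
#' `ln(RMS) = a + b_spikerate ln(rate) + b_ISI ln(ISI)`, where the spike rate
#' is averaged over the stimulus interval plus a 50 ms offset. Rows with zero
#' rate or RMS are excluded (log transform).
#'
#' @param table data.frame with columns `rms`, `spike_rate`, `isi_ms`.
#' @param settings a [sampler_settings()].
#' @return `blr_fit` with terms `intercept`, `b_spikerate`, `b_ISI`.
#' @export
fit_spike_lfp_lr <- function(table, settings = sampler_settings()) {
  df <- table[table$spike_rate > 0 & table$rms > 0, ]
  if (!nrow(df)) stop("no rows with positive spike rate and RMS")
  X <- cbind(intercept = 1, b_spikerate = log(df$spike_rate),
             b_ISI = log(df$isi_ms))
  fit_blr(log(df$rms), X, settings)
}

#' Mean spike rate over the stimulus interval (+50 ms) per trial
#'
#' @param ts a [trial_set()] with spikes.
#' @param unit unit name.
#' @param offset_s window extension past the train end (default 50 ms).
#' @return data.frame `animal, electrode, trial, energy_mJ, isi_ms,
#'   spike_rate`.
#' @export
stimulus_spike_rates <- function(ts, unit = "u1", offset_s = 0.05) {
  rows <- lapply(ts$trials, function(tr) {
    st <- tr$stimulus
    w0 <- st$prestim_s
    w1 <- min(st$prestim_s + st$train_duration_s + offset_s, st$trial_length_s)
    sp <- tr$spikes[[unit]]
    rate <- if (is.null(sp)) 0 else sum(sp >= w0 & sp < w1) / (w1 - w0)
    data.frame(animal = tr$animal, electrode = tr$electrode, trial = tr$trial,
               energy_mJ = st$energy_mJ, isi_ms = st$isi_ms,
               spike_rate = rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locate a knot (step discontinuity) in mean SFC versus energy
#'
#' Computes the derivative of mean SFC with respect to `ln(E)` and places the
#' knot at the interior energy with the largest jump in that derivative. If no
#' jump exceeds twice the median absolute jump (plus a numerical floor), the
#' verdict is "no knot" and a plain linear model should be used.
#'
#' @param energy_mJ energies (>= 8 distinct values).
#' @param mean_sfc mean SFC at each energy.
#' @return list: `knot_mJ` (`NA` when none), `has_knot`, `jumps`.
#' @export
find_knot <- function(energy_mJ, mean_sfc) {
  o <- order(energy_mJ)
  e <- energy_mJ[o]; s <- mean_sfc[o]
  if (length(unique(e)) < 8) stop("need at least 8 energy points")
  le <- log(e)
  d <- diff(s) / diff(le)                    # derivative over ln(E)
  jumps <- abs(diff(d))                      # step discontinuity candidates
  floor_tol <- 1e-8 * max(abs(d), 1e-12)
  thresh <- 2 * stats::median(jumps) + floor_tol
  if (max(jumps) <= thresh) {
    return(list(knot_mJ = NA_real_, has_knot = FALSE, jumps = jumps))
  }
  list(knot_mJ = e[which.max(jumps) + 1L], has_knot = TRUE, jumps = jumps)
}

#' Piecewise (basis-spline) Bayesian SFC regression with a fixed knot
#'
#' Continuous two-segment linear model in `ln(E)`:
#' `SFC = alpha + b_below * min(lnE, ln t) + b_above * max(lnE - ln t, 0)`,
#' so each slope term only influences its own energy domain. Per-segment
#' significance is the HDI-excludes-0 rule.
#'
#' @param energy_mJ energies.
#' @param sfc SFC observations.
#' @param knot_mJ the knot from [find_knot()].
#' @param settings a [sampler_settings()].
#' @return `blr_fit` with terms `intercept`, `b_below`, `b_above`; segments
#'   with fewer than 4 points are flagged in `$flags`.
#' @export
fit_spline_sfc <- function(energy_mJ, sfc, knot_mJ,
                           settings = sampler_settings()) {
  le <- log(energy_mJ); lt <- log(knot_mJ)
  X <- cbind(intercept = 1, b_below = pmin(le, lt),
             b_above = pmax(le - lt, 0))
  fit <- fit_blr(sfc, X, settings)
  flags <- character(0)
  if (sum(energy_mJ < knot_mJ) < 4) flags <- c(flags, "below-knot segment has < 4 points")
  if (sum(energy_mJ >= knot_mJ) < 4) flags <- c(flags, "above-knot segment has < 4 points")
  fit$flags <- flags
  fit
}
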