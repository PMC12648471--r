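# Wavelet time-frequency decomposition and band-power statistics.
#
# The decomposition is an analytic Morlet continuous wavelet transform
# implemented as a constant-Q Gaussian filter bank in the FFT domain
# (center-frequency parameter omega0 = 6, 12 voices per octave). S_f is a
# one-sided power spectral density normalized so that for a band-limited
# signal, P_f = 2 * integral of the time-averaged S_f over the band
# approximates the time-domain power (the factor 2 accounting for the
# negative-frequency half).

#' Canonical LFP band definitions
#'
#' @return named list of `c(f_lo, f_hi)` Hz pairs: theta (4-8), alpha (8-13),
#'   beta (13-30), gamma_low (30-80), gamma_high (80-200).
#' @export
lfp_bands <- function() band_edges_hz()

#' Continuous wavelet power decomposition
#'
#' @param x numeric LFP vector (at the 1526 Hz analysis rate; for band
#'   analyses only the 3 Hz hardware high-pass is assumed, not the 10 Hz
#'   drift filter).
#' @param rate sampling rate, Hz.
#' @param freqs frequency grid, Hz; default log-spaced, 12 voices per octave,
#'   covering 4-200 Hz. All frequencies must lie in (0, Nyquist).
#' @param omega0 Morlet center-frequency parameter (quality factor).
#' @return object of class `cwt_power`: `freqs`, `rate`, `power` (an
#'   nfreq-by-ntime one-sided PSD matrix, units x^2/Hz), and `coi_s`,
#'   the per-frequency cone-of-influence edge margin in seconds.
#' @export
cwt_decompose <- function(x, rate, freqs = NULL, omega0 = 6) {
  if (is.null(freqs)) {
    n_oct <- log2(200 / 4)
    freqs <- 4 * 2^(seq(0, n_oct, by = 1 / 12))
  }
  if (any(freqs <= 0) || any(freqs >= rate / 2)) {
    stop("frequency grid must lie strictly inside (0, Nyquist)")
  }
  n <- length(x)
  X <- stats::fft(x)
  fgrid <- (0:(n - 1)) * rate / n
  pos <- fgrid <= rate / 2
  power <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sf <- f0 / omega0
    H <- numeric(n)
    H[pos] <- 2 * exp(-((fgrid[pos] - f0)^2) / (2 * sf^2))
    H[1] <- H[1] / 2      # DC bin is its own conjugate
    w <- stats::fft(X * H, inverse = TRUE) / n
    # one-sided PSD: time-averaged |w|^2 integrates (over f) to the
    # analytic-signal power; 1/(4 sqrt(pi) sf) calibrates the Gaussian bank
    power[k, ] <- Mod(w)^2 / (4 * sqrt(pi) * sf)
  }
  structure(list(freqs = freqs, rate = rate, power = power, n = n,
                 coi_s = sqrt(2) * omega0 / (2 * pi * freqs)),
            class = "cwt_power")
}

#' Composite Simpson integration on a (possibly nonuniform) grid
#'
#' Exact for quadratics on any grid; falls back to the trapezoid rule (with a
#' warning) when fewer than 3 points are available.
#'
#' @param x ordered abscissae.
#' @param y integrand values.
#' @return the integral estimate.
#' @export
simpson_int <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) return(0)
  if (n < 3) {
    warning("fewer than 3 grid points: falling back to trapezoid rule")
    return(sum(diff(x) * (y[-n] + y[-1]) / 2))
  }
  total <- 0
  i <- 1
  while (i + 2 <= n) {
    h0 <- x[i + 1] - x[i]; h1 <- x[i + 2] - x[i + 1]
    total <- total + (h0 + h1) / 6 *
      ((2 - h1 / h0) * y[i] +
         (h0 + h1)^2 / (h0 * h1) * y[i + 1] +
         (2 - h0 / h1) * y[i + 2])
    i <- i + 2
  }
  if (i < n) {
    # one interval left over: integrate the quadratic through the last three
    # points over [x_{n-1}, x_n] (keeps quadratic exactness)
    xs <- x[(n - 2):n]; ys <- y[(n - 2):n]
    cf <- solve(cbind(1, xs, xs^2), ys)
    anti <- function(t) cf[1] * t + cf[2] * t^2 / 2 + cf[3] * t^3 / 3
    total <- total + anti(x[n]) - anti(x[n - 1])
  }
  unname(total)
}

coi_mask <- function(cw, k, idx) {
  # drop samples of window idx inside the cone of influence at frequency k;
  # if that empties the window, keep the full window (flagged upstream)
  margin <- ceiling(cw$coi_s[k] * cw$rate)
  keep <- idx[idx > margin & idx <= cw$n - margin]
  if (length(keep)) keep else idx
}

#' Integrated band power over a time window
#'
#' `P_f = 2 * integral(S_f df)` over the band, Simpson's rule on the grid,
#' where `S_f` is the time-averaged wavelet PSD over the window
#' (cone-of-influence samples excluded).
#'
#' @param cw a [cwt_decompose()] result.
#' @param band `c(f_lo, f_hi)` Hz, or a band name from [lfp_bands()].
#' @param window `c(start, end)` seconds (half-open), or `NULL` for the whole
#'   series.
#' @return integrated band power (signal units squared).
#' @export
band_power <- function(cw, band, window = NULL) {
  stopifnot(inherits(cw, "cwt_power"))
  if (is.character(band)) band <- lfp_bands()[[band]]
  sel <- which(cw$freqs >= band[1] & cw$freqs <= band[2])
  if (!length(sel)) stop("no grid frequencies inside band")
  idx <- if (is.null(window)) seq_len(cw$n)
    else window_samples(window, cw$rate, cw$n)
  if (!length(idx)) stop("empty time window")
  sbar <- vapply(sel, function(k) mean(cw$power[k, coi_mask(cw, k, idx)]),
                 numeric(1))
  2 * simpson_int(cw$freqs[sel], sbar)
}

#' Stimulus-induced band power change in dB
#'
#' @param p_f band power in the analysis window.
#' @param mu_b mean baseline band power (must be > 0).
#' @return `10 * log10(p_f / mu_b)`; `NA` with a warning when `mu_b` is 0.
#' @export
db_change <- function(p_f, mu_b) {
  if (any(mu_b <= 0)) {
    warning("baseline power is zero: dB change undefined")
    return(ifelse(mu_b > 0, 10 * log10(p_f / mu_b), NA_real_))
  }
  10 * log10(p_f / mu_b)
}

band_db_timecourse <- function(cw, band, baseline_window) {
  # instantaneous integrated band power and its dB change from baseline
  if (is.character(band)) band <- lfp_bands()[[band]]
  sel <- which(cw$freqs >= band[1] & cw$freqs <= band[2])
  pf_t <- 2 * apply(cw$power[sel, , drop = FALSE], 2, function(col)
    simpson_int(cw$freqs[sel], col))
  mu_b <- band_power(cw, band, baseline_window)
  list(pf_t = pf_t, mu_b = mu_b, db_t = 10 * log10(pf_t / mu_b))
}

#' Band-power results table for a trial set
#'
#' For each (animal, electrode, energy, ISI) condition the trial-mean LFP is
#' wavelet-decomposed and, per band and window (onset, offset), the integrated
#' power, baseline power, window dB change, and the regression statistic
#' (`max` dB over the onset window, `mean` dB over the offset window) are
#' reported.
#'
#' @param ts a [trial_set()] (raw LFPs; only the hardware 3 Hz high-pass is
#'   assumed).
#' @param bands named list of band edges (default [lfp_bands()]).
#' @return data.frame `animal, electrode, energy_mJ, isi_ms, window, band,
#'   power, baseline_power, db_change, stat_db`.
#' @export
band_power_results <- function(ts, bands = lfp_bands()) {
  stopifnot(inherits(ts, "trial_set"))
  tt <- trial_table(ts)
  key <- interaction(tt$animal, tt$electrode, tt$energy_mJ, tt$isi_ms,
                     drop = TRUE)
  rows <- list()
  for (g in levels(key)) {
    idx <- tt$row[key == g]
    tr1 <- ts$trials[[idx[1]]]
    lfp <- rowMeans(vapply(idx, function(i) ts$trials[[i]]$lfp,
                           numeric(length(tr1$lfp))))
    win <- compute_windows(tr1$stimulus)
    cw <- cwt_decompose(lfp, tr1$rate)
    for (b in names(bands)) {
      tc <- band_db_timecourse(cw, bands[[b]], win$baseline)
      for (w in c("onset", "offset")) {
        wi <- window_samples(win[[w]], tr1$rate, cw$n)
        if (!length(wi)) next
        p_f <- band_power(cw, bands[[b]], win[[w]])
        stat <- if (w == "onset") max(tc$db_t[wi]) else mean(tc$db_t[wi])
        rows[[length(rows) + 1L]] <- data.frame(
          animal = tr1$animal, electrode = tr1$electrode,
          energy_mJ = tr1$stimulus$energy_mJ, isi_ms = tr1$stimulus$isi_ms,
          window = w, band = b, power = p_f, baseline_power = tc$mu_b,
          db_change = db_change(p_f, tc$mu_b), stat_db = stat,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlation between two numeric series with a shuffle-surrogate p
#'
#' Two-sided p: probability that `|R|` of one series shuffled against the
#' other is at least the observed `|R|`, with the +1 permutation correction.
#'
#' @param x,y paired observations.
#' @param n_shuffle number of shuffles.
#' @param seed RNG seed.
#' @return list `r`, `p`.
#' @export
cor_shuffle_test <- function(x, y, n_shuffle = 1000, seed = 1L) {
  r <- stats::cor(x, y)
  with_seed(seed, {
    rs <- vapply(seq_len(n_shuffle), function(i)
      stats::cor(sample(x), y), numeric(1))
    p <- (1 + sum(abs(rs) >= abs(r))) / (n_shuffle + 1)
    list(r = r, p = p)
  })
}

#' Between-band power correlations within energy bins
#'
#' @param results a [band_power_results()] table.
#' @param pair two band names, e.g. `c("beta", "gamma_low")`.
#' @param window `"onset"` or `"offset"`.
#' @param energy_bin_width bin width in mJ (default 0.5, i.e. 500 uJ).
#' @param n_shuffle shuffle count for the surrogate p.
#' @param seed RNG seed.
#' @param min_pairs bins with fewer paired observations are skipped.
#' @return data.frame `bin_lo, bin_hi, n, r, p` (skipped bins omitted).
#' @export
band_correlations <- function(results, pair, window = "onset",
                              energy_bin_width = 0.5, n_shuffle = 1000,
                              seed = 1L, min_pairs = 3L) {
  a <- results[results$band == pair[1] & results$window == window, ]
  b <- results[results$band == pair[2] & results$window == window, ]
  key <- c("animal", "electrode", "energy_mJ", "isi_ms")
  m <- merge(a, b, by = key, suffixes = c("_1", "_2"))
  bins <- floor(m$energy_mJ / energy_bin_width)
  out <- list()
  for (bn in sort(unique(bins))) {
    sub <- m[bins == bn, ]
    if (nrow(sub) < min_pairs) {
      message("energy bin [", bn * energy_bin_width, ", ",
              (bn + 1) * energy_bin_width, ") skipped: ", nrow(sub),
              " pairs < ", min_pairs)
      next
    }
    ct <- cor_shuffle_test(sub$power_1, sub$power_2, n_shuffle, seed + bn)
    out[[length(out) + 1L]] <- data.frame(
      bin_lo = bn * energy_bin_width, bin_hi = (bn + 1) * energy_bin_width,
      n = nrow(sub), r = ct$r, p = ct$p)
  }
  if (!length(out)) return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                      n = integer(0), r = numeric(0),
                                      p = numeric(0)))
  do.call(rbind, out)
}
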