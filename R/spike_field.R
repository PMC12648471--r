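# Spike-field coherence: normalized magnitude of the trial-averaged
# spike-LFP cross power spectral density,
#   SFC(f) = |<S_ny>| / (sqrt(<S_nn>) sqrt(<S_yy>)),
# bounded in [0, 1] by Cauchy-Schwarz; 1 = perfect across-trial phase locking.

#' Spike-field coherence spectrum
#'
#' Spike trains are binarized onto the LFP sample grid within the analysis
#' window; both the (mean-removed) spike indicator and LFP are Hann-tapered
#' and per-trial cross- and auto-spectra averaged across trials before
#' normalization.
#'
#' @param spike_trains list (one element per trial) of spike-time vectors, s.
#' @param lfps list (same length) of LFP vectors, or a samples-by-trials
#'   matrix.
#' @param rate sampling rate, Hz.
#' @param window `c(start, end)` s analysis window (typically the onset
#'   window).
#' @param min_trials minimum trial count (default 5; a single trial gives
#'   SFC = 1 identically and is refused unless `min_trials` is lowered).
#' @return object of class `sfc_spectrum`: `freqs` (Hz), `sfc` in \[0, 1\]
#'   (`NA` where the averaged auto-spectra vanish), `n_trials`, `defined`
#'   (FALSE with all-`NA` sfc when no trial contains a spike).
#' @export
compute_sfc <- function(spike_trains, lfps, rate, window, min_trials = 5L) {
  if (is.matrix(lfps)) lfps <- lapply(seq_len(ncol(lfps)), function(j) lfps[, j])
  n_trials <- length(spike_trains)
  stopifnot(length(lfps) == n_trials)
  if (n_trials < min_trials) stop("need at least ", min_trials, " trials")
  n_full <- length(lfps[[1]])
  idx <- window_samples(window, rate, n_full)
  nw <- length(idx)
  w <- hann_window(nw)
  freqs <- (0:(floor(nw / 2))) * rate / nw
  s_ny <- complex(length(freqs))
  s_nn <- numeric(length(freqs))
  s_yy <- numeric(length(freqs))
  any_spike <- FALSE
  for (j in seq_len(n_trials)) {
    spk <- numeric(nw)
    st <- spike_trains[[j]]
    if (length(st)) {
      bins <- floor(st * rate) + 1L
      bins <- bins[bins %in% idx]
      if (length(bins)) {
        any_spike <- TRUE
        tb <- tabulate(match(bins, idx), nbins = nw)
        spk <- tb
      }
    }
    y <- lfps[[j]][idx]
    nf <- stats::fft(w * (spk - mean(spk)))[seq_along(freqs)]
    yf <- stats::fft(w * (y - mean(y)))[seq_along(freqs)]
    s_ny <- s_ny + nf * Conj(yf)
    s_nn <- s_nn + Mod(nf)^2
    s_yy <- s_yy + Mod(yf)^2
  }
  if (!any_spike) {
    warning("no spikes in any trial: SFC undefined")
    return(structure(list(freqs = freqs, sfc = rep(NA_real_, length(freqs)),
                          n_trials = n_trials, defined = FALSE),
                     class = "sfc_spectrum"))
  }
  denom <- sqrt(s_nn / n_trials) * sqrt(s_yy / n_trials)
  sfc <- ifelse(denom > 0, Mod(s_ny / n_trials) / denom, NA_real_)
  structure(list(freqs = freqs, sfc = sfc, n_trials = n_trials,
                 defined = TRUE),
            class = "sfc_spectrum")
}

#' Band-averaged spike-field coherence
#'
#' @param spectrum a [compute_sfc()] result.
#' @param band `c(f_lo, f_hi)` Hz or a band name from [lfp_bands()].
#' @return mean SFC over the band's frequency bins.
#' @export
band_sfc <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "sfc_spectrum"))
  if (is.character(band)) band <- lfp_bands()[[band]]
  sel <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside band")
  mean(spectrum$sfc[sel], na.rm = TRUE)
}

#' Per-energy band SFC table for a trial set
#'
#' Groups trials by (animal, electrode, energy), computes the onset-window SFC
#' for the named unit, and averages it over each LFP band.
#'
#' @param ts a [trial_set()] with spike trains attached.
#' @param unit unit name.
#' @param bands named band list.
#' @param min_trials minimum trials per group.
#' @return data.frame `unit, animal, electrode, energy_mJ, band, sfc, n_trials`.
#' @export
sfc_table <- function(ts, unit = "u1", bands = lfp_bands(), min_trials = 5L) {
  tt <- trial_table(ts)
  key <- interaction(tt$animal, tt$electrode, tt$energy_mJ, drop = TRUE)
  rows <- list()
  for (g in levels(key)) {
    idx <- tt$row[key == g]
    if (length(idx) < min_trials) next
    tr1 <- ts$trials[[idx[1]]]
    win <- compute_windows(tr1$stimulus)$onset
    spk <- lapply(idx, function(i) ts$trials[[i]]$spikes[[unit]])
    lf <- lapply(idx, function(i) ts$trials[[i]]$lfp)
    sp <- tryCatch(compute_sfc(spk, lf, tr1$rate, win,
                               min_trials = min_trials),
                   warning = function(w) NULL)
    if (is.null(sp) || !sp$defined) next
    for (b in names(bands)) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, animal = tr1$animal, electrode = tr1$electrode,
        energy_mJ = tr1$stimulus$energy_mJ, band = b,
        sfc = band_sfc(sp, bands[[b]]), n_trials = sp$n_trials,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
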