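# Rate conversion, drift filtering, PSTH construction, and unit-responsiveness
# classification.

#' Anti-aliased downsampling of a trial LFP
#'
#' Low-pass filters (8th-order Butterworth at 0.8x the target Nyquist, applied
#' forward-backward) then decimates by an integer factor. The stored rate is
#' snapped to `target_rate` when the achieved rate differs by < 0.1% (nominal
#' rate convention, e.g. 24414.0625 Hz / 16 = 1525.88 Hz recorded as 1526 Hz).
#'
#' @param trial a [trial_recording()].
#' @param target_rate requested output rate, Hz (default the 1526 Hz analysis
#'   rate).
#' @return a [trial_recording()] at the target rate.
#' @export
downsample_lfp <- function(trial, target_rate = 1526) {
  stopifnot(inherits(trial, "trial_recording"))
  if (target_rate > trial$rate) stop("cannot upsample: target rate above input rate")
  if (abs(target_rate - trial$rate) / trial$rate < 1e-3) return(trial)
  factor <- round(trial$rate / target_rate)
  achieved <- trial$rate / factor
  if (abs(achieved - target_rate) / target_rate > 1e-3) {
    stop("rate ratio ", format(trial$rate / target_rate),
         " is not close to an integer decimation factor")
  }
  lp <- butter_design(8, 0.8 / factor, "low")
  y <- filtfilt(lp, trial$lfp)
  y <- y[seq(1, length(y), by = factor)]
  out_rate <- if (abs(achieved - target_rate) / target_rate < 1e-3)
    target_rate else achieved
  n_expect <- round(trial$stimulus$trial_length_s * out_rate)
  y <- y[seq_len(min(length(y), n_expect))]
  if (length(y) < n_expect) y <- c(y, rep(y[length(y)], n_expect - length(y)))
  trial_recording(y, out_rate, trial$spikes, trial$stimulus,
                  trial$animal, trial$electrode, trial$trial)
}

#' Remove slow baseline drift with a zero-phase Chebyshev II high-pass
#'
#' Order 4, 40 dB stopband attenuation, default 10 Hz cutoff, applied
#' forward-backward so N1/P2 latencies are not shifted. The mean (DC) is
#' removed before filtering.
#'
#' @param trial a [trial_recording()].
#' @param cutoff_hz high-pass cutoff, Hz (must be below Nyquist).
#' @return filtered [trial_recording()].
#' @export
highpass_drift <- function(trial, cutoff_hz = 10) {
  stopifnot(inherits(trial, "trial_recording"), cutoff_hz < trial$rate / 2)
  hp <- cheby2_design(4, 40, cutoff_hz / (trial$rate / 2), "high")
  y <- filtfilt(hp, trial$lfp - mean(trial$lfp))
  trial_recording(y, trial$rate, trial$spikes, trial$stimulus,
                  trial$animal, trial$electrode, trial$trial)
}

#' Drift-filter every trial of a set in one batch
#'
#' Same filter as [highpass_drift()], applied column-wise to all trials of
#' equal length at once (much faster than per-trial filtering).
#'
#' @param ts a [trial_set()].
#' @param cutoff_hz high-pass cutoff, Hz.
#' @return the trial set with filtered LFPs.
#' @export
highpass_trialset <- function(ts, cutoff_hz = 10) {
  stopifnot(inherits(ts, "trial_set"))
  lens <- vapply(ts$trials, function(tr) length(tr$lfp), integer(1))
  rates <- vapply(ts$trials, function(tr) tr$rate, numeric(1))
  for (grp in split(seq_along(ts$trials), paste(lens, rates))) {
    rate <- rates[grp[1]]
    hp <- cheby2_design(4, 40, cutoff_hz / (rate / 2), "high")
    X <- vapply(grp, function(i) {
      x <- ts$trials[[i]]$lfp
      x - mean(x)
    }, numeric(lens[grp[1]]))
    Y <- filtfilt(hp, X)
    for (j in seq_along(grp)) {
      i <- grp[j]
      tr <- ts$trials[[i]]
      ts$trials[[i]] <- trial_recording(Y[, j], tr$rate, tr$spikes,
                                        tr$stimulus, tr$animal, tr$electrode,
                                        tr$trial)
    }
  }
  ts
}

#' Peri-stimulus time histogram across trials
#'
#' @param ts a [trial_set()]; all trials must share geometry.
#' @param unit unit name to histogram.
#' @param bin_width_s PSTH bin width, s (default 10 ms, resolving 5-pulse
#'   trains at short ISIs).
#' @return object of class `psth`: bin `edges` (s), per-bin `rate` (Hz,
#'   count / (n_trials * bin_width)), and spontaneous `spont_mean`/`spont_sd`
#'   (Hz) computed over baseline bins.
#' @export
build_psth <- function(ts, unit = NULL, bin_width_s = 0.01) {
  stopifnot(inherits(ts, "trial_set"), bin_width_s > 0)
  n_trials <- length(ts$trials)
  if (n_trials == 0) stop("PSTH requires at least one trial")
  stim <- ts$trials[[1]]$stimulus
  edges <- seq(0, stim$trial_length_s, by = bin_width_s)
  if (edges[length(edges)] < stim$trial_length_s)
    edges <- c(edges, stim$trial_length_s)
  counts <- numeric(length(edges) - 1)
  # per-trial baseline rates for spontaneous statistics
  base_end <- stim$prestim_s
  base_rates <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- ts$trials[[i]]
    sp <- if (is.null(unit)) unlist(tr$spikes, use.names = FALSE)
      else tr$spikes[[unit]]
    if (is.null(sp)) sp <- numeric(0)
    if (length(sp)) {
      h <- findInterval(sp, edges, rightmost.closed = TRUE)
      h <- h[h >= 1 & h <= length(counts)]
      counts <- counts + tabulate(h, nbins = length(counts))
      base_rates[i] <- sum(sp < base_end) / base_end
    }
  }
  widths <- diff(edges)
  structure(
    list(edges = edges, rate = counts / (n_trials * widths),
         spont_mean = mean(base_rates), spont_sd = stats::sd(base_rates),
         n_trials = n_trials,
         windows = compute_windows(stim)),
    class = "psth")
}

#' Classify a unit as INS-responsive
#'
#' A unit is responsive if any PSTH bin inside the stimulus (onset) window has
#' a firing-rate z-score of at least 3.92 (2 x 1.96) above the mean
#' spontaneous rate, the z-score computed against the across-trial baseline
#' rate SD. The threshold is inclusive.
#'
#' @param psth a [build_psth()] result.
#' @param threshold z threshold (default 3.92).
#' @return list: `responsive` (logical), `max_z`, and `note` ("undefined z;
#'   responsive by nonzero evoked count" when the spontaneous SD is zero but
#'   evoked spikes exist).
#' @export
classify_responsive <- function(psth, threshold = 3.92) {
  stopifnot(inherits(psth, "psth"))
  on <- psth$windows$onset
  centers <- (psth$edges[-1] + psth$edges[-length(psth$edges)]) / 2
  stim_bins <- centers >= on[1] & centers < on[2]
  rates <- psth$rate[stim_bins]
  if (psth$spont_sd == 0 || !is.finite(psth$spont_sd)) {
    evoked <- any(rates > 0)
    return(list(responsive = evoked, max_z = NA_real_,
                note = if (evoked)
                  "undefined z; responsive by nonzero evoked count"
                else "undefined z; no evoked spikes"))
  }
  z <- (rates - psth$spont_mean) / psth$spont_sd
  list(responsive = max(z) >= threshold, max_z = max(z), note = NULL)
}
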