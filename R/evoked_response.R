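# N1-P2 detection and RMS dose-response features.
#
# The evoked-magnitude statistic is the RMS of the (high-pass filtered) LFP
# from stimulus onset through the P2 peak sample, where N1 is the first local
# minimum after onset with baseline z <= -2 and P2 the first subsequent local
# maximum with z >= +2, both inside the train-end + 150 ms search window.

local_extrema <- function(x) {
  # indices of strict-or-plateau local minima and maxima (ties -> earliest)
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  turn <- diff(s)
  list(minima = which(turn > 0) + 1L, maxima = which(turn < 0) + 1L)
}

zoo_locf <- function(s) {
  # forward-fill NAs (plateau handling); leading NAs become +1
  if (all(is.na(s))) return(rep(1, length(s)))
  idx <- cummax(ifelse(is.na(s), 0L, seq_along(s)))
  out <- ifelse(idx == 0L, 1, s[pmax(idx, 1L)])
  out
}

#' Detect the N1-P2 complex in a single trial
#'
#' @param trial a [trial_recording()], already 10 Hz high-pass filtered (see
#'   [highpass_drift()]).
#' @param windows optional [compute_windows()] result (recomputed otherwise).
#' @param z_threshold peak significance threshold in baseline SD units
#'   (default 2).
#' @return object of class `n1p2_feature`: `n1_time`, `p2_time` (s), `n1_z`,
#'   `p2_z`, `rms` (uV), `valid`, `reason`, and the trial's identifying keys.
#' @export
detect_n1p2 <- function(trial, windows = NULL, z_threshold = 2) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(windows)) windows <- compute_windows(trial$stimulus)
  x <- trial$lfp
  n <- length(x)
  base_i <- window_samples(windows$baseline, trial$rate, n)
  search_i <- window_samples(windows$n1p2_search, trial$rate, n)
  feat <- list(n1_time = NA_real_, p2_time = NA_real_, n1_z = NA_real_,
               p2_z = NA_real_, rms = NA_real_, valid = FALSE, reason = NULL,
               animal = trial$animal, electrode = trial$electrode,
               trial = trial$trial, energy_mJ = trial$stimulus$energy_mJ,
               isi_ms = trial$stimulus$isi_ms)
  class(feat) <- "n1p2_feature"
  mu <- mean(x[base_i]); sdv <- stats::sd(x[base_i])
  if (!is.finite(sdv) || sdv == 0) {
    feat$reason <- "baseline SD is zero"
    return(feat)
  }
  z <- (x - mu) / sdv
  ext <- local_extrema(x)
  mins <- ext$minima[ext$minima %in% search_i]
  n1 <- mins[z[mins] <= -z_threshold]
  if (!length(n1)) {
    feat$reason <- "no significant negative peak"
    return(feat)
  }
  n1 <- n1[1]
  maxs <- ext$maxima[ext$maxima %in% search_i & ext$maxima > n1]
  p2 <- maxs[z[maxs] >= z_threshold]
  if (!length(p2)) {
    feat$reason <- "no significant positive peak after N1"
    feat$n1_time <- (n1 - 1) / trial$rate
    feat$n1_z <- z[n1]
    return(feat)
  }
  p2 <- p2[1]
  feat$n1_time <- (n1 - 1) / trial$rate
  feat$p2_time <- (p2 - 1) / trial$rate
  feat$n1_z <- z[n1]
  feat$p2_z <- z[p2]
  feat$valid <- TRUE
  feat$rms <- rms_n1p2(trial, feat, windows)
  feat
}

#' RMS magnitude from stimulus onset through the P2 sample
#'
#' @param trial a [trial_recording()].
#' @param feature a valid [detect_n1p2()] feature.
#' @param windows optional precomputed windows.
#' @return RMS in the LFP's units; `NA` (with a warning) for invalid features.
#' @export
rms_n1p2 <- function(trial, feature, windows = NULL) {
  if (!isTRUE(feature$valid) && is.na(feature$p2_time)) {
    warning("RMS undefined for invalid N1-P2 feature")
    return(NA_real_)
  }
  if (is.null(windows)) windows <- compute_windows(trial$stimulus)
  onset_i <- window_samples(windows$onset, trial$rate, length(trial$lfp))[1]
  p2_i <- round(feature$p2_time * trial$rate) + 1L
  sqrt(mean(trial$lfp[onset_i:p2_i]^2))
}

#' Per-trial dose-response table
#'
#' Runs N1-P2 detection on every trial (after 10 Hz high-pass filtering unless
#' `prefiltered = TRUE`) and collects valid features into a regression-ready
#' table with hierarchical group keys.
#'
#' @param ts a [trial_set()].
#' @param prefiltered set TRUE if trials are already drift-filtered.
#' @return data.frame `animal, electrode, trial, energy_mJ, isi_ms, rms, valid`;
#'   invalid trials keep their row with `valid = FALSE` and `rms = NA`.
#' @export
dose_response_table <- function(ts, prefiltered = FALSE) {
  stopifnot(inherits(ts, "trial_set"))
  if (!prefiltered) ts <- highpass_trialset(ts)
  rows <- lapply(ts$trials, function(tr) {
    f <- detect_n1p2(tr)
    data.frame(animal = tr$animal, electrode = tr$electrode, trial = tr$trial,
               energy_mJ = tr$stimulus$energy_mJ, isi_ms = tr$stimulus$isi_ms,
               rms = f$rms, valid = f$valid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$valid)) warning("no valid N1-P2 features in trial set")
  out
}
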