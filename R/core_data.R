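# Domain types and on-disk I/O for trial-epoched INS recordings.
#
# Conventions: time is in seconds, trial-relative (0 = trial start); sample
# indices are 0-based in documentation and 1-based in R code; analysis windows
# are half-open [start, end). LFP samples are snapped to float32-representable
# doubles at construction so that the float32 on-disk format round-trips
# bit-exactly.

as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

#' Laser pulse-train stimulus description
#'
#' @param energy_mJ energy per pulse, mJ, in \[0, 4.5\].
#' @param isi_ms interpulse stimulus interval (offset-to-onset gap), ms,
#'   in \[0.2, 100\].
#' @param n_pulses number of pulses in the train (>= 1).
#' @param pulse_width_ms optical pulse width, ms, in \[0.1, 100\]. Defaults to
#'   10 ms (mid-range of hardware capability) when a dataset does not record it.
#' @param prestim_s prestimulus (baseline) interval, s.
#' @param trial_length_s total trial length, s.
#' @return object of class `stimulus_train`.
#' @export
stimulus_train <- function(energy_mJ, isi_ms, n_pulses = 5L,
                           pulse_width_ms = 10, prestim_s = 0.2,
                           trial_length_s = 1) {
  energy_mJ <- as.numeric(energy_mJ)
  isi_ms <- as.numeric(isi_ms)
  pulse_width_ms <- as.numeric(pulse_width_ms)
  prestim_s <- as.numeric(prestim_s)
  trial_length_s <- as.numeric(trial_length_s)
  stopifnot(
    energy_mJ >= 0, energy_mJ <= 4.5,
    isi_ms >= 0.2, isi_ms <= 100,
    n_pulses >= 1,
    pulse_width_ms >= 0.1, pulse_width_ms <= 100,
    prestim_s >= 0, trial_length_s > 0
  )
  dur_s <- (n_pulses * pulse_width_ms + (n_pulses - 1) * isi_ms) / 1000
  if (prestim_s + dur_s > trial_length_s) {
    stop("invalid stimulus: pulse train extends past trial end (duration ",
         format(dur_s), " s + prestim ", format(prestim_s), " s > ",
         format(trial_length_s), " s)")
  }
  structure(
    list(energy_mJ = energy_mJ, isi_ms = isi_ms, n_pulses = as.integer(n_pulses),
         pulse_width_ms = pulse_width_ms, prestim_s = prestim_s,
         trial_length_s = trial_length_s, train_duration_s = dur_s),
    class = "stimulus_train"
  )
}

#' Analysis windows derived from a stimulus train
#'
#' Baseline is the prestimulus interval; the onset window runs from stimulus
#' onset to 100 ms after the end of the pulse train (clamped to the trial);
#' offset is the remainder of the trial; the N1-P2 search window extends at
#' most 150 ms past the train end. All windows are half-open `[start, end)`.
#'
#' @param stim a [stimulus_train()].
#' @return object of class `analysis_windows`: list of `c(start, end)` pairs
#'   (s) named `baseline`, `onset`, `offset`, `n1p2_search`.
#' @export
compute_windows <- function(stim) {
  stopifnot(inherits(stim, "stimulus_train"))
  train_end <- stim$prestim_s + stim$train_duration_s
  onset_end <- min(train_end + 0.1, stim$trial_length_s)
  structure(
    list(
      baseline = c(0, stim$prestim_s),
      onset = c(stim$prestim_s, onset_end),
      offset = c(onset_end, stim$trial_length_s),
      n1p2_search = c(stim$prestim_s, min(train_end + 0.15, stim$trial_length_s))
    ),
    class = "analysis_windows"
  )
}

#' Convert a time window to 1-based sample indices
#'
#' Half-open convention: sample k (0-based) at time k/rate belongs to the
#' window iff start <= k/rate < end. Exact to one sample at any rate.
#'
#' @param window `c(start, end)` in seconds.
#' @param rate sampling rate, Hz.
#' @param n_samples total samples available (indices are clamped).
#' @return integer vector of 1-based sample indices (possibly empty).
#' @export
window_samples <- function(window, rate, n_samples) {
  lo <- ceiling(window[1] * rate - 1e-9)       # first 0-based index inside
  hi <- ceiling(window[2] * rate - 1e-9) - 1   # last 0-based index inside
  lo <- max(lo, 0)
  hi <- min(hi, n_samples - 1)
  if (hi < lo) return(integer(0))
  seq.int(lo + 1L, hi + 1L)
}

#' Single-trial recording
#'
#' @param lfp numeric vector of LFP samples (uV); coerced to float32 precision.
#' @param rate sampling rate, Hz.
#' @param spikes named list of numeric vectors, one per sorted unit, of spike
#'   times in seconds (trial-relative).
#' @param stimulus a [stimulus_train()].
#' @param animal,electrode,trial identifying keys.
#' @return object of class `trial_recording`.
#' @export
trial_recording <- function(lfp, rate, spikes = list(), stimulus,
                            animal = "a1", electrode = "e1", trial = 1L) {
  stopifnot(inherits(stimulus, "stimulus_train"), rate > 0)
  expected <- round(stimulus$trial_length_s * rate)
  if (length(lfp) != expected) {
    stop("lfp length ", length(lfp), " != round(trial_length * rate) = ", expected)
  }
  for (u in spikes) {
    if (length(u) && (min(u) < 0 || max(u) > stimulus$trial_length_s)) {
      stop("spike times outside [0, trial_length]")
    }
  }
  structure(
    list(lfp = as_float32(lfp), rate = rate, spikes = spikes,
         stimulus = stimulus, animal = as.character(animal),
         electrode = as.character(electrode), trial = as.integer(trial)),
    class = "trial_recording"
  )
}

#' Collection of trial recordings plus study-level metadata
#'
#' @param trials list of [trial_recording()] objects with unique
#'   (animal, electrode, trial) keys.
#' @param manifest named list of study metadata (seed, generator settings, ...).
#' @return object of class `trial_set`.
#' @export
trial_set <- function(trials, manifest = list()) {
  keys <- vapply(trials, function(tr) {
    paste(tr$animal, tr$electrode, tr$trial, sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate (animal, electrode, trial) keys")
  structure(list(trials = trials, manifest = manifest), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", length(x$trials), "trials,",
      length(unique(vapply(x$trials, function(t) t$electrode, character(1)))),
      "electrodes\n")
  invisible(x)
}

#' Table of per-trial stimulus metadata
#'
#' @param ts a [trial_set()].
#' @return data.frame with one row per trial.
#' @export
trial_table <- function(ts) {
  do.call(rbind, lapply(seq_along(ts$trials), function(i) {
    tr <- ts$trials[[i]]
    data.frame(row = i, animal = tr$animal, electrode = tr$electrode,
               trial = tr$trial, energy_mJ = tr$stimulus$energy_mJ,
               isi_ms = tr$stimulus$isi_ms, n_pulses = tr$stimulus$n_pulses,
               pulse_width_ms = tr$stimulus$pulse_width_ms,
               stringsAsFactors = FALSE)
  }))
}

MANIFEST_REQUIRED <- c("schema_version", "sampling_rate", "trial_length_s",
                       "prestim_s", "conditions")

#' Save a trial set to a directory
#'
#' Layout: `manifest.json` (UTF-8 JSON; schema version, sampling rate, trial
#' geometry, condition table, seed), one `lfp_<electrode>.f32` little-endian
#' float32 file per electrode holding its trials-by-samples LFP matrix
#' (row-major, trial order as in `trials_<electrode>.csv`), and a single
#' `spikes.csv` event table with columns `animal,electrode,trial,unit,time_s`.
#'
#' @param ts a [trial_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tt <- trial_table(ts)
  s0 <- ts$trials[[1]]$stimulus
  conds <- unique(tt[, c("energy_mJ", "isi_ms", "n_pulses", "pulse_width_ms")])
  rownames(conds) <- NULL
  manifest <- c(list(
    schema_version = 1L,
    sampling_rate = ts$trials[[1]]$rate,
    trial_length_s = s0$trial_length_s,
    prestim_s = s0$prestim_s,
    conditions = conds,
    electrodes = sort(unique(tt$electrode))
  ), ts$manifest[setdiff(names(ts$manifest), "conditions")])
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  spike_rows <- list()
  for (el in manifest$electrodes) {
    idx <- tt$row[tt$electrode == el]
    mat <- t(vapply(idx, function(i) ts$trials[[i]]$lfp,
                    numeric(length(ts$trials[[idx[1]]]$lfp))))
    con <- file(file.path(path, paste0("lfp_", el, ".f32")), "wb")
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
    close(con)
    utils::write.csv(tt[tt$electrode == el, ],
                     file.path(path, paste0("trials_", el, ".csv")),
                     row.names = FALSE)
    for (i in idx) {
      tr <- ts$trials[[i]]
      for (u in names(tr$spikes)) {
        if (length(tr$spikes[[u]])) {
          spike_rows[[length(spike_rows) + 1L]] <- data.frame(
            animal = tr$animal, electrode = tr$electrode, trial = tr$trial,
            unit = u, time_s = tr$spikes[[u]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  spikes <- if (length(spike_rows)) do.call(rbind, spike_rows) else
    data.frame(animal = character(0), electrode = character(0),
               trial = integer(0), unit = character(0), time_s = numeric(0))
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a trial set saved by [save_trialset()]
#'
#' @param path directory written by [save_trialset()].
#' @return a [trial_set()]; LFP samples and spike times round-trip bit-exactly.
#' @export
load_trialset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  missing <- setdiff(MANIFEST_REQUIRED, names(manifest))
  if (length(missing)) {
    stop("malformed manifest: missing fields: ", paste(missing, collapse = ", "))
  }
  rate <- manifest$sampling_rate
  n_samp <- round(manifest$trial_length_s * rate)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c(unit = "character",
                                           animal = "character",
                                           electrode = "character"))
  trials <- list()
  for (el in manifest$electrodes) {
    tt <- utils::read.csv(file.path(path, paste0("trials_", el, ".csv")),
                          colClasses = c(animal = "character",
                                         electrode = "character"))
    con <- file(file.path(path, paste0("lfp_", el, ".f32")), "rb")
    dat <- readBin(con, "numeric", n = nrow(tt) * n_samp, size = 4L,
                   endian = "little")
    close(con)
    for (k in seq_len(nrow(tt))) {
      r <- tt[k, ]
      st <- stimulus_train(r$energy_mJ, r$isi_ms, r$n_pulses, r$pulse_width_ms,
                           manifest$prestim_s, manifest$trial_length_s)
      sp <- spikes[spikes$animal == r$animal & spikes$electrode == el &
                     spikes$trial == r$trial, ]
      spl <- split(sp$time_s, sp$unit)
      trials[[length(trials) + 1L]] <- trial_recording(
        lfp = dat[((k - 1) * n_samp + 1):(k * n_samp)], rate = rate,
        spikes = spl, stimulus = st, animal = r$animal, electrode = el,
        trial = r$trial)
    }
  }
  extra <- manifest[setdiff(names(manifest),
                            c(MANIFEST_REQUIRED, "electrodes"))]
  trial_set(trials, manifest = extra)
}
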