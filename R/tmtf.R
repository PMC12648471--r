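# Temporal modulation transfer functions: LFP power change at the interpulse
# stimulus-interval (ISI) frequency, stimulation window versus baseline.
#
# tMTF = 10 log10(P_s / P_B); a response is significantly modulated when
# |tMTF| >= 3 dB (a doubling/halving of power at the ISI frequency). ISI
# frequencies at or above 763 Hz (the analysis-rate Nyquist) are excluded.

TMTF_NYQUIST_HZ <- 763

#' Spectral power at an exact frequency
#'
#' Evaluates the windowed discrete-time Fourier transform at an arbitrary
#' frequency (the single-frequency chirp-z/Bluestein value), with a Hann taper
#' and amplitude (coherent-gain) normalization `2 |X(f)|^2 / (sum w)^2` so that
#' a unit sinusoid yields 0.5 regardless of window length — unequal baseline
#' and stimulation windows are therefore directly comparable.
#'
#' @param x numeric segment.
#' @param rate sampling rate, Hz.
#' @param f frequency, Hz; must satisfy `f < rate/2` and the segment must
#'   cover at least 2 cycles of `f`.
#' @return power estimate (signal units squared).
#' @export
power_at_frequency <- function(x, rate, f) {
  n <- length(x)
  if (f >= rate / 2) stop("frequency at or above Nyquist")
  if (n < 2 * rate / f) {
    warning("window shorter than 2 cycles of ", f, " Hz")
  }
  w <- hann_window(n)
  ph <- exp(-2i * pi * f * (0:(n - 1)) / rate)
  X <- sum(w * x * ph)
  2 * Mod(X)^2 / sum(w)^2
}

#' tMTF for a single response
#'
#' @param x full-trial LFP vector (raw; the 10 Hz drift filter is not used for
#'   spectral analyses).
#' @param rate sampling rate, Hz.
#' @param windows [compute_windows()] result; baseline is the 200 ms
#'   prestimulus window, the stimulation window is the onset window (train
#'   duration + 100 ms).
#' @param f_isi ISI frequency, Hz.
#' @return object of class `tmtf_result`: `f_isi`, `p_s`, `p_b`, `tmtf_db`,
#'   `significant` in `{"increase","decrease","none"}`, and `excluded`
#'   (with `reason = "Nyquist"` for f_isi >= 763 Hz; `tmtf_db` is `NA` when
#'   baseline power is zero).
#' @export
compute_tmtf <- function(x, rate, windows, f_isi) {
  res <- list(f_isi = f_isi, p_s = NA_real_, p_b = NA_real_,
              tmtf_db = NA_real_, significant = NA_character_,
              excluded = FALSE, reason = NULL)
  class(res) <- "tmtf_result"
  if (f_isi >= TMTF_NYQUIST_HZ) {
    res$excluded <- TRUE
    res$reason <- "Nyquist"
    return(res)
  }
  n <- length(x)
  bi <- window_samples(windows$baseline, rate, n)
  si <- window_samples(windows$onset, rate, n)
  res$p_b <- power_at_frequency(x[bi], rate, f_isi)
  res$p_s <- power_at_frequency(x[si], rate, f_isi)
  if (res$p_b == 0) {
    res$reason <- "zero baseline power"
    return(res)
  }
  res$tmtf_db <- 10 * log10(res$p_s / res$p_b)
  res$significant <- if (res$tmtf_db >= 3) "increase"
    else if (res$tmtf_db <= -3) "decrease" else "none"
  res
}

#' tMTF table for a trial set
#'
#' One response per (animal, electrode, condition), computed on the trial-mean
#' LFP. By default the analyzed frequency is `1/ISI` (so 100, 50, 25, 10, 5 ms
#' map to 10, 20, 40, 100, 200 Hz); `freq_mode = "pulse_period"` analyzes the
#' generator-consistent pulse repetition rate `1/(pulse_width + ISI)` instead.
#'
#' @param ts a [trial_set()].
#' @param freq_mode `"isi"` or `"pulse_period"`.
#' @return data.frame `animal, electrode, energy_mJ, isi_ms, f_isi_hz, p_s,
#'   p_b, tmtf_db, significant, excluded`.
#' @export
tmtf_table <- function(ts, freq_mode = c("isi", "pulse_period")) {
  freq_mode <- match.arg(freq_mode)
  tt <- trial_table(ts)
  key <- interaction(tt$animal, tt$electrode, tt$energy_mJ, tt$isi_ms,
                     drop = TRUE)
  rows <- list()
  for (g in levels(key)) {
    idx <- tt$row[key == g]
    tr1 <- ts$trials[[idx[1]]]
    lfp <- rowMeans(vapply(idx, function(i) ts$trials[[i]]$lfp,
                           numeric(length(tr1$lfp))))
    f <- if (freq_mode == "isi") 1000 / tr1$stimulus$isi_ms
      else 1000 / (tr1$stimulus$isi_ms + tr1$stimulus$pulse_width_ms)
    r <- compute_tmtf(lfp, tr1$rate, compute_windows(tr1$stimulus), f)
    rows[[length(rows) + 1L]] <- data.frame(
      animal = tr1$animal, electrode = tr1$electrode,
      energy_mJ = tr1$stimulus$energy_mJ, isi_ms = tr1$stimulus$isi_ms,
      f_isi_hz = f, p_s = r$p_s, p_b = r$p_b, tmtf_db = r$tmtf_db,
      significant = if (is.na(r$tmtf_db)) NA_character_ else r$significant,
      excluded = r$excluded, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Percentages of significantly modulated tMTF responses per energy bin
#'
#' @param results a [tmtf_table()].
#' @param energy_breaks bin edges in mJ; the default gives 0-0.5, 0.5-1, ...,
#'   3-3.5, >3.5 bins.
#' @return data.frame `energy_bin, f_isi_hz, pct_increase, pct_decrease, n`;
#'   empty cells are reported with `n = 0` and `NA` percentages.
#' @export
tmtf_proportions <- function(results,
                             energy_breaks = c(seq(0, 3.5, by = 0.5), Inf)) {
  results <- results[!results$excluded & !is.na(results$tmtf_db), ]
  labs <- paste0(utils::head(energy_breaks, -1), "-",
                 ifelse(is.finite(energy_breaks[-1]),
                        energy_breaks[-1], ""))
  labs[length(labs)] <- paste0(">", energy_breaks[length(energy_breaks) - 1])
  bin <- cut(results$energy_mJ, energy_breaks, labels = labs, right = TRUE,
             include.lowest = TRUE)
  fvals <- sort(unique(results$f_isi_hz))
  out <- expand.grid(energy_bin = labs, f_isi_hz = fvals,
                     stringsAsFactors = FALSE)
  out$pct_increase <- NA_real_; out$pct_decrease <- NA_real_; out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sub <- results[bin == out$energy_bin[i] &
                     results$f_isi_hz == out$f_isi_hz[i], ]
    out$n[i] <- nrow(sub)
    if (nrow(sub)) {
      out$pct_increase[i] <- 100 * mean(sub$significant == "increase")
      out$pct_decrease[i] <- 100 * mean(sub$significant == "decrease")
    }
  }
  out
}
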