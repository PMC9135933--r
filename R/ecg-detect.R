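#' Detect R peaks in an ECG recording
#'
#' Energy-detector in the Pan-Tompkins family, scaled to rodent heart rates:
#' the chosen lead is band-pass filtered (zero-phase Butterworth), squared
#' and smoothed into an energy envelope; envelope maxima above an adaptive
#' threshold are accepted greedily in time order under a refractory period of
#' 0.4 times the running median R-R interval; each accepted peak is then
#' refined to the extremum of the band-passed signal within +/- 10 ms.
#'
#' @param rec An `ecg_recording` (or a plain list with `signal` matrix and
#'   `fs`).
#' @param lead Lead name, default `"L1"` (limb lead I, the conventional
#'   display lead for rodent rhythm strips).
#' @param band Band-pass edges in Hz for the QRS energy filter.
#' @param smooth_ms Width of the moving-average envelope smoother (ms).
#' @param thresh_frac Threshold as a fraction of the median height of the
#'   strongest envelope peaks.
#' @return Numeric vector of R-peak times in seconds (possibly empty, with a
#'   warning, for flat input).
#' @examples
#' sim <- simulate_ecg(ecg_params("nmr"), duration_s = 10, seed = 1)
#' r <- detect_r_peaks(sim$recording)
#' @export
detect_r_peaks <- function(rec, lead = "L1", band = c(20, 250),
                           smooth_ms = 9, thresh_frac = 0.25) {
  fs <- rec$fs
  if (fs < 500) stop("sampling rate < 500 Hz is rejected for rodent ECG")
  x <- rec$signal[, lead]
  dur_s <- length(x) / fs
  if (dur_s < 2) stop("recording must be at least 2 s long")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("flat or all-equal signal; no R peaks detected")
    return(numeric(0))
  }

  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(2, c(band[1], hi) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  env <- bp^2
  w <- max(3, 2 * floor(smooth_ms / 1000 * fs / 2) + 1)
  env <- stats::filter(env, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  # local maxima of the envelope
  d <- diff(env)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (length(cand) < 2) {
    warning("no envelope peaks found")
    return(numeric(0))
  }
  h <- env[cand]
  # the strongest ~2/s candidates are R peaks for any rodent rate >= 120 bpm
  n_ref <- min(length(h), max(5L, ceiling(2 * dur_s)))
  h_ref <- stats::median(sort(h, decreasing = TRUE)[seq_len(n_ref)])
  thr <- thresh_frac * h_ref
  cand <- cand[h >= thr]
  if (length(cand) == 0) {
    warning("no peaks above threshold")
    return(numeric(0))
  }

  # greedy accept with refractory = 0.4 * running median RR
  rr0 <- if (length(cand) > 2) stats::median(diff(cand)) else 0.1 * fs
  acc <- integer(0)
  rr_recent <- rr0
  for (i in cand) {
    if (length(acc) == 0) { acc <- i; next }
    refr <- 0.4 * stats::median(rr_recent)
    gap <- i - acc[length(acc)]
    if (gap >= refr) {
      acc <- c(acc, i)
      nr <- length(acc)
      rr_recent <- diff(acc[max(1, nr - 11):nr])
    } else if (env[i] > env[acc[length(acc)]]) {
      acc[length(acc)] <- i  # keep the taller of two close candidates
    }
  }

  # refine to the band-passed extremum within +/- 10 ms
  hw <- round(0.010 * fs)
  pol <- sign(sum(sign(bp[acc])))
  if (pol == 0) pol <- 1
  r_idx <- vapply(acc, function(i) {
    idx <- max(1, i - hw):min(length(bp), i + hw)
    idx[which.max(pol * bp[idx])]
  }, integer(1))
  (unique(r_idx) - 1) / fs
}

#' Build an R-R interval series from R-peak times
#'
#' @param r_times Strictly increasing R-peak times in seconds.
#' @return Object of class `rr_series`: `r_times` (s), `rr_ms` (ms, length
#'   `length(r_times) - 1`), and `n_beats`.
#' @seealso [heart_rate()] for the rhythm-screened heart rate.
#' @export
rr_series <- function(r_times) {
  if (is.unsorted(r_times, strictly = TRUE)) {
    stop("r_times must be strictly increasing")
  }
  structure(
    list(r_times = r_times, rr_ms = diff(r_times) * 1000,
         n_beats = length(r_times)),
    class = "rr_series"
  )
}

#' Heart rate from non-flagged R-R intervals
#'
#' Mean heart rate in bpm computed as `60000 / mean(rr)` over intervals not
#' flagged as suspect, matching rhythm-screened reporting.
#'
#' @param rr An `rr_series`.
#' @param flags Optional `beat_flags` from [flag_irregular()]; flagged
#'   intervals are excluded.
#' @return Heart rate in beats per minute.
#' @export
heart_rate <- function(rr, flags = NULL) {
  keep <- rep(TRUE, length(rr$rr_ms))
  if (!is.null(flags)) keep[flags$interval[flags$suspect]] <- FALSE
  60000 / mean(rr$rr_ms[keep])
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series: %d beats, mean RR %.1f ms (%.0f bpm)>\n",
              x$n_beats, mean(x$rr_ms), 60000 / mean(x$rr_ms)))
  invisible(x)
}
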