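#' Ensemble-average ECG beats
#'
#' Averages up to `n` (default 100, the conventional count for rodent ECG
#' pattern analysis) rhythm-screened beats. Beats are usable when neither of
#' their adjacent R-R intervals is suspect and the extraction window fits
#' inside the recording; the first `n` usable beats are taken. Windows span
#' `[-0.45, +0.55]` of the median R-R interval, aligned on the R peak.
#'
#' @param rec An `ecg_recording`.
#' @param rr The [rr_series()] for `rec`.
#' @param flags Optional [flag_irregular()] output; without it all beats are
#'   treated as non-suspect.
#' @param n Number of beats to average (all usable beats if fewer).
#' @return Object of class `averaged_beat`: `time_ms` axis centred at R,
#'   `mean` and `sd` matrices (samples x leads, mV), `n_averaged`,
#'   `median_rr_ms`, `fs`.
#' @export
average_beats <- function(rec, rr, flags = NULL, n = 100) {
  stopifnot(inherits(rr, "rr_series"))
  fs <- rec$fs
  nb <- rr$n_beats
  bad_int <- if (is.null(flags)) logical(nb - 1) else flags$suspect
  med_rr <- stats::median(rr$rr_ms[!bad_int])

  pre <- round(0.45 * med_rr / 1000 * fs)
  post <- round(0.55 * med_rr / 1000 * fs)
  n_samp <- nrow(rec$signal)

  usable <- integer(0)
  for (b in seq_len(nb)) {
    prev_ok <- b == 1 || !bad_int[b - 1]
    next_ok <- b == nb || !bad_int[b]
    # interior beats only: require both flanking intervals present and clean
    if (b == 1 || b == nb || !prev_ok || !next_ok) next
    ctr <- round(rr$r_times[b] * fs) + 1
    if (ctr - pre < 1 || ctr + post > n_samp) next
    usable <- c(usable, b)
    if (length(usable) >= n) break
  }
  if (length(usable) < 20) {
    stop(sprintf("only %d usable beats; need at least 20", length(usable)))
  }

  idx_rel <- (-pre):post
  nl <- ncol(rec$signal)
  acc <- array(0, c(length(idx_rel), nl, length(usable)))
  for (k in seq_along(usable)) {
    ctr <- round(rr$r_times[usable[k]] * fs) + 1
    acc[, , k] <- rec$signal[ctr + idx_rel, , drop = FALSE]
  }
  m <- apply(acc, c(1, 2), mean)
  s <- apply(acc, c(1, 2), stats::sd)
  colnames(m) <- colnames(s) <- colnames(rec$signal)

  structure(
    list(time_ms = idx_rel / fs * 1000, mean = m, sd = s,
         n_averaged = length(usable), median_rr_ms = med_rr, fs = fs),
    class = "averaged_beat"
  )
}

#' Measure fiducial points and conduction intervals on an averaged beat
#'
#' The isoelectric baseline is the median of the segment
#' `[-0.40, -0.30] * median RR` before the R peak. QRS onset/offset are the
#' nearest points flanking R where the absolute baseline-corrected signal
#' falls below 5% of the R amplitude and stays below for at least 1 ms. The
#' P peak is the largest absolute deflection between the baseline segment
#' and QRS onset; P onset applies the same 5% sustain rule to the P
#' amplitude. Intervals: QRS = offset - onset, PQ = QRS onset - P onset,
#' PR = R peak - P onset (both atrio-ventricular conventions are returned,
#' since reports differ in which they quote).
#'
#' @param avg An [average_beats()] result.
#' @param lead Lead to measure on (default `"L1"`).
#' @param p_noise_mult P-wave detectability: the P deflection must exceed
#'   this multiple of the baseline-segment noise SD, else PR/PQ are `NA`.
#' @return Object of class `fiducial_set`: `p_onset_ms`, `p_peak_ms`,
#'   `qrs_onset_ms`, `r_peak_ms` (0), `qrs_offset_ms`, and intervals
#'   `qrs_ms`, `pr_ms`, `pq_ms`.
#' @export
measure_intervals <- function(avg, lead = "L1", p_noise_mult = 3) {
  stopifnot(inherits(avg, "averaged_beat"))
  t <- avg$time_ms
  y <- avg$mean[, lead]
  fs <- avg$fs
  rr <- avg$median_rr_ms

  base_idx <- which(t >= -0.40 * rr & t <= -0.30 * rr)
  if (length(base_idx) < 3) stop("averaged beat too short for baseline segment")
  baseline <- stats::median(y[base_idx])
  base_sd <- stats::sd(y[base_idx])
  yc <- y - baseline

  # R amplitude: extremum within +/- 3 ms of the alignment point
  near_r <- which(abs(t) <= 3)
  r_i <- near_r[which.max(abs(yc[near_r]))]
  r_amp <- abs(yc[r_i])
  if (r_amp < .Machine$double.eps^0.5) stop("flat-line averaged beat")

  sustain <- max(1L, round(0.001 * fs))
  below <- abs(yc) < 0.05 * r_amp

  sustained_left <- function(i) all(below[max(1, i - sustain + 1):i])
  sustained_right <- function(i) all(below[i:min(length(t), i + sustain - 1)])

  on_i <- NA_integer_
  for (i in seq(r_i - 1, 1)) {
    if (below[i] && sustained_left(i)) { on_i <- i; break }
  }
  off_i <- NA_integer_
  for (i in seq(r_i + 1, length(t))) {
    if (below[i] && sustained_right(i)) { off_i <- i; break }
  }
  if (is.na(on_i) || is.na(off_i)) stop("could not delimit the QRS complex")
  qrs_on <- t[on_i]; qrs_off <- t[off_i]

  # P wave: largest |deflection| between baseline segment and QRS onset
  p_lo <- max(base_idx) + 1
  p_hi <- on_i - max(1L, round(0.002 * fs))
  p_onset <- p_peak <- NA_real_
  if (p_hi > p_lo) {
    p_win <- p_lo:p_hi
    p_i <- p_win[which.max(abs(yc[p_win]))]
    p_amp <- abs(yc[p_i])
    # detectable only above the baseline noise AND a physiologic floor
    # (1% of R): wave tails are never mistaken for atrial activity
    if (p_amp >= max(p_noise_mult * base_sd, 0.01 * r_amp)) {
      p_below <- abs(yc) < 0.05 * p_amp
      po_i <- NA_integer_
      for (i in seq(p_i - 1, 1)) {
        if (p_below[i] && all(p_below[max(1, i - sustain + 1):i])) {
          po_i <- i; break
        }
      }
      if (!is.na(po_i)) { p_onset <- t[po_i]; p_peak <- t[p_i] }
    }
  }

  structure(
    list(p_onset_ms = p_onset, p_peak_ms = p_peak,
         qrs_onset_ms = qrs_on, r_peak_ms = 0, qrs_offset_ms = qrs_off,
         qrs_ms = qrs_off - qrs_on,
         pr_ms = if (is.na(p_onset)) NA_real_ else 0 - p_onset,
         pq_ms = if (is.na(p_onset)) NA_real_ else qrs_on - p_onset,
         lead = lead),
    class = "fiducial_set"
  )
}

#' @export
print.averaged_beat <- function(x, ...) {
  cat(sprintf("<averaged_beat: %d beats, window %.1f..%.1f ms, %d leads>\n",
              x$n_averaged, min(x$time_ms), max(x$time_ms), ncol(x$mean)))
  invisible(x)
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set [%s]: QRS %.2f ms, PR %s, PQ %s>\n", x$lead,
              x$qrs_ms,
              if (is.na(x$pr_ms)) "NA" else sprintf("%.2f ms", x$pr_ms),
              if (is.na(x$pq_ms)) "NA" else sprintf("%.2f ms", x$pq_ms)))
  invisible(x)
}
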