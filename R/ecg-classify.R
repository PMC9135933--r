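#' Classify flagged premature beats as APB, VPB or JPB
#'
#' Rule-based stand-in for expert adjudication of screened beats. For each
#' flagged event with a premature partner (an interval below the `low`
#' threshold), the premature beat is the one terminating the short interval
#' and is classified by two morphological rules applied to the single beat:
#'
#' 1. QRS width, measured with the same 5% baseline rule as
#'    [measure_intervals()], more than 1.5 times the template width ->
#'    ventricular premature beat (VPB);
#' 2. otherwise, a P-wave presence score -- the maximum normalized
#'    cross-correlation between the template P wave and the detrended
#'    pre-QRS window of the beat, searched over the physiologic PQ range
#'    (0.6 to 1.6 times the template PQ) -- of at least `p_score_min`
#'    -> atrial premature beat (APB); below it -> junctional (JPB).
#'
#' Events flagged only for a long pause (ratio above the `high` threshold
#' with no premature partner) remain `"unclassified"`. Without a usable
#' template (fewer than 20 averaged beats) every suspect stays unclassified.
#'
#' @param rec The `ecg_recording`.
#' @param rr Its [rr_series()].
#' @param flags [flag_irregular()] output.
#' @param template [average_beats()] result from the same recording.
#' @param lead Lead used for morphology (default `"L1"`).
#' @param width_ratio_min Template-relative QRS width ratio above which a
#'   beat is called ventricular.
#' @param p_score_min Minimum P-wave correlation score for an atrial call.
#' @return `flags` with the `class` column filled in for suspect beats.
#' @export
classify_flagged <- function(rec, rr, flags, template, lead = "L1",
                             width_ratio_min = 1.5, p_score_min = 0.6) {
  stopifnot(inherits(flags, "beat_flags"))
  if (!any(flags$suspect)) return(flags)
  if (is.null(template) || !inherits(template, "averaged_beat") ||
      template$n_averaged < 20) {
    warning("no usable template (need >= 20 averaged beats); ",
            "suspects left unclassified")
    return(flags)
  }
  thr <- attr(flags, "thresholds")
  fs <- rec$fs
  x <- rec$signal[, lead]
  tf <- measure_intervals(template, lead = lead)
  if (is.na(tf$pq_ms)) {
    warning("template has no measurable P wave; suspects left unclassified")
    return(flags)
  }

  # template P segment: from P onset (with margin) to just before QRS onset
  tt <- template$time_ms
  p_seg_idx <- which(tt >= tf$p_onset_ms - 2 & tt <= tf$qrs_onset_ms - 1)
  base_t <- which(tt >= -0.40 * template$median_rr_ms &
                    tt <= -0.30 * template$median_rr_ms)
  p_tpl <- template$mean[p_seg_idx, lead] -
    stats::median(template$mean[base_t, lead])
  p_tpl <- p_tpl - mean(p_tpl)

  # template waveform for neighbour-beat subtraction (baseline-corrected)
  tpl_y <- template$mean[, lead] -
    stats::median(template$mean[base_t, lead])

  for (ev in unique(flags$event[flags$suspect])) {
    rows <- which(!is.na(flags$event) & flags$event == ev)
    short <- rows[flags$rr_ratio[rows] < thr[["low"]]]
    if (length(short) == 0) next  # long pause only -> unclassified
    b <- flags$beat[short[1]]  # beat terminating the short interval
    prev_offset_ms <- if (b > 1) (rr$r_times[b - 1] - rr$r_times[b]) * 1000
      else NA_real_
    cls <- classify_one_beat(x, fs, rr$r_times[b], tf, p_tpl,
                             tt, tpl_y, prev_offset_ms,
                             width_ratio_min, p_score_min)
    flags$class[rows] <- cls
  }
  flags
}

# Classify a single premature beat from its raw waveform around time t_r (s).
# A premature beat's pre-QRS window rides on the previous beat's
# repolarization; the averaged-beat template shifted to the previous R is
# subtracted before P-wave scoring (signal-averaged residual analysis).
classify_one_beat <- function(x, fs, t_r, tf, p_tpl,
                              tpl_t, tpl_y, prev_offset_ms,
                              width_ratio_min, p_score_min) {
  ctr <- round(t_r * fs) + 1
  # window generous enough for a 2.5x widened complex plus the P search
  pre_ms <- max(60, 2.5 * abs(tf$p_onset_ms) + 10)
  post_ms <- max(40, 4 * tf$qrs_offset_ms + 10)
  lo <- ctr - round(pre_ms / 1000 * fs); hi <- ctr + round(post_ms / 1000 * fs)
  if (lo < 1 || hi > length(x)) return("unclassified")
  y <- x[lo:hi]
  t_ms <- ((lo:hi) - ctr) / fs * 1000

  qrs <- single_beat_qrs(y, t_ms, fs, tf)
  if (!is.na(qrs) && qrs / tf$qrs_ms > width_ratio_min) return("VPB")

  if (!is.na(prev_offset_ms)) {
    rel_prev <- t_ms - prev_offset_ms   # time relative to the previous R
    prev_contrib <- stats::approx(tpl_t, tpl_y, xout = rel_prev,
                                  yleft = 0, yright = 0)$y
    y <- y - prev_contrib
  }

  # P presence: slide the template P wave over the physiologic PQ range.
  # The pre-QRS window of a premature beat rides on the previous beat's T
  # tail; a quadratic detrend removes that slow curvature, and segments
  # whose residual amplitude is far from the template P amplitude are not
  # P-wave candidates (shape-only correlation of near-flat noise is
  # meaningless).
  qrs_on <- if (is.na(qrs)) tf$qrs_onset_ms else attr(qrs, "onset_ms")
  pq_range <- c(0.6, 1.6) * tf$pq_ms
  np <- length(p_tpl)
  ptp_tpl <- diff(range(p_tpl))
  X <- cbind(1, seq_len(np), seq_len(np)^2)
  best <- -Inf
  for (pq in seq(pq_range[1], pq_range[2], by = 1000 / fs)) {
    on_target <- qrs_on - pq       # candidate P onset (ms, relative to R)
    i0 <- which.min(abs(t_ms - (on_target - 2)))
    seg <- y[i0:(i0 + np - 1)]
    if (length(seg) < np || anyNA(seg)) next
    seg <- stats::residuals(stats::lm.fit(X, seg))
    ratio <- diff(range(seg)) / ptp_tpl
    if (ratio < 0.35 || ratio > 3) next
    if (stats::sd(seg) < .Machine$double.eps^0.5) next
    best <- max(best, stats::cor(seg, p_tpl))
  }
  if (is.finite(best) && best >= p_score_min) "APB" else "JPB"
}

# QRS width of one beat by the 5% sustained-threshold rule, using a local
# baseline taken left of the template P-search region.
single_beat_qrs <- function(y, t_ms, fs, tf) {
  # median over everything left of a (possibly widened) complex: brief P and
  # neighbouring-beat deflections are outvoted by isoelectric samples
  base_idx <- which(t_ms <= 2.5 * tf$qrs_onset_ms)
  if (length(base_idx) < 3) base_idx <- seq_len(max(3, round(0.01 * fs)))
  baseline <- stats::median(y[base_idx])
  yc <- y - baseline
  near_r <- which(abs(t_ms) <= 3)
  r_i <- near_r[which.max(abs(yc[near_r]))]
  r_amp <- abs(yc[r_i])
  if (r_amp < .Machine$double.eps^0.5) return(NA_real_)
  sustain <- max(1L, round(0.001 * fs))
  below <- abs(yc) < 0.05 * r_amp
  on_i <- off_i <- NA_integer_
  for (i in seq(r_i - 1, 1)) {
    if (below[i] && all(below[max(1, i - sustain + 1):i])) { on_i <- i; break }
  }
  for (i in seq(r_i + 1, length(yc))) {
    if (below[i] && all(below[i:min(length(yc), i + sustain - 1)])) {
      off_i <- i; break
    }
  }
  if (is.na(on_i) || is.na(off_i)) return(NA_real_)
  out <- t_ms[off_i] - t_ms[on_i]
  attr(out, "onset_ms") <- t_ms[on_i]
  out
}
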