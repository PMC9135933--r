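#' Species-specific synthetic ECG parameters
#'
#' Builds the parameter set describing one species' anesthetized ECG: heart
#' rate, a five-wave (P, Q, R, S, T) sum-of-Gaussians beat template,
#' respiratory modulation of the R-R interval, and per-lead projection
#' weights. Defaults encode anesthetized laboratory-mouse and naked mole-rat
#' (NMR) physiology: mouse heart rates around 550 bpm with a narrow
#' (~9 ms) QRS, NMR around 240 bpm with a wider complex, and breathing rates
#' in the anesthesia maintenance ranges (mouse 50-80, NMR 40-50 breaths/min).
#'
#' Each wave is a Gaussian with an amplitude (mV), a center offset from the
#' R peak (ms) and a width sigma (ms). Wave onset/offset are defined as
#' center +/- 2*sigma; the true QRS duration is S offset minus Q onset, the
#' PQ interval is Q onset minus P onset, and the PR interval is the R peak
#' minus P onset. These conventions give the generator analytic ground-truth
#' fiducials.
#'
#' @param species `"mouse"` or `"nmr"`.
#' @param hr_mean,hr_sd Mean heart rate and its between-animal SD (bpm).
#' @param qrs_ms Optional target true QRS duration (ms); Q and S centers and
#'   widths are rescaled proportionally to hit it.
#' @param pq_ms Optional target true PQ interval (ms); the P wave is shifted.
#' @param waves Optional 5-row data.frame (`wave`, `amp_mv`, `center_ms`,
#'   `sigma_ms`) overriding the default template. Rows must be P,Q,R,S,T.
#' @param resp_rate_bpm,resp_depth Respiratory R-R modulation: breathing rate
#'   (breaths/min) and fractional modulation depth.
#' @param rr_jitter Fractional SD of white beat-to-beat R-R jitter.
#' @param lead_weights 3x3 numeric matrix of projection weights, rows
#'   `L1,L2,L3`, columns wave groups `P,QRS,T`.
#' @return An object of class `species_ecg_params`.
#' @examples
#' p <- ecg_params("mouse")
#' ecg_true_intervals(p)   # ground-truth QRS/PR/PQ implied by the template
#' @export
ecg_params <- function(species = c("mouse", "nmr"),
                       hr_mean = NULL, hr_sd = NULL,
                       qrs_ms = NULL, pq_ms = NULL,
                       waves = NULL,
                       resp_rate_bpm = NULL, resp_depth = 0.03,
                       rr_jitter = 0.01,
                       lead_weights = NULL) {
  species <- match.arg(species)
  def <- if (species == "mouse") {
    list(
      hr_mean = 550, hr_sd = 35, resp_rate_bpm = 65,
      waves = data.frame(
        wave      = c("P", "Q", "R", "S", "T"),
        amp_mv    = c(0.10, -0.15, 1.00, -0.35, 0.15),
        center_ms = c(-28, -3.0, 0, 3.0, 15),
        sigma_ms  = c(2.6, 0.7, 1.2, 1.0, 6.0),
        stringsAsFactors = FALSE
      )
    )
  } else {
    list(
      hr_mean = 240, hr_sd = 20, resp_rate_bpm = 45,
      waves = data.frame(
        wave      = c("P", "Q", "R", "S", "T"),
        amp_mv    = c(0.10, -0.16, 0.80, -0.25, 0.12),
        center_ms = c(-48, -4.0, 0, 4.0, 40),
        sigma_ms  = c(2.8, 1.0, 1.8, 1.3, 10.0),
        stringsAsFactors = FALSE
      )
    )
  }
  if (is.null(hr_sd)) hr_sd <- def$hr_sd
  if (is.null(resp_rate_bpm)) resp_rate_bpm <- def$resp_rate_bpm
  if (is.null(waves)) {
    waves <- def$waves
    # atrio-ventricular conduction shortens modestly at faster rates: the
    # default P position tracks the cycle length so the pre-P baseline
    # segment stays isoelectric across the physiologic heart-rate range
    if (!is.null(hr_mean) && hr_mean != def$hr_mean) {
      r <- min(1.25, max(0.75, def$hr_mean / hr_mean))
      ip <- waves$wave == "P"
      waves$center_ms[ip] <- waves$center_ms[ip] * r
    }
  }
  if (is.null(hr_mean)) hr_mean <- def$hr_mean
  if (is.null(lead_weights)) {
    lead_weights <- matrix(
      c(1.00, 1.00, 1.00,
        0.70, 0.85, 0.80,
        0.45, 0.45, 0.50),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("L1", "L2", "L3"), c("P", "QRS", "T"))
    )
  }

  stopifnot(is.data.frame(waves), nrow(waves) == 5,
            identical(waves$wave, c("P", "Q", "R", "S", "T")))
  if (hr_mean <= 0) stop("hr_mean must be positive")
  if (any(waves$sigma_ms <= 0)) stop("wave widths must be positive")

  # Rescale the ventricular group (Q,R,S and the following T) to a target
  # true QRS duration; a slower complex slows repolarization timing with it.
  if (!is.null(qrs_ms)) {
    iq <- waves$wave == "Q"; is_ <- waves$wave == "S"
    qrs0 <- (waves$center_ms[is_] + 2 * waves$sigma_ms[is_]) -
      (waves$center_ms[iq] - 2 * waves$sigma_ms[iq])
    k <- qrs_ms / qrs0
    for (i in which(waves$wave %in% c("Q", "R", "S", "T"))) {
      waves$center_ms[i] <- waves$center_ms[i] * k
      waves$sigma_ms[i] <- waves$sigma_ms[i] * k
    }
  }
  if (!is.null(pq_ms)) {
    ip <- waves$wave == "P"; iq <- waves$wave == "Q"
    qrs_on <- waves$center_ms[iq] - 2 * waves$sigma_ms[iq]
    waves$center_ms[ip] <- qrs_on - pq_ms + 2 * waves$sigma_ms[ip]
  }

  ord <- order(waves$center_ms)
  if (!identical(waves$wave[ord], waves$wave)) {
    stop("wave centers must be ordered P < Q < R(=0) < S < T")
  }
  if (waves$center_ms[waves$wave == "R"] != 0) stop("R center must be 0")

  structure(
    list(species = species, hr_mean = hr_mean, hr_sd = hr_sd,
         waves = waves, resp_rate_bpm = resp_rate_bpm,
         resp_depth = resp_depth, rr_jitter = rr_jitter,
         lead_weights = lead_weights),
    class = "species_ecg_params"
  )
}

#' Ground-truth fiducials and intervals implied by an ECG template
#'
#' Wave onset/offset are center +/- 2*sigma of the corresponding Gaussian;
#' QRS onset = Q onset, QRS offset = S offset.
#'
#' @param params A `species_ecg_params` object.
#' @return A list with `p_onset_ms`, `p_peak_ms`, `qrs_onset_ms`,
#'   `qrs_offset_ms` (ms relative to the R peak) and the derived `qrs_ms`,
#'   `pr_ms`, `pq_ms` intervals.
#' @export
ecg_true_intervals <- function(params) {
  w <- params$waves
  g <- function(name) w[w$wave == name, , drop = FALSE]
  p <- g("P"); q <- g("Q"); s <- g("S")
  p_on <- p$center_ms - 2 * p$sigma_ms
  qrs_on <- q$center_ms - 2 * q$sigma_ms
  qrs_off <- s$center_ms + 2 * s$sigma_ms
  list(p_onset_ms = p_on, p_peak_ms = p$center_ms,
       qrs_onset_ms = qrs_on, qrs_offset_ms = qrs_off,
       qrs_ms = qrs_off - qrs_on,
       pr_ms = 0 - p_on,
       pq_ms = qrs_on - p_on)
}

#' Premature-beat injection specification
#'
#' Event probabilities per beat for the three premature-beat classes used in
#' rodent rhythm screening: atrial (APB: preserved P wave, normal QRS),
#' ventricular (VPB: absent P, widened QRS) and junctional (JPB: absent P,
#' normal QRS). Prematurity is drawn uniformly from `prematurity` (as a
#' fraction of the mean R-R interval). Post-event pause convention follows
#' textbook electrophysiology: VPB fully compensatory (the pre- and
#' post-event intervals sum to twice the mean R-R), APB and JPB resetting.
#'
#' @param p_apb,p_vpb,p_jpb Per-beat event probabilities; their sum must not
#'   exceed 0.2 (beyond that the clean-template averaging assumption of the
#'   downstream analysis breaks down).
#' @param prematurity Length-2 range, fraction of mean R-R, subset of (0, 0.7].
#' @param vpb_width_mult QRS width multiplier for ventricular beats.
#' @param pause Named character vector giving the pause convention
#'   (`"resetting"` or `"compensatory"`) per class.
#' @return An object of class `arrhythmia_spec`.
#' @export
arrhythmia_spec <- function(p_apb = 0, p_vpb = 0, p_jpb = 0,
                            prematurity = c(0.5, 0.65),
                            vpb_width_mult = 2.5,
                            pause = c(APB = "resetting",
                                      VPB = "compensatory",
                                      JPB = "resetting")) {
  p <- c(APB = p_apb, VPB = p_vpb, JPB = p_jpb)
  if (any(p < 0)) stop("event probabilities must be >= 0")
  if (sum(p) > 0.2) {
    stop("sum of event probabilities exceeds 0.2; template averaging ",
         "assumption broken")
  }
  if (length(prematurity) != 2 || prematurity[1] > prematurity[2] ||
      prematurity[1] <= 0 || prematurity[2] > 0.7) {
    stop("prematurity must be a range within (0, 0.7]")
  }
  if (vpb_width_mult <= 0) stop("vpb_width_mult must be positive")
  pause <- pause[c("APB", "VPB", "JPB")]
  if (!all(pause %in% c("resetting", "compensatory"))) {
    stop("pause conventions must be 'resetting' or 'compensatory'")
  }
  structure(list(prob = p, prematurity = prematurity,
                 vpb_width_mult = vpb_width_mult, pause = pause),
            class = "arrhythmia_spec")
}

# Render one beat's contribution for a wave subset onto a sample grid.
# t_ms: sample times (ms) relative to this beat's R peak.
render_waves <- function(t_ms, waves, which_waves, width_mult = 1) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(waves))) {
    if (!(waves$wave[i] %in% which_waves)) next
    s <- waves$sigma_ms[i] * width_mult
    c0 <- waves$center_ms[i] * width_mult
    out <- out + waves$amp_mv[i] * exp(-((t_ms - c0)^2) / (2 * s^2))
  }
  out
}

#' @export
print.species_ecg_params <- function(x, ...) {
  ti <- ecg_true_intervals(x)
  cat(sprintf("<species_ecg_params: %s>\n", x$species))
  cat(sprintf("  heart rate %g +/- %g bpm; breathing %g /min (depth %.1f%%)\n",
              x$hr_mean, x$hr_sd, x$resp_rate_bpm, 100 * x$resp_depth))
  cat(sprintf("  true intervals: QRS %.1f ms, PR %.1f ms, PQ %.1f ms\n",
              ti$qrs_ms, ti$pr_ms, ti$pq_ms))
  invisible(x)
}
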