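#' Simulate a multi-lead rodent ECG recording with known ground truth
#'
#' Generates a three-lead (L1, L2, L3) ECG as a sum-of-Gaussians beat train:
#' the R-R process carries sinusoidal respiratory modulation plus white
#' beat-to-beat jitter, premature beats are injected per [arrhythmia_spec()],
#' and white measurement noise is added per lead. The random number stream is
#' split into independent substreams for the R-R process, event placement and
#' measurement noise, so changing the noise level does not perturb beat
#' placement.
#'
#' Premature-beat rendering follows the class definitions: APB keeps the P
#' wave and normal QRS; VPB drops the P wave and widens the ventricular
#' complex by `arr$vpb_width_mult`; JPB drops the P wave with a normal QRS.
#' Timing: the premature interval is `u * mean RR` with `u` drawn from
#' `arr$prematurity`; a resetting event is followed by a normal interval, a
#' compensatory event by `(2 - u) * mean RR` so that the flanking intervals
#' sum to twice the mean R-R.
#'
#' @param params [ecg_params()] object.
#' @param arr [arrhythmia_spec()] object; default injects no events.
#' @param duration_s Recording length in seconds (> 0).
#' @param noise_sd White noise SD per lead (mV). See [ecg_noise_sd()] to set
#'   it from a target SNR.
#' @param fs Sampling rate in Hz (>= 1000; default 2000 -- a mouse QRS of
#'   ~9 ms needs sub-millisecond resolution).
#' @param seed Integer seed (required; equal seeds give bit-identical output).
#' @param aux_channels If `TRUE`, include breathing and temperature channels.
#' @return A list with components `recording` (class `ecg_recording`: `signal`
#'   matrix of mV with columns L1..L3, `fs`, `species`, `duration_s`, optional
#'   `aux`) and `truth` (class `ecg_ground_truth`: `r_times` in s, per-beat
#'   `labels`, template `fiducials` and true `intervals`).
#' @examples
#' sim <- simulate_ecg(ecg_params("nmr"), duration_s = 10, seed = 1)
#' length(sim$truth$r_times)  # ~40 beats at 240 bpm
#' @export
simulate_ecg <- function(params, arr = arrhythmia_spec(),
                         duration_s = 300, noise_sd = 0,
                         fs = 2000, seed, aux_channels = TRUE) {
  stopifnot(inherits(params, "species_ecg_params"),
            inherits(arr, "arrhythmia_spec"))
  if (missing(seed)) stop("seed must be supplied")
  if (duration_s <= 0) stop("duration must be positive")
  if (fs < 1000) stop("sampling rate must be >= 1000 Hz for rodent ECG")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  sub <- derive_subseeds(seed, 3L)
  rr_mean_ms <- 60000 / params$hr_mean

  # --- substream 1: normal R-R process ---------------------------------
  set.seed(sub[1])
  n_max <- ceiling(duration_s * 1000 / rr_mean_ms * 1.3) + 10
  f_resp_hz <- params$resp_rate_bpm / 60
  t_ms <- numeric(n_max); t_ms[1] <- rr_mean_ms
  jit <- stats::rnorm(n_max, 0, params$rr_jitter)
  for (i in 2:n_max) {
    mod <- 1 + params$resp_depth * sin(2 * pi * f_resp_hz * t_ms[i - 1] / 1000) +
      jit[i]
    t_ms[i] <- t_ms[i - 1] + rr_mean_ms * max(0.5, mod)
  }
  t_ms <- t_ms[t_ms < duration_s * 1000 - rr_mean_ms * 0.6]
  n <- length(t_ms)
  labels <- rep("normal", n)

  # --- substream 2: event placement ------------------------------------
  set.seed(sub[2])
  p_tot <- sum(arr$prob)
  if (p_tot > 0 && n > 6) {
    u_ev <- stats::runif(n)
    u_pm <- stats::runif(n, arr$prematurity[1], arr$prematurity[2])
    classes <- c("APB", "VPB", "JPB")
    # rebuild the beat sequence interval by interval
    new_t <- t_ms[1]; new_lab <- "normal"
    i <- 1
    while (i < n) {
      ev <- i >= 3 && i <= n - 3 && u_ev[i] < p_tot &&
        new_lab[length(new_lab)] == "normal"
      if (ev) {
        cls <- classes[findInterval(u_ev[i], c(0, cumsum(arr$prob)),
                                    rightmost.closed = TRUE)]
        u <- u_pm[i]
        tp <- new_t[length(new_t)] + u * rr_mean_ms
        new_t <- c(new_t, tp); new_lab <- c(new_lab, cls)
        if (arr$pause[[cls]] == "compensatory") {
          # consume two normal intervals; flanking RRs sum to 2*mean RR
          new_t <- c(new_t, tp + (2 - u) * rr_mean_ms)
          new_lab <- c(new_lab, "normal")
          i <- i + 2
        } else {
          # resetting: next normal beat one mean RR after the ectopic
          new_t <- c(new_t, tp + rr_mean_ms)
          new_lab <- c(new_lab, "normal")
          i <- i + 1
        }
      } else {
        rr_i <- t_ms[i + 1] - t_ms[i]
        new_t <- c(new_t, new_t[length(new_t)] + rr_i)
        new_lab <- c(new_lab, "normal")
        i <- i + 1
      }
    }
    keep <- new_t < duration_s * 1000 - rr_mean_ms * 0.6
    t_ms <- new_t[keep]; labels <- new_lab[keep]
    n <- length(t_ms)
  }

  # --- waveform rendering ----------------------------------------------
  n_samp <- floor(duration_s * fs)
  time_s <- (seq_len(n_samp) - 1) / fs
  groups <- list(P = "P", QRS = c("Q", "R", "S"), T = "T")
  comp <- matrix(0, n_samp, 3, dimnames = list(NULL, names(groups)))
  half_win_ms <- max(abs(params$waves$center_ms) +
                       6 * params$waves$sigma_ms) * max(1, arr$vpb_width_mult)
  hw <- ceiling(half_win_ms / 1000 * fs)
  for (b in seq_len(n)) {
    ctr <- round(t_ms[b] / 1000 * fs) + 1
    idx <- max(1, ctr - hw):min(n_samp, ctr + hw)
    rel_ms <- (idx - 1) / fs * 1000 - t_ms[b]
    lab <- labels[b]
    for (g in names(groups)) {
      if (g == "P" && lab %in% c("VPB", "JPB")) next
      wm <- if (g == "QRS" && lab == "VPB") arr$vpb_width_mult else 1
      comp[idx, g] <- comp[idx, g] +
        render_waves(rel_ms, params$waves, groups[[g]], width_mult = wm)
    }
  }
  sig <- comp %*% t(params$lead_weights)
  colnames(sig) <- rownames(params$lead_weights)

  # --- substream 3: measurement noise ----------------------------------
  if (noise_sd > 0) {
    set.seed(sub[3])
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow = n_samp)
  }

  aux <- NULL
  if (aux_channels) {
    temp_c <- if (params$species == "mouse") 37 else 34
    aux <- data.frame(
      breath = sin(2 * pi * f_resp_hz * time_s),
      temp_c = rep(temp_c, n_samp)
    )
  }

  fid <- ecg_true_intervals(params)
  rec <- structure(
    list(signal = sig, fs = fs, species = params$species,
         duration_s = duration_s, leads = colnames(sig), aux = aux,
         seed = seed),
    class = "ecg_recording"
  )
  truth <- structure(
    list(r_times = t_ms / 1000, labels = labels,
         fiducials = fid[c("p_onset_ms", "p_peak_ms",
                           "qrs_onset_ms", "qrs_offset_ms")],
         intervals = fid[c("qrs_ms", "pr_ms", "pq_ms")],
         rr_mean_ms = rr_mean_ms),
    class = "ecg_ground_truth"
  )
  list(recording = rec, truth = truth)
}

#' Noise SD for a target signal-to-noise ratio
#'
#' Computes the white-noise SD (mV) that yields a given SNR in dB on lead L1,
#' where signal power is the mean square of one noise-free template beat over
#' one mean R-R interval.
#'
#' @param params [ecg_params()] object.
#' @param snr_db Target SNR in dB.
#' @param fs Sampling rate used for the template (Hz).
#' @return Noise SD in mV.
#' @export
ecg_noise_sd <- function(params, snr_db, fs = 2000) {
  rr_ms <- 60000 / params$hr_mean
  t_ms <- seq(-0.45 * rr_ms, 0.55 * rr_ms, by = 1000 / fs)
  w <- params$lead_weights["L1", ]
  v <- w[["P"]] * render_waves(t_ms, params$waves, "P") +
    w[["QRS"]] * render_waves(t_ms, params$waves, c("Q", "R", "S")) +
    w[["T"]] * render_waves(t_ms, params$waves, "T")
  sqrt(mean(v^2)) / 10^(snr_db / 20)
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording: %s, %.1f s at %d Hz, leads %s>\n",
              x$species, x$duration_s, x$fs, paste(x$leads, collapse = ",")))
  invisible(x)
}

#' @export
print.ecg_ground_truth <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<ecg_ground_truth: %d beats (%s); true QRS %.1f, PR %.1f, PQ %.1f ms>\n",
              length(x$r_times),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              x$intervals$qrs_ms, x$intervals$pr_ms, x$intervals$pq_ms))
  invisible(x)
}

# Derive k reproducible 31-bit subseeds from one user seed.
derive_subseeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, k)
}
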