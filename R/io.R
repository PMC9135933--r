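#' Write an ECG recording as CSV plus JSON sidecar
#'
#' The CSV carries `time_s`, one `<lead>_mV` column per lead and any
#' auxiliary channels; the JSON sidecar carries sampling rate, species,
#' seed, units and (when given) the ground-truth annotations, so a
#' simulated recording round-trips losslessly through the file pair.
#'
#' @param rec An `ecg_recording`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param truth Optional `ecg_ground_truth` to embed in the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_recording <- function(rec, prefix, truth = NULL) {
  df <- data.frame(time_s = (seq_len(nrow(rec$signal)) - 1) / rec$fs)
  for (ld in colnames(rec$signal)) df[[paste0(ld, "_mV")]] <- rec$signal[, ld]
  if (!is.null(rec$aux)) df <- cbind(df, rec$aux)
  csv <- paste0(prefix, ".csv")
  data.table::fwrite(df, csv)
  meta <- list(
    sampling_rate_hz = rec$fs, species = rec$species,
    duration_s = rec$duration_s, leads = rec$leads,
    units = list(signal = "mV", time = "s"), seed = rec$seed
  )
  if (!is.null(truth)) {
    meta$ground_truth <- list(
      r_times_s = truth$r_times, labels = truth$labels,
      fiducials_ms = truth$fiducials, intervals_ms = truth$intervals
    )
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}

#' Load an ECG recording from CSV (+ optional JSON sidecar)
#'
#' Validates monotone, uniform sampling (relative timing jitter at most
#' 1 ppm of the sampling interval) and the presence of the standard leads.
#' Missing leads load with a warning; analysis is then restricted to the
#' leads present.
#'
#' @param path Path to the CSV, or the prefix used by [write_recording()].
#' @return An `ecg_recording` (with a `truth` attribute when the sidecar
#'   carries ground-truth annotations).
#' @export
load_recording <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  if (!file.exists(csv)) stop("no such file: ", csv)
  df <- data.table::fread(csv, data.table = FALSE)
  if (!"time_s" %in% names(df)) stop("CSV must have a time_s column")
  t <- df$time_s
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  dt <- diff(t)
  dt0 <- stats::median(dt)
  jitter <- max(abs(dt - dt0)) / dt0
  if (jitter > 1e-6) {
    stop(sprintf("nonuniform sampling: relative jitter %.3g exceeds 1 ppm",
                 jitter))
  }
  fs <- 1 / dt0
  lead_cols <- grep("^L[0-9]+_mV$", names(df), value = TRUE)
  if (length(lead_cols) == 0) stop("no lead columns (L*_mV) found")
  expected <- c("L1_mV", "L2_mV", "L3_mV")
  if (!all(expected %in% lead_cols)) {
    warning("missing leads: ",
            paste(setdiff(expected, lead_cols), collapse = ", "),
            "; analysis restricted to present leads")
  }
  sig <- as.matrix(df[, lead_cols, drop = FALSE])
  colnames(sig) <- sub("_mV$", "", lead_cols)

  meta <- NULL
  json <- sub("\\.csv$", ".json", csv)
  if (file.exists(json)) meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  aux_cols <- setdiff(names(df), c("time_s", lead_cols))
  rec <- structure(
    list(signal = sig, fs = round(fs), species = meta$species,
         duration_s = nrow(df) / fs, leads = colnames(sig),
         aux = if (length(aux_cols)) df[, aux_cols, drop = FALSE] else NULL,
         seed = meta$seed),
    class = "ecg_recording"
  )
  if (!is.null(meta$ground_truth)) attr(rec, "truth") <- meta$ground_truth
  rec
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table` data.frame.
#' @param path Output CSV path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: the table.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("animal_id", "species", "sex", "age_years")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Analyze one ECG recording end to end
#'
#' Convenience wrapper chaining R-peak detection, R-R screening, beat
#' averaging, interval measurement and premature-beat classification with
#' the standard defaults (70%/130% thresholds, 11-interval moving average,
#' 100-beat template).
#'
#' @param rec An `ecg_recording`.
#' @param lead Analysis lead.
#' @param low,high,window Screening parameters, see [flag_irregular()].
#' @param n_avg Beats to average, see [average_beats()].
#' @return List with `rr`, `flags`, `template`, `fiducials`, `hr_bpm`,
#'   and `event_counts` (classified events by class).
#' @export
analyze_ecg <- function(rec, lead = "L1", low = 0.70, high = 1.30,
                        window = 11, n_avg = 100) {
  r_times <- detect_r_peaks(rec, lead = lead)
  if (length(r_times) < 4) stop("too few beats detected")
  rr <- rr_series(r_times)
  flags <- flag_irregular(rr, low = low, high = high, window = window)
  template <- average_beats(rec, rr, flags, n = n_avg)
  fiducials <- measure_intervals(template, lead = lead)
  flags <- classify_flagged(rec, rr, flags, template, lead = lead)
  ev <- flags[flags$suspect & !duplicated(flags$event), "class"]
  counts <- vapply(c("APB", "VPB", "JPB", "unclassified"),
                   function(cl) sum(ev == cl), integer(1))
  list(rr = rr, flags = flags, template = template, fiducials = fiducials,
       hr_bpm = heart_rate(rr, flags), event_counts = counts)
}
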