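# Independent oracles used across test files.

# Literal implementation of the irregular-beat rule: for each interval, the
# moving average of up to `window` neighbouring intervals centred on it,
# excluding itself, truncated at the edges; suspect iff ratio < low or
# ratio > high. Plain loops, no shared code with the package.
brute_force_flags <- function(rr_ms, low = 0.70, high = 1.30, window = 11) {
  n <- length(rr_ms)
  half <- (window - 1) %/% 2
  suspect <- logical(n)
  for (i in seq_len(n)) {
    idx <- setdiff(max(1, i - half):min(n, i + half), i)
    ma <- mean(rr_ms[idx])
    r <- rr_ms[i] / ma
    suspect[i] <- r < low || r > high
  }
  suspect
}

# Full-enumeration two-sided rank-sum p-value for tie-free samples.
enumerate_wilcoxon_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  r_all <- rank(pooled)
  u_all <- apply(combos, 2, function(ix) sum(r_all[ix]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Match detected against true event times; returns TP/FN/FP counts.
match_peaks <- function(detected_s, true_s, tol_s = 0.002) {
  fn <- sum(vapply(true_s, function(x) all(abs(detected_s - x) > tol_s),
                   logical(1)))
  fp <- sum(vapply(detected_s, function(x) all(abs(true_s - x) > tol_s),
                   logical(1)))
  list(tp = length(true_s) - fn, fn = fn, fp = fp)
}

f1_score <- function(m) 2 * m$tp / (2 * m$tp + m$fn + m$fp)

# Map each detected beat to the label of the nearest ground-truth beat.
truth_labels_for <- function(det_times, truth) {
  truth$labels[vapply(det_times,
                      function(x) which.min(abs(truth$r_times - x)),
                      integer(1))]
}

# One classified call per flagged event: the premature beat terminates the
# short interval (first interval of the event when none is short).
event_calls <- function(flags, low = 0.70) {
  ev <- unique(flags$event[flags$suspect])
  out <- data.frame(event = ev, beat = NA_integer_, class = NA_character_)
  for (k in seq_along(ev)) {
    rows <- which(!is.na(flags$event) & flags$event == ev[k])
    short <- rows[flags$rr_ratio[rows] < low]
    out$beat[k] <- if (length(short)) flags$beat[short[1]]
      else flags$beat[rows[1]]
    out$class[k] <- flags$class[rows[1]]
  }
  out
}
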