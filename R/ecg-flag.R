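#' Screen an R-R series for irregular heartbeats
#'
#' Flags potentially irregular heartbeats as R-R intervals shorter than
#' `low` (default 70%) or longer than `high` (default 130%) of the moving
#' average R-R interval. The moving average for interval i is the mean of up
#' to `window` neighbouring intervals centred on i, excluding interval i
#' itself, truncated at the ends of the series. The beat terminating a
#' suspect interval carries the flag; consecutive suspect intervals that
#' share a beat (the short and long interval flanking one premature beat)
#' are merged into a single event.
#'
#' @param rr An [rr_series()] with at least 3 intervals.
#' @param low,high Ratio thresholds (defaults 0.70 / 1.30).
#' @param window Moving-average window length in intervals (default 11).
#' @return A data.frame of class `beat_flags`, one row per interval:
#'   `interval` (index), `beat` (index of the terminating beat), `time_s`,
#'   `rr_ms`, `ma_ms`, `rr_ratio`, `suspect`, `event` (event id, `NA` when
#'   not suspect) and `class` (initialised `"normal"`/`"unclassified"`).
#' @examples
#' rr <- rr_series(cumsum(c(0, rep(0.25, 10), 0.15, rep(0.25, 10))))
#' f <- flag_irregular(rr)
#' f[f$suspect, c("interval", "rr_ratio")]  # one flag at ratio 0.60
#' @export
flag_irregular <- function(rr, low = 0.70, high = 1.30, window = 11) {
  stopifnot(inherits(rr, "rr_series"))
  if (low >= high || low <= 0) stop("need 0 < low < high")
  x <- rr$rr_ms
  n <- length(x)
  if (n < 3) stop("need at least 3 R-R intervals")
  half <- (window - 1) %/% 2

  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  ma <- (cs[hi + 1] - cs[lo]- x) / (hi - lo)  # window sum minus self
  ratio <- x / ma
  suspect <- ratio < low | ratio > high

  event <- rep(NA_integer_, n)
  if (any(suspect)) {
    r <- rle(suspect)
    ev_id <- 0L
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      ev_id <- ev_id + 1L
      event[pos[k]:(pos[k + 1] - 1)] <- ev_id
    }
  }

  out <- data.frame(
    interval = seq_len(n),
    beat = seq_len(n) + 1L,
    time_s = rr$r_times[-1],
    rr_ms = x,
    ma_ms = ma,
    rr_ratio = ratio,
    suspect = suspect,
    event = event,
    class = ifelse(suspect, "unclassified", "normal"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("beat_flags", "data.frame")
  attr(out, "thresholds") <- c(low = low, high = high, window = window)
  out
}

#' Number of distinct irregular-beat events in a flag table
#'
#' @param flags A `beat_flags` data.frame.
#' @return Integer count of merged events.
#' @export
n_events <- function(flags) {
  if (!any(flags$suspect)) return(0L)
  length(unique(flags$event[flags$suspect]))
}
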