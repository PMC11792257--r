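#' Construct a beat-to-beat variability series
#'
#' Container for aligned per-beat heart period (HP, ms), systolic arterial
#' pressure (SAP, mmHg) and respiration (RESP, arbitrary units) values. Beat
#' `n` spans the interval between R-wave peaks `n` and `n+1`:
#' `hp[n] = 1000 * (t[n+1] - t[n])`.
#'
#' @param hp Per-beat heart period, ms (all > 0).
#' @param sap Per-beat SAP, mmHg.
#' @param resp Per-beat RESP sample, a.u.
#' @param r_peak_times R-wave peak times in seconds, length `n_beats + 1`
#'   (beat onsets plus the closing peak). Defaults to the cumulative HP.
#' @param interpolated Logical per-beat flag marking repaired beats.
#' @return Object of class `beat_series`.
#' @export
beat_series <- function(hp, sap, resp,
                        r_peak_times = cumsum(c(0, hp)) / 1000,
                        interpolated = rep(FALSE, length(hp))) {
  n <- length(hp)
  if (length(sap) != n || length(resp) != n || length(interpolated) != n) {
    stop("hp, sap, resp and interpolated must have equal length", call. = FALSE)
  }
  if (length(r_peak_times) != n + 1L) {
    stop("r_peak_times must have length n_beats + 1", call. = FALSE)
  }
  if (any(hp <= 0)) stop("all hp must be positive", call. = FALSE)
  structure(list(hp = as.numeric(hp), sap = as.numeric(sap),
                 resp = as.numeric(resp),
                 r_peak_times = as.numeric(r_peak_times),
                 interpolated = as.logical(interpolated),
                 n_beats = n),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats (%.1f s), %d interpolated (%.1f%%)\n",
              x$n_beats, diff(range(x$r_peak_times)), sum(x$interpolated),
              100 * mean(x$interpolated)))
  cat(sprintf("  HP   %.0f ms (var %.0f ms^2)\n", mean(x$hp), pop_var(x$hp)))
  cat(sprintf("  SAP  %.1f mmHg (var %.1f mmHg^2)\n", mean(x$sap), pop_var(x$sap)))
  invisible(x)
}

#' @export
as.data.frame.beat_series <- function(x, ...) {
  data.frame(beat_index = seq_len(x$n_beats),
             t_r_peak_s = x$r_peak_times[seq_len(x$n_beats)],
             hp_ms = x$hp, sap_mmhg = x$sap, resp_au = x$resp,
             interpolated = as.integer(x$interpolated))
}

## subset consecutive beats [from, to]
subset_beats <- function(series, from, to) {
  idx <- from:to
  beat_series(series$hp[idx], series$sap[idx], series$resp[idx],
              r_peak_times = series$r_peak_times[c(idx, to + 1L)],
              interpolated = series$interpolated[idx])
}

#' Write / read a beat series as CSV
#'
#' The CSV layout has one row per beat with columns `beat_index`,
#' `t_r_peak_s`, `hp_ms`, `sap_mmhg`, `resp_au`, `interpolated` (0/1).
#'
#' @param series A `beat_series`.
#' @param path File path.
#' @return `read_beat_series` returns a `beat_series`;
#'   `write_beat_series` returns `path` invisibly.
#' @export
write_beat_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_series
#' @export
read_beat_series <- function(path) {
  d <- read.csv(path)
  need <- c("t_r_peak_s", "hp_ms", "sap_mmhg", "resp_au")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(d)
  beat_series(d$hp_ms, d$sap_mmhg, d$resp_au,
              r_peak_times = c(d$t_r_peak_s, d$t_r_peak_s[n] + d$hp_ms[n] / 1000),
              interpolated = if ("interpolated" %in% names(d))
                as.logical(d$interpolated) else rep(FALSE, n))
}
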