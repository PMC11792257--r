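#' Detect R-wave peaks on an ECG channel
#'
#' Threshold-based detector on the ECG first derivative with an adaptive
#' threshold: a crossing is declared where the positive derivative exceeds
#' `threshold_factor` times its running maximum over the preceding 2 s
#' (never less than 10% of the global derivative maximum, which suppresses
#' spurious crossings on baseline noise before the first QRS). Each crossing
#' is refined to the argmax of the raw ECG within the following 100 ms,
#' making the detection robust to beat-to-beat amplitude changes, and a
#' refractory period suppresses double detections.
#'
#' @param ecg Numeric ECG samples.
#' @param fs Sampling rate, Hz.
#' @param threshold_factor Fraction of the running derivative maximum
#'   (0 < f < 1, default 0.4).
#' @param refractory Minimum distance between peaks, s (default 0.25).
#' @return Strictly increasing R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_factor = 0.4, refractory = 0.25) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  if (threshold_factor <= 0 || threshold_factor >= 1) {
    stop("threshold_factor must be in (0, 1)", call. = FALSE)
  }
  if (refractory <= 0) stop("refractory must be positive", call. = FALSE)
  n <- length(ecg)
  if (n < 2L) stop("no peaks detected: signal too short", call. = FALSE)
  d <- c(0, diff(ecg)) * fs
  dpos <- pmax(d, 0)
  if (max(dpos) <= 0) stop("no peaks detected: derivative never positive", call. = FALSE)
  w <- max(2L, round(2 * fs))
  thr <- pmax(threshold_factor * trailing_max(dpos, w), 0.1 * max(dpos))
  above <- dpos > thr
  crossings <- which(above & !c(FALSE, above[-n]))
  if (length(crossings) == 0L) stop("no peaks detected", call. = FALSE)
  win <- max(1L, round(0.1 * fs))
  peaks <- integer(0)
  last <- -Inf
  for (i in crossings) {
    hi <- min(n, i + win)
    pk <- i - 1L + which.max(ecg[i:hi])
    t_pk <- (pk - 1L) / fs
    if (t_pk - last >= refractory) {
      peaks <- c(peaks, pk)
      last <- t_pk
    }
  }
  if (length(peaks) == 0L) stop("no peaks detected", call. = FALSE)
  (unique(peaks) - 1L) / fs
}

#' Build a beat series from R-peak times and raw AP/RESP channels
#'
#' The n-th heart period is the interval between consecutive R peaks, in ms;
#' the n-th SAP is the maximum of the arterial pressure over the half-open
#' sample window `[t[n], t[n+1])`; the n-th RESP value is the respiration
#' sample nearest to the beat-opening R peak.
#'
#' @param r_peak_times R-peak times in seconds (at least 3).
#' @param ap Arterial pressure samples, mmHg.
#' @param resp Respiration samples, a.u.
#' @param fs Sampling rate of `ap` and `resp`, Hz.
#' @return A [beat_series] with `length(r_peak_times) - 1` beats.
#' @export
build_beat_series <- function(r_peak_times, ap, resp, fs) {
  if (length(r_peak_times) < 3L) {
    stop("insufficient beats: need at least 3 R-peak times", call. = FALSE)
  }
  if (is.unsorted(r_peak_times, strictly = TRUE)) {
    stop("r_peak_times must be strictly increasing", call. = FALSE)
  }
  n_samp <- length(ap)
  if (length(resp) != n_samp) stop("ap and resp must have equal length", call. = FALSE)
  if (max(r_peak_times) > n_samp / fs) {
    stop("beat times exceed signal duration", call. = FALSE)
  }
  nb <- length(r_peak_times) - 1L
  hp <- 1000 * diff(r_peak_times)
  idx <- pmin(pmax(round(r_peak_times * fs) + 1L, 1L), n_samp)
  first <- floor(r_peak_times * fs) + 1L
  sap <- vapply(seq_len(nb), function(k) {
    lo <- first[k]
    hi <- max(lo, first[k + 1L] - 1L)  # half-open window [t_n, t_{n+1})
    max(ap[lo:min(hi, n_samp)])
  }, numeric(1))
  beat_series(hp, sap, resp[idx[seq_len(nb)]], r_peak_times = r_peak_times)
}

#' Repair out-of-range beats by linear interpolation
#'
#' Beats whose HP falls outside `hp_range` (missed detections, ectopic or
#' otherwise arrhythmic beats) are replaced by linear interpolation, over
#' the beat index, between the nearest in-range neighbours; SAP and RESP at
#' the same beats are interpolated identically. If the first or last beat is
#' out of range it takes the value of the nearest in-range beat. Repair
#' never changes the number of beats and is idempotent.
#'
#' @param series A [beat_series].
#' @param hp_range `c(lo, hi)` acceptable HP range in ms (default
#'   `c(300, 2000)`).
#' @return The repaired `beat_series`, with the `interpolated` mask updated
#'   and an attached `repair_report` attribute: list with `fraction`,
#'   `n_interpolated` and `warn` (`TRUE` when more than 5% of the series
#'   needed interpolation).
#' @export
repair_series <- function(series, hp_range = c(300, 2000)) {
  stopifnot(inherits(series, "beat_series"))
  if (hp_range[1] <= 0 || hp_range[1] >= hp_range[2]) {
    stop("hp_range must satisfy 0 < lo < hi", call. = FALSE)
  }
  bad <- series$hp < hp_range[1] | series$hp > hp_range[2]
  if (all(bad)) stop("unrepairable series: every beat out of range", call. = FALSE)
  out <- series
  if (any(bad)) {
    good <- which(!bad)
    fix <- function(v) {
      v[bad] <- approx(good, v[good], xout = which(bad), rule = 2)$y
      v
    }
    out$hp <- fix(series$hp)
    out$sap <- fix(series$sap)
    out$resp <- fix(series$resp)
    out$interpolated <- series$interpolated | bad
  }
  frac <- mean(bad)
  attr(out, "repair_report") <- list(fraction = frac,
                                     n_interpolated = sum(bad),
                                     warn = frac > 0.05)
  out
}

#' Randomly select a fixed-length segment of consecutive beats
#'
#' Draws the start index uniformly over all valid starts; the same seed
#' always yields the same segment.
#'
#' @param series A [beat_series].
#' @param length Segment length in beats (default 256).
#' @param seed Integer seed.
#' @return A `beat_series` of exactly `length` beats, with attribute
#'   `segment_start` (1-based start index).
#' @export
select_segment <- function(series, length = 256L, seed = 1L) {
  stopifnot(inherits(series, "beat_series"))
  length <- as.integer(length)
  if (series$n_beats < length) {
    stop(sprintf("series too short: %d beats required, %d available",
                 length, series$n_beats), call. = FALSE)
  }
  n_starts <- series$n_beats - length + 1L
  start <- if (n_starts == 1L) 1L else with_seed(seed, sample.int(n_starts, 1L))
  out <- subset_beats(series, start, start + length - 1L)
  attr(out, "segment_start") <- start
  out
}
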