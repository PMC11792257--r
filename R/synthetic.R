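## Synthetic closed-loop generators. These define the bench conditions for
## every estimator in the package: beat series with known directional
## coupling (RSA-like RESP->HP at the respiratory frequency, baroreflex-like
## SAP->HP at the LF rhythm, mechanical feedforward HP->SAP, and the weak
## HP->RESP pathway), plus raw-waveform synthesis for the extraction stage.

sim_presets <- function() {
  list(
    ## Orthostatically responsive subject: STAND withdraws the RSA pathway
    ## and engages the baroreflex.
    HEALTHY_REST  = list(condition = "REST",  mean_hp_ms = 884, sd_hp_ms = sqrt(749),
                         mean_sap_mmhg = 138, sd_sap_mmhg = sqrt(28.5),
                         resp_freq_hz = 0.268,
                         gain_resp_to_hp = 1.2, gain_sap_to_hp = 0.3,
                         gain_hp_to_sap = -0.4, gain_hp_to_resp = 0.05),
    HEALTHY_STAND = list(condition = "STAND", mean_hp_ms = 798, sd_hp_ms = sqrt(683),
                         mean_sap_mmhg = 143, sd_sap_mmhg = sqrt(40.6),
                         resp_freq_hz = 0.273,
                         gain_resp_to_hp = 0.35, gain_sap_to_hp = 1.0,
                         gain_hp_to_sap = -0.4, gain_hp_to_resp = 0.03),
    ## Blunted autonomic response: the coupling gains do not react to the
    ## postural challenge even though the haemodynamic operating point does.
    COVID_REST    = list(condition = "REST",  mean_hp_ms = 884, sd_hp_ms = sqrt(749),
                         mean_sap_mmhg = 138, sd_sap_mmhg = sqrt(28.5),
                         resp_freq_hz = 0.268,
                         gain_resp_to_hp = 0.7, gain_sap_to_hp = 0.5,
                         gain_hp_to_sap = -0.4, gain_hp_to_resp = 0.04),
    COVID_STAND   = list(condition = "STAND", mean_hp_ms = 798, sd_hp_ms = sqrt(683),
                         mean_sap_mmhg = 143, sd_sap_mmhg = sqrt(40.6),
                         resp_freq_hz = 0.273,
                         gain_resp_to_hp = 0.7, gain_sap_to_hp = 0.5,
                         gain_hp_to_sap = -0.4, gain_hp_to_resp = 0.04),
    UNCOUPLED     = list(condition = "REST",  gain_resp_to_hp = 0,
                         gain_sap_to_hp = 0, gain_hp_to_sap = 0,
                         gain_hp_to_resp = 0)
  )
}

#' Five-point coupling-gain ladder
#'
#' The fixed ladder of coupling gains referenced by the estimator-recovery
#' and statistical-power validations, from barely-coupled to strongly
#' coupled. `LADDER_5` is "top of the ladder".
#'
#' @return Named numeric vector `LADDER_1` .. `LADDER_5`.
#' @export
coupling_ladder <- function() {
  c(LADDER_1 = 0.1, LADDER_2 = 0.25, LADDER_3 = 0.5, LADDER_4 = 1, LADDER_5 = 2)
}

#' Configuration for the synthetic beat-series generators
#'
#' Bundles every tunable of the closed-loop generator: regime (means,
#' variances, respiratory and LF rhythm frequencies), directional coupling
#' gains, oscillator pole moduli and innovation scales. Presets encode the
#' study conditions: `HEALTHY_*` react to standing (RSA gain drops,
#' baroreflex gain rises), `COVID_*` keep their coupling gains across
#' conditions, `UNCOUPLED` has all four gains at zero.
#'
#' @param preset Optional preset name (`"HEALTHY_REST"`, `"HEALTHY_STAND"`,
#'   `"COVID_REST"`, `"COVID_STAND"`, `"UNCOUPLED"`).
#' @param ... Named overrides of individual fields. Available fields and
#'   defaults: `n_beats` (256), `mean_hp_ms` (884), `sd_hp_ms` (sqrt(749)),
#'   `mean_sap_mmhg` (138), `sd_sap_mmhg` (sqrt(28.5)), `resp_freq_hz`
#'   (0.268), `lf_freq_hz` (0.1), `gain_resp_to_hp`, `gain_hp_to_resp`,
#'   `gain_sap_to_hp`, `gain_hp_to_sap`, `resp_pole_modulus` (0.9),
#'   `lf_pole_modulus` (0.85), `hp_ar1` (0.3), `innovation_sd`
#'   (c(hp, sap, resp) = 1), `resp_noise_sd` (0.1), `condition`, `seed`.
#' @return Object of class `sim_config` (a validated list). The generating
#'   model's stability is checked at construction.
#' @export
#' @examples
#' cfg <- sim_config("HEALTHY_REST", seed = 7)
#' cfg$gain_resp_to_hp
sim_config <- function(preset = NULL, ...) {
  cfg <- list(
    n_beats = 256L,
    mean_hp_ms = 884, sd_hp_ms = sqrt(749),
    mean_sap_mmhg = 138, sd_sap_mmhg = sqrt(28.5),
    resp_freq_hz = 0.268, lf_freq_hz = 0.1,
    gain_resp_to_hp = 1.2, gain_hp_to_resp = 0.05,
    gain_sap_to_hp = 0.3, gain_hp_to_sap = -0.4,
    resp_pole_modulus = 0.9, lf_pole_modulus = 0.85,
    hp_ar1 = 0.3,
    innovation_sd = c(hp = 1, sap = 1, resp = 1),
    resp_noise_sd = 0.1,
    condition = "REST",
    seed = 1L
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(sim_presets()))
    cfg[names(sim_presets()[[preset]])] <- sim_presets()[[preset]]
    cfg$preset <- preset
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "preset"))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg$n_beats <- as.integer(cfg$n_beats)
  if (cfg$n_beats < 64L) stop("n_beats must be >= 64", call. = FALSE)
  mean_hp_s <- cfg$mean_hp_ms / 1000
  nyq <- 1 / (2 * mean_hp_s)
  if (cfg$resp_freq_hz <= 0 || cfg$resp_freq_hz >= nyq ||
      cfg$lf_freq_hz <= 0 || cfg$lf_freq_hz >= nyq) {
    stop("rhythm frequencies must lie in (0, ", round(nyq, 3), ") Hz", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  if (!subject_model_stable(cfg)) {
    stop("unstable generator configuration", call. = FALSE)
  }
  cfg
}

## Structural coefficient matrices of the trivariate closed loop, channel
## order (hp, sap, resp). Lag-0: hp <- sap, hp <- resp. Lag-1: sap <- hp,
## resp <- hp, own AR terms. Lag-2: oscillator terms.
subject_model_matrices <- function(cfg) {
  mean_hp_s <- cfg$mean_hp_ms / 1000
  th_r <- 2 * pi * cfg$resp_freq_hz * mean_hp_s
  th_l <- 2 * pi * cfg$lf_freq_hz * mean_hp_s
  rr <- cfg$resp_pole_modulus; rl <- cfg$lf_pole_modulus
  A0 <- rbind(c(0, cfg$gain_sap_to_hp, cfg$gain_resp_to_hp), 0, 0)
  A1 <- rbind(c(cfg$hp_ar1, 0, 0),
              c(cfg$gain_hp_to_sap, 2 * rl * cos(th_l), 0),
              c(cfg$gain_hp_to_resp, 0, 2 * rr * cos(th_r)))
  A2 <- rbind(0, c(0, -rl^2, 0), c(0, 0, -rr^2))
  list(A0 = A0, A1 = A1, A2 = A2)
}

companion_stable <- function(A0, lags) {
  d <- nrow(A0)
  p <- length(lags)
  M0 <- solve(diag(d) - A0)
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[1:d, (d * k - d + 1L):(d * k)] <- M0 %*% lags[[k]]
  if (p > 1L) comp[(d + 1L):(d * p), 1:(d * p - d)] <- diag(d * p - d)
  all(Mod(eigen(comp, only.values = TRUE)$values) < 1)
}

subject_model_stable <- function(cfg) {
  m <- subject_model_matrices(cfg)
  companion_stable(m$A0, list(m$A1, m$A2))
}

#' Simulate a coupled series pair with known directional coupling
#'
#' Bivariate bench generator: `x` is a narrow-band autoregressive source
#' (an AR(2) resonance at the configured rhythm frequency) and `y` a
#' first-order autoregression; coupling `x -> y` acts at lag 0 with gain
#' `gain_resp_to_hp`, coupling `y -> x` at lag 1 with gain
#' `gain_hp_to_resp`. With `band = "hf"` the source sits at
#' `resp_freq_hz` (RSA-like pair), with `band = "lf"` at `lf_freq_hz`
#' (baroreflex-like pair).
#'
#' @param config A [sim_config()].
#' @param band `"hf"` or `"lf"`: which rhythm the source oscillates at.
#' @return List with numeric vectors `x`, `y` and `ground_truth` (list with
#'   the generating coefficients and logical coupling flags).
#' @export
#' @examples
#' sim <- simulate_coupled_pair(sim_config(seed = 3, gain_resp_to_hp = 2))
#' cor(sim$x, sim$y)
simulate_coupled_pair <- function(config, band = c("hf", "lf")) {
  stopifnot(inherits(config, "sim_config"))
  band <- match.arg(band)
  mean_hp_s <- config$mean_hp_ms / 1000
  f_hz <- if (band == "hf") config$resp_freq_hz else config$lf_freq_hz
  th <- 2 * pi * f_hz * mean_hp_s
  rho <- if (band == "hf") config$resp_pole_modulus else config$lf_pole_modulus
  g_xy <- config$gain_resp_to_hp
  g_yx <- config$gain_hp_to_resp
  a_y <- config$hp_ar1
  ## stability of the 2-channel loop
  A0 <- rbind(c(0, 0), c(g_xy, 0))
  A1 <- rbind(c(2 * rho * cos(th), g_yx), c(0, a_y))
  A2 <- rbind(c(-rho^2, 0), c(0, 0))
  if (!companion_stable(A0, list(A1, A2))) {
    stop("unstable generator configuration", call. = FALSE)
  }
  n <- config$n_beats
  burn <- 256L
  sim <- with_seed(config$seed, {
    ex <- rnorm(n + burn)
    ey <- rnorm(n + burn)
    x <- numeric(n + burn); y <- numeric(n + burn)
    for (k in 3:(n + burn)) {
      x[k] <- 2 * rho * cos(th) * x[k - 1L] - rho^2 * x[k - 2L] +
        g_yx * y[k - 1L] + ex[k]
      y[k] <- a_y * y[k - 1L] + g_xy * x[k] + ey[k]
    }
    list(x = x[(burn + 1L):(burn + n)], y = y[(burn + 1L):(burn + n)])
  })
  list(x = sim$x, y = sim$y,
       ground_truth = list(
         band = band, source_freq_hz = f_hz, pole_modulus = rho,
         gain_x_to_y = g_xy, gain_y_to_x = g_yx,
         coupling = c(x_to_y = g_xy != 0, y_to_x = g_yx != 0),
         mean_hp_s = mean_hp_s))
}

#' Simulate a closed-loop subject (HP, SAP, RESP beat series)
#'
#' Trivariate closed-loop realization: RESP is an autonomous narrow-band
#' oscillation at the respiratory frequency (optionally fed back from HP at
#' lag 1), SAP carries an LF resonance (Mayer-wave-like) and is driven by HP
#' at lag 1 (mechanical feedforward), HP is driven by RESP (lag 0, RSA) and
#' SAP (lag 0, baroreflex arm). Channels are rescaled to the configured
#' means and standard deviations; a small white measurement noise is added
#' to RESP only.
#'
#' @param config A [sim_config()].
#' @return A [beat_series] of `config$n_beats` beats with attribute
#'   `ground_truth`: list with the structural coefficient matrices, the
#'   coupling gains and per-direction coupling flags, and the config used.
#' @export
#' @examples
#' bs <- simulate_subject(sim_config("HEALTHY_REST", seed = 11))
#' bs
simulate_subject <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- subject_model_matrices(config)
  n <- config$n_beats
  burn <- 512L
  ntot <- n + burn
  sds <- config$innovation_sd
  z <- with_seed(config$seed, {
    e <- cbind(rnorm(ntot, sd = sds[["hp"]]), rnorm(ntot, sd = sds[["sap"]]),
               rnorm(ntot, sd = sds[["resp"]]))
    noise_r <- rnorm(n, sd = config$resp_noise_sd)
    z <- matrix(0, ntot, 3L)  # (hp, sap, resp)
    for (k in 3:ntot) {
      lagged <- m$A1 %*% z[k - 1L, ] + m$A2 %*% z[k - 2L, ]
      ## generation order inside the beat: resp, sap, then hp (lag-0 links)
      z[k, 3L] <- lagged[3L] + e[k, 3L]
      z[k, 2L] <- lagged[2L] + e[k, 2L]
      z[k, 1L] <- lagged[1L] + m$A0[1L, 2L] * z[k, 2L] +
        m$A0[1L, 3L] * z[k, 3L] + e[k, 1L]
    }
    z <- z[(burn + 1L):ntot, , drop = FALSE]
    z[, 3L] <- z[, 3L] + noise_r
    z
  })
  rescale <- function(v, mu, s) mu + s * (v - mean(v)) / stats::sd(v)
  hp <- rescale(z[, 1L], config$mean_hp_ms, config$sd_hp_ms)
  sap <- rescale(z[, 2L], config$mean_sap_mmhg, config$sd_sap_mmhg)
  resp <- rescale(z[, 3L], 0, 1)
  out <- beat_series(hp, sap, resp)
  attr(out, "ground_truth") <- list(
    matrices = m,
    gains = c(resp_to_hp = config$gain_resp_to_hp,
              hp_to_resp = config$gain_hp_to_resp,
              sap_to_hp = config$gain_sap_to_hp,
              hp_to_sap = config$gain_hp_to_sap),
    coupling = c(resp_to_hp = config$gain_resp_to_hp != 0,
                 hp_to_resp = config$gain_hp_to_resp != 0,
                 sap_to_hp = config$gain_sap_to_hp != 0,
                 hp_to_sap = config$gain_hp_to_sap != 0),
    config = config)
  out
}

#' Synthesize raw 400 Hz waveforms from a beat series
#'
#' Builds a raw recording whose beat-level ground truth is known: the ECG is
#' a train of template QRS complexes centred at the cumulative R-peak times,
#' the arterial pressure is a per-beat half-sine pulse whose maximum equals
#' the SAP value of that beat, and the respiration channel is a smooth
#' spline through the per-beat RESP values. Feeding the result through
#' [detect_r_peaks()] and [build_beat_series()] recovers the generating HP
#' within sampling tolerance and SAP at the pulse maxima.
#'
#' @param series A [beat_series].
#' @param fs Sampling rate, Hz (default 400).
#' @param noise_sd Standard deviation of additive ECG noise relative to the
#'   QRS amplitude (default 0.002); set 0 for a clean signal.
#' @param seed Seed for the noise.
#' @return Object of class `raw_recording`: list with `ecg`, `ap`, `resp`,
#'   `fs`, `t`, `condition_label` and `r_peak_times`, the ground-truth peak
#'   times (the input beat grid shifted by a 0.5 s baseline lead-in).
#' @export
simulate_raw_signals <- function(series, fs = 400, noise_sd = 0.002, seed = 1L) {
  stopifnot(inherits(series, "beat_series"))
  qrs_half <- 0.025  # s, half-width of the QRS template
  if (min(series$hp) / 1000 <= 2 * qrs_half || fs < 4 / (min(series$hp) / 1000)) {
    stop("fs too low to resolve the shortest heart period", call. = FALSE)
  }
  lead_in <- 0.5  # s of baseline before the first QRS
  tk <- series$r_peak_times + lead_in
  dur <- tk[length(tk)] + 0.5
  t <- seq(0, dur, by = 1 / fs)
  nt <- length(t)
  ## ECG: raised-cosine-power QRS template, unique maximum at each tk
  ecg <- numeric(nt)
  for (tc in tk) {
    lo <- max(1L, ceiling((tc - qrs_half) * fs) + 1L)
    hi <- min(nt, floor((tc + qrs_half) * fs) + 1L)
    u <- (t[lo:hi] - tc) / qrs_half
    ecg[lo:hi] <- ecg[lo:hi] + cos(pi * u / 2)^4
  }
  if (noise_sd > 0) {
    ecg <- ecg + with_seed(seed, rnorm(nt, sd = noise_sd))
  }
  ## AP: half-sine systolic pulse per beat over a diastolic baseline
  pulse_dur <- 0.25
  ap <- numeric(nt)
  dia <- series$sap - 40
  ap[] <- dia[1L]
  for (k in seq_len(series$n_beats)) {
    lo <- floor(tk[k] * fs) + 1L
    hi <- min(nt, floor(tk[k + 1L] * fs))
    seg <- t[lo:hi] - tk[k]
    wav <- dia[k] + (series$sap[k] - dia[k]) * pmax(0, sin(pi * seg / pulse_dur))
    ap[lo:hi] <- wav
  }
  ## RESP: smooth curve through the per-beat values
  nb <- series$n_beats
  resp <- spline(tk[seq_len(nb)], series$resp, xout = t, method = "natural")$y
  structure(list(ecg = ecg, ap = ap, resp = resp, fs = fs, t = t,
                 r_peak_times = tk,   # ground truth, shifted by the lead-in
                 condition_label = "SYNTHETIC"),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %.1f s at %g Hz (%d samples), label %s\n",
              x$t[length(x$t)], x$fs, length(x$ecg), x$condition_label))
  invisible(x)
}

#' Read a raw three-channel recording from a delimited text file
#'
#' Expects a header with columns named `ecg`, `ap` and `resp` (case
#' insensitive); the sampling rate is supplied by the caller.
#'
#' @param path CSV file path.
#' @param fs Sampling rate, Hz.
#' @param condition_label Free-text condition tag.
#' @return A `raw_recording`.
#' @export
read_raw_recording <- function(path, fs, condition_label = "") {
  d <- read.csv(path)
  names(d) <- tolower(names(d))
  need <- c("ecg", "ap", "resp")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "),
         call. = FALSE)
  }
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (nrow(d) < 2 * fs) stop("recording shorter than 2 s", call. = FALSE)
  structure(list(ecg = d$ecg, ap = d$ap, resp = d$resp, fs = fs,
                 t = (seq_len(nrow(d)) - 1L) / fs,
                 condition_label = condition_label),
            class = "raw_recording")
}
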