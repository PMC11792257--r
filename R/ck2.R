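#' Parametric cross-spectral matrix of a bivariate AR model
#'
#' Evaluates `S(f) = H(f) Lambda H(f)^H` with `H(f) = [I - A(f)]^-1`, where
#' `A(f)` is the coefficient polynomial matrix evaluated at
#' `z = exp(-i 2 pi f)` (including the lag-0 instantaneous term) and `Lambda`
#' the diagonal innovation covariance, on a uniform grid of `n_freq` points
#' over `[0, 0.5]` cycles/beat.
#'
#' @param model A stable `bar_model`.
#' @param n_freq Grid size (default 1025).
#' @return List with `f_cpb` (grid, cycles/beat), real vectors `S11`, `S22`
#'   and complex vector `S12`.
#' @export
spectral_matrix <- function(model, n_freq = 1025L) {
  stopifnot(inherits(model, "bar_model"))
  if (!model$stable) stop("refusing to evaluate an unstable model", call. = FALSE)
  bar_spectrum(model$A, model$lambda, model$order, n_freq)
}

## Spectral matrix from raw coefficient array (shared with the causal path,
## which evaluates a modified coefficient set without refitting). `f` may be
## any subset of beat-domain frequencies, e.g. just the points of one band.
bar_spectrum <- function(A, lambda, p, n_freq, f = seq(0, 0.5, length.out = n_freq)) {
  E <- exp(-2i * pi * outer(f, 0:p))
  A11 <- as.vector(E %*% A[1L, 1L, ])
  A12 <- as.vector(E %*% A[1L, 2L, ])
  A21 <- as.vector(E %*% A[2L, 1L, ])
  A22 <- as.vector(E %*% A[2L, 2L, ])
  det <- (1 - A11) * (1 - A22) - A12 * A21
  if (min(Mod(det)) < 1e-12) stop("spectral singularity", call. = FALSE)
  H11 <- (1 - A22) / det
  H12 <- A12 / det
  H21 <- A21 / det
  H22 <- (1 - A11) / det
  l1 <- lambda[1L]; l2 <- lambda[2L]
  S11 <- l1 * Mod(H11)^2 + l2 * Mod(H12)^2
  S22 <- l1 * Mod(H21)^2 + l2 * Mod(H22)^2
  S12 <- l1 * H11 * Conj(H21) + l2 * H12 * Conj(H22)
  list(f_cpb = f, S11 = S11, S22 = S22, S12 = S12)
}

coherence_from_spectrum <- function(S) {
  if (min(S$S11) <= 0 || min(S$S22) <= 0) stop("spectral singularity", call. = FALSE)
  k2 <- Mod(S$S12)^2 / (S$S11 * S$S22)
  ## |S12|^2 <= S11*S22 holds exactly (S is positive semidefinite); anything
  ## beyond rounding error signals a real defect and must not be masked
  if (max(k2) > 1 + 1e-9) {
    stop("coherence exceeded 1 beyond numerical tolerance", call. = FALSE)
  }
  pmin(pmax(k2, 0), 1)
}

#' Squared coherence function of a bivariate AR model
#'
#' `K2(f) = |S12(f)|^2 / (S11(f) S22(f))`, the parametric squared coherence,
#' lies in `[0, 1]` and is symmetric under exchange of the two channels.
#'
#' @inheritParams spectral_matrix
#' @return List with `f_cpb` and `k2`.
#' @export
squared_coherence <- function(model, n_freq = 1025L) {
  S <- spectral_matrix(model, n_freq)
  list(f_cpb = S$f_cpb, k2 = coherence_from_spectrum(S))
}

#' Causal squared coherence function of a bivariate AR model
#'
#' The causal squared coherence in a given direction is the squared
#' coherence of a modified model in which every cross-regression coefficient
#' on the reverse pathway (from the effect back to the cause) is forced to
#' zero, all other coefficients and the innovation variances being kept. The
#' marker is directional: it rises above zero only with the strength of the
#' coupling from the cause to the effect, and when the reverse pathway is
#' already zero it coincides with the ordinary squared coherence.
#'
#' @inheritParams spectral_matrix
#' @param direction `"x_to_y"` (channel 1 drives channel 2) or `"y_to_x"`.
#' @return List with `f_cpb`, `ck2` and `direction`.
#' @export
causal_squared_coherence <- function(model, direction = c("x_to_y", "y_to_x"),
                                     n_freq = 1025L) {
  stopifnot(inherits(model, "bar_model"))
  if (!model$stable) stop("refusing to evaluate an unstable model", call. = FALSE)
  direction <- match.arg(direction)
  A <- model$A
  if (direction == "x_to_y") {
    A[1L, 2L, ] <- 0   # silence the y -> x (effect -> cause) pathway
  } else {
    A[2L, 1L, ] <- 0   # silence the x -> y pathway
  }
  S <- bar_spectrum(A, model$lambda, model$order, n_freq)
  list(f_cpb = S$f_cpb, ck2 = coherence_from_spectrum(S), direction = direction)
}

#' Average a spectral function over a frequency band
#'
#' Arithmetic mean of a function sampled on the beat-domain frequency grid
#' over the grid points whose Hz-equivalent frequency (`f_cpb / mean_hp_s`)
#' falls in the closed-open band `[lo, hi)`.
#'
#' @param values Function values on the grid.
#' @param f_cpb Grid in cycles/beat.
#' @param band `c(lo, hi)` in Hz.
#' @param mean_hp_s Mean heart period of the segment in seconds.
#' @return Scalar band average.
#' @export
band_average <- function(values, f_cpb, band, mean_hp_s) {
  stopifnot(length(values) == length(f_cpb), length(band) == 2L, band[1] < band[2],
            mean_hp_s > 0)
  f_hz <- f_cpb / mean_hp_s
  idx <- f_hz >= band[1] & f_hz < band[2]
  if (!any(idx)) {
    stop("empty band: no grid point in [", band[1], ", ", band[2], ") Hz",
         call. = FALSE)
  }
  mean(values[idx])
}

#' Closed-loop spectral coupling analysis of a beat-series pair
#'
#' The main fitting function of the package. Both series are linearly
#' detrended and scaled to unit variance, a bivariate AR model with the
#' requested direction-specific latencies is identified (order selected by
#' the multivariate Akaike figure of merit), and the squared coherence `K2`
#' plus the causal squared coherence `CK2` in both directions are evaluated
#' on a uniform frequency grid and averaged in the LF and HF bands.
#'
#' For the cardiorespiratory pair call `ck2(resp, hp, ...)` with the default
#' latency `c(0, 1)` (RESP acts on HP within the beat, HP on RESP one beat
#' later) and read the HF-band markers; for the cardiovascular pair call
#' `ck2(sap, hp, ...)` (SAP on HP within the beat via the baroreflex, HP on
#' SAP one beat later via the mechanical feedforward) and read the LF-band
#' markers.
#'
#' @param x Cause-side series of the lag-0 pathway (e.g. RESP or SAP).
#' @param y Effect-side series (e.g. HP).
#' @param mean_hp_s Mean heart period of the segment in seconds; converts
#'   beat-domain frequencies to Hz. For HP in ms use `mean(hp)/1000`.
#' @param order_range BAR candidate orders, default `c(5, 14)`.
#' @param latency `c(k_xy, k_yx)` minimum cross-regression lags.
#' @param n_freq Frequency-grid size, default 1025.
#' @param bands Band definition as returned by [lf_hf_bands()].
#' @param labels Channel names for printing.
#' @return Object of class `ck2`: the fitted `bar_model` (`$model`), spectral
#'   functions (`$f_cpb`, `$f_hz`, `$k2`, `$ck2_x_to_y`, `$ck2_y_to_x`) and a
#'   named vector `$markers` with the band-averaged markers
#'   `k2_lf`, `k2_hf`, `ck2_x_to_y_lf`, `ck2_x_to_y_hf`, `ck2_y_to_x_lf`,
#'   `ck2_y_to_x_hf`. If the selected model is unstable the spectral fields
#'   are `NULL` and the markers `NA` (flagged in `$stable`).
#' @export
#' @examples
#' sim <- simulate_coupled_pair(sim_config(seed = 1,
#'   gain_resp_to_hp = 2, gain_hp_to_resp = 0))
#' fit <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
#' fit
ck2 <- function(x, y, mean_hp_s = 1, order_range = c(5L, 14L),
                latency = c(0L, 1L), n_freq = 1025L, bands = lf_hf_bands(),
                labels = c(deparse(substitute(x))[1], deparse(substitute(y))[1])) {
  xs <- normalize_series(x)
  ys <- normalize_series(y)
  model <- fit_bar(xs, ys, order_range = order_range, latency = latency,
                   labels = labels)
  marker_names <- c("k2_lf", "k2_hf", "ck2_x_to_y_lf", "ck2_x_to_y_hf",
                    "ck2_y_to_x_lf", "ck2_y_to_x_hf")
  out <- list(model = model, mean_hp_s = mean_hp_s, bands = bands,
              stable = model$stable, labels = labels, n_freq = n_freq)
  if (!model$stable) {
    out$markers <- stats::setNames(rep(NA_real_, 6L), marker_names)
    class(out) <- "ck2"
    return(out)
  }
  k2 <- squared_coherence(model, n_freq)
  cxy <- causal_squared_coherence(model, "x_to_y", n_freq)
  cyx <- causal_squared_coherence(model, "y_to_x", n_freq)
  f <- k2$f_cpb
  ba <- function(v, band) band_average(v, f, band, mean_hp_s)
  out$f_cpb <- f
  out$f_hz <- f / mean_hp_s
  out$k2 <- k2$k2
  out$ck2_x_to_y <- cxy$ck2
  out$ck2_y_to_x <- cyx$ck2
  out$markers <- stats::setNames(c(
    ba(k2$k2, bands$lf), ba(k2$k2, bands$hf),
    ba(cxy$ck2, bands$lf), ba(cxy$ck2, bands$hf),
    ba(cyx$ck2, bands$lf), ba(cyx$ck2, bands$hf)
  ), marker_names)
  class(out) <- "ck2"
  out
}

#' @export
print.ck2 <- function(x, digits = 3, ...) {
  cat(sprintf("Closed-loop spectral coupling: %s <-> %s (BAR order %d)\n",
              x$labels[1], x$labels[2], x$model$order))
  if (!x$stable) {
    cat("Selected model is UNSTABLE; markers are NA.\n")
    return(invisible(x))
  }
  m <- x$markers
  cat(sprintf("  K2      LF %.*f   HF %.*f\n", digits, m["k2_lf"], digits, m["k2_hf"]))
  cat(sprintf("  CK2 %s->%s  LF %.*f   HF %.*f\n", x$labels[1], x$labels[2],
              digits, m["ck2_x_to_y_lf"], digits, m["ck2_x_to_y_hf"]))
  cat(sprintf("  CK2 %s->%s  LF %.*f   HF %.*f\n", x$labels[2], x$labels[1],
              digits, m["ck2_y_to_x_lf"], digits, m["ck2_y_to_x_hf"]))
  invisible(x)
}

#' @export
summary.ck2 <- function(object, ...) {
  print(object$model)
  print(object)
  invisible(object)
}

#' @export
coef.ck2 <- function(object, ...) coef(object$model)

#' @export
residuals.ck2 <- function(object, ...) residuals(object$model)

#' Plot K2 and CK2 spectral functions
#'
#' Draws the squared coherence and both causal squared coherence functions
#' against frequency in Hz, with the LF and HF bands shaded.
#'
#' @param x A `ck2` object.
#' @param ... Passed to the underlying plot call.
#' @export
plot.ck2 <- function(x, ...) {
  if (!x$stable) stop("nothing to plot: model unstable", call. = FALSE)
  plot.default(x$f_hz, x$k2, type = "l", ylim = c(0, 1),
               xlab = "Frequency [Hz]", ylab = expression(K^2 ~ "/" ~ CK^2), ...)
  for (b in x$bands) {
    polygon(c(b[1], b[2], b[2], b[1]), c(0, 0, 1, 1),
            col = adjustcolor("grey", 0.25), border = NA)
  }
  lines(x$f_hz, x$k2, lwd = 2)
  lines(x$f_hz, x$ck2_x_to_y, col = "firebrick", lwd = 1.5)
  lines(x$f_hz, x$ck2_y_to_x, col = "steelblue", lwd = 1.5)
  legend("topright", bty = "n", lwd = c(2, 1.5, 1.5),
         col = c("black", "firebrick", "steelblue"),
         legend = c(expression(K^2),
                    paste0(x$labels[1], " → ", x$labels[2]),
                    paste0(x$labels[2], " → ", x$labels[1])))
  invisible(x)
}
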