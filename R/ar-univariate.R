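#' Time-domain markers of a beat series
#'
#' Mean and variance of a beat-to-beat series (e.g. heart period in ms or
#' systolic pressure in mmHg). The variance uses the population (divide-by-n)
#' convention, consistent with the biased autocorrelation estimate used by
#' [fit_ar()].
#'
#' @param x Numeric vector, length >= 2.
#' @return Named list with elements `mean` and `variance`.
#' @export
#' @examples
#' time_domain_markers(c(700, 900))
time_domain_markers <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("series must be numeric with length >= 2", call. = FALSE)
  }
  list(mean = mean(x), variance = pop_var(x))
}

## Levinson-Durbin recursion on an autocovariance sequence r[0..p].
## Returns coefficients a[1..m] (x(n) = sum a_k x(n-k) + w) and the
## prediction-error variance for every order m = 1..p.
levinson_durbin <- function(r, order) {
  p <- order
  a_prev <- numeric(0)
  e <- r[1L]
  coefs <- vector("list", p)
  sig2 <- numeric(p)
  for (m in seq_len(p)) {
    k <- (r[m + 1L] - if (m > 1L) sum(a_prev * r[m:2L]) else 0) / e
    a <- c(a_prev - k * rev(a_prev), k)
    e <- e * (1 - k^2)
    coefs[[m]] <- a
    sig2[m] <- e
    a_prev <- a
  }
  list(coefficients = coefs, sigma2 = sig2)
}

#' Fit a univariate autoregressive model to a beat series
#'
#' Solves the least-squares AR identification problem via the Levinson-Durbin
#' recursion on the biased (divide-by-n) autocorrelation estimate, selecting
#' the order that minimises the Akaike information criterion
#' `n*log(sigma2_w) + 2p` over `order_range`. The series is linearly detrended
#' (which removes the mean) before fitting; the raw-series mean and the
#' detrended-series variance are stored alongside the coefficients.
#'
#' The biased autocorrelation estimate guarantees that the fitted model is
#' stable (all poles strictly inside the unit circle).
#'
#' @param x Numeric beat series.
#' @param order_range Integer vector `c(min, max)` of candidate orders
#'   (default `c(8, 14)`).
#' @param mean_hp_s Mean heart period of the analysed segment, in seconds.
#'   Beat-domain frequencies (cycles/beat) are converted to Hz by dividing by
#'   this value; use the segment's mean HP even when fitting SAP or RESP
#'   series, since all three share the beat axis.
#' @return An object of class `ar_model`: list with `coefficients`, `order`,
#'   `sigma2_w`, `series_mean`, `series_variance` (detrended, population
#'   convention), `mean_hp_s`, `n`, `aic` (per candidate order) and `stable`.
#' @seealso [decompose_spectrum()], [band_power()], [ar_psd()]
#' @export
#' @examples
#' x <- as.numeric(arima.sim(list(ar = c(1.2, -0.8)), 512))
#' m <- fit_ar(x)
#' m$order
fit_ar <- function(x, order_range = c(8L, 14L), mean_hp_s = 1) {
  if (!is.numeric(x)) stop("series must be numeric", call. = FALSE)
  order_range <- as.integer(order_range)
  p_max <- max(order_range)
  p_min <- min(order_range)
  n <- length(x)
  if (n <= p_max + 1L) {
    stop("series too short for maximum candidate order ", p_max, call. = FALSE)
  }
  mu <- mean(x)
  xd <- lin_detrend(x)
  v <- mean(xd^2)
  if (v <= 0 || !is.finite(v)) stop("degenerate series: zero variance", call. = FALSE)
  ## biased autocovariance r[0..p_max]
  r <- vapply(0:p_max, function(k) sum(xd[seq_len(n - k)] * xd[(1L + k):n]) / n,
              numeric(1))
  ld <- levinson_durbin(r, p_max)
  orders <- p_min:p_max
  aic <- n * log(ld$sigma2[orders]) + 2 * orders
  p <- orders[which.min(aic)]
  a <- ld$coefficients[[p]]
  poles <- ar_poles(a)
  structure(list(
    coefficients = a,
    order = p,
    sigma2_w = ld$sigma2[p],
    series_mean = mu,
    series_variance = v,
    mean_hp_s = mean_hp_s,
    n = n,
    aic = stats::setNames(aic, orders),
    poles = poles,
    stable = all(Mod(poles) < 1)
  ), class = "ar_model")
}

## Poles of 1 - sum a_k z^-k: reciprocal roots of the polynomial in z^-1.
ar_poles <- function(a) {
  1 / polyroot(c(1, -a))
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("AR(%d) model, n = %d, sigma2_w = %.4g (series variance %.4g)\n",
              x$order, x$n, x$sigma2_w, x$series_variance))
  if (!x$stable) cat("WARNING: model unstable (pole on/outside unit circle)\n")
  invisible(x)
}

#' @export
coef.ar_model <- function(object, ...) object$coefficients

#' Parametric power spectral density of a fitted AR model
#'
#' @param model An `ar_model`.
#' @param f_cpb Frequencies in cycles/beat (vector in `[0, 0.5]`).
#' @return PSD values `sigma2_w / |1 - sum a_k e^(-i 2 pi f k)|^2`, in series
#'   units squared per cycle/beat (two-sided convention: integrating over
#'   `[-0.5, 0.5]` returns the process variance).
#' @export
ar_psd <- function(model, f_cpb = seq(0, 0.5, length.out = 1025L)) {
  a <- model$coefficients
  E <- exp(-2i * pi * outer(f_cpb, seq_along(a)))
  A <- 1 - as.vector(E %*% a)
  model$sigma2_w / Mod(A)^2
}

#' @export
plot.ar_model <- function(x, n_freq = 1025L, log = "y", ...) {
  f <- seq(0, 0.5, length.out = n_freq)
  psd <- ar_psd(x, f)
  fhz <- f / x$mean_hp_s
  plot.default(fhz, psd, type = "l", log = log, xlab = "Frequency [Hz]",
               ylab = "PSD", ...)
  comps <- decompose_spectrum(x)
  abline(v = comps$central_frequency_hz, lty = 3, col = "grey50")
  invisible(x)
}
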