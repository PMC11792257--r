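## Shared fixtures and independent oracles, all built in code.

## Random stable AR(p) coefficients: poles drawn inside the unit circle
## (moduli <= 0.95), mixed real/complex-conjugate, polynomial assembled by
## convolution so coefficients are exactly real.
random_stable_ar <- function(p, seed) {
  withr::with_seed(seed, {
    coefs <- c(1)
    k <- 0L
    while (k < p) {
      if (p - k >= 2L && runif(1) < 0.8) {
        rho <- runif(1, 0.3, 0.95)
        th <- runif(1, 0.05, 0.95) * pi
        ## (1 - 2 rho cos(th) z^-1 + rho^2 z^-2)
        coefs <- convolve(coefs, rev(c(1, -2 * rho * cos(th), rho^2)),
                          type = "open")
        k <- k + 2L
      } else {
        r <- runif(1, -0.9, 0.9)
        coefs <- convolve(coefs, rev(c(1, -r)), type = "open")
        k <- k + 1L
      }
    }
    -coefs[-1]  # x(n) = sum a_k x(n-k) + w
  })
}

## Build an ar_model object directly from known coefficients.
ar_model_from_coef <- function(a, sigma2 = 1, mean_hp_s = 1) {
  structure(list(coefficients = a, order = length(a), sigma2_w = sigma2,
                 series_mean = 0, series_variance = NA_real_,
                 mean_hp_s = mean_hp_s, n = NA_integer_, aic = NULL,
                 poles = 1 / polyroot(c(1, -a)),
                 stable = all(Mod(1 / polyroot(c(1, -a))) < 1)),
            class = "ar_model")
}

## Oracle: process variance of an AR model by dense trapezoidal integration
## of its PSD over [-1/2, 1/2] (independent of the residue path).
ar_variance_by_integration <- function(a, sigma2, n_grid = 8193L) {
  f <- seq(-0.5, 0.5, length.out = n_grid)
  A <- 1 - vapply(f, function(ff) sum(a * exp(-2i * pi * ff * seq_along(a))),
                  complex(1))
  psd <- sigma2 / Mod(A)^2
  sum(diff(f) * (psd[-1] + psd[-n_grid])) / 2
}

## Oracle: Yule-Walker coefficients by a direct Toeplitz normal-equations
## solve on the biased autocovariance (independent of Levinson-Durbin).
yule_walker_direct <- function(x, p) {
  n <- length(x)
  xd <- x - mean(x)
  r <- vapply(0:p, function(k) sum(xd[seq_len(n - k)] * xd[(1L + k):n]) / n,
              numeric(1))
  solve(toeplitz(r[1:p]), r[2:(p + 1L)])
}

## Independent linear detrend via lm (oracle for the package's detrending).
lin_detrend_oracle <- function(x) {
  unname(stats::residuals(stats::lm(x ~ seq_along(x))))
}

## Relabel the two channels of a bar_model (oracle for K2 swap symmetry).
swap_bar_channels <- function(model) {
  out <- model
  p1 <- model$order + 1L
  A <- array(0, dim = dim(model$A))
  for (i in 1:2) for (j in 1:2) A[i, j, ] <- model$A[3L - i, 3L - j, ]
  out$A <- A
  out$lambda <- rev(model$lambda)
  out$labels <- rev(model$labels)
  out$latency <- rev(model$latency)
  out
}

## Oracle: exact stationary variance of channel 1 of a bivariate AR model by
## solving the discrete Lyapunov equation of its companion form.
bar_channel_variance <- function(model) {
  A <- model$A; p <- model$order
  M0 <- solve(diag(2) - A[, , 1L])
  FF <- matrix(0, 2L * p, 2L * p)
  for (k in seq_len(p)) FF[1:2, (2L * k - 1L):(2L * k)] <- M0 %*% A[, , k + 1L]
  if (p > 1L) FF[3:(2L * p), 1:(2L * p - 2L)] <- diag(2L * p - 2L)
  Q <- matrix(0, 2L * p, 2L * p)
  Q[1:2, 1:2] <- M0 %*% diag(model$lambda) %*% t(M0)
  vecP <- solve(diag((2 * p)^2) - kronecker(FF, FF), as.vector(Q))
  matrix(vecP, 2L * p)[1L, 1L]
}

## A fitted stable BAR model on data from a randomized coupled generator;
## retries seeds until the fit is stable (returns NULL after 5 attempts).
random_stable_bar_fit <- function(seed) {
  for (k in 0:4) {
    cfg <- tryCatch(
      withr::with_seed(seed + 1000L * k, {
        sim_config(seed = seed + 1000L * k,
                   gain_resp_to_hp = runif(1, 0, 2),
                   gain_hp_to_resp = runif(1, 0, 0.4),
                   resp_freq_hz = runif(1, 0.18, 0.35),
                   resp_pole_modulus = runif(1, 0.6, 0.95),
                   hp_ar1 = runif(1, -0.5, 0.7))
      }),
      error = function(e) NULL)  # randomly drawn loop may be unstable: redraw
    if (is.null(cfg)) next
    sim <- simulate_coupled_pair(cfg)
    m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
    if (m$stable) return(m)
  }
  NULL
}

## Suppress only the clipped-residue warning emitted on near-cancelling poles.
quiet_clip <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("clipped", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}
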