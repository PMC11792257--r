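test_that("normalisation removes the linear trend and scales to unit variance", {
  expect_error(normalize_series(as.numeric(1:256)), "degenerate")
  x <- withr::with_seed(1, rnorm(256, 50, 4))
  z <- normalize_series(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(mean(z^2) - 1), 1e-10)
  ## an embedded trend is gone: re-fitting a slope finds none
  y <- sin(2 * pi * 0.1 * (1:256)) + 0.01 * (1:256)
  zy <- normalize_series(y)
  slope <- unname(coef(lm(zy ~ seq_along(zy)))[2])
  expect_lt(abs(slope), 1e-10)
})

test_that("BAR least squares recovers a known unidirectional coefficient", {
  est <- vapply(1:100, function(i) {
    withr::with_seed(i, {
      x <- rnorm(2048)
      y <- 0.8 * c(0, head(x, -1)) + rnorm(2048)
    })
    m <- fit_bar(normalize_series(x), normalize_series(y),
                 order_range = c(5, 5), latency = c(1, 1))
    ## equation of y (row 2), regressor x (col 1), lag 1; undo the
    ## normalisation scale to compare with the generating gain
    m$A[2, 1, 2] * sd(y) / sd(x)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.05)
  expect_lt(abs(median(est) - 0.8), 0.05)
})

test_that("cross coefficients on independent noise behave like asymptotic LS theory", {
  frac_small <- vapply(1:50, function(i) {
    withr::with_seed(1000 + i, {
      x <- rnorm(256); y <- rnorm(256)
    })
    m <- fit_bar(normalize_series(x), normalize_series(y))
    cross <- c(m$A[1, 2, ], m$A[2, 1, ])
    cross <- cross[cross != 0]
    mean(abs(cross) < 2.5 / sqrt(256))
  }, numeric(1))
  expect_gt(mean(frac_small), 0.9)
})

test_that("identification is deterministic", {
  sim <- simulate_coupled_pair(sim_config(seed = 12))
  m1 <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  m2 <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  expect_identical(m1$A, m2$A)
  expect_identical(m1$lambda, m2$lambda)
})

test_that("the spectral matrix matches closed forms and Parseval", {
  ## decoupled channels: zero cross-spectrum
  sim <- simulate_coupled_pair(sim_config(seed = 3, gain_resp_to_hp = 0,
                                          gain_hp_to_resp = 0))
  m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  m0 <- m
  m0$A[1, 2, ] <- 0; m0$A[2, 1, ] <- 0
  S0 <- spectral_matrix(m0)
  expect_true(all(Mod(S0$S12) == 0))

  ## diagonal AR(1): S11(0) = 1/|1-0.5|^2 = 4
  m1 <- m
  m1$A <- array(0, dim = c(2, 2, 2))
  m1$A[1, 1, 2] <- 0.5; m1$A[2, 2, 2] <- 0.5
  m1$order <- 1L
  m1$lambda <- c(x = 1, y = 1)
  m1$stable <- TRUE
  S1 <- spectral_matrix(m1, n_freq = 5)
  expect_equal(S1$S11[1], 4, tolerance = 1e-12)

  ## Parseval: 2 * integral of S11 over [0, 1/2] equals the exact stationary
  ## channel variance from the Lyapunov-equation oracle
  m2 <- fit_bar(normalize_series(simulate_coupled_pair(sim_config(seed = 8))$x),
                normalize_series(simulate_coupled_pair(sim_config(seed = 8))$y))
  S2 <- spectral_matrix(m2, n_freq = 4097)
  v_int <- 2 * sum(diff(S2$f_cpb) * (S2$S11[-1] + S2$S11[-4097]) / 2)
  v_exact <- bar_channel_variance(m2)
  expect_lt(abs(v_int - v_exact) / v_exact, 1e-4)
})

test_that("squared coherence hits its degenerate limits", {
  sim <- simulate_coupled_pair(sim_config(seed = 5, gain_resp_to_hp = 0,
                                          gain_hp_to_resp = 0))
  m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  m$A[1, 2, ] <- 0; m$A[2, 1, ] <- 0
  expect_true(all(squared_coherence(m)$k2 == 0))

  ## y an (almost) noiseless instantaneous copy of x -> K2 -> 1
  mc <- m
  mc$A <- array(0, dim = c(2, 2, 2))
  mc$A[2, 1, 1] <- 1
  mc$order <- 1L
  mc$lambda <- c(x = 1, y = 1e-10)
  mc$stable <- TRUE
  expect_true(all(squared_coherence(mc)$k2 > 1 - 1e-6))
})

test_that("parametric K2 agrees with a nonparametric Welch-type oracle", {
  sim <- simulate_coupled_pair(sim_config(seed = 21, gain_resp_to_hp = 1,
                                          gain_hp_to_resp = 0, n_beats = 2048))
  m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  long <- simulate(m, nsim = 2^16, seed = 99)
  sp <- stats::spec.pgram(stats::ts(long), spans = c(101, 101), plot = FALSE,
                          detrend = TRUE, taper = 0)
  k2_fit <- squared_coherence(m, n_freq = 1025)
  peak_f <- k2_fit$f_cpb[which.max(k2_fit$k2)]
  oracle <- sp$coh[which.min(abs(sp$freq - peak_f))]
  expect_lt(abs(max(k2_fit$k2) - oracle), 0.05)
})

test_that("zeroing an absent reverse pathway leaves K2 unchanged (causal identity)", {
  sim <- simulate_coupled_pair(sim_config(seed = 2, gain_resp_to_hp = 1,
                                          gain_hp_to_resp = 0))
  m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  m$A[1, 2, ] <- 0  # make the reverse path structurally zero
  m$stable <- ck2coh:::bar_stable(m)
  expect_true(m$stable)
  k2 <- squared_coherence(m)
  c1 <- causal_squared_coherence(m, "x_to_y")
  expect_lt(max(abs(k2$k2 - c1$ck2)), 1e-10)
})

test_that("zeroing both pathways kills the coherence entirely", {
  sim <- simulate_coupled_pair(sim_config(seed = 2))
  m <- fit_bar(normalize_series(sim$x), normalize_series(sim$y))
  m$A[2, 1, ] <- 0
  m$stable <- ck2coh:::bar_stable(m)
  c1 <- causal_squared_coherence(m, "x_to_y")  # also zeroes A[1,2,]
  expect_true(all(c1$ck2 == 0))
})

test_that("finite-sample reverse-direction leakage stays small", {
  meds <- vapply(1:50, function(i) {
    sim <- simulate_coupled_pair(sim_config(seed = 3000 + i,
                                            gain_resp_to_hp = 2,
                                            gain_hp_to_resp = 0))
    fit <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
    c(fit$markers[["ck2_x_to_y_hf"]], fit$markers[["ck2_y_to_x_hf"]])
  }, numeric(2))
  expect_gt(median(meds[1, ]), 0.5)
  expect_lt(median(meds[2, ]), 0.1)
})

test_that("bidirectional coupling gives CK2 below K2 in both directions at the peak", {
  cfg <- sim_config(seed = 9, gain_resp_to_hp = 0.5, gain_hp_to_resp = 0.5,
                    n_beats = 8192)
  sim <- simulate_coupled_pair(cfg)
  fit <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
  i_peak <- which.max(fit$k2)
  expect_gt(fit$ck2_x_to_y[i_peak], 0)
  expect_gt(fit$ck2_y_to_x[i_peak], 0)
  expect_lt(fit$ck2_x_to_y[i_peak], fit$k2[i_peak])
  expect_lt(fit$ck2_y_to_x[i_peak], fit$k2[i_peak])
})

test_that("band averaging follows the closed-open rule on the Hz grid", {
  f <- seq(0, 0.5, length.out = 1025)
  bands <- lf_hf_bands()
  expect_equal(band_average(rep(3.5, 1025), f, bands$lf, 0.884), 3.5)
  f_hz <- f / 0.884
  ind <- as.numeric(f_hz >= 0.15 & f_hz < 0.4)
  expect_equal(band_average(ind, f, bands$hf, 0.884), 1)
  expect_equal(band_average(ind, f, bands$lf, 0.884), 0)
  ## a grid too coarse to place any point inside the band errors
  expect_error(band_average(c(1, 1), c(0, 0.5), bands$lf, 1), "empty band")
})

test_that("HF-confined coupling shows band selectivity", {
  hits <- vapply(1:50, function(i) {
    sim <- simulate_coupled_pair(sim_config(seed = 500 + i, gain_resp_to_hp = 1,
                                            gain_hp_to_resp = 0))
    fit <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
    fit$markers[["ck2_x_to_y_hf"]] > fit$markers[["ck2_x_to_y_lf"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("markers are invariant to input scaling", {
  sim <- simulate_coupled_pair(sim_config(seed = 14))
  f1 <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
  f2 <- ck2(sim$x * 1000, sim$y * 250, mean_hp_s = 0.884)
  expect_equal(f1$markers, f2$markers, tolerance = 1e-10)
})

test_that("coupling gain increases the coupled-direction marker monotonically", {
  ladder <- coupling_ladder()
  med <- vapply(ladder, function(g) {
    vals <- vapply(1:100, function(i) {
      sim <- simulate_coupled_pair(sim_config(seed = 7000 + i,
                                              gain_resp_to_hp = g,
                                              gain_hp_to_resp = 0))
      fit <- ck2(sim$x, sim$y, mean_hp_s = 0.884)
      fit$markers[["ck2_x_to_y_hf"]]
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_gt(cor(seq_along(ladder), med, method = "spearman"), 0.9)
  expect_true(all(diff(med) > 0))
})

test_that("invalid latency structures are rejected", {
  x <- rnorm(256); y <- rnorm(256)
  expect_error(fit_bar(x, y, latency = c(0, 0)), "latency")
  expect_error(fit_bar(x, y[-1]), "equal length")
  expect_error(fit_bar(x[1:40], y[1:40]), "too short")
})
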