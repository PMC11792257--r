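test_that("IAAFT surrogates preserve the value distribution exactly and are seeded", {
  sim <- simulate_coupled_pair(sim_config(seed = 6))
  x <- sim$x
  s1 <- iaaft_surrogate(x, seed = 5)
  s2 <- iaaft_surrogate(x, seed = 5)
  s3 <- iaaft_surrogate(x, seed = 6)
  expect_identical(sort(as.numeric(s1)), sort(x))
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_false(identical(as.numeric(s1), as.numeric(s3)))
  expect_error(iaaft_surrogate(rep(3, 256)), "degenerate")
  expect_error(iaaft_surrogate(rnorm(16)), "too short")
})

test_that("spectral discrepancy improves with iterations", {
  better <- vapply(1:100, function(i) {
    x <- withr::with_seed(i, as.numeric(arima.sim(list(ar = c(1.6, -0.9)), 256)))
    d100 <- attr(iaaft_surrogate(x, n_iter = 100, seed = i), "spectral_discrepancy")
    d1 <- attr(iaaft_surrogate(x, n_iter = 1, seed = i), "spectral_discrepancy")
    d100 < d1
  }, logical(1))
  expect_gte(mean(better), 0.95)
})

test_that("surrogate pairs destroy cross-correlation even for identical inputs", {
  n <- 256
  cc_stat <- function(a, b) {
    mean(stats::ccf(a, b, lag.max = 10, plot = FALSE, demean = TRUE)$acf^2)
  }
  gen <- function(seed) {
    withr::with_seed(seed, as.numeric(arima.sim(list(ar = c(1.5, -0.8)), n)))
  }
  ## reference: surrogate pairs built from two UNRELATED realizations -- the
  ## cross-correlation floor attainable when nothing is shared (same
  ## autocorrelation, hence the same Bartlett inflation of the ccf)
  ref <- vapply(1:200, function(i) {
    p <- surrogate_pair(gen(5000 + i), gen(7000 + i), 2 * i, 2 * i + 1)
    cc_stat(as.numeric(p$x), as.numeric(p$y))
  }, numeric(1))
  ## test: both surrogates derived from one identical series; the shared
  ## periodogram keeps the floor slightly above the unrelated-pair floor,
  ## but the coupling itself (cc of x with x is 1 at lag 0) must be wiped out
  res <- vapply(1:100, function(i) {
    x <- gen(i)
    p <- surrogate_pair(x, x, seed_x = 2 * i, seed_y = 2 * i + 1)
    c(surr = cc_stat(as.numeric(p$x), as.numeric(p$y)),
      orig = cc_stat(x, x))
  }, numeric(2))
  expect_lt(median(res["surr", ] / res["orig", ]), 0.25)
  expect_lt(median(res["surr", ]), 2 * median(ref))
  expect_error(surrogate_pair(rnorm(64), rnorm(64), 3, 3), "seed")
})

test_that("surrogate K2 of a coupled pair matches the independent-pair null level", {
  spec <- marker_spec("k2", band = "hf", mean_hp_s = 0.884)
  gen <- function(seed) {
    simulate_coupled_pair(sim_config(seed = seed, gain_resp_to_hp = 1,
                                     gain_hp_to_resp = 0))
  }
  coupled_null <- vapply(1:60, function(i) {
    sim <- gen(100 + i)
    p <- surrogate_pair(sim$x, sim$y, 2 * i, 2 * i + 1)
    ck2coh:::eval_marker(p$x, p$y, spec)$value
  }, numeric(1))
  ## independent reference with matched marginal spectra: pair the x of one
  ## realization with the y of an unrelated realization of the same coupled
  ## generator
  indep <- vapply(1:60, function(i) {
    ck2coh:::eval_marker(gen(300 + i)$x, gen(700 + i)$y, spec)$value
  }, numeric(1))
  original <- vapply(1:30, function(i) {
    sim <- gen(100 + i)
    ck2coh:::eval_marker(sim$x, sim$y, spec)$value
  }, numeric(1))
  expect_lt(abs(median(coupled_null, na.rm = TRUE) - median(indep, na.rm = TRUE)),
            0.05)
  ## the null sits far below the coupled originals it calibrates
  expect_lt(median(coupled_null, na.rm = TRUE), 0.3 * median(original))
})

test_that("the uncoupling test is reproducible and honours the strict rejection rule", {
  sim <- simulate_coupled_pair(sim_config(seed = 4, gain_resp_to_hp = 2,
                                          gain_hp_to_resp = 0))
  spec <- marker_spec("ck2", "x_to_y", "hf", mean_hp_s = 0.884)
  t1 <- uncoupling_test(sim$x, sim$y, spec, n_pairs = 30, master_seed = 9)
  t2 <- uncoupling_test(sim$x, sim$y, spec, n_pairs = 30, master_seed = 9)
  expect_identical(t1$null_distribution, t2$null_distribution)
  expect_identical(t1$threshold, t2$threshold)
  expect_identical(t1$reject, t2$reject)
  ## threshold is the nearest-rank element of the null itself
  expect_true(t1$threshold %in% t1$null_distribution)
  expect_identical(t1$threshold,
                   sort(t1$null_distribution)[ceiling(0.95 * 30)])
  ## strict ">" rule: rejection iff strictly above the threshold
  expect_identical(t1$reject, t1$original_marker > t1$threshold)
  ## strong HF coupling must reject its null here
  expect_true(t1$reject)
})

test_that("frozen-order surrogate fits reuse the original BAR order", {
  sim <- simulate_coupled_pair(sim_config(seed = 4, gain_resp_to_hp = 1))
  spec <- marker_spec("k2", band = "hf", mean_hp_s = 0.884)
  t_fixed <- uncoupling_test(sim$x, sim$y, spec, n_pairs = 10, master_seed = 2,
                             refit_order = FALSE)
  expect_s3_class(t_fixed, "uncoupling_test")
  expect_false(anyNA(t_fixed$null_distribution))
})

test_that("rejection proportion reduces to simple percentages", {
  mk <- function(rej) structure(list(reject = rej), class = "uncoupling_test")
  expect_equal(rejection_proportion(replicate(27, mk(FALSE), simplify = FALSE)), 0)
  expect_equal(rejection_proportion(replicate(27, mk(TRUE), simplify = FALSE)), 100)
  expect_equal(rejection_proportion(c(TRUE, FALSE, TRUE, FALSE)), 50)
  expect_error(rejection_proportion(list()), "empty")
})

test_that("a mixed coupled/uncoupled cohort lands near its designed rejection rate", {
  spec <- marker_spec("ck2", "x_to_y", "hf", mean_hp_s = 0.884)
  flags <- vapply(1:20, function(i) {
    g <- if (i <= 10) 2 else 0
    sim <- simulate_coupled_pair(sim_config(seed = 4000 + i, gain_resp_to_hp = g,
                                            gain_hp_to_resp = 0))
    uncoupling_test(sim$x, sim$y, spec, n_pairs = 40, percentile = 95,
                    master_seed = 555 + i)$reject
  }, logical(1))
  expect_lt(abs(rejection_proportion(flags) - 50), 15 + 1e-9)
})
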