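# shared small cell for bootstrap tests: reported IVs with known truth
make_boot_cell <- function(n = 80, rho = 0.4, beta = c(hispanic = 0.8, poverty = -0.4),
                           theta = c(0.3, 0.1), sigma = 0.2, moe = 0.03,
                           seed = 1) {
  cents <- grid_centroids(ceiling(sqrt(n)), ceiling(sqrt(n)),
                          jitter = 0.3, seed = seed)[seq_len(n), ]
  w <- knn_weights(cents, 3)
  set.seed(seed + 500)
  truth <- matrix(pmin(pmax(rnorm(n * length(beta), 0.4, 0.2), 0), 1),
                  n, length(beta), dimnames = list(NULL, names(beta)))
  dgp <- dgp_config(rho = rho, beta = beta, theta = theta, sigma = sigma)
  y <- gen_outcome(truth, w, dgp, seed = seed + 900)
  reported <- pmin(pmax(truth + rnorm(length(truth), 0, moe), 0), 1)
  ivs <- data.frame(unit_id = cents$unit_id)
  for (v in names(beta)) {
    ivs[[paste0(v, "_est")]] <- reported[, v]
    ivs[[paste0(v, "_moe")]] <- moe
  }
  list(y = y, ivs = ivs, w = w, dgp = dgp, truth = truth)
}

test_that("resampling with zero MOEs or moe_to_sd = 0 is the identity", {
  cell <- make_boot_cell(n = 30)
  ivs0 <- cell$ivs
  ivs0$hispanic_moe <- 0; ivs0$poverty_moe <- 0
  expect_equal(resample_ivs(ivs0, seed = 3), ivs0)
  expect_equal(resample_ivs(cell$ivs, moe_to_sd = 0, seed = 3), cell$ivs)
})

test_that("resampled values have sd moe_to_sd * MOE and respect clamping", {
  ivs <- data.frame(unit_id = sprintf("u%05d", 1:10000),
                    v_est = rep(0.5, 10000), v_moe = rep(0.1, 10000))
  r <- resample_ivs(ivs, moe_to_sd = 0.7, seed = 5)
  expect_equal(sd(r$v_est - ivs$v_est), 0.07, tolerance = 0.02)

  low <- data.frame(unit_id = ivs$unit_id, v_est = rep(0.02, 10000),
                    v_moe = rep(0.1, 10000))
  rl <- resample_ivs(low, seed = 6)
  expect_true(all(rl$v_est >= 0))
  expect_true(all(rl$v_est <= 1))
  # without clamping the same draws go negative
  rn <- resample_ivs(low, clamp_proportions = FALSE, seed = 6)
  expect_true(any(rn$v_est < 0))

  bad <- data.frame(unit_id = "u", v_est = 0.5, v_moe = NA_real_)
  expect_error(resample_ivs(bad, vars = "v", seed = 1), "margin of error.*v")
})

test_that("bootstrap pools n_resamples x mc_draws draws and is reproducible", {
  cell <- make_boot_cell(n = 60, seed = 2)
  cfg <- bootstrap_config(n_resamples = 6, mc_draws_per_resample = 8, seed = 7)
  b1 <- run_bootstrap(cell$y, cell$ivs, cell$w, cfg,
                      iv_vars = c("hispanic", "poverty"))
  expect_equal(b1$n_pooled_draws, 48)
  expect_equal(b1$n_failed, 0)
  expect_true(all(b1$summary$total_p5 <= b1$summary$total_median))
  expect_true(all(b1$summary$total_median <= b1$summary$total_p95))
  expect_equal(length(b1$rho), 6)

  b2 <- run_bootstrap(cell$y, cell$ivs, cell$w, cfg,
                      iv_vars = c("hispanic", "poverty"))
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$rho, b2$rho)
})

test_that("default bootstrap configuration reproduces the 500 x 100 design", {
  cfg <- bootstrap_config()
  expect_equal(cfg$n_resamples * cfg$mc_draws_per_resample, 50000)
  expect_equal(cfg$moe_to_sd, 1.0)
  expect_true(cfg$clamp_proportions)
})

test_that("with moe_to_sd = 0 the summary collapses to the observed-data MC percentiles", {
  cell <- make_boot_cell(n = 144, seed = 3)
  cfg <- bootstrap_config(n_resamples = 4, mc_draws_per_resample = 1000,
                          moe_to_sd = 0, seed = 11)
  b <- run_bootstrap(cell$y, cell$ivs, cell$w, cfg,
                     iv_vars = c("hispanic", "poverty"))
  # every resample refits identical data, so pooled quantiles match the
  # observed-data Monte Carlo quantiles up to Monte Carlo noise
  expect_lt(max(abs(b$summary$total_median - b$observed$total_median)), 0.05)
  expect_lt(max(abs(b$summary$total_p95 - b$observed$total_p95)), 0.15)
  expect_true(all(abs(b$rho - b$rho[1]) < 1e-12))
})

test_that("the reporting transform matches its interpretation", {
  expect_equal(transform_impact(0), 1)
  expect_equal(transform_impact(10), 10)
  # zeta_trans = 1.5 <=> a 10-point IV increase multiplies local use by 1.5
  zeta <- 10 * log10(1.5)
  expect_equal(transform_impact(zeta), 1.5)
  # monotone map: transformed intervals keep their order
  expect_true(transform_impact(-1) < transform_impact(0.2))
})

test_that("attenuation: naive slope halves when sigma_e = sigma_x and intervals widen", {
  demo <- attenuation_demo(beta = 1, sigma_x = 1, sigma_e_levels = c(0, 0.5, 1),
                           n = 10000, n_resamples = 60, seed = 21)
  expect_equal(demo$naive_slope[1], 1, tolerance = 0.02)     # no error: unbiased
  expect_equal(demo$naive_slope[3], 0.5, tolerance = 0.05)   # sigma_e = sigma_x
  expect_equal(demo$naive_slope, demo$expected_slope, tolerance = 0.05)
  expect_true(all(diff(demo$boot_width) > 0))
})
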