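test_that("landscape tracts tile the extent without overlap and are deterministic", {
  land <- gen_landscape(4, 10, seed = 5)
  tr <- land$units[land$units$geography_class == "tract", ]
  expect_equal(nrow(tr), 4)
  expect_equal(sum(tr$area_km2), 100)
  # rectangles on a grid: pairwise interiors disjoint
  boxes <- t(vapply(tr$ring, function(r)
    c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])), numeric(4)))
  for (i in 1:3) for (j in (i + 1):4) {
    overlap_x <- min(boxes[i, 2], boxes[j, 2]) - max(boxes[i, 1], boxes[j, 1])
    overlap_y <- min(boxes[i, 4], boxes[j, 4]) - max(boxes[i, 3], boxes[j, 3])
    expect_lte(min(overlap_x, overlap_y), 0)
  }
  # every unit has at least one block point
  expect_true(all(land$units$unit_id %in% land$blocks$unit_id))

  land2 <- gen_landscape(4, 10, seed = 5)
  expect_identical(land$blocks, land2$blocks)
  expect_identical(land$units$unit_id, land2$units$unit_id)
  expect_identical(land$sections, land2$sections)
})

test_that("1.6 km section lattice over a 16 km extent has 100 centroids", {
  land <- gen_landscape(16, 16, seed = 1)
  expect_equal(nrow(land$sections), 100)
  expect_equal(sort(unique(land$sections$x_km)), seq(0.8, 15.2, by = 1.6))
})

test_that("non-rectangular unit counts are adjusted to the nearest grid", {
  expect_message(land <- gen_landscape(7, 10, seed = 1), "not a grid")
  expect_true(land$adjusted)
  tr <- sum(land$units$geography_class == "tract")
  expect_equal(tr, prod(land$dims))
})

test_that("use records respect intensity and bounds", {
  land <- gen_landscape(16, 16, seed = 2)
  zero <- gen_use_records(land$sections, function(x, y) rep(0, length(x)), seed = 1)
  expect_equal(nrow(zero), 0)

  one <- gen_use_records(land$sections, bounds = c(1, 1), seed = 1, years = 2011)
  expect_equal(nrow(one), nrow(land$sections))
  expect_true(all(one$pounds == 1))

  many <- gen_use_records(land$sections, seed = 3, bounds = c(1e-2, 1e4),
                          years = 2011:2110)  # 10,000 draws
  expect_equal(nrow(many), 10000)
  expect_true(all(many$pounds >= 1e-2 & many$pounds <= 1e4))

  expect_error(gen_use_records(land$sections, function(x, y) -x, seed = 1),
               "nonnegative")
})

test_that("demographic noise matches moe_scale and respects proportion bounds", {
  land <- gen_landscape(10000, 100, seed = 4, make_places = FALSE,
                        k_blocks_per_unit = 1)
  dgp0 <- dgp_config(moe_scale = 0)
  d0 <- gen_demographics(land, dgp0, seed = 9)
  tr <- attr(d0, "truth")
  expect_equal(d0$hispanic_est / d0$total_pop_est, tr$hispanic, tolerance = 1e-12)

  dgp <- dgp_config(moe_scale = 0.05)
  d <- suppressMessages(gen_demographics(land, dgp, seed = 9))
  p_rep <- d$hispanic_est / d$total_pop_est
  err <- p_rep - attr(d, "truth")$hispanic
  # clamping slightly shrinks the spread; Monte Carlo check within 2%
  expect_equal(sd(err[p_rep > 0 & p_rep < 1]), 0.05, tolerance = 0.02)
  expect_true(all(p_rep >= 0 & p_rep <= 1))
  expect_true(all(d$hispanic_moe > 0))
})

test_that("gen_outcome reduces to Xb and matches a dense solve", {
  dat <- make_sdm_data(n = 25, seed = 2)
  dgp0 <- dgp_config(rho = 0, beta = c(a = 0.8, b = -0.5), theta = c(0, 0), sigma = 0)
  y0 <- gen_outcome(dat$X, dat$w, dgp0, seed = 1)
  expect_equal(y0, drop(dat$X %*% dgp0$beta), tolerance = 1e-12)

  # sigma = 0, n = 5: brute-force linear solve oracle
  cents <- grid_centroids(1, 5, jitter = 0.1, seed = 3)
  w5 <- knn_weights(cents, 2)
  dgp5 <- dgp_config(rho = 0.5, beta = c(a = 1), theta = c(0.3), sigma = 0)
  X5 <- matrix(c(0.2, -1, 0.5, 2, 0), 5, 1, dimnames = list(NULL, "a"))
  y5 <- gen_outcome(X5, w5, dgp5, seed = 1)
  W5 <- as.matrix(w5$W)
  oracle <- solve(diag(5) - 0.5 * W5, X5 * 1 + W5 %*% X5 * 0.3)
  expect_equal(y5, drop(oracle), tolerance = 1e-12)
})

test_that("outcomes under positive rho are spatially autocorrelated", {
  cents <- grid_centroids(8, 8, jitter = 0.2, seed = 11)
  w <- knn_weights(cents, 3)
  dgp <- dgp_config(rho = 0.5, beta = c(a = 0), theta = c(0), sigma = 1)
  mi <- vapply(1:100, function(s) {
    y <- gen_outcome(matrix(0, 64, 1, dimnames = list(NULL, "a")), w, dgp, seed = s)
    morans_i(y, w)
  }, numeric(1))
  expect_gt(mean(mi), 0)
  expect_gt(mean(mi > 0), 0.8)
})

test_that("residual Moran's I of OLS on X alone is positive under rho > 0", {
  dat <- make_sdm_data(n = 100, rho = 0.6, sigma = 0.5, seed = 13)
  ols <- lm(dat$y ~ dat$X)
  expect_gt(morans_i(residuals(ols), dat$w), 0)
})

test_that("synthetic inputs round-trip through the written files", {
  land <- gen_landscape(9, 6, seed = 21)
  demo <- suppressMessages(gen_demographics(land, dgp_config(), seed = 21))
  recs <- gen_use_records(land$sections, seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(land, demo, recs, dir)
  expect_true(all(file.exists(unlist(paths))))

  units2 <- read_geography(paths$geography)
  expect_equal(units2$unit_id, land$units$unit_id)
  expect_equal(units2$area_km2, land$units$area_km2, tolerance = 1e-12)
  expect_equal(units2$ring[[3]], land$units$ring[[3]], tolerance = 1e-12,
               ignore_attr = TRUE)
  recs2 <- utils::read.csv(paths$use_records)
  expect_equal(recs2$pounds, recs$pounds, tolerance = 1e-12)
})
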