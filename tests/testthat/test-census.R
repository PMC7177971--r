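test_that("weighted centroids match hand computations and are translation-equivariant", {
  one <- data.frame(x_km = 3, y_km = 4, pop = 10)
  expect_equal(weighted_centroid(one), c(x_km = 3, y_km = 4))

  sym <- data.frame(x_km = c(0, 2), y_km = c(0, 0), pop = c(5, 5))
  expect_equal(weighted_centroid(sym), c(x_km = 1, y_km = 0))

  skew <- data.frame(x_km = c(0, 4), y_km = c(0, 0), pop = c(1, 3))
  expect_equal(weighted_centroid(skew), c(x_km = 3, y_km = 0))

  set.seed(7)
  blocks <- data.frame(x_km = runif(6), y_km = runif(6), pop = rpois(6, 20) + 1)
  shifted <- transform(blocks, x_km = x_km + 2.5, y_km = y_km - 1.25)
  expect_equal(weighted_centroid(shifted),
               weighted_centroid(blocks) + c(2.5, -1.25), tolerance = 1e-12)

  expect_error(weighted_centroid(data.frame(x_km = 1, y_km = 1, pop = 0)),
               "excluded")
})

test_that("derived proportions propagate MOEs with the fallback branch", {
  a <- derive_proportion(50, 10, 100, 0)
  expect_equal(a$est, 0.5)
  expect_equal(a$moe, 0.1)

  z <- derive_proportion(0, 0, 100, 5)
  expect_equal(z$est, 0)
  expect_equal(z$moe, 0)

  # negative radicand: 25 - 0.81 * 400 < 0 -> ratio formula sqrt(25 + 324)/100
  f <- derive_proportion(90, 5, 100, 20)
  expect_equal(f$est, 0.9)
  expect_equal(f$moe, sqrt(25 + 0.81 * 400) / 100)

  expect_error(derive_proportion(5, 1, 0, 0), "denominator")
})

test_that("derived-proportion MOE is always real and nonnegative", {
  set.seed(3)
  num <- runif(500, 0, 100)
  r <- derive_proportion(num, runif(500, 0, 30), num + runif(500, 1, 100),
                         runif(500, 0, 50))
  expect_true(all(is.finite(r$moe)))
  expect_true(all(r$moe >= 0))
})

test_that("log density and county controls aggregate counts", {
  expect_equal(derive_density(100, 1), 2)
  expect_equal(derive_density(1, 10), -1)
  expect_error(derive_density(0, 1), "excluded")

  tab <- data.frame(unit_id = c("a", "b", "c"),
                    county_id = c("C1", "C1", "C2"),
                    total_pop_est = c(100, 300, 50),
                    area_km2 = c(1, 1, 2),
                    total_employment_est = c(100, 100, 40),
                    ag_employment_est = c(10, 30, 4))
  cc <- county_controls(tab)
  expect_equal(cc$county_log_density[1:2], rep(log10(200), 2))
  expect_equal(cc$county_ag_employment[1:2], rep(0.2, 2))
  expect_equal(cc$county_log_density[3], log10(25))
})

test_that("the exclusion filter drops zero-population/employment units and is idempotent", {
  tab <- data.frame(unit_id = c("u1", "u2", "u3", "u4"),
                    total_pop_est = c(0, 500, 200, 300),
                    total_employment_est = c(10, 0, 80, 120))
  f <- filter_units(tab)
  expect_equal(f$excluded$unit_id, c("u1", "u2"))
  expect_equal(f$excluded$reason, c("zero population", "zero employment"))
  expect_equal(f$retained$unit_id, c("u3", "u4"))

  f2 <- filter_units(f$retained)
  expect_equal(f2$retained, f$retained)
  expect_equal(nrow(f2$excluded), 0)

  ok <- data.frame(unit_id = "u", total_pop_est = 1, total_employment_est = 1)
  expect_equal(filter_units(ok)$retained, ok)
})

test_that("prepare_units assembles proportions, density, controls and centroids", {
  land <- gen_landscape(16, 8, seed = 31, make_places = FALSE)
  demo <- gen_demographics(land, dgp_config(moe_scale = 0.02), seed = 31)
  prep <- prepare_units(demo, land$blocks)
  expect_s3_class(prep, "derived_ivs")
  expect_setequal(prep$proportion_vars, c("hispanic", "poverty", "ag_employment"))
  expect_equal(prep$ivs$hispanic_est,
               demo$hispanic_est / demo$total_pop_est, tolerance = 1e-12)
  expect_equal(prep$ivs$hispanic_moe,
               demo$hispanic_moe / demo$total_pop_est, tolerance = 1e-12)
  expect_equal(prep$ivs$log_density_est,
               log10(demo$total_pop_est / demo$area_km2))
  expect_equal(nrow(prep$centroids), nrow(prep$ivs))
  # centroid lies inside the bounding box of the unit's blocks
  b1 <- land$blocks[land$blocks$unit_id == prep$centroids$unit_id[1], ]
  expect_gte(prep$centroids$x_km[1], min(b1$x_km))
  expect_lte(prep$centroids$x_km[1], max(b1$x_km))

  X <- iv_matrix(prep$ivs, c("hispanic", "log_density"))
  expect_equal(colnames(X), c("hispanic", "log_density"))
  expect_error(iv_matrix(prep$ivs, "nope"), "missing IV columns")
})

test_that("subgroup counts exceeding the population are clamped with a warning", {
  tab <- data.frame(unit_id = c("a", "b"), geography_class = "tract",
                    county_id = "C1", area_km2 = 1,
                    total_pop_est = c(100, 100), total_pop_moe = 0,
                    grp_est = c(120, 40), grp_moe = c(10, 5),
                    total_employment_est = 50, total_employment_moe = 0,
                    ag_employment_est = 5, ag_employment_moe = 0)
  blocks <- data.frame(unit_id = c("a", "b"), x_km = 1, y_km = 1, pop = 10)
  expect_warning(prep <- prepare_units(tab, blocks, iv_names = "grp"), "clamped")
  expect_equal(prep$ivs$grp_est, c(1, 0.4))
})
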