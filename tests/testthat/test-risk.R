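test_that("interval probabilities are direct counts that partition to one", {
  std <- seqs_cd_china()
  # one cell, L = 8: pH values spread over the four intervals
  ph <- toy_stack(matrix(c(5.0, 5.2, 5.9, 6.0, 6.6, 7.0, 7.4, 8.1), nrow = 1))
  expect_equal(interval_probability(ph, std, 1)$values, 2 / 8)
  expect_equal(interval_probability(ph, std, 2)$values, 2 / 8)
  expect_equal(interval_probability(ph, std, 3)$values, 3 / 8)
  expect_equal(interval_probability(ph, std, 4)$values, 1 / 8)
  # all values in one interval
  all3 <- toy_stack(matrix(rep(7.0, 6), nrow = 1))
  expect_equal(interval_probability(all3, std, 3)$values, 1)
  # partition property on random stacks
  set.seed(6)
  ph2 <- toy_stack(matrix(runif(9 * 20, 0, 14), nrow = 9))
  tot <- Reduce(`+`, lapply(1:std$S,
                            function(i) interval_probability(ph2, std, i)$values))
  expect_equal(tot, rep(1, 9))
})

test_that("threshold probabilities count strict exceedances", {
  cd <- toy_stack(matrix(c(0.2, 0.4, 0.6, 0.8), nrow = 1))
  expect_equal(threshold_probability(cd, 0.5)$values, 0.5)
  expect_equal(threshold_probability(cd, 0.1)$values, 1)
  expect_equal(threshold_probability(cd, 10)$values, 0)
  # strict: a realization exactly at the threshold does not exceed
  expect_equal(threshold_probability(cd, 0.8)$values, 0)
  expect_equal(threshold_probability(cd, 0.7999)$values, 0.25)
})

test_that("product mode reproduces the hand-enumerated mixture", {
  std <- seqs_cd_china()
  g <- grid_spec(0, 0, 60, 1, 1)
  # L = 4; pH interval counts (2, 2, 0, 0); paddy thresholds 0.25, 0.30
  ph <- toy_stack(matrix(c(5.0, 5.2, 6.0, 6.2), nrow = 1), g)
  cd <- toy_stack(matrix(c(0.10, 0.20, 0.28, 0.40), nrow = 1), g)
  lu <- uniform_landuse(g, "paddy field")
  # counts: P(cd > 0.25) = 2/4, P(cd > 0.30) = 1/4
  expected <- 0.5 * 0.5 + 0.5 * 0.25
  pm <- exceedance_probability(cd, ph, lu, std, "product")
  expect_equal(pm$values, expected, tolerance = 1e-12)
  # matches the analytic sum assembled from the two building blocks
  analytic <- sum(vapply(1:std$S, function(i)
    interval_probability(ph, std, i)$values *
      threshold_probability(cd, std$thresholds["paddy field", i])$values,
    numeric(1)))
  expect_equal(pm$values, analytic, tolerance = 1e-12)
})

test_that("joint and product modes coincide for a degenerate pH mixture", {
  std <- seqs_cd_china()
  g <- grid_spec(0, 0, 60, 2, 2)
  set.seed(7)
  ph <- toy_stack(matrix(runif(4 * 10, 6.6, 7.4), nrow = 4), g) # interval 3 only
  cd <- toy_stack(matrix(rlnorm(4 * 10, -0.5, 0.5), nrow = 4), g)
  lu <- uniform_landuse(g, "dry farmland")
  pp <- exceedance_probability(cd, ph, lu, std, "product")$values
  pj <- exceedance_probability(cd, ph, lu, std, "joint")$values
  direct <- threshold_probability(cd, std$thresholds["dry farmland", 3])$values
  expect_equal(pp, direct)
  expect_equal(pj, direct)
})

test_that("joint mode counts paired realizations", {
  std <- seqs_cd_china()
  g <- grid_spec(0, 0, 60, 1, 1)
  ph <- toy_stack(matrix(c(5.0, 6.0, 7.0, 8.0), nrow = 1), g)
  cd <- toy_stack(matrix(c(0.26, 0.26, 0.26, 0.26), nrow = 1), g)
  lu <- uniform_landuse(g, "paddy field")
  # thresholds by realization: 0.25, 0.30, 0.50, 1.00 -> only r = 1 exceeds
  expect_equal(exceedance_probability(cd, ph, lu, std, "joint")$values, 0.25)
})

test_that("probabilities respect threshold and land-use monotonicity", {
  sc <- small_scenario(1)
  set.seed(8)
  L <- 16
  nc <- n_cells(sc$grid)
  cd <- toy_stack(matrix(rlnorm(nc * L, -0.4, 0.5), nrow = nc), sc$grid)
  ph <- toy_stack(matrix(runif(nc * L, 4, 9), nrow = nc), sc$grid)
  std <- seqs_cd_china()
  base <- exceedance_probability(cd, ph, sc$landuse, std)$values
  expect_true(all(base >= 0 & base <= 1))
  # raising every threshold weakly lowers every cell
  raised <- composite_standard(std$breakpoints, std$land_uses,
                               std$thresholds * 1.5)
  expect_true(all(exceedance_probability(cd, ph, sc$landuse, raised)$values
                  <= base + 1e-12))
  # all-nonfarmland map is cellwise below the mixed map
  nonfarm <- uniform_landuse(sc$grid, "nonfarmland")
  expect_true(all(exceedance_probability(cd, ph, nonfarm, std)$values
                  <= base + 1e-12))
  # grid mismatch and unknown codes error out
  other <- toy_stack(matrix(runif(4 * L, 4, 9), nrow = 4))
  expect_error(exceedance_probability(cd, other, sc$landuse, std),
               "share one grid")
  badlu <- land_use_map(sc$grid, rep(1, nc), c("orchard"))
  expect_error(exceedance_probability(cd, ph, badlu, std), "not in standard")
})

test_that("risk masks threshold inclusively and nest by p_c", {
  g <- grid_spec(0, 0, 60, 3, 1)
  pm <- grid_map(g, c(0.89, 0.90, 0.96), "p_exceed")
  m90 <- delineate_risk(pm, 0.90)
  expect_equal(m90$values, c(FALSE, TRUE, TRUE))
  expect_equal(m90$n_flagged, 2L)
  expect_equal(m90$area_km2, 2 * 60^2 / 1e6)
  m95 <- delineate_risk(pm, 0.95)
  expect_true(all(m95$values <= m90$values))  # mask(0.95) inside mask(0.90)
  empty <- delineate_risk(grid_map(g, rep(0, 3)), 0.5)
  expect_equal(empty$n_flagged, 0L)
  # p_c = 1 attainable when every realization exceeds
  full <- delineate_risk(grid_map(g, c(1, 1, 0.999)), 1)
  expect_equal(full$n_flagged, 2L)
})

test_that("descriptive statistics classify variability by CV", {
  s <- sample_set(1:3, rep(0, 3), rep(0.74, 3))
  d <- descriptive_stats(s)
  expect_equal(d$sd, 0)
  expect_equal(d$cv_pct, 0)
  expect_equal(d$variability, "low")
  # CV from summary-level mean 0.74 and SD 0.32 is 43.24%, moderate
  expect_equal(round(100 * 0.32 / 0.74, 2), 43.24)
  sc <- small_scenario(1)
  dcd <- descriptive_stats(sc$samples$cd)
  expect_true(dcd$min <= dcd$median && dcd$median <= dcd$max)
  expect_equal(dcd$cv_pct, 100 * dcd$sd / dcd$mean)
  expect_equal(dcd$variability, "moderate")
  # extensive variability above 90%
  set.seed(9)
  wild <- sample_set(1:50, rep(0, 50), rlnorm(50, 0, 1.5))
  dw <- descriptive_stats(wild)
  if (dw$cv_pct > 90) expect_equal(dw$variability, "extensive")
  expect_gt(dw$cv_pct, 90)
})

test_that("cross-correlogram matches the paired-product formula", {
  x <- c(0, 100, 200, 300)
  a <- sample_set(x, rep(0, 4), c(1.0, 2.0, 1.5, 0.5), "a")
  b <- sample_set(x, rep(0, 4), c(0.9, 2.2, 1.1, 0.7), "b")
  cc <- cross_correlogram(a, b, n_lags = 3, max_lag = 150)
  # lag-0 bin: co-located pairs -> plain Pearson correlation
  expect_equal(cc$rho[cc$lag == 0], cor(a$value, b$value))
  # self correlogram at lag 0 is exactly 1
  cs <- cross_correlogram(a, a, n_lags = 3, max_lag = 150)
  expect_equal(cs$rho[cs$lag == 0], 1)
  # first positive bin: brute-force over the 3 ordered+reversed 100 m pairs
  hd <- c(a$value[1:3], a$value[2:4])
  tl <- c(b$value[2:4], b$value[1:3])
  expect_equal(cc$rho[2], cor(hd, tl))
  expect_true(all(abs(cc$rho) <= 1))
})

test_that("independent fields show no cross-correlation structure", {
  sc <- small_scenario(1)
  cc <- cross_correlogram(sc$samples$cd, sc$samples$ph)
  bound <- 2 / sqrt(cc$np)
  expect_gte(mean(abs(cc$rho) < bound), 0.9)
  expect_lt(abs(cc$rho[cc$lag == 0]), 0.25)
})
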