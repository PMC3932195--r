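test_that("experimental variogram matches a brute-force pair enumeration", {
  # 5 toy points: oracle loops over all 10 pairs explicitly
  x <- c(0, 100, 250, 400, 700)
  y <- c(0, 50, 0, 300, 100)
  v <- c(1.2, 0.8, 1.9, 0.4, 1.1)
  s <- sample_set(x, y, v, "toy")
  n_lags <- 4
  max_lag <- 800
  ev <- experimental_variogram(s, n_lags = n_lags, max_lag = max_lag)

  gsum <- np <- numeric(n_lags)
  for (i in 1:4) for (j in (i + 1):5) {
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (h <= max_lag) {
      b <- min(floor(h / (max_lag / n_lags)) + 1, n_lags)
      gsum[b] <- gsum[b] + (v[i] - v[j])^2
      np[b] <- np[b] + 1
    }
  }
  keep <- np > 0
  expect_equal(ev$np, np[keep])
  expect_equal(ev$gamma, (gsum / (2 * np))[keep])
})

test_that("constant samples give zero semivariance at every lag", {
  set.seed(1)
  s <- sample_set(runif(30, 0, 1000), runif(30, 0, 1000), rep(2.5, 30))
  ev <- experimental_variogram(s)
  expect_true(all(ev$gamma == 0))
})

test_that("the estimator is a single omnidirectional output", {
  set.seed(2)
  s <- sample_set(runif(40, 0, 1000), runif(40, 0, 1000), rnorm(40))
  ev <- experimental_variogram(s, n_lags = 8)
  expect_s3_class(ev, "experimental_variogram")
  expect_null(ev$direction)
  expect_true(all(diff(ev$lag) > 0))
  expect_error(experimental_variogram(s, n_lags = 8, max_lag = 0.5),
               "no pairs")
})

test_that("noiseless fits recover the generating model parameters", {
  h <- seq(100, 3000, length.out = 15)
  for (model in c("spherical", "gaussian", "exponential")) {
    gen <- variogram_model(model, nugget = 0.3, psill = 0.7, range = 1500)
    ev <- structure(data.frame(lag = h, gamma = variogram_gamma(gen, h),
                               np = rep(100, length(h))),
                    class = c("experimental_variogram", "data.frame"))
    fit <- fit_variogram(ev, model)
    expect_lt(abs(fit$nugget - 0.3) / 0.3, 0.05)
    expect_lt(abs(fit$psill - 0.7) / 0.7, 0.05)
    expect_lt(abs(fit$range - 1500) / 1500, 0.05)
  }
})

test_that("spatially shuffled data fit as pure nugget", {
  g <- grid_spec(0, 0, 60, 30, 30)
  vm <- variogram_model("spherical", 0.1, 0.9, 800)
  set.seed(7)
  field <- gaussian_random_field(g, vm, n = 1)[, 1]
  ctr <- grid_centres(g)
  idx <- sample(n_cells(g), 150)
  shuffled <- sample(field[idx])          # destroy the spatial arrangement
  s <- sample_set(ctr[idx, 1], ctr[idx, 2], shuffled)
  fit <- fit_variogram(experimental_variogram(s), "spherical")
  expect_gt(nugget_ratio(fit), 0.8)
})

test_that("nugget ratio is the nugget fraction of the sill", {
  expect_equal(nugget_ratio(variogram_model("spherical", 1, 3, 100)), 0.25)
  expect_equal(nugget_ratio(variogram_model("gaussian", 0, 5, 100)), 0)
  expect_equal(nugget_ratio(variogram_model("exponential", 2, 2, 100)), 0.5)
})

test_that("variogram models evaluate consistently with their covariance", {
  h <- c(0, 10, 500, 1500, 5000)
  for (model in c("spherical", "gaussian", "exponential")) {
    vm <- variogram_model(model, 0.2, 0.8, 1200)
    expect_equal(variogram_gamma(vm, 0), 0)
    expect_equal(variogram_cov(vm, 0), 1)
    # gamma(h) + C(h) = sill for h > 0
    expect_equal(variogram_gamma(vm, h[-1]) + variogram_cov(vm, h[-1]),
                 rep(1, 4))
    expect_true(all(diff(variogram_gamma(vm, seq(0, 3000, 50))) >= -1e-12))
  }
  # spherical reaches its sill exactly at the range
  vm <- variogram_model("spherical", 0.2, 0.8, 1200)
  expect_equal(variogram_gamma(vm, 1200), 1)
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_variogram_json(vm, path)
  expect_equal(read_variogram_json(path), vm)
})

test_that("sample sets reject duplicate coordinates and NA", {
  expect_error(sample_set(c(0, 0), c(1, 1), c(1, 2)), "duplicate")
  expect_error(sample_set(c(0, 1), c(1, 1), c(1, NA)), "complete")
})
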