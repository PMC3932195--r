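test_that("pure-nugget spec yields a spatially unstructured field", {
  g <- grid_spec(0, 0, 60, 30, 30)
  spec <- list(vgm = variogram_model("spherical", 1, 1e-9, 500),
               marginal = cd_marginal_default())
  flds <- generate_fields(g, spec, list(vgm = spec$vgm,
                                        marginal = ph_marginal_default()),
                          seed = 3)
  set.seed(10)
  idx <- sample(n_cells(g), 200)
  ctr <- grid_centres(g)
  s <- sample_set(ctr[idx, 1], ctr[idx, 2], flds$cd$values[idx])
  ev <- experimental_variogram(s, n_lags = 8)
  # flat at the sill: every lag within 35% of the overall variance
  expect_true(all(abs(ev$gamma / var(s$value) - 1) < 0.35))
})

test_that("fields recover the requested range and marginal", {
  g <- grid_spec(0, 0, 60, 40, 40)
  cd_spec <- list(vgm = variogram_model("spherical", 0.3, 0.7, 600),
                  marginal = cd_marginal_default())
  ph_spec <- list(vgm = variogram_model("gaussian", 0.5, 0.5, 800),
                  marginal = ph_marginal_default())
  flds <- suppressWarnings(generate_fields(g, cd_spec, ph_spec, seed = 11))
  cd <- flds$cd$values
  ph <- flds$ph$values
  # marginal targets
  expect_true(all(cd >= 0.26 & cd <= 1.94))
  expect_true(all(ph >= 4.29 & ph <= 9.08))
  expect_lt(abs(mean(cd) - 0.74), 0.1)
  expect_lt(abs(mean(ph) - 6.71), 0.4)
  # range recovery within 20% on the normal scores of a dense regular
  # subsample (every other cell) of the field itself
  idx <- which(((seq_len(n_cells(g)) - 1) %% g$nx) %% 2 == 0 &
                 ((seq_len(n_cells(g)) - 1) %/% g$nx) %% 2 == 0)
  ctr <- grid_centres(g)
  z <- qnorm((rank(cd[idx]) - 0.5) / length(idx))
  s <- sample_set(ctr[idx, 1], ctr[idx, 2], z)
  fit <- fit_variogram(experimental_variogram(s, n_lags = 12, max_lag = 1500),
                       "spherical")
  expect_lt(abs(fit$range - 600) / 600, 0.2)
  expect_error(marginal_spec("normal_clipped", min = 5, max = 5,
                             mean = 5, sd = 1),
               "infeasible")
})

test_that("independently seeded fields are uncorrelated at lag zero", {
  sc <- small_scenario(1)
  expect_lt(abs(cor(sc$cd_true$values, sc$ph_true$values)), 0.1)
})

test_that("land-use generation respects proportions and patchiness", {
  g <- grid_spec(0, 0, 60, 40, 40)
  # degenerate single class
  lu1 <- suppressWarnings(suppressMessages(generate_landuse(
    g, c(a = 1, b = 0, c = 0), seed = 13)))
  expect_true(all(lu1$values == 1))
  # patch scale much larger than the domain: dominated by giant patches
  lu2 <- suppressWarnings(generate_landuse(g, c(a = 0.5, b = 0.3, c = 0.2),
                                           patch_scale = 1e6, seed = 13))
  expect_lte(length(unique(component_sizes(lu2))) , 20)
  # default 3-class call: all classes present, shares within +-10%,
  # contiguous patches (median component at least 4 cells)
  lu <- generate_landuse(g, patch_scale = 1200, seed = 14)
  shares <- as.numeric(table(factor(lu$values, levels = 1:3))) / n_cells(g)
  expect_equal(sort(unique(lu$values)), 1:3)
  expect_true(all(abs(shares - c(0.4, 0.3, 0.3)) <= 0.1))
  expect_gte(median(component_sizes(lu)), 4)
})

test_that("sample draws are exhaustive, deterministic and unbiased", {
  g <- grid_spec(0, 0, 60, 12, 12)
  sc <- list(grid = g,
             cd_true = grid_map(g, seq_len(n_cells(g)) / 10, "cd"),
             ph_true = grid_map(g, rep(7, n_cells(g)), "ph"))
  # n = all cells reproduces the whole field
  all_s <- draw_samples(sc, n = n_cells(g), seed = 15)
  expect_setequal(all_s$cd$value, sc$cd_true$values)
  # determinism
  a <- draw_samples(sc, n = 30, seed = 16)
  b <- draw_samples(sc, n = 30, seed = 16)
  expect_identical(a$cd, b$cd)
  expect_identical(a$ph, b$ph)
  expect_error(draw_samples(sc, n = n_cells(g) + 1, seed = 1), "exceeds")
  # sampling-distribution check on the default-size scenario
  big <- small_scenario(1)
  smp <- big$samples$cd
  se <- sd(big$cd_true$values) / sqrt(nrow(smp))
  expect_lt(abs(mean(smp$value) - mean(big$cd_true$values)), 3 * se)
  # optional measurement noise perturbs values
  noisy <- draw_samples(sc, n = 30, seed = 16, noise_sd = 0.05)
  expect_false(identical(noisy$cd$value, a$cd$value))
})

test_that("scenario files round-trip through plain text", {
  sc <- small_scenario(1)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("samples.csv", "landuse.asc", "cd_true.asc", "ph_true.asc",
           "scenario.json")))))
  back <- read_samples_csv(file.path(dir, "samples.csv"))
  expect_equal(back$cd$value, sc$samples$cd$value)
  lu <- read_ascii_grid(file.path(dir, "landuse.asc"),
                        levels = sc$landuse$levels)
  expect_identical(lu$values, sc$landuse$values)
  js <- jsonlite::read_json(file.path(dir, "scenario.json"),
                            simplifyVector = TRUE)
  expect_equal(js$seed, sc$seed)
  expect_equal(js$cd_spec$vgm$range, sc$cd_spec$vgm$range)
})
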