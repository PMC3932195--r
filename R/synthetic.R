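#' Marginal distribution specification for synthetic fields
#'
#' Describes the target marginal a synthetic Gaussian field is mapped to by
#' quantile anamorphosis. Two shapes cover the soil attributes emulated
#' here: a right-skewed shifted lognormal (trace-metal concentrations) and
#' a clipped normal (pH). Both are clipped to `[min, max]`.
#'
#' @param type `"lognormal_shifted"` (parameters `shift`, `meanlog`,
#'   `sdlog`) or `"normal_clipped"` (parameters `mean`, `sd`).
#' @param min,max hard bounds in attribute units, `min < max`.
#' @param ... shape parameters (see `type`).
#' @return A `marginal_spec` with a quantile function `qfun(p)`.
#' @export
marginal_spec <- function(type = c("lognormal_shifted", "normal_clipped"),
                          min, max, ...) {
  type <- match.arg(type)
  if (!(min < max)) stop("infeasible marginal: min must be < max")
  pars <- list(...)
  qfun <- switch(type,
    lognormal_shifted = function(p)
      pmin(pmax(pars$shift + stats::qlnorm(p, pars$meanlog, pars$sdlog), min), max),
    normal_clipped = function(p)
      pmin(pmax(stats::qnorm(p, pars$mean, pars$sd), min), max))
  structure(list(type = type, min = min, max = max, pars = pars, qfun = qfun),
            class = "marginal_spec")
}

#' Default Cd marginal
#'
#' Right-skewed shifted lognormal clipped to \[0.26, 1.94\] mg/kg with
#' median 0.68 and mean ~0.74 (SD ~0.30), the marginal the synthetic study
#' area emulates for topsoil Cd.
#' @return A [marginal_spec()].
#' @export
cd_marginal_default <- function() {
  # shift + exp(meanlog) = 0.68 (median); shift + exp(meanlog + sdlog^2/2) = 0.74
  marginal_spec("lognormal_shifted", min = 0.26, max = 1.94,
                shift = 0.1, meanlog = log(0.58),
                sdlog = sqrt(2 * log(0.64 / 0.58)))
}

#' Default pH marginal
#'
#' Normal with mean 6.71 and SD 0.98, clipped to \[4.29, 9.08\].
#' @return A [marginal_spec()].
#' @export
ph_marginal_default <- function() {
  marginal_spec("normal_clipped", min = 4.29, max = 9.08,
                mean = 6.71, sd = 0.98)
}

#' Unconditional Gaussian random fields by circulant embedding
#'
#' Exact spectral simulation of zero-mean stationary Gaussian fields on a
#' regular grid: the structured covariance is embedded in a circulant
#' torus, its FFT gives the eigenvalues, and each complex white-noise draw
#' yields two independent fields. Nugget variance is added as iid noise.
#' Uses the current RNG state (call `set.seed()` first for
#' reproducibility).
#'
#' @param grid a [grid_spec()].
#' @param vm a [variogram_model()] giving nugget, partial sill and range
#'   of the target covariance.
#' @param n number of independent fields.
#' @return A `n_cells(grid)` x `n` matrix of field values (storage order).
#' @export
gaussian_random_field <- function(grid, vm, n = 1) {
  stopifnot(inherits(grid, "grid_spec"), inherits(vm, "variogram_model"),
            n >= 1)
  nx <- grid$nx; ny <- grid$ny; cell <- grid$cell_size
  Mx <- stats::nextn(2 * nx, c(2, 3, 5))
  My <- stats::nextn(2 * ny, c(2, 3, 5))
  ix <- 0:(Mx - 1); iy <- 0:(My - 1)
  dx <- pmin(ix, Mx - ix) * cell
  dy <- pmin(iy, My - iy) * cell
  D <- sqrt(outer(dx^2, dy^2, "+"))
  Cm <- vm$psill * (1 - .vgm_g(vm$model, D, vm$range))
  lam <- Re(stats::fft(Cm))
  neg <- lam < 0
  if (any(neg)) {
    # small negative eigenvalues are expected for very smooth covariances;
    # warn only when the clamped mass would distort the covariance
    if (sum(-lam[neg]) > 1e-3 * sum(lam[!neg]))
      warning("circulant embedding not nonnegative definite; clamping eigenvalues")
    lam[neg] <- 0
  }
  out <- matrix(NA_real_, nrow = nx * ny, ncol = n)
  slam <- sqrt(lam)
  for (k in seq_len(ceiling(n / 2))) {
    Z <- matrix(complex(real = rnorm(Mx * My), imaginary = rnorm(Mx * My)),
                Mx, My)
    W <- stats::fft(slam * Z) / sqrt(Mx * My)
    out[, 2 * k - 1] <- as.vector(Re(W)[1:nx, 1:ny])
    if (2 * k <= n) out[, 2 * k] <- as.vector(Im(W)[1:nx, 1:ny])
  }
  if (vm$nugget > 0)
    out <- out + matrix(rnorm(length(out), sd = sqrt(vm$nugget)), nrow(out))
  out
}

#' Generate independent true Cd and pH fields
#'
#' Draws one unconditional Gaussian field per attribute (disjoint seed
#' streams, so the fields are independent by construction), standardizes
#' it, and maps it through the marginal's quantile function so the field
#' histogram matches the target marginal while the spatial correlation
#' follows the requested variogram.
#'
#' @param grid a [grid_spec()].
#' @param cd_spec,ph_spec lists with elements `vgm` (a
#'   [variogram_model()]; only its nugget ratio and range matter, the sill
#'   is standardized away) and `marginal` (a [marginal_spec()]).
#' @param seed integer seed.
#' @return A list of two [grid_map()]s, `cd` and `ph`.
#' @export
generate_fields <- function(grid, cd_spec, ph_spec, seed = 1) {
  specs <- list(cd = cd_spec, ph = ph_spec)
  out <- vector("list", 2)
  names(out) <- names(specs)
  for (k in 1:2) {
    sp <- specs[[k]]
    stopifnot(inherits(sp$vgm, "variogram_model"),
              inherits(sp$marginal, "marginal_spec"))
    set.seed(.realization_seed(seed, k))
    z <- gaussian_random_field(grid, sp$vgm, n = 1)[, 1]
    z <- z / sqrt(sp$vgm$nugget + sp$vgm$psill)
    out[[k]] <- grid_map(grid, sp$marginal$qfun(pnorm(z)),
                         attribute = names(specs)[k])
  }
  out
}

#' Generate a patchy categorical land-use map
#'
#' Thresholds a smooth latent Gaussian field at its empirical quantiles,
#' so realized class shares match the requested proportions up to cell
#' rounding and classes form contiguous patches of characteristic size
#' `patch_scale`.
#'
#' @param grid a [grid_spec()].
#' @param proportions named numeric vector of class shares summing to 1
#'   (names become the land-use levels). A zero share is allowed (the
#'   class is then absent).
#' @param patch_scale correlation range of the latent field (m).
#' @param seed integer seed.
#' @return A [land_use_map()].
#' @export
generate_landuse <- function(grid,
                             proportions = c("paddy field" = 0.4,
                                             "dry farmland" = 0.3,
                                             "nonfarmland" = 0.3),
                             patch_scale = 2500, seed = 1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
  if (any(proportions == 0))
    message("land-use class(es) with zero share: ",
            paste(names(proportions)[proportions == 0], collapse = ", "))
  set.seed(.realization_seed(seed, 3L))
  latent <- gaussian_random_field(
    grid, variogram_model("gaussian", nugget = 0, psill = 1,
                          range = patch_scale), n = 1)[, 1]
  # exact class counts assigned along the latent field's rank order
  nc <- n_cells(grid)
  counts <- diff(c(0, round(cumsum(proportions) * nc)))
  codes <- integer(nc)
  codes[order(latent)] <- rep.int(seq_along(proportions), counts)
  land_use_map(grid, codes, levels = names(proportions))
}

#' Synthetic study-area scenario
#'
#' Bundles the true fields, land-use map and a sample draw into one
#' reproducible object emulating a ~52 km2 peri-urban study area: 120 x
#' 120 cells of 60 m, a right-skewed Cd field (spherical variogram, nugget
#' ratio 0.4, range 1500 m), an independent pH field (Gaussian-model
#' variogram, nugget ratio 0.5, range 2000 m), three patchy land-use
#' classes, and 150 co-located Cd/pH samples.
#'
#' @param seed integer master seed.
#' @param grid a [grid_spec()]; default 120 x 120 at 60 m.
#' @param n_samples sample count (default 150).
#' @param proportions land-use class shares (named, sum 1).
#' @return A `synthetic_scenario`: list with `grid`, `cd_true`, `ph_true`,
#'   `landuse`, `cd_spec`, `ph_spec`, `samples` (list of two
#'   [sample_set()]s), `seed`.
#' @export
default_scenario <- function(seed = 1, grid = grid_spec(0, 0, 60, 120, 120),
                             n_samples = 150,
                             proportions = c("paddy field" = 0.4,
                                             "dry farmland" = 0.3,
                                             "nonfarmland" = 0.3)) {
  cd_spec <- list(vgm = variogram_model("spherical", nugget = 0.4,
                                        psill = 0.6, range = 1500),
                  marginal = cd_marginal_default())
  ph_spec <- list(vgm = variogram_model("gaussian", nugget = 0.5,
                                        psill = 0.5, range = 2000),
                  marginal = ph_marginal_default())
  fields <- generate_fields(grid, cd_spec, ph_spec, seed = seed)
  lu <- generate_landuse(grid, proportions = proportions, seed = seed)
  sc <- structure(list(grid = grid, cd_true = fields$cd, ph_true = fields$ph,
                       landuse = lu, cd_spec = cd_spec, ph_spec = ph_spec,
                       samples = NULL, seed = seed),
                  class = "synthetic_scenario")
  sc$samples <- draw_samples(sc, n = n_samples, seed = seed)
  sc
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("synthetic_scenario (seed %s): %d x %d cells of %g m; %d samples\n",
              format(x$seed), x$grid$nx, x$grid$ny, x$grid$cell_size,
              if (is.null(x$samples)) 0L else nrow(x$samples$cd)))
  invisible(x)
}

#' Draw co-located samples from a scenario's true fields
#'
#' Picks `n` distinct cell centres uniformly at random and reads both true
#' fields there. By default the values are exact; a positive `noise_sd`
#' adds iid Gaussian measurement noise.
#'
#' @param scenario a [default_scenario()] (or compatible list).
#' @param n number of samples, at most the cell count.
#' @param seed integer seed.
#' @param noise_sd optional measurement-noise SD (same units as each
#'   attribute), length 1 or 2 (`cd`, `ph`).
#' @return A list of two [sample_set()]s, `cd` and `ph`, co-located.
#' @export
draw_samples <- function(scenario, n = 150, seed = 1, noise_sd = 0) {
  grid <- scenario$grid
  if (n > n_cells(grid)) stop("n exceeds the number of grid cells")
  noise_sd <- rep_len(noise_sd, 2)
  set.seed(.realization_seed(seed, 4L))
  idx <- sample.int(n_cells(grid), n)
  ctr <- grid_centres(grid)
  cd <- scenario$cd_true$values[idx] + rnorm(n, sd = noise_sd[1])
  ph <- scenario$ph_true$values[idx] + rnorm(n, sd = noise_sd[2])
  list(cd = sample_set(ctr[idx, 1], ctr[idx, 2], cd, attribute = "cd"),
       ph = sample_set(ctr[idx, 1], ctr[idx, 2],
                       pmin(pmax(ph, 0), 14), attribute = "ph"))
}

#' Write a scenario to plain-text files
#'
#' Writes `samples.csv` (x, y, cd, ph), `landuse.asc`, `cd_true.asc`,
#' `ph_true.asc` and `scenario.json` (seed, grid, variogram and marginal
#' specs, land-use levels) into `dir`, enough to regenerate or reuse the
#' scenario exactly.
#'
#' @param scenario a [default_scenario()] output.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples_csv(scenario$samples, file.path(dir, "samples.csv"))
  write_ascii_grid(scenario$landuse, file.path(dir, "landuse.asc"))
  write_ascii_grid(scenario$cd_true, file.path(dir, "cd_true.asc"))
  write_ascii_grid(scenario$ph_true, file.path(dir, "ph_true.asc"))
  spec_json <- function(sp) list(
    vgm = list(model = sp$vgm$model, nugget = sp$vgm$nugget,
               psill = sp$vgm$psill, range = sp$vgm$range),
    marginal = c(list(type = sp$marginal$type, min = sp$marginal$min,
                      max = sp$marginal$max), sp$marginal$pars))
  jsonlite::write_json(
    list(seed = scenario$seed,
         grid = scenario$grid[c("origin_x", "origin_y", "cell_size", "nx", "ny")],
         land_use_levels = scenario$landuse$levels,
         cd_spec = spec_json(scenario$cd_spec),
         ph_spec = spec_json(scenario$ph_spec)),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
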