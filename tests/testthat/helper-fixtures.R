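# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A realization stack with prescribed values (cells x L), default grid.
toy_stack <- function(values, grid = NULL, attribute = "value") {
  values <- as.matrix(values)
  if (is.null(grid)) {
    nc <- nrow(values)
    nx <- max(1L, as.integer(floor(sqrt(nc))))
    ny <- nc / nx
    stopifnot(ny == as.integer(ny))
    grid <- grid_spec(0, 0, 60, nx, as.integer(ny))
  }
  realization_stack(grid, values, attribute = attribute)
}

# Uniform single-class land-use map matching a grid.
uniform_landuse <- function(grid, class = "paddy field",
                            levels = c("paddy field", "dry farmland",
                                       "nonfarmland")) {
  land_use_map(grid, rep(match(class, levels), n_cells(grid)), levels)
}

# Small synthetic scenario (40 x 40 cells at 60 m, 100 samples) with
# short-range fields: the domain spans several correlation ranges, so
# per-realization histograms are close to ergodic and distributional
# checks are not confounded by domain-scale fluctuation.
small_scenario <- function(seed = 1) {
  cached(paste0("small_scenario_", seed), {
    g <- grid_spec(0, 0, 60, 40, 40)
    cd_spec <- list(vgm = variogram_model("spherical", 0.3, 0.7, 600),
                    marginal = cd_marginal_default())
    ph_spec <- list(vgm = variogram_model("gaussian", 0.5, 0.5, 800),
                    marginal = ph_marginal_default())
    flds <- suppressWarnings(generate_fields(g, cd_spec, ph_spec, seed = seed))
    lu <- suppressWarnings(generate_landuse(g, patch_scale = 1200, seed = seed))
    sc <- structure(list(grid = g, cd_true = flds$cd, ph_true = flds$ph,
                         landuse = lu, cd_spec = cd_spec, ph_spec = ph_spec,
                         samples = NULL, seed = seed),
                    class = "synthetic_scenario")
    sc$samples <- draw_samples(sc, n = 100, seed = seed)
    sc
  })
}

# Average experimental variogram of a stack of grids (score space),
# computed over all node pairs up to max_lag in n_bins bins.
stack_mean_variogram <- function(stack, max_lag, n_bins = 10) {
  ctr <- grid_centres(stack$grid)
  dm <- as.matrix(dist(ctr))
  iu <- which(upper.tri(dm))
  h <- dm[iu]
  keep <- h <= max_lag
  bins <- factor(pmin(floor(h[keep] / (max_lag / n_bins)) + 1L, n_bins),
                 levels = seq_len(n_bins))
  occupied <- levels(bins)[tabulate(bins, n_bins) > 0]
  n <- nrow(dm)
  ii <- ((iu - 1) %% n + 1)[keep]
  jj <- ((iu - 1) %/% n + 1)[keep]
  gm <- vapply(seq_len(stack$L), function(r) {
    v <- stack$values[, r]
    as.numeric((tapply((v[ii] - v[jj])^2, bins, mean) / 2)[occupied])
  }, numeric(length(occupied)))
  list(lag = as.numeric(tapply(h[keep], bins, mean)[occupied]),
       gamma = rowMeans(as.matrix(gm)))
}

# Mann-Whitney AUC of a score for a binary truth label.
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Connected-component sizes of a categorical grid map (4-neighbour).
component_sizes <- function(lu) {
  nx <- lu$grid$nx
  ny <- lu$grid$ny
  codes <- lu$values
  seen <- logical(length(codes))
  sizes <- integer(0)
  for (start in seq_along(codes)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      ix <- (cur - 1L) %% nx + 1L
      iy <- (cur - 1L) %/% nx + 1L
      for (nb in c(if (ix > 1) cur - 1L, if (ix < nx) cur + 1L,
                   if (iy > 1) cur - nx, if (iy < ny) cur + nx)) {
        if (!seen[nb] && codes[nb] == codes[cur]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}
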