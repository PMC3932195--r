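#' Stack of simulated realizations
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix, `n_cells(grid)` rows by `L` columns
#'   (one column per realization, cells in storage order).
#' @param attribute attribute name.
#' @param seed master seed the stack was generated from (metadata).
#' @return A `realization_stack` with elements `grid`, `values`, `L`,
#'   `attribute`, `seed`.
#' @export
realization_stack <- function(grid, values, attribute = "value", seed = NA) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == n_cells(grid), ncol(values) >= 1)
  if (!all(is.finite(values))) stop("realization values must be finite")
  structure(list(grid = grid, values = values, L = ncol(values),
                 attribute = attribute, seed = seed),
            class = "realization_stack")
}

#' @export
print.realization_stack <- function(x, ...) {
  cat(sprintf("realization_stack '%s': L = %d over %d x %d cells; pooled range [%.4g, %.4g]\n",
              x$attribute, x$L, x$grid$nx, x$grid$ny,
              min(x$values), max(x$values)))
  invisible(x)
}

# per-realization seed: an independent, reproducible stream per realization
.realization_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 2147483647 + r * 100003) %% 2147483647)
}

# assign samples to nearest grid nodes; on collision the sample closest to
# the node centre wins (the others are dropped from conditioning)
.assign_to_nodes <- function(grid, s) {
  node <- grid_node_index(grid, s$x, s$y)
  keep <- !is.na(node)
  if (!all(keep))
    warning(sum(!keep), " sample(s) outside the grid dropped from conditioning")
  node <- node[keep]
  idx <- which(keep)
  ctr <- grid_centres(grid)
  d2 <- (s$x[idx] - ctr[node, 1])^2 + (s$y[idx] - ctr[node, 2])^2
  o <- order(node, d2)
  first <- !duplicated(node[o])
  list(node = node[o][first], sample = idx[o][first])
}

#' Conditional sequential Gaussian simulation
#'
#' Simulates `L` equiprobable fields of an attribute on a regular grid,
#' conditioned to point samples. Samples are normal-score transformed and
#' assigned to their nearest grid nodes; each realization then visits the
#' remaining nodes along a fresh uniform random path, estimates the
#' Gaussian conditional distribution at each node by simple kriging (known
#' mean 0) from up to `nmax` informed nodes within the search radius, draws
#' from it, and finally back-transforms every node to original units.
#' Nodes holding a sample keep that sample's value exactly in every
#' realization. A singular kriging system falls back to a draw from the
#' marginal.
#'
#' @param s a [sample_set()] (conditioning data, original units).
#' @param vm a [variogram_model()] fitted on the normal scores of `s`
#'   (its sill `C0 + C` should be close to 1).
#' @param grid a [grid_spec()].
#' @param L number of realizations.
#' @param seed integer master seed; realization `r` uses a seed derived
#'   from it, so stacks are bit-reproducible.
#' @param nsmap optional pre-fitted [normal_score_fit()] for `s` (fitted
#'   internally when `NULL`).
#' @param nmax maximum informed nodes in each kriging system.
#' @param radius search radius in metres; default 1.5 x the variogram
#'   range.
#' @param back_transform if `FALSE`, return the simulated normal scores
#'   instead of original units (used for variogram-reproduction checks).
#' @return A [realization_stack()].
#' @export
sgs_simulate <- function(s, vm, grid, L = 500, seed = 1, nsmap = NULL,
                         nmax = 16, radius = NULL, back_transform = TRUE) {
  stopifnot(inherits(s, "sample_set"), inherits(vm, "variogram_model"),
            inherits(grid, "grid_spec"), L >= 1)
  if (nrow(s) < 10)
    warning("fewer than 10 samples: variogram and transform are unreliable")
  sill <- vm$nugget + vm$psill
  if (abs(sill - 1) > 0.3)
    warning(sprintf("variogram sill %.3g is far from 1; expected a normal-score model", sill))
  if (is.null(radius)) radius <- 1.5 * vm$range
  if (is.null(nsmap)) nsmap <- normal_score_fit(s)
  asg <- .assign_to_nodes(grid, s)
  data_score <- normal_score_transform(nsmap, s$value[asg$sample])
  model_id <- match(vm$model, c("spherical", "gaussian", "exponential"))
  out <- matrix(NA_real_, nrow = n_cells(grid), ncol = L)
  for (r in seq_len(L)) {
    set.seed(.realization_seed(seed, r))
    sim <- sgs_core(grid$nx, grid$ny, grid$cell_size,
                    asg$node - 1L, data_score,
                    model_id, vm$nugget, vm$psill, vm$range,
                    as.integer(nmax), radius)
    if (back_transform) {
      sim <- normal_score_back_transform(nsmap, sim)
      # conditioning nodes reproduce the sample values bit-exactly
      sim[asg$node] <- s$value[asg$sample]
    }
    out[, r] <- sim
  }
  realization_stack(grid, out, attribute = attr(s, "attribute"), seed = seed)
}

#' E-type estimate
#'
#' Cell-wise arithmetic mean over the realizations of a stack: the optimal
#' (but smoothed) point estimate implied by the simulation.
#'
#' @param stack a [realization_stack()].
#' @return A [grid_map()] of per-cell means.
#' @export
etype_estimate <- function(stack) {
  stopifnot(inherits(stack, "realization_stack"))
  grid_map(stack$grid, rowMeans(stack$values),
           attribute = paste0(stack$attribute, "_etype"))
}
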