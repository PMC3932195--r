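#' Per-cell probability that pH falls in a standard interval
#'
#' Frequency estimator over realizations: the fraction of the `L` simulated
#' pH values at each cell that fall in interval `i` of the composite
#' standard (left-closed/right-open, last interval closed at 14).
#'
#' @param ph_stack a pH [realization_stack()].
#' @param std a [composite_standard()].
#' @param i interval ordinal in `1..S`.
#' @return A [grid_map()] of probabilities (exact multiples of `1/L`).
#' @export
interval_probability <- function(ph_stack, std, i) {
  stopifnot(inherits(ph_stack, "realization_stack"),
            inherits(std, "composite_standard"),
            i >= 1, i <= std$S)
  v <- pmin(pmax(ph_stack$values, 0), 14)
  iv <- findInterval(v, std$breakpoints, rightmost.closed = TRUE)
  grid_map(ph_stack$grid, rowMeans(matrix(iv == i, nrow = nrow(v))),
           attribute = sprintf("p_ph_interval_%d", i))
}

#' Per-cell probability that Cd exceeds a single threshold
#'
#' @param cd_stack a Cd [realization_stack()].
#' @param beta threshold (mg/kg), > 0. Exceedance is strict: a realization
#'   exactly at the threshold does not count.
#' @return A [grid_map()] of probabilities (exact multiples of `1/L`).
#' @export
threshold_probability <- function(cd_stack, beta) {
  stopifnot(inherits(cd_stack, "realization_stack"), beta > 0)
  grid_map(cd_stack$grid, rowMeans(cd_stack$values > beta),
           attribute = sprintf("p_cd_gt_%g", beta))
}

#' Standard-exceeding probability map
#'
#' Combines Cd and pH realization stacks with the land-use map and the
#' composite standard into the per-cell probability that Cd exceeds its
#' locally applicable threshold.
#'
#' In `"product"` mode (the default, valid when the Cd and pH fields are
#' simulated independently) the probability is the sum over pH intervals of
#' the interval frequency times the exceedance frequency of that interval's
#' threshold for the cell's land use. In `"joint"` mode the paired
#' realizations are counted directly: realization `r`'s simulated pH picks
#' the threshold that realization `r`'s simulated Cd is compared against.
#'
#' @param cd_stack,ph_stack [realization_stack()]s on the same grid with
#'   the same `L`.
#' @param lu a [land_use_map()] on the same grid, whose levels must all be
#'   declared in the standard.
#' @param std a [composite_standard()].
#' @param mode `"product"` or `"joint"`.
#' @return A `probability_map` (a [grid_map()] subclass) with values in
#'   \[0, 1\]; attribute `mode` records the estimator.
#' @export
exceedance_probability <- function(cd_stack, ph_stack, lu, std,
                                   mode = c("product", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cd_stack, "realization_stack"),
            inherits(ph_stack, "realization_stack"),
            inherits(lu, "land_use_map"),
            inherits(std, "composite_standard"))
  if (!same_grid(cd_stack$grid, ph_stack$grid) ||
      !same_grid(cd_stack$grid, lu$grid))
    stop("Cd stack, pH stack and land-use map must share one grid")
  if (cd_stack$L != ph_stack$L)
    stop("Cd and pH stacks must hold the same number of realizations")
  lu_row <- match(lu$levels, std$land_uses)
  if (anyNA(lu_row))
    stop("land-use type(s) not in standard: ",
         paste(lu$levels[is.na(lu_row)], collapse = ", "))
  nc <- n_cells(cd_stack$grid)
  L <- cd_stack$L
  # thresholds per cell x interval, from each cell's land use
  beta <- std$thresholds[lu_row[lu$values], , drop = FALSE] # nc x S

  if (mode == "product") {
    p <- numeric(nc)
    phv <- pmin(pmax(ph_stack$values, 0), 14)
    iv <- matrix(findInterval(phv, std$breakpoints, rightmost.closed = TRUE),
                 nrow = nc)
    for (i in seq_len(std$S)) {
      p_ph <- rowMeans(iv == i)
      p_cd <- rowMeans(cd_stack$values > beta[, i])
      p <- p + p_ph * p_cd
    }
  } else {
    phv <- pmin(pmax(ph_stack$values, 0), 14)
    iv <- matrix(findInterval(phv, std$breakpoints, rightmost.closed = TRUE),
                 nrow = nc)
    beta_r <- matrix(beta[cbind(rep(seq_len(nc), L), as.vector(iv))], nrow = nc)
    p <- rowMeans(cd_stack$values > beta_r)
  }
  out <- grid_map(cd_stack$grid, p, attribute = "p_exceed")
  out$mode <- mode
  class(out) <- c("probability_map", class(out))
  out
}

#' Delineate priority-remediation areas
#'
#' Flags every cell whose exceedance probability is at least the critical
#' probability `p_c`. Raising `p_c` can only shrink the flagged area.
#'
#' @param pm a probability map ([exceedance_probability()] output or any
#'   [grid_map()] with values in \[0, 1\]).
#' @param p_c critical probability in (0, 1\].
#' @return A `risk_mask` (a [grid_map()] of logicals) with fields `p_c`,
#'   `n_flagged` and `area_km2`.
#' @export
delineate_risk <- function(pm, p_c) {
  stopifnot(inherits(pm, "grid_map"), p_c > 0, p_c <= 1)
  v <- pm$values
  stopifnot(all(v >= 0 & v <= 1, na.rm = TRUE))
  flag <- !is.na(v) & v >= p_c
  out <- grid_map(pm$grid, flag, attribute = "risk_mask")
  out$p_c <- p_c
  out$n_flagged <- sum(flag)
  out$area_km2 <- sum(flag) * pm$grid$cell_size^2 / 1e6
  class(out) <- c("risk_mask", class(out))
  out
}

#' @export
print.risk_mask <- function(x, ...) {
  cat(sprintf("risk_mask: p_c = %.2f; %d cells flagged (%.3f km2)\n",
              x$p_c, x$n_flagged, x$area_km2))
  invisible(x)
}

#' Descriptive statistics with CV classification
#'
#' @param s a [sample_set()] with `n >= 2`.
#' @return A one-row data frame: `min`, `max`, `median`, `mean`, `sd`,
#'   `cv_pct` (`100 * sd / mean`, `NA` when `mean <= 0`) and
#'   `variability` (`"low"` below 10%, `"extensive"` above 90%,
#'   `"moderate"` otherwise, boundaries inclusive to moderate).
#' @export
descriptive_stats <- function(s) {
  stopifnot(inherits(s, "sample_set"), nrow(s) >= 2)
  v <- s$value
  m <- mean(v)
  cv <- if (m > 0) 100 * sd(v) / m else NA_real_
  cls <- if (is.na(cv)) NA_character_
         else if (cv < 10) "low"
         else if (cv > 90) "extensive"
         else "moderate"
  if (is.na(cv)) warning("mean <= 0: CV undefined")
  data.frame(attribute = attr(s, "attribute"), n = nrow(s),
             min = min(v), max = max(v), median = median(v),
             mean = m, sd = sd(v), cv_pct = cv, variability = cls,
             stringsAsFactors = FALSE)
}

#' Omnidirectional cross-correlogram between two attributes
#'
#' Lag-binned Pearson cross-correlation of head/tail pairs: for every
#' ordered pair of sample locations whose separation falls in a lag bin,
#' the head value of attribute `a` is paired with the tail value of
#' attribute `b`, and the bin's statistic is the Pearson correlation of
#' those pairs. Bin 0 (separations up to `lag0_tol`) contains the
#' co-located pairs, so the lag-0 correlogram of an attribute with itself
#' is exactly 1.
#'
#' @param a,b [sample_set()]s on identical (co-located) coordinates.
#' @param n_lags number of positive-lag bins.
#' @param max_lag largest separation (m); defaults to half the maximum
#'   pairwise distance.
#' @param lag0_tol co-location tolerance (m) for the zero-lag bin.
#' @return A `cross_correlogram` data frame: `lag`, `rho`, `np` (ordered
#'   pair count).
#' @export
cross_correlogram <- function(a, b, n_lags = 12, max_lag = NULL,
                              lag0_tol = 1e-6) {
  stopifnot(inherits(a, "sample_set"), inherits(b, "sample_set"),
            nrow(a) == nrow(b))
  if (max(abs(a$x - b$x), abs(a$y - b$y)) > lag0_tol)
    stop("cross_correlogram requires co-located sample sets")
  n <- nrow(a)
  d <- as.matrix(dist(a[, c("x", "y")]))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  width <- max_lag / n_lags
  edges <- c(lag0_tol, seq_len(n_lags) * width)
  lag_centre <- c(0, (seq_len(n_lags) - 0.5) * width)
  rho <- rep(NA_real_, n_lags + 1)
  np <- integer(n_lags + 1)
  for (k in seq_along(edges)) {
    lo <- if (k == 1) -1 else edges[k - 1]
    sel <- which(d > lo & d <= edges[k], arr.ind = TRUE)
    if (k == 1) sel <- rbind(sel, cbind(seq_len(n), seq_len(n)))
    np[k] <- nrow(sel)
    if (np[k] >= 2) {
      head_a <- a$value[sel[, 1]]
      tail_b <- b$value[sel[, 2]]
      if (sd(head_a) > 0 && sd(tail_b) > 0)
        rho[k] <- cor(head_a, tail_b)
    }
  }
  keep <- np >= 2 & !is.na(rho)
  if (!any(keep)) stop("fewer than 2 pairs in every lag bin")
  out <- data.frame(lag = lag_centre[keep], rho = rho[keep], np = np[keep])
  structure(out, class = c("cross_correlogram", "data.frame"))
}
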