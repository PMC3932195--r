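#' Georeferenced point samples of one attribute
#'
#' @param x,y coordinates in metres.
#' @param value measured attribute values.
#' @param attribute attribute name (e.g. `"cd"`, `"ph"`).
#' @param coord_tol two samples closer than this (m) are considered
#'   duplicates and rejected.
#' @return A `sample_set`: a data frame with columns `x`, `y`, `value` and
#'   attributes `attribute` and `n`.
#' @export
sample_set <- function(x, y, value, attribute = "value", coord_tol = 1e-6) {
  stopifnot(length(x) == length(y), length(x) == length(value))
  if (anyNA(x) || anyNA(y) || anyNA(value))
    stop("sample coordinates and values must be complete (no NA)")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   value = as.numeric(value))
  if (nrow(df) >= 2) {
    d <- dist(df[, c("x", "y")])
    if (any(d < coord_tol))
      stop("duplicate sample coordinates (within tolerance)")
  }
  structure(df, attribute = attribute, n = nrow(df),
            class = c("sample_set", "data.frame"))
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set '%s': n = %d, value range [%.4g, %.4g]\n",
              attr(x, "attribute"), nrow(x), min(x$value), max(x$value)))
  invisible(x)
}

#' Omnidirectional experimental variogram
#'
#' Matheron's method-of-moments estimator on isotropic distance bins:
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over all sample pairs whose
#' separation falls in the bin around `h`.
#'
#' @param s a [sample_set()] with at least 2 points.
#' @param n_lags number of equal-width lag bins.
#' @param max_lag largest separation considered (m); defaults to half the
#'   maximum pairwise distance.
#' @return An `experimental_variogram`: data frame with columns `lag`
#'   (bin centre, m), `gamma` (semivariance), `np` (pair count); empty bins
#'   are dropped (their count is kept in attribute `n_empty`).
#' @export
experimental_variogram <- function(s, n_lags = 12, max_lag = NULL) {
  stopifnot(inherits(s, "sample_set"), nrow(s) >= 2, n_lags >= 1)
  d <- as.matrix(dist(s[, c("x", "y")]))
  iu <- which(upper.tri(d))
  h <- d[iu]
  dz2 <- (outer(s$value, s$value, "-")[iu])^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  stopifnot(max_lag > 0)
  keep <- h <= max_lag & h > 0
  if (!any(keep)) stop("no pairs in any lag (all separations exceed max_lag)")
  width <- max_lag / n_lags
  bin <- pmin(floor(h[keep] / width) + 1L, n_lags)
  np <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags),
                 function(b) sum(dz2[keep][bin == b]), numeric(1))
  lag <- vapply(seq_len(n_lags),
                function(b) if (np[b] > 0) mean(h[keep][bin == b]) else
                  (b - 0.5) * width, numeric(1))
  gamma <- ifelse(np > 0, gsum / (2 * np), NA_real_)
  out <- data.frame(lag = lag, gamma = gamma, np = np)[np > 0, ]
  rownames(out) <- NULL
  structure(out, attribute = attr(s, "attribute"),
            n_empty = sum(np == 0), max_lag = max_lag,
            class = c("experimental_variogram", "data.frame"))
}

#' Parametric variogram model
#'
#' Supported families (isotropic): `spherical` (range `a` is the actual
#' range), `gaussian` and `exponential` (range `a` is the practical range,
#' i.e. `gamma` reaches ~95% of the sill at `h = a`).
#'
#' @param model one of `"spherical"`, `"gaussian"`, `"exponential"`.
#' @param nugget nugget variance C0 (attribute units squared), >= 0.
#' @param psill partial sill C (units squared), > 0.
#' @param range range parameter a (m), > 0.
#' @return A `variogram_model`.
#' @export
variogram_model <- function(model = c("spherical", "gaussian", "exponential"),
                            nugget, psill, range) {
  model <- match.arg(model)
  stopifnot(nugget >= 0, psill > 0, range > 0)
  structure(list(model = model, nugget = as.numeric(nugget),
                 psill = as.numeric(psill), range = as.numeric(range)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, C0 = %.4g, C = %.4g, a = %.4g m (nugget ratio %.2f)\n",
              x$model, x$nugget, x$psill, x$range, nugget_ratio(x)))
  invisible(x)
}

# unit-sill correlation part of the semivariance, g(h) in [0, 1]
.vgm_g <- function(model, h, a) {
  switch(model,
         spherical = ifelse(h >= a, 1, 1.5 * (h / a) - 0.5 * (h / a)^3),
         gaussian = 1 - exp(-3 * (h / a)^2),
         exponential = 1 - exp(-3 * h / a))
}

#' Evaluate a variogram model
#' @param vm a [variogram_model()].
#' @param h lag distances (m), >= 0.
#' @return `gamma(h) = C0 + C g(h)` for `h > 0`; 0 at `h = 0`.
#' @export
variogram_gamma <- function(vm, h) {
  stopifnot(inherits(vm, "variogram_model"), all(h >= 0))
  ifelse(h == 0, 0, vm$nugget + vm$psill * .vgm_g(vm$model, h, vm$range))
}

#' Covariance implied by a variogram model
#' @param vm a [variogram_model()].
#' @param h lag distances (m).
#' @return `C(h) = C0 + C` at `h = 0`, `C (1 - g(h))` otherwise.
#' @export
variogram_cov <- function(vm, h) {
  stopifnot(inherits(vm, "variogram_model"))
  ifelse(h == 0, vm$nugget + vm$psill,
         vm$psill * (1 - .vgm_g(vm$model, h, vm$range)))
}

#' Relative nugget effect
#' @param vm a [variogram_model()].
#' @return `C0 / (C0 + C)` in \[0, 1\]; values between 0.25 and 0.75 are
#'   conventionally read as moderate spatial autocorrelation.
#' @export
nugget_ratio <- function(vm) {
  stopifnot(inherits(vm, "variogram_model"), vm$nugget + vm$psill > 0)
  vm$nugget / (vm$nugget + vm$psill)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum_j N(h_j) * (gamma_emp(h_j) - gamma_mod(h_j))^2 /
#' gamma_mod(h_j)^2` (Cressie-style weights, recomputed from the current
#' model inside the objective) over (C0, C, a) with `optim(L-BFGS-B)` from
#' a small grid of starting values.
#'
#' @param ev an [experimental_variogram()] with at least 3 non-empty lags.
#' @param model model family to fit.
#' @return A [variogram_model()]; attribute `wss` holds the attained
#'   objective. A non-convergent fit errors but carries the best candidate
#'   in the condition's `best` field.
#' @export
fit_variogram <- function(ev, model = c("spherical", "gaussian", "exponential")) {
  model <- match.arg(model)
  stopifnot(inherits(ev, "experimental_variogram"), nrow(ev) >= 3)
  h <- ev$lag; g <- ev$gamma; np <- ev$np
  obj <- function(par) {
    gm <- par[1] + par[2] * .vgm_g(model, h, par[3])
    if (any(gm <= 0)) return(1e12)
    sum(np * (g - gm)^2 / gm^2)
  }
  sill0 <- max(mean(g[(length(g) - 2):length(g)]), 1e-8)
  nr0 <- max(min(g[1] / sill0, 0.9), 0)
  starts <- expand.grid(nr = unique(c(nr0, 0.1, 0.5)),
                        a = max(h) * c(0.3, 0.6, 1.0))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(starts$nr[k] * sill0, (1 - starts$nr[k]) * sill0, starts$a[k])
    fit <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B",
            lower = c(0, 1e-10, max(h) * 1e-3),
            upper = c(sill0 * 4, sill0 * 4, max(h) * 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed from every starting value")
  if (best$convergence != 0 && best$value > 1e6) {
    cond <- simpleError("variogram fit did not converge")
    cond$best <- best
    stop(cond)
  }
  vm <- variogram_model(model, nugget = best$par[1], psill = best$par[2],
                        range = best$par[3])
  attr(vm, "wss") <- best$value
  vm
}

#' Write / read a variogram model as JSON
#' @param vm a [variogram_model()].
#' @param path file path.
#' @return `path` (write) or a [variogram_model()] (read).
#' @export
write_variogram_json <- function(vm, path) {
  stopifnot(inherits(vm, "variogram_model"))
  jsonlite::write_json(list(model = vm$model, nugget = vm$nugget,
                            psill = vm$psill, range = vm$range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_variogram_json
#' @export
read_variogram_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  variogram_model(j$model, j$nugget, j$psill, j$range)
}
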