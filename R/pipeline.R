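#' Build and validate a run configuration
#'
#' A run configuration collects everything the end-to-end workflow needs.
#' It can be built from a named list or read from a JSON file; unspecified
#' fields take the defaults below.
#'
#' Fields: `samples` (CSV path; `NULL` means generate the synthetic
#' scenario), `landuse` (ESRI ASCII path) and `land_use_levels` (class
#' names for its integer codes), `standard` (JSON path; `NULL` means the
#' packaged Cd standard), `out_dir` (`NULL` means keep results in memory),
#' `L` (realizations, default 500), `seed` (default 1), `mode`
#' (`"product"`/`"joint"`), `p_c` (critical probabilities, default 0.90
#' and 0.95), `cd_model`/`ph_model` (variogram families, default
#' spherical/gaussian), `n_lags`, `nmax`, `overwrite`, and — for synthetic
#' runs only — `grid` (a [grid_spec()] or its field list) and `n_samples`.
#'
#' @param x named list or JSON file path.
#' @return A validated `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  stopifnot(is.list(x))
  cfg <- list(samples = NULL, landuse = NULL, land_use_levels = NULL,
              standard = NULL, out_dir = NULL,
              L = 500L, seed = 1L, mode = "product", p_c = c(0.90, 0.95),
              cd_model = "spherical", ph_model = "gaussian",
              n_lags = 12L, nmax = 16L, overwrite = FALSE,
              grid = NULL, n_samples = 150L)
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(x)] <- x
  cfg$L <- as.integer(cfg$L)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$L < 1) stop("L must be at least 1")
  if (any(cfg$p_c <= 0 | cfg$p_c > 1)) stop("each p_c must lie in (0, 1]")
  if (!cfg$mode %in% c("product", "joint")) stop("mode must be product or joint")
  if (xor(is.null(cfg$samples), is.null(cfg$landuse)))
    stop("provide both samples and landuse paths, or neither (synthetic run)")
  for (p in c(cfg$samples, cfg$landuse, cfg$standard))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (!is.null(cfg$landuse) && is.null(cfg$land_use_levels))
    stop("land_use_levels must name the classes of the land-use grid")
  if (!is.null(cfg$grid) && !inherits(cfg$grid, "grid_spec"))
    cfg$grid <- do.call(grid_spec, as.list(cfg$grid))
  cfg$n_samples <- as.integer(cfg$n_samples)
  structure(cfg, class = "run_config")
}

#' Fit a normal-score variogram for one attribute
#'
#' Transforms the samples to normal scores, estimates the omnidirectional
#' experimental variogram of the scores and fits the requested model
#' family — the modelling route the simulation expects.
#'
#' @param s a [sample_set()].
#' @param model variogram family.
#' @param n_lags number of lag bins.
#' @return List with `nsmap`, `scores` (a [sample_set()]), `ev`, `vm`.
#' @export
fit_normal_score_variogram <- function(s, model = "spherical", n_lags = 12) {
  nsmap <- normal_score_fit(s)
  scores <- sample_set(s$x, s$y, normal_score_transform(nsmap, s$value),
                       attribute = paste0(attr(s, "attribute"), "_ns"))
  ev <- experimental_variogram(scores, n_lags = n_lags)
  vm <- fit_variogram(ev, model = model)
  list(nsmap = nsmap, scores = scores, ev = ev, vm = vm)
}

#' Run the full exceedance-probability workflow
#'
#' Chains every stage: load (or synthesize) samples, land use and the
#' composite standard; fit normal-score variograms for Cd and pH; simulate
#' `L` conditional realizations of each by SGS (independent seed streams);
#' estimate the per-cell standard-exceeding probability; and delineate a
#' risk mask at each critical probability. With `out_dir` set, writes the
#' E-type estimates, probability map and masks as ESRI ASCII grids, the
#' fitted variograms and a JSON run report.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @param quiet suppress progress messages.
#' @return List with `samples`, `landuse`, `standard`, `cd_fit`, `ph_fit`
#'   (see [fit_normal_score_variogram()]), `cd_stack`, `ph_stack`,
#'   `cd_etype`, `ph_etype`, `prob_map`, `masks` (one [delineate_risk()]
#'   per `p_c`), `report` (the run summary written to JSON), and
#'   `scenario` for synthetic runs.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  if (!is.null(config$out_dir) &&
      file.exists(file.path(config$out_dir, "report.json")) &&
      !config$overwrite)
    stop("output already exists in ", config$out_dir, " (use overwrite)")

  scenario <- NULL
  if (is.null(config$samples)) {
    say("synthesizing default scenario (seed ", config$seed, ")")
    scenario <- if (is.null(config$grid))
      default_scenario(seed = config$seed, n_samples = config$n_samples)
    else
      default_scenario(seed = config$seed, grid = config$grid,
                       n_samples = config$n_samples)
    samples <- scenario$samples
    lu <- scenario$landuse
    grid <- scenario$grid
  } else {
    samples <- read_samples_csv(config$samples)
    if (!all(c("cd", "ph") %in% names(samples)))
      stop("samples CSV must provide cd and ph columns")
    lu <- read_ascii_grid(config$landuse, levels = config$land_use_levels)
    grid <- lu$grid
  }
  std <- if (is.null(config$standard)) seqs_cd_china()
         else parse_standard(config$standard)

  say("fitting normal-score variograms")
  cd_fit <- fit_normal_score_variogram(samples$cd, config$cd_model,
                                       config$n_lags)
  ph_fit <- fit_normal_score_variogram(samples$ph, config$ph_model,
                                       config$n_lags)

  say("simulating ", config$L, " realizations per attribute")
  cd_stack <- sgs_simulate(samples$cd, cd_fit$vm, grid, L = config$L,
                           seed = config$seed, nsmap = cd_fit$nsmap,
                           nmax = config$nmax)
  ph_stack <- sgs_simulate(samples$ph, ph_fit$vm, grid, L = config$L,
                           seed = config$seed + 50001L, nsmap = ph_fit$nsmap,
                           nmax = config$nmax)

  say("estimating exceedance probabilities (", config$mode, " mode)")
  pm <- exceedance_probability(cd_stack, ph_stack, lu, std, mode = config$mode)
  masks <- lapply(config$p_c, function(p) delineate_risk(pm, p))
  names(masks) <- sprintf("p%.2f", config$p_c)

  per_lu <- vapply(seq_along(lu$levels), function(k) {
    v <- pm$values[lu$values == k]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  report <- list(
    seed = config$seed, L = config$L, mode = config$mode,
    n_samples = nrow(samples$cd),
    grid = grid[c("origin_x", "origin_y", "cell_size", "nx", "ny")],
    variograms = list(
      cd = c(model = cd_fit$vm$model, nugget = cd_fit$vm$nugget,
             psill = cd_fit$vm$psill, range = cd_fit$vm$range),
      ph = c(model = ph_fit$vm$model, nugget = ph_fit$vm$nugget,
             psill = ph_fit$vm$psill, range = ph_fit$vm$range)),
    max_probability_by_land_use = stats::setNames(as.list(per_lu), lu$levels),
    risk_areas = lapply(masks, function(m)
      list(p_c = m$p_c, n_flagged = m$n_flagged, area_km2 = m$area_km2)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_ascii_grid(etype_estimate(cd_stack), file.path(dir, "cd_etype.asc"))
    write_ascii_grid(etype_estimate(ph_stack), file.path(dir, "ph_etype.asc"))
    write_ascii_grid(pm, file.path(dir, "probability.asc"))
    for (nm in names(masks))
      write_ascii_grid(masks[[nm]], file.path(dir, paste0("risk_", nm, ".asc")))
    write_variogram_json(cd_fit$vm, file.path(dir, "variogram_cd.json"))
    write_variogram_json(ph_fit$vm, file.path(dir, "variogram_ph.json"))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("outputs written to ", dir)
  }

  invisible(list(scenario = scenario, samples = samples, landuse = lu,
                 standard = std, cd_fit = cd_fit, ph_fit = ph_fit,
                 cd_stack = cd_stack, ph_stack = ph_stack,
                 cd_etype = etype_estimate(cd_stack),
                 ph_etype = etype_estimate(ph_stack),
                 prob_map = pm, masks = masks, report = report))
}
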