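#' Read point samples from CSV
#'
#' Expects a header with `x`, `y` and at least one attribute column (e.g.
#' `cd`, `ph`). Every attribute column becomes one [sample_set()]. A `ph`
#' column is range-checked against \[0, 14\]. Errors name the offending
#' rows.
#'
#' @param path CSV file path.
#' @return Named list of [sample_set()]s, one per attribute column.
#' @export
read_samples_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("x", "y") %in% names(df)))
    stop("samples CSV must have columns x and y")
  attrs <- setdiff(names(df), c("x", "y"))
  if (!length(attrs)) stop("samples CSV has no attribute column")
  for (col in c("x", "y", attrs)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric or missing '%s' in row(s) %s", col,
                   paste(head(bad, 5), collapse = ", ")))
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("ph" %in% attrs) {
    bad <- which(df$ph < 0 | df$ph > 14)
    if (length(bad))
      stop("pH outside [0, 14] in row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  out <- lapply(attrs, function(a) sample_set(df$x, df$y, df[[a]], attribute = a))
  names(out) <- attrs
  out
}

#' Write co-located sample sets to CSV
#' @param samples named list of co-located [sample_set()]s (e.g.
#'   `list(cd = ..., ph = ...)`) or a single sample set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  if (inherits(samples, "sample_set"))
    samples <- stats::setNames(list(samples), attr(samples, "attribute"))
  base <- samples[[1]]
  df <- data.frame(x = base$x, y = base$y)
  for (nm in names(samples)) {
    s <- samples[[nm]]
    if (max(abs(s$x - base$x), abs(s$y - base$y)) > 1e-9)
      stop("sample sets must be co-located to share one CSV")
    df[[nm]] <- s$value
  }
  # 17 significant digits so doubles survive the text round trip exactly
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header and the row-major body (top row first), converting to the
#' package's bottom-row-first storage order. NODATA cells become `NA`.
#'
#' @param path `.asc` file path.
#' @param levels optional character vector: interpret the grid as a
#'   categorical [land_use_map()] with these class names (codes 1-based).
#' @param attribute attribute name for the returned map.
#' @return A [grid_map()] (or [land_use_map()] when `levels` is given).
#' @export
read_ascii_grid <- function(path, levels = NULL, attribute = "value") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  if (length(vals) != nx * ny)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d = %d",
                 length(vals), nx, ny, nx * ny))
  vals[vals == nodata] <- NA
  m <- matrix(vals, nrow = nx, ncol = ny)        # column = file row (top first)
  storage <- as.vector(m[, ny:1])                # flip to bottom-row-first
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nx, ny)
  if (is.null(levels)) grid_map(grid, storage, attribute = attribute)
  else land_use_map(grid, storage, levels = levels)
}

#' Write a grid map as an ESRI ASCII grid
#'
#' @param map a [grid_map()] (logical values are written as 0/1,
#'   land-use maps as their integer codes).
#' @param path output `.asc` path.
#' @param na_value NODATA sentinel.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(map, path, na_value = -9999) {
  stopifnot(inherits(map, "grid_map"))
  g <- map$grid
  v <- as.numeric(map$values)
  v[is.na(v)] <- na_value
  m <- matrix(v, nrow = g$nx, ncol = g$ny)[, g$ny:1, drop = FALSE]
  hdr <- c(sprintf("ncols %d", g$nx),
           sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", na_value))
  body <- apply(m, 2, function(row) paste(sprintf("%.15g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
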