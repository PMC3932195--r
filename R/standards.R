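#' Composite soil environmental quality standard
#'
#' A composite standard gives one contaminant threshold per combination of
#' soil-pH interval and land-use type: `S` pH intervals are defined by
#' `S + 1` breakpoints spanning the full pH scale, and each land use has a
#' row of `S` thresholds. Intervals are left-closed/right-open, except the
#' last which is closed at pH 14, so every pH in \[0, 14\] falls in exactly
#' one interval.
#'
#' @param breakpoints strictly increasing numeric vector of `S + 1` pH
#'   breakpoints; the first must be 0 and the last 14.
#' @param land_uses character vector of land-use type names.
#' @param thresholds numeric matrix of Cd thresholds (mg/kg), one row per
#'   land use and one column per pH interval; strictly positive and, within
#'   each row, non-decreasing with pH interval.
#' @return A `composite_standard` with elements `breakpoints`, `land_uses`,
#'   `thresholds` (dimnamed matrix) and `S` (interval count).
#' @seealso [seqs_cd_china()] for the packaged Cd standard,
#'   [lookup_threshold()], [interval_index()].
#' @examples
#' std <- composite_standard(c(0, 14), "farmland", matrix(1.0, 1, 1))
#' std$S
#' @export
composite_standard <- function(breakpoints, land_uses, thresholds) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 2 || any(diff(breakpoints) <= 0))
    stop("pH breakpoints must be strictly increasing with at least one interval")
  if (breakpoints[1] != 0 || breakpoints[length(breakpoints)] != 14)
    stop("pH breakpoints must start at 0 and end at 14")
  land_uses <- as.character(land_uses)
  if (!length(land_uses) || anyDuplicated(land_uses))
    stop("land-use names must be non-empty and unique")
  S <- length(breakpoints) - 1L
  thresholds <- as.matrix(thresholds)
  if (!is.numeric(thresholds) || anyNA(thresholds))
    stop("thresholds must be a complete numeric matrix (one value per land use and interval)")
  if (nrow(thresholds) != length(land_uses) || ncol(thresholds) != S)
    stop(sprintf("threshold matrix must be %d land uses x %d intervals, got %d x %d",
                 length(land_uses), S, nrow(thresholds), ncol(thresholds)))
  if (any(thresholds <= 0))
    stop("thresholds must be strictly positive")
  if (any(apply(thresholds, 1, function(r) any(diff(r) < 0))))
    stop("within each land use, thresholds must be non-decreasing with pH interval")
  dimnames(thresholds) <- list(
    land_uses,
    sprintf("[%g,%g%s", breakpoints[-length(breakpoints)], breakpoints[-1],
            c(rep(")", S - 1), "]")))
  structure(list(breakpoints = breakpoints, land_uses = land_uses,
                 thresholds = thresholds, S = S),
            class = "composite_standard")
}

#' @export
print.composite_standard <- function(x, ...) {
  cat(sprintf("composite_standard: %d pH intervals x %d land uses (mg/kg)\n",
              x$S, length(x$land_uses)))
  print(x$thresholds)
  invisible(x)
}

#' Parse a composite standard from a structured document
#'
#' Accepts either a path to a JSON file or an already-parsed list with
#' fields `breakpoints`, `land_uses` and `thresholds` (a matrix, or a list
#' of per-land-use rows). The result is fully validated.
#'
#' @param document file path or list.
#' @return A [composite_standard()].
#' @export
parse_standard <- function(document) {
  if (is.character(document) && length(document) == 1) {
    document <- jsonlite::read_json(document, simplifyVector = TRUE)
  }
  if (!is.list(document))
    stop("standard document must be a JSON path or a list")
  need <- c("breakpoints", "land_uses", "thresholds")
  miss <- setdiff(need, names(document))
  if (length(miss))
    stop("standard document missing field(s): ", paste(miss, collapse = ", "))
  th <- document$thresholds
  if (is.list(th) && !is.data.frame(th)) {
    len <- lengths(th)
    if (length(unique(len)) != 1)
      stop("ragged threshold matrix: rows have lengths ",
           paste(len, collapse = ", "))
    th <- do.call(rbind, lapply(th, as.numeric))
  }
  composite_standard(document$breakpoints, document$land_uses, th)
}

#' Write a composite standard as JSON
#' @param std a [composite_standard()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_standard_json <- function(std, path) {
  stopifnot(inherits(std, "composite_standard"))
  jsonlite::write_json(
    list(breakpoints = std$breakpoints, land_uses = std$land_uses,
         thresholds = unname(split(std$thresholds, row(std$thresholds)))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' The Chinese grade-II soil quality standard for cadmium
#'
#' The packaged composite standard for total Cd in soil: four pH intervals
#' (breakpoints 0, 5.5, 6.5, 7.5, 14) and three land-use types. Paddy field
#' thresholds are 0.25/0.30/0.50/1.00 mg/kg, dry farmland
#' 0.25/0.30/0.45/0.80 mg/kg, and nonfarmland 10.00 mg/kg in every
#' interval.
#'
#' @return A [composite_standard()] with `S = 4` intervals.
#' @examples
#' lookup_threshold(seqs_cd_china(), ph = 6.88, land_use = "paddy field")
#' @export
seqs_cd_china <- function() {
  parse_standard(system.file("extdata", "seqs_cd_china.json",
                             package = "cdrisk", mustWork = TRUE))
}

#' pH interval ordinal under a composite standard
#'
#' @param std a [composite_standard()].
#' @param ph numeric pH values in \[0, 14\].
#' @return Integer interval ordinals in `1..S`: the unique `i` with
#'   `breakpoints[i] <= ph < breakpoints[i + 1]` (last interval closed).
#' @export
interval_index <- function(std, ph) {
  stopifnot(inherits(std, "composite_standard"))
  ph <- as.numeric(ph)
  if (anyNA(ph) || any(ph < 0 | ph > 14))
    stop("pH values must lie in [0, 14]")
  findInterval(ph, std$breakpoints, rightmost.closed = TRUE)
}

#' Threshold applicable at a given pH and land use
#'
#' @param std a [composite_standard()].
#' @param ph numeric pH values in \[0, 14\].
#' @param land_use land-use name(s), recycled against `ph`.
#' @return Cd threshold(s) in mg/kg.
#' @examples
#' std <- seqs_cd_china()
#' lookup_threshold(std, 8.0, "dry farmland") # 0.80
#' @export
lookup_threshold <- function(std, ph, land_use) {
  stopifnot(inherits(std, "composite_standard"))
  lu <- match(as.character(land_use), std$land_uses)
  if (anyNA(lu))
    stop("unknown land use: ",
         paste(unique(land_use[is.na(lu)]), collapse = ", "))
  i <- interval_index(std, ph)
  n <- max(length(i), length(lu))
  std$thresholds[cbind(rep_len(lu, n), rep_len(i, n))]
}
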