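#' Fit a normal-score transform
#'
#' Rank-based Gaussian anamorphosis: the value of rank `r` among `n`
#' samples is paired with the standard-normal quantile of `(r - 0.5) / n`.
#' Tied values receive the average of their ranks' scores and collapse to
#' a single table knot, so both table columns are strictly increasing.
#'
#' Back-transformation interpolates linearly between knots. In the tails it
#' interpolates linearly from the outermost knot to a configurable bound
#' (default: sample minimum minus one SD, clamped at the anchor score
#' `qnorm(1e-4)`; symmetric above), and clamps beyond the anchors, so no
#' back-transformed value can escape `[lower, upper]`.
#'
#' @param s a [sample_set()] (or bare numeric vector) with `n >= 2` and at
#'   least two distinct values.
#' @param lower,upper tail bounds in original units; defaults
#'   `min - sd` and `max + sd` of the data.
#' @return A `normal_score_map` with knot table (`value`, `score`), tail
#'   bounds and anchor score.
#' @export
normal_score_fit <- function(s, lower = NULL, upper = NULL) {
  v <- if (inherits(s, "sample_set")) s$value else as.numeric(s)
  n <- length(v)
  stopifnot(n >= 2)
  if (diff(range(v)) == 0)
    stop("normal-score transform undefined: all sample values identical")
  ord <- order(v)
  sc <- qnorm((seq_len(n) - 0.5) / n)
  vs <- v[ord]
  knot_value <- unique(vs)
  knot_score <- vapply(knot_value, function(u) mean(sc[vs == u]), numeric(1))
  sdv <- sd(v)
  if (is.null(lower)) lower <- min(v) - sdv
  if (is.null(upper)) upper <- max(v) + sdv
  stopifnot(lower <= min(v), upper >= max(v))
  structure(list(value = knot_value, score = knot_score,
                 lower = lower, upper = upper,
                 anchor = qnorm(1e-4)),
            class = "normal_score_map")
}

#' @export
print.normal_score_map <- function(x, ...) {
  cat(sprintf("normal_score_map: %d knots on [%.4g, %.4g], tails to [%.4g, %.4g]\n",
              length(x$value), min(x$value), max(x$value), x$lower, x$upper))
  invisible(x)
}

#' Forward normal-score transform
#'
#' Sample values sitting exactly on a table knot get that knot's score;
#' other values are interpolated linearly (tails toward the anchors).
#'
#' @param map a fitted [normal_score_fit()].
#' @param v values in original units.
#' @return Standard-normal scores.
#' @export
normal_score_transform <- function(map, v) {
  stopifnot(inherits(map, "normal_score_map"))
  xs <- c(map$lower, map$value, map$upper)
  ys <- c(map$anchor, map$score, -map$anchor)
  out <- approx(xs, ys, xout = pmin(pmax(v, map$lower), map$upper),
                ties = "ordered")$y
  hit <- match(v, map$value)
  out[!is.na(hit)] <- map$score[hit[!is.na(hit)]]
  out
}

#' Back-transform normal scores to original units
#'
#' Exact at table knots (a score equal to a knot score returns that knot's
#' value bit-for-bit); linear between knots; linear to the configured
#' bounds between the outermost knots and the anchor scores; clamped at
#' the bounds beyond.
#'
#' @param map a fitted [normal_score_fit()].
#' @param scores standard-normal scores.
#' @return Values in original units, inside `[map$lower, map$upper]`.
#' @export
normal_score_back_transform <- function(map, scores) {
  stopifnot(inherits(map, "normal_score_map"))
  xs <- c(map$anchor, map$score, -map$anchor)
  ys <- c(map$lower, map$value, map$upper)
  out <- approx(xs, ys, xout = pmin(pmax(scores, map$anchor), -map$anchor),
                ties = "ordered")$y
  hit <- match(scores, map$score)
  out[!is.na(hit)] <- map$value[hit[!is.na(hit)]]
  out
}
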