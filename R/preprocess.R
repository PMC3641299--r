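# Stage-1 pre-processing of the 16-day composite cube:
# quality screening -> gap filling -> adaptive weighted Savitzky-Golay
# smoothing -> growing-season summation.

#' Default quality-flag weighting
#'
#' Pixel-reliability style mapping: flag 0 (good) keeps full weight, flag 1
#' (marginal) half weight, flags 2 and 3 (snow/ice, cloudy) weight 0, i.e.
#' treated as missing. Override by passing a named vector to
#' [screenQuality()].
#'
#' @return named numeric vector of weights indexed by flag value.
#' @export
defaultFlagWeights <- function() c(`0` = 1.0, `1` = 0.5, `2` = 0.0, `3` = 0.0)

#' Screen cube observations by quality flag
#'
#' Assigns a fit weight to every observation from its quality flag and
#' masks (sets to `NA`) observations whose weight is 0. Values, dates and
#' flags are otherwise unchanged.
#'
#' @param cube an [NDVICube-class].
#' @param flag_weights named numeric vector mapping flag value to weight in
#'   `[0, 1]`; every flag present in the cube must be covered.
#' @return the screened [NDVICube-class].
#' @export
screenQuality <- function(cube, flag_weights = defaultFlagWeights()) {
  flags <- sort(unique(as.vector(cube@quality)))
  unknown <- setdiff(as.character(flags), names(flag_weights))
  if (length(unknown))
    stop("no weight defined for quality flag(s): ",
         paste(unknown, collapse = ", "))
  w <- flag_weights[as.character(cube@quality)]
  weights <- array(as.numeric(w), dim(cube@quality))
  values <- cube@values
  values[weights == 0] <- NA_real_
  ndviCube(cube@spec, cube@dates, values, cube@quality, weights)
}

#' Fill gaps in one dated series by linear interpolation
#'
#' Interior gaps are replaced by linear interpolation in time between the
#' flanking valid observations; leading and trailing gaps are held at the
#' nearest valid value (never extrapolated). Filled entries receive the
#' configured minimum positive weight so they have little influence on the
#' subsequent smoothing.
#'
#' @param values numeric series; `NA` marks a missing observation.
#' @param times numeric or `Date` observation times (equal length).
#' @param weights per-point weights (0 at missing points).
#' @param min_weight weight assigned to filled entries (default 0.5).
#' @return list with `values`, `weights` and `usable`; `usable` is `FALSE`
#'   when fewer than 2 valid observations exist, in which case the series
#'   must be masked downstream.
#' @export
fillGapsLinear <- function(values, times = seq_along(values),
                           weights = as.numeric(!is.na(values)),
                           min_weight = 0.5) {
  tt <- as.numeric(times)
  miss <- is.na(values) | weights == 0
  if (sum(!miss) < 2L)
    return(list(values = values, weights = weights, usable = FALSE))
  if (!any(miss))
    return(list(values = values, weights = weights, usable = TRUE))
  filled <- approx(tt[!miss], values[!miss], xout = tt, rule = 2)$y
  values[miss] <- filled[miss]
  weights[miss] <- min_weight
  list(values = values, weights = weights, usable = TRUE)
}

#' Fill gaps across a screened cube
#'
#' Applies [fillGapsLinear()] to every pixel. Pixels with fewer than 2
#' valid observations are flagged unusable: their full series is set to
#' `NA` and masked in all downstream grids.
#'
#' @param cube a screened [NDVICube-class].
#' @param min_weight weight for filled entries; defaults to the smallest
#'   positive weight occurring in the cube.
#' @return list with `cube` (gap-filled) and `unusable` (logical matrix).
#' @export
fillGaps <- function(cube, min_weight = NULL) {
  w <- cube@weights
  if (is.null(min_weight)) {
    pos <- w[w > 0]
    min_weight <- if (length(pos)) min(pos) else 0.5
  }
  vals <- cube@values
  nr <- cube@spec@nRows; nc <- cube@spec@nCols
  unusable <- matrix(FALSE, nr, nc)
  tt <- as.numeric(cube@dates)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- vals[, i, j]
    if (!anyNA(v) && all(w[, i, j] > 0)) next
    f <- fillGapsLinear(v, tt, w[, i, j], min_weight)
    if (!f$usable) {
      vals[, i, j] <- NA_real_
      w[, i, j] <- 0
      unusable[i, j] <- TRUE
    } else {
      vals[, i, j] <- f$values
      w[, i, j] <- f$weights
    }
  }
  list(cube = ndviCube(cube@spec, cube@dates, vals, cube@quality, w),
       unusable = unusable)
}

#' Adaptive weighted Savitzky-Golay smoothing of one series
#'
#' Each point is replaced by the value at its own position of a weighted
#' least-squares polynomial of degree `poly_order` fitted over a window of
#' `2 * half_window + 1` points (truncated at the series ends). With
#' `envelope_iters > 0`, points lying below the current fit have their
#' weights multiplied by `weight_decay` and the fit is repeated, adapting
#' the curve to the upper envelope of the observations (cloud and snow
#' artefacts bias the index downward, so the envelope is the physically
#' plausible side).
#'
#' @param values complete numeric series (gap-filled, no `NA`).
#' @param weights per-point weights in `[0, 1]`.
#' @param half_window window half-width in points (default 4).
#' @param poly_order polynomial degree (default 2).
#' @param envelope_iters number of envelope-adaptation iterations
#'   (default 2; 0 gives the plain linear filter).
#' @param weight_decay factor applied to below-fit weights per iteration
#'   (default 0.5).
#' @return smoothed numeric series of the same length.
#' @export
savgolAdaptive <- function(values, weights = rep(1, length(values)),
                           half_window = 4L, poly_order = 2L,
                           envelope_iters = 2L, weight_decay = 0.5) {
  if (anyNA(values)) stop("series must be gap-filled (no NA) before smoothing")
  res <- .sg_adaptive_cpp(cbind(as.numeric(values)),
                          cbind(as.numeric(weights)),
                          as.integer(half_window), as.integer(poly_order),
                          as.integer(envelope_iters), weight_decay)
  if (res$degenerate > 0)
    warning(res$degenerate,
            " window(s) had all-zero weights; unweighted fit used")
  as.numeric(res$values)
}

#' Smooth every pixel of a gap-filled cube
#'
#' @param cube gap-filled [NDVICube-class] (unusable pixels all-`NA`).
#' @inheritParams savgolAdaptive
#' @return the smoothed [NDVICube-class]; unusable pixels stay `NA`.
#' @export
smoothCube <- function(cube, half_window = 4L, poly_order = 2L,
                       envelope_iters = 2L, weight_decay = 0.5) {
  d <- dim(cube@values)
  vmat <- matrix(cube@values, d[1L], d[2L] * d[3L])
  wmat <- matrix(cube@weights, d[1L], d[2L] * d[3L])
  ok <- !colSums(is.na(vmat))
  out <- vmat
  if (any(ok)) {
    res <- .sg_adaptive_cpp(vmat[, ok, drop = FALSE],
                            wmat[, ok, drop = FALSE],
                            as.integer(half_window), as.integer(poly_order),
                            as.integer(envelope_iters), weight_decay)
    if (res$degenerate > 0)
      warning(res$degenerate,
              " window(s) had all-zero weights; unweighted fit used")
    out[, ok] <- res$values
  }
  ndviCube(cube@spec, cube@dates, array(out, d), cube@quality, cube@weights)
}

#' Growing-season window
#'
#' @param start,end inclusive month-day bounds (`"MM-DD"`); defaults
#'   April 1 to October 31, the crop-growing season in the irrigated
#'   drylands this package targets.
#' @return list of class `seasonWindow`.
#' @export
seasonWindow <- function(start = "04-01", end = "10-31") {
  stopifnot(grepl("^\\d{2}-\\d{2}$", start), grepl("^\\d{2}-\\d{2}$", end))
  if (start >= end) stop("season start must precede end within the year")
  structure(list(start = start, end = end), class = "seasonWindow")
}

.in_season <- function(dates, window) {
  md <- format(as.Date(dates), "%m-%d")
  md >= window$start & md <= window$end
}

#' Sum smoothed composites over the growing season
#'
#' Per pixel and year, the seasonal sum is the plain sum of smoothed values
#' of composites whose *start date* falls inside the season window (16-day
#' composites straddle months, so membership is decided by the start date).
#' Pixels that were unusable at the gap-filling stage stay masked.
#'
#' @param cube smoothed [NDVICube-class].
#' @param window a [seasonWindow()].
#' @param years integer years to include; default all years present.
#' @return an [AnnualSumStack-class].
#' @export
seasonalSum <- function(cube, window = seasonWindow(), years = NULL) {
  yr <- as.integer(format(cube@dates, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  years <- as.integer(years)
  inwin <- .in_season(cube@dates, window)
  missing_years <- years[vapply(years, function(y)
    !any(inwin & yr == y), TRUE)]
  if (length(missing_years))
    stop("no in-season composites for year(s): ",
         paste(missing_years, collapse = ", "))
  d <- dim(cube@values)
  out <- array(NA_real_, c(length(years), d[2L], d[3L]))
  for (k in seq_along(years)) {
    idx <- which(inwin & yr == years[k])
    out[k, , ] <- apply(cube@values[idx, , , drop = FALSE], c(2, 3), sum)
  }
  annualSumStack(cube@spec, years, out)
}
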