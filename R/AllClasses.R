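#' @import methods
#' @importFrom stats approx coef cov dist glm lm lm.fit optim pchisq
#'   pnorm pt quantile rbinom rnorm runif sd setNames var vcov binomial
#'   plogis qnorm logLik
#' @importFrom utils read.csv write.csv head
#' @useDynLib degrisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# GridSpec: geometry of a single-resolution raster layer.
# Origin is the map coordinate of the *top-left corner* of cell (1, 1);
# row index increases southward.  Cell centers sit at
#   x = originX + (j - 0.5) * cellSize,  y = originY - (i - 0.5) * cellSize.
# ---------------------------------------------------------------------------

#' Raster grid geometry
#'
#' A `GridSpec` fixes the geometry shared by every raster layer in an
#' analysis: grid dimensions, map coordinate of the top-left corner, square
#' cell size in metres, and an opaque coordinate-reference-system label that
#' is compared for equality only (no reprojection is ever attempted).
#'
#' @slot nRows,nCols integer grid dimensions (>= 1).
#' @slot originX,originY map coordinates (m) of the top-left corner.
#' @slot cellSize square cell edge length in metres (> 0).
#' @slot crs free-text CRS label, checked for equality across layers.
#'
#' @seealso [gridSpec()], [Grid-class], [validateStack()]
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer",
    originX = "numeric", originY = "numeric",
    cellSize = "numeric", crs = "character"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (!is.finite(object@originX) || !is.finite(object@originY))
    msg <- c(msg, "origin coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a raster grid geometry
#'
#' @param nRows,nCols grid dimensions.
#' @param originX,originY map coordinates (m) of the top-left grid corner.
#' @param cellSize square cell size in metres (default 250, the resolution
#'   of 16-day vegetation-index composites this package targets).
#' @param crs coordinate-system label (opaque; equality-checked only).
#' @return a [GridSpec-class] object.
#' @examples
#' gridSpec(10, 10, cellSize = 250)
#' @export
gridSpec <- function(nRows, nCols, originX = 0, originY = nRows * cellSize,
                     cellSize = 250, crs = "local") {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    originX = as.numeric(originX), originY = as.numeric(originY),
    cellSize = as.numeric(cellSize), crs = as.character(crs)
  )
}

#' Cell-center coordinates of a grid
#'
#' @param spec a [GridSpec-class].
#' @return list with `x` (length `nCols`) and `y` (length `nRows`) center
#'   coordinates; `y` decreases with row index.
#' @export
cellCenters <- function(spec) {
  list(
    x = spec@originX + (seq_len(spec@nCols) - 0.5) * spec@cellSize,
    y = spec@originY - (seq_len(spec@nRows) - 0.5) * spec@cellSize
  )
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g m, origin (%g, %g), crs \"%s\"\n",
    object@nRows, object@nCols, object@cellSize,
    object@originX, object@originY, object@crs
  ))
})

# ---------------------------------------------------------------------------
# Grid: one raster layer = geometry + values + nodata mask.
# ---------------------------------------------------------------------------

#' Single raster layer with nodata mask
#'
#' The universal spatial carrier of the package: a numeric matrix aligned to
#' a [GridSpec-class] plus a logical nodata mask. Masked cells are excluded
#' from every statistic. Values at masked cells are stored as `NA`.
#'
#' @slot spec the grid geometry.
#' @slot values numeric matrix (`nRows` x `nCols`).
#' @slot mask logical matrix, `TRUE` where the cell holds no data.
#' @seealso [newGrid()], [readRaster()], [writeRaster()]
#' @export
setClass("Grid",
  representation(spec = "GridSpec", values = "matrix", mask = "matrix")
)

setValidity("Grid", function(object) {
  d <- c(object@spec@nRows, object@spec@nCols)
  if (!identical(dim(object@values), as.integer(d)))
    return("values dimensions do not match spec")
  if (!identical(dim(object@mask), as.integer(d)))
    return("mask dimensions do not match spec")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (any(is.na(object@mask)))
    return("mask must not contain NA")
  TRUE
})

#' Construct a Grid
#'
#' @param spec a [GridSpec-class].
#' @param values numeric matrix or single number (recycled).
#' @param mask logical matrix of nodata cells; defaults to `is.na(values)`.
#' @return a [Grid-class]; values at masked cells are set to `NA`.
#' @examples
#' g <- newGrid(gridSpec(3, 3), 1)
#' gridValues(g)
#' @export
newGrid <- function(spec, values, mask = NULL) {
  v <- matrix(as.numeric(values), spec@nRows, spec@nCols)
  if (is.null(mask)) mask <- is.na(v)
  m <- matrix(as.logical(mask), spec@nRows, spec@nCols)
  v[m] <- NA_real_
  new("Grid", spec = spec, values = v, mask = m)
}

#' @describeIn newGrid values matrix accessor (masked cells are `NA`).
#' @param x a `Grid`.
#' @export
gridValues <- function(x) x@values

#' @describeIn newGrid nodata mask accessor (`TRUE` = nodata).
#' @export
gridMask <- function(x) x@mask

#' @describeIn newGrid geometry accessor.
#' @export
gridGeometry <- function(x) x@spec

setMethod("show", "Grid", function(object) {
  v <- object@values[!object@mask]
  cat(sprintf(
    "Grid %d x %d (%g m cells), %d/%d cells masked\n",
    object@spec@nRows, object@spec@nCols, object@spec@cellSize,
    sum(object@mask), length(object@mask)
  ))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
})

# ---------------------------------------------------------------------------
# NDVICube: dated stack of vegetation-index grids with quality weights.
# ---------------------------------------------------------------------------

#' Dated vegetation-index cube with quality weights
#'
#' Holds a stack of 16-day composite layers: index values in `[-1, 1]`,
#' integer quality flags, and derived weights in `[0, 1]`. Weight 0 marks an
#' observation treated as missing (its value is `NA` after screening).
#'
#' @slot spec shared [GridSpec-class].
#' @slot dates strictly increasing composite start dates.
#' @slot values 3-D array `(time, row, col)` of index values.
#' @slot quality 3-D integer array of per-observation quality flags.
#' @slot weights 3-D array of fit weights in `[0, 1]`.
#' @seealso [screenQuality()], [fillGaps()], [smoothCube()], [seasonalSum()]
#' @export
setClass("NDVICube",
  representation(
    spec = "GridSpec", dates = "Date",
    values = "array", quality = "array", weights = "array"
  )
)

setValidity("NDVICube", function(object) {
  msg <- character()
  dv <- dim(object@values)
  if (length(dv) != 3L) msg <- c(msg, "values must be a 3-D array")
  if (length(object@dates) != dv[1L])
    msg <- c(msg, "length(dates) must equal dim(values)[1]")
  if (is.unsorted(object@dates, strictly = TRUE))
    msg <- c(msg, "dates must be strictly increasing")
  if (!identical(dim(object@quality), dv))
    msg <- c(msg, "quality shape must match values")
  if (!identical(dim(object@weights), dv))
    msg <- c(msg, "weights shape must match values")
  if (length(dv) == 3L &&
      !identical(dv[2:3], c(object@spec@nRows, object@spec@nCols)))
    msg <- c(msg, "spatial dimensions must match spec")
  w <- object@weights
  if (any(w < 0 | w > 1, na.rm = TRUE))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an NDVICube
#'
#' @param spec [GridSpec-class] shared by all layers.
#' @param dates composite start dates (coerced to `Date`), strictly
#'   increasing.
#' @param values 3-D array `(time, row, col)`.
#' @param quality integer flag array of the same shape (default all 0 =
#'   best quality).
#' @param weights weight array of the same shape (default all 1).
#' @return an [NDVICube-class].
#' @export
ndviCube <- function(spec, dates, values, quality = NULL, weights = NULL) {
  dates <- as.Date(dates)
  if (is.null(quality))
    quality <- array(0L, dim(values))
  if (is.null(weights))
    weights <- array(1, dim(values))
  new("NDVICube",
    spec = spec, dates = dates, values = values,
    quality = quality, weights = weights
  )
}

#' @describeIn ndviCube composite start dates.
#' @param x an `NDVICube`.
#' @export
cubeDates <- function(x) x@dates

#' @describeIn ndviCube 3-D value array `(time, row, col)`.
#' @export
cubeValues <- function(x) x@values

#' @describeIn ndviCube 3-D weight array.
#' @export
cubeWeights <- function(x) x@weights

setMethod("show", "NDVICube", function(object) {
  cat(sprintf(
    "NDVICube: %d composites (%s .. %s) on %d x %d grid\n",
    length(object@dates), min(object@dates), max(object@dates),
    object@spec@nRows, object@spec@nCols
  ))
  cat(sprintf("  zero-weight observations: %.1f%%\n",
              100 * mean(object@weights == 0)))
})

# ---------------------------------------------------------------------------
# AnnualSumStack: one seasonal-sum layer per year.
# ---------------------------------------------------------------------------

#' Annual growing-season sum stack
#'
#' One layer per year holding the seasonal sum of the smoothed vegetation
#' index over the configured growing-season window; the regressand of the
#' per-pixel trend analysis.
#'
#' @slot spec shared [GridSpec-class].
#' @slot years ordered integer years.
#' @slot values 3-D array `(year, row, col)`; `NA` on masked cells.
#' @slot mask logical matrix; `TRUE` where a pixel is unusable (masked in
#'   any year).
#' @seealso [seasonalSum()], [fitPixelTrend()]
#' @export
setClass("AnnualSumStack",
  representation(
    spec = "GridSpec", years = "integer", values = "array", mask = "matrix"
  )
)

setValidity("AnnualSumStack", function(object) {
  dv <- dim(object@values)
  if (length(dv) != 3L) return("values must be 3-D (year, row, col)")
  if (length(object@years) != dv[1L])
    return("one layer per year required")
  if (is.unsorted(object@years, strictly = TRUE))
    return("years must be strictly increasing")
  if (!identical(dv[2:3], c(object@spec@nRows, object@spec@nCols)))
    return("spatial dimensions must match spec")
  TRUE
})

#' @rdname AnnualSumStack-class
#' @param spec,years,values,mask see slot descriptions.
#' @export
annualSumStack <- function(spec, years, values, mask = NULL) {
  if (is.null(mask))
    mask <- apply(is.na(values), c(2, 3), any)
  new("AnnualSumStack",
    spec = spec, years = as.integer(years), values = values, mask = mask
  )
}

#' @rdname AnnualSumStack-class
#' @param x an `AnnualSumStack`.
#' @export
stackYears <- function(x) x@years

#' @rdname AnnualSumStack-class
#' @export
stackValues <- function(x) x@values

setMethod("show", "AnnualSumStack", function(object) {
  cat(sprintf(
    "AnnualSumStack: years %d-%d on %d x %d grid, %d pixels masked\n",
    min(object@years), max(object@years),
    object@spec@nRows, object@spec@nCols, sum(object@mask)
  ))
})

# ---------------------------------------------------------------------------
# FactorStack: named, aligned predictor layers.
# ---------------------------------------------------------------------------

#' Aligned stack of predictor grids
#'
#' Named predictor layers (x1..x18 in the standard vocabulary) sharing one
#' [GridSpec-class], each tagged `"binary"` or `"continuous"`. The combined
#' mask is the union of the layer masks.
#'
#' @slot spec shared geometry.
#' @slot layers named list of value matrices (`NA` = masked).
#' @slot kinds named character vector, `"binary"` or `"continuous"`.
#' @seealso [assembleFactorStack()], [blockSample()], [riskDeciles()]
#' @export
setClass("FactorStack",
  representation(spec = "GridSpec", layers = "list", kinds = "character")
)

setValidity("FactorStack", function(object) {
  msg <- character()
  if (length(object@layers) == 0L) msg <- c(msg, "at least one layer required")
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    msg <- c(msg, "layers must be named")
  if (!identical(names(object@layers), names(object@kinds)))
    msg <- c(msg, "kinds must be named like layers")
  if (!all(object@kinds %in% c("binary", "continuous")))
    msg <- c(msg, "kinds must be 'binary' or 'continuous'")
  d <- c(object@spec@nRows, object@spec@nCols)
  for (nm in names(object@layers)) {
    lay <- object@layers[[nm]]
    if (!identical(dim(lay), as.integer(d))) {
      msg <- c(msg, sprintf("layer %s has wrong dimensions", nm))
      next
    }
    if (identical(unname(object@kinds[nm]), "binary")) {
      v <- lay[!is.na(lay)]
      if (length(v) && !all(v %in% c(0, 1)))
        msg <- c(msg, sprintf("binary layer %s has values outside {0,1}", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FactorStack-class
#' @param x a `FactorStack`.
#' @export
factorNames <- function(x) names(x@layers)

#' @rdname FactorStack-class
#' @param name layer name.
#' @export
factorLayer <- function(x, name) {
  if (!name %in% names(x@layers))
    stop("no factor layer named '", name, "'")
  x@layers[[name]]
}

#' @rdname FactorStack-class
#' @export
factorKinds <- function(x) x@kinds

#' @rdname FactorStack-class
#' @return `factorMask()`: logical matrix, `TRUE` where any layer is masked.
#' @export
factorMask <- function(x) {
  Reduce(`|`, lapply(x@layers, is.na))
}

setMethod("show", "FactorStack", function(object) {
  cat(sprintf(
    "FactorStack: %d layers on %d x %d grid\n",
    length(object@layers), object@spec@nRows, object@spec@nCols
  ))
  cat("  ", paste0(names(object@layers), " (",
                   substr(object@kinds, 1, 4), ")", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# VariogramModel (spherical only).
# ---------------------------------------------------------------------------

#' Spherical semivariogram model
#'
#' gamma(h) = nugget + psill * (1.5 h/r - 0.5 (h/r)^3) for 0 < h <= r and
#' nugget + psill beyond the range; gamma(0) = 0 so that kriging with zero
#' nugget interpolates exactly.
#'
#' @slot nugget,psill,range model parameters (all >= 0, range > 0).
#' @seealso [fitSphericalVariogram()], [krigeSpherical()]
#' @export
setClass("VariogramModel",
  representation(nugget = "numeric", psill = "numeric", range = "numeric")
)

setValidity("VariogramModel", function(object) {
  if (object@nugget < 0 || object@psill < 0 || object@range <= 0)
    return("nugget, psill must be >= 0 and range > 0")
  TRUE
})

#' @rdname VariogramModel-class
#' @param nugget,psill,range spherical model parameters.
#' @export
variogramModel <- function(nugget, psill, range) {
  new("VariogramModel",
    nugget = as.numeric(nugget), psill = as.numeric(psill),
    range = as.numeric(range)
  )
}

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "Spherical variogram: nugget %.4g, partial sill %.4g, range %.4g m\n",
    object@nugget, object@psill, object@range
  ))
})

# ---------------------------------------------------------------------------
# TrendResult: per-pixel trend statistics + class map.
# ---------------------------------------------------------------------------

#' Per-pixel trend analysis result
#'
#' Slope and intercept of the ordinary-least-squares regression of the
#' annual seasonal sum on the year index, the t statistic and two-sided p
#' value of the slope, and (after [classifyTrend()]) the four-class trend
#' map: 1 = high negative, 2 = medium negative, 3 = low negative,
#' 4 = other (non-negative) slope.
#'
#' @slot slope,intercept,tStat,pValue [Grid-class] layers.
#' @slot classMap [Grid-class] of class codes 1-4 (`NA` until classified).
#' @seealso [fitPixelTrend()], [classifyTrend()], [binarizeDegraded()]
#' @export
setClass("TrendResult",
  representation(
    slope = "Grid", intercept = "Grid", tStat = "Grid",
    pValue = "Grid", classMap = "Grid"
  )
)

#' @rdname TrendResult-class
#' @param x a `TrendResult`.
#' @param what one of `"slope"`, `"intercept"`, `"t"`, `"p"`, `"class"`.
#' @export
trendLayer <- function(x, what = c("slope", "intercept", "t", "p", "class")) {
  switch(match.arg(what),
    slope = x@slope, intercept = x@intercept,
    t = x@tStat, p = x@pValue, class = x@classMap
  )
}

setMethod("show", "TrendResult", function(object) {
  s <- object@slope@values[!object@slope@mask]
  cat(sprintf(
    "TrendResult on %d x %d grid: slope mean %.4g (%.1f%% negative)\n",
    object@slope@spec@nRows, object@slope@spec@nCols,
    mean(s), 100 * mean(s < 0)
  ))
  cl <- object@classMap@values[!object@classMap@mask]
  if (length(cl) && !all(is.na(cl))) {
    tb <- table(factor(cl, levels = 1:4,
                       labels = c("high-neg", "med-neg", "low-neg", "other")))
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})
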