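# Predictor-layer construction: distance grids, line densities, land-use
# flags, district-level surfaces, and assembly of the aligned factor stack.

#' Euclidean distance to the nearest target cell
#'
#' Exact center-to-center distance from every cell to the nearest cell with
#' value 1 in the presence grid; target cells get 0. The input's nodata
#' mask is preserved (distances are still computed for masked cells'
#' positions but reported as `NA`).
#'
#' @param targets presence [Grid-class] (1 = target).
#' @return [Grid-class] of distances in metres.
#' @export
euclideanDistance <- function(targets) {
  spec <- targets@spec
  tv <- targets@values
  sel <- !is.na(tv) & tv == 1
  if (!any(sel)) stop("no target cells in presence grid")
  ctr <- cellCenters(spec)
  idx <- which(sel, arr.ind = TRUE)
  tx <- ctr$x[idx[, 2]]
  ty <- ctr$y[idx[, 1]]
  out <- matrix(NA_real_, spec@nRows, spec@nCols)
  # chunk rows so the cells x targets distance matrix stays small
  chunk <- max(1L, as.integer(2e6 / max(length(tx), 1L) / spec@nCols))
  for (i0 in seq(1L, spec@nRows, by = chunk)) {
    rows <- i0:min(spec@nRows, i0 + chunk - 1L)
    cx <- rep(ctr$x, times = length(rows))
    cy <- rep(ctr$y[rows], each = spec@nCols)
    d2 <- outer(cx, tx, function(a, b) (a - b)^2) +
          outer(cy, ty, function(a, b) (a - b)^2)
    dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
    out[rows, ] <- matrix(dmin, length(rows), spec@nCols, byrow = TRUE)
  }
  out[targets@mask] <- NA_real_
  newGrid(spec, out, targets@mask)
}

#' Polyline density grid
#'
#' Per cell, the total polyline length clipped to the cell rectangle
#' divided by the cell area (m per square metre).
#'
#' @param lines feature set of line features in map units.
#' @param spec target [GridSpec-class].
#' @return [Grid-class] of densities; all zero for an empty line set.
#' @export
lineDensity <- function(lines, spec) {
  out <- matrix(0, spec@nRows, spec@nCols)
  for (f in lines) {
    if (f$type != "line") next
    for (part in f$parts) {
      n <- nrow(part)
      if (n < 2L) next
      for (s in seq_len(n - 1L)) {
        x1 <- part[s, 1]; y1 <- part[s, 2]
        x2 <- part[s + 1L, 1]; y2 <- part[s + 1L, 2]
        seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
        if (seglen == 0) next
        .visit_segment_cells(spec, x1, y1, x2, y2, function(i, j, r) {
          cl <- .clip_segment(x1, y1, x2, y2, r["xmin"], r["xmax"],
                              r["ymin"], r["ymax"])
          if (!is.null(cl))
            out[i, j] <<- out[i, j] + (cl[2] - cl[1]) * seglen
        })
      }
    }
  }
  newGrid(spec, out / spec@cellSize^2)
}

# ---------------------------------------------------------------------------
# Land-use series and derived binary flags.
# ---------------------------------------------------------------------------

#' Annual land-use class series
#'
#' Aligned integer class grids, one per year, with a designated set of
#' uncultivated/fallow class codes.
#'
#' @slot spec shared [GridSpec-class].
#' @slot years ordered integer years.
#' @slot values 3-D integer array `(year, row, col)` of class codes.
#' @slot fallowCodes class codes counted as uncultivated/fallow.
#' @seealso [lulcFlags()]
#' @export
setClass("LULCSeries",
  representation(spec = "GridSpec", years = "integer", values = "array",
                 fallowCodes = "numeric")
)

setValidity("LULCSeries", function(object) {
  dv <- dim(object@values)
  if (length(dv) != 3L) return("values must be 3-D (year, row, col)")
  if (length(object@years) != dv[1L]) return("one layer per year required")
  if (is.unsorted(object@years, strictly = TRUE))
    return("years must be strictly increasing")
  if (!identical(dv[2:3], c(object@spec@nRows, object@spec@nCols)))
    return("spatial dimensions must match spec")
  TRUE
})

#' @rdname LULCSeries-class
#' @param spec,years,values,fallowCodes see slots.
#' @export
lulcSeries <- function(spec, years, values, fallowCodes = 0) {
  new("LULCSeries", spec = spec, years = as.integer(years), values = values,
      fallowCodes = as.numeric(fallowCodes))
}

#' Land-use change and abandonment flags
#'
#' Derives the two land-use predictors from an annual class series:
#' `no_change` is 1 where one identical land-use class persists for at
#' least `min_years` *consecutive* years; `uncultivated` is 1 where the
#' cell carries a fallow/uncultivated code for at least `min_years` years
#' (in total by default, or consecutively with
#' `uncultivated_mode = "consecutive"`). Cells masked in any year are
#' masked in both outputs.
#'
#' @param series a [LULCSeries-class].
#' @param min_years persistence threshold in years (default 6).
#' @param uncultivated_mode `"total"` (default) or `"consecutive"`.
#' @return list with binary [Grid-class] layers `no_change` and
#'   `uncultivated`.
#' @export
lulcFlags <- function(series, min_years = 6L,
                      uncultivated_mode = c("total", "consecutive")) {
  uncultivated_mode <- match.arg(uncultivated_mode)
  ny <- length(series@years)
  if (ny < min_years)
    stop("series must span at least min_years (", min_years, ") years")
  d <- dim(series@values)
  V <- matrix(series@values, ny, d[2L] * d[3L])
  bad <- colSums(is.na(V)) > 0L

  # longest run of identical consecutive classes
  run <- rep(1, ncol(V)); best <- rep(1, ncol(V))
  if (ny > 1L) for (t in 2:ny) {
    same <- V[t, ] == V[t - 1L, ]
    same[is.na(same)] <- FALSE
    run <- ifelse(same, run + 1, 1)
    best <- pmax(best, run)
  }
  x1 <- as.numeric(best >= min_years)

  fal <- matrix(V %in% series@fallowCodes, ny, ncol(V))
  if (uncultivated_mode == "total") {
    x2 <- as.numeric(colSums(fal) >= min_years)
  } else {
    runf <- rep(0, ncol(V)); bestf <- rep(0, ncol(V))
    for (t in seq_len(ny)) {
      runf <- ifelse(fal[t, ], runf + 1, 0)
      bestf <- pmax(bestf, runf)
    }
    x2 <- as.numeric(bestf >= min_years)
  }
  x1[bad] <- NA_real_; x2[bad] <- NA_real_
  g <- function(v) newGrid(series@spec, matrix(v, d[2L], d[3L]))
  list(no_change = g(x1), uncultivated = g(x2))
}

#' Mean absolute consecutive-year difference
#'
#' The "average delta" summary of an annual series: the mean of the
#' absolute differences between consecutive years.
#'
#' @param series numeric annual series (length >= 2).
#' @return single number.
#' @examples
#' meanAbsDelta(c(10, 12, 9))  # (2 + 3) / 2 = 2.5
#' @export
meanAbsDelta <- function(series) {
  if (length(series) < 2L) stop("series must have at least 2 years")
  mean(abs(diff(as.numeric(series))))
}

#' Spread district-level values over a zone grid
#'
#' Each cell takes the value attached to its district. A district entry
#' may be a scalar, or an annual series which is summarised by
#' [meanAbsDelta()] (the water-use "average delta" convention).
#'
#' @param zones [Grid-class] of integer zone ids.
#' @param table named list or vector: names are zone ids, entries scalars
#'   or numeric series.
#' @return [Grid-class] of district values.
#' @export
districtLayer <- function(zones, table) {
  zv <- zones@values
  zids <- sort(unique(zv[!is.na(zv)]))
  missing_ids <- setdiff(as.character(zids), names(table))
  if (length(missing_ids))
    stop("no table entry for zone id(s): ",
         paste(missing_ids, collapse = ", "))
  val <- vapply(table, function(v)
    if (length(v) > 1L) meanAbsDelta(v) else as.numeric(v), numeric(1))
  out <- matrix(NA_real_, nrow(zv), ncol(zv))
  for (z in zids)
    out[!is.na(zv) & zv == z] <- val[[as.character(z)]]
  newGrid(zones@spec, out, mask = zones@mask)
}

# standard factor vocabulary: name -> kind
.FACTOR_KINDS <- c(
  x1 = "binary", x2 = "binary", x3 = "binary", x4 = "binary",
  x5 = "binary", x6 = "binary",
  x7 = "continuous", x8 = "continuous", x9 = "continuous",
  x10 = "continuous", x11 = "continuous", x12 = "continuous",
  x13 = "continuous", x14 = "continuous", x15 = "continuous",
  x16 = "continuous", x17 = "continuous", x18 = "continuous"
)

#' Assemble an aligned factor stack
#'
#' Expands a soil-fertility (bonitation) class grid into four binary dummy
#' layers (x3-x6, one per class I-IV), tags every layer binary or
#' continuous following the standard x1..x18 vocabulary (x1 land-use
#' no-change, x2 uncultivated, x3-x6 bonitation dummies, x7-x8 canal and
#' collector density, x9 district water-use delta, x10 slope, x11-x12
#' groundwater table and salinity, x13-x18 distances), verifies alignment
#' and value ranges, and applies the combined nodata mask (union of layer
#' masks) to every layer.
#'
#' @param layers named list of [Grid-class] layers (standard names x1,
#'   x2, x7..x18; any additional names keep their given order after the
#'   standard ones).
#' @param bonitation optional [Grid-class] of fertility classes 1-4,
#'   expanded into dummies x3..x6.
#' @param kinds optional named character vector overriding the default
#'   binary/continuous tags.
#' @return a [FactorStack-class].
#' @export
assembleFactorStack <- function(layers, bonitation = NULL, kinds = NULL) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  if (!is.null(bonitation)) {
    b <- bonitation@values
    bad <- b[!is.na(b)]
    if (length(bad) && !all(bad %in% 1:4))
      stop("bonitation classes must be 1-4")
    for (k in 1:4) {
      dummy <- ifelse(is.na(b), NA_real_, as.numeric(b == k))
      layers[[paste0("x", k + 2)]] <- newGrid(bonitation@spec, dummy)
    }
  }
  rep_ok <- validateStack(layers)
  if (!rep_ok$pass)
    stop("factor layers are not aligned: ",
         paste(rep_ok$mismatches, collapse = ", "))
  std <- intersect(names(.FACTOR_KINDS), names(layers))
  layers <- layers[c(std, setdiff(names(layers), std))]
  kind <- .FACTOR_KINDS[names(layers)]
  kind[is.na(kind)] <- "continuous"
  names(kind) <- names(layers)
  if (!is.null(kinds)) kind[names(kinds)] <- kinds
  mats <- lapply(layers, function(g) g@values)
  cmask <- Reduce(`|`, lapply(layers, function(g) g@mask))
  mats <- lapply(mats, function(m) { m[cmask] <- NA_real_; m })
  for (nm in names(mats)) {
    if (kind[[nm]] == "binary") {
      v <- mats[[nm]][!is.na(mats[[nm]])]
      if (length(v) && !all(v %in% c(0, 1)))
        stop("binary layer ", nm, " has values outside {0, 1}")
    }
  }
  new("FactorStack", spec = layers[[1L]]@spec, layers = mats, kinds = kind)
}
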