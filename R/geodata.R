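# Vector features, rasterization and stack alignment checks.
# Geometry is handled in map coordinates (metres) with exact segment-
# rectangle clipping (Liang-Barsky) and even-odd ray casting.

#' Construct vector features
#'
#' Lightweight vector-feature containers used for rasterization, distance
#' and density grids. A feature set is a list of features, each holding a
#' geometry type (`"line"`, `"polygon"` or `"point"`), one or more
#' coordinate parts (two-column `x,y` matrices; polygon parts are rings),
#' and a property list.
#'
#' @param coords two-column coordinate matrix (a polyline, one ring, or
#'   points).
#' @param props named list of feature properties (e.g. `zone` for zone
#'   rasterization).
#' @return a single feature; combine features with [featureSet()].
#' @seealso [readGeoJSON()], [rasterizeFeatures()], [lineDensity()]
#' @export
lineFeature <- function(coords, props = list()) {
  structure(list(type = "line", parts = list(.as_coords(coords)),
                 props = props), class = "geoFeature")
}

#' @rdname lineFeature
#' @param rings list of two-column ring matrices (first = outer ring).
#' @export
polygonFeature <- function(rings, props = list()) {
  if (is.matrix(rings)) rings <- list(rings)
  structure(list(type = "polygon", parts = lapply(rings, .as_coords),
                 props = props), class = "geoFeature")
}

#' @rdname lineFeature
#' @export
pointFeature <- function(coords, props = list()) {
  structure(list(type = "point", parts = list(.as_coords(coords)),
                 props = props), class = "geoFeature")
}

#' @rdname lineFeature
#' @param ... features built by [lineFeature()], [polygonFeature()] or
#'   [pointFeature()], or a single list of them.
#' @export
featureSet <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "geoFeature")) fs <- fs[[1L]]
  stopifnot(all(vapply(fs, inherits, TRUE, "geoFeature")))
  structure(fs, class = "geoFeatureSet")
}

.as_coords <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) < 2) stop("coordinates need x and y columns")
  m[, 1:2, drop = FALSE]
}

#' Read vector features from a GeoJSON file
#'
#' Supports Feature/FeatureCollection with (Multi)LineString, (Multi)Polygon
#' and (Multi)Point geometries. Coordinates are taken as planar map
#' coordinates in metres; no reprojection is performed.
#'
#' @param path path to a `.geojson`/`.json` file.
#' @return a feature set (see [featureSet()]).
#' @export
readGeoJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(js$type, "FeatureCollection")) js$features
           else if (identical(js$type, "Feature")) list(js)
           else list(list(type = "Feature", geometry = js, properties = NULL))
  out <- lapply(feats, function(f) {
    g <- f$geometry
    props <- if (is.null(f$properties)) list() else f$properties
    cm <- function(cc) do.call(rbind, lapply(cc, function(p)
      c(p[[1]], p[[2]])))
    switch(g$type,
      LineString = lineFeature(cm(g$coordinates), props),
      MultiLineString = structure(list(type = "line",
        parts = lapply(g$coordinates, cm), props = props),
        class = "geoFeature"),
      Polygon = polygonFeature(lapply(g$coordinates, cm), props),
      MultiPolygon = structure(list(type = "polygon",
        parts = unlist(lapply(g$coordinates, function(poly)
          lapply(poly, cm)), recursive = FALSE), props = props),
        class = "geoFeature"),
      Point = pointFeature(matrix(unlist(g$coordinates[1:2]), 1), props),
      MultiPoint = pointFeature(cm(g$coordinates), props),
      stop("unsupported GeoJSON geometry: ", g$type)
    )
  })
  featureSet(out)
}

#' Write vector features to a GeoJSON file
#'
#' @param features a feature set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(features, path) {
  tojson <- function(f) {
    cc <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    geom <- switch(f$type,
      line = if (length(f$parts) == 1L)
        list(type = "LineString", coordinates = cc(f$parts[[1L]]))
      else list(type = "MultiLineString", coordinates = lapply(f$parts, cc)),
      polygon = list(type = "Polygon", coordinates = lapply(f$parts, cc)),
      point = list(type = "Point",
                   coordinates = c(f$parts[[1L]][1, 1], f$parts[[1L]][1, 2]))
    )
    list(type = "Feature", geometry = geom,
         properties = if (length(f$props)) f$props else NULL)
  }
  obj <- list(type = "FeatureCollection", features = lapply(features, tojson))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# --- geometry primitives ----------------------------------------------------

# Liang-Barsky clip of segment (x1,y1)-(x2,y2) to closed rectangle.
# Returns c(t0, t1) clip parameters in [0,1], or NULL if disjoint.
.clip_segment <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  c(t0, t1)
}

# Even-odd point-in-polygon over a list of rings.
.point_in_rings <- function(px, py, rings) {
  inside <- FALSE
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2]; yj <- ring[j, 2]
      if ((yi > py) != (yj > py)) {
        xint <- ring[i, 1] + (py - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

.cell_range <- function(lo, hi, orig, cellSize, nmax, outward = TRUE) {
  # grid index range [i0, i1] of cells whose span may intersect [lo, hi]
  i0 <- max(1L, min(nmax, as.integer(floor((lo - orig) / cellSize)) + 1L))
  i1 <- max(1L, min(nmax, as.integer(ceiling((hi - orig) / cellSize))))
  if (i1 < i0) integer(0) else i0:i1
}

# cell rectangle bounds for row i, col j
.cell_rect <- function(spec, i, j) {
  x0 <- spec@originX + (j - 1) * spec@cellSize
  y1 <- spec@originY - (i - 1) * spec@cellSize
  c(xmin = x0, xmax = x0 + spec@cellSize, ymin = y1 - spec@cellSize, ymax = y1)
}

# visit each cell a segment may touch; fn(i, j, rect) on candidates
.visit_segment_cells <- function(spec, x1, y1, x2, y2, fn) {
  cols <- .cell_range(min(x1, x2), max(x1, x2), spec@originX, spec@cellSize,
                      spec@nCols)
  # rows count downward from originY
  ytop <- spec@originY
  rlo <- (ytop - max(y1, y2)) ; rhi <- (ytop - min(y1, y2))
  rows <- .cell_range(rlo, rhi, 0, spec@cellSize, spec@nRows)
  for (i in rows) for (j in cols) {
    r <- .cell_rect(spec, i, j)
    fn(i, j, r)
  }
}

#' Rasterize vector features onto a grid
#'
#' In `presence` mode a cell gets 1 if any feature intersects its closed
#' rectangle (lines and polygon boundaries by exact segment clipping;
#' polygon interiors and points by containment), else 0. In `zone` mode
#' cells take the integer id of the polygon containing their center (the
#' `zone` property if present, else the feature index); cells covered by no
#' polygon are masked.
#'
#' @param features a feature set (see [featureSet()]).
#' @param spec target [GridSpec-class].
#' @param mode `"presence"` or `"zone"`.
#' @return a [Grid-class]; zone grids carry integer ids >= 1.
#' @export
rasterizeFeatures <- function(features, spec, mode = c("presence", "zone")) {
  mode <- match.arg(mode)
  nr <- spec@nRows; nc <- spec@nCols
  if (mode == "presence") {
    out <- matrix(0, nr, nc)
    for (f in features) {
      if (f$type == "point") {
        for (part in f$parts) for (k in seq_len(nrow(part))) {
          j <- floor((part[k, 1] - spec@originX) / spec@cellSize) + 1
          i <- floor((spec@originY - part[k, 2]) / spec@cellSize) + 1
          if (i >= 1 && i <= nr && j >= 1 && j <= nc) out[i, j] <- 1
        }
        next
      }
      for (part in f$parts) {
        n <- nrow(part)
        segs <- if (f$type == "polygon") seq_len(n) else seq_len(n - 1L)
        for (s in segs) {
          s2 <- if (f$type == "polygon" && s == n) 1L else s + 1L
          .visit_segment_cells(spec, part[s, 1], part[s, 2],
                               part[s2, 1], part[s2, 2], function(i, j, r) {
            cl <- .clip_segment(part[s, 1], part[s, 2], part[s2, 1],
                                part[s2, 2], r["xmin"], r["xmax"],
                                r["ymin"], r["ymax"])
            if (!is.null(cl)) out[i, j] <<- 1
          })
        }
      }
      if (f$type == "polygon") {
        # interior coverage: cell centers inside the rings
        ctr <- cellCenters(spec)
        bb <- do.call(rbind, f$parts)
        cols <- .cell_range(min(bb[, 1]), max(bb[, 1]), spec@originX,
                            spec@cellSize, nc)
        rows <- .cell_range(spec@originY - max(bb[, 2]),
                            spec@originY - min(bb[, 2]), 0, spec@cellSize, nr)
        for (i in rows) for (j in cols)
          if (out[i, j] == 0 &&
              .point_in_rings(ctr$x[j], ctr$y[i], f$parts))
            out[i, j] <- 1
      }
    }
    return(newGrid(spec, out))
  }
  # zone mode
  out <- matrix(NA_real_, nr, nc)
  ctr <- cellCenters(spec)
  zid <- 0L
  for (f in features) {
    if (f$type != "polygon") stop("zone rasterization requires polygons")
    zid <- zid + 1L
    id <- if (!is.null(f$props$zone)) as.numeric(f$props$zone) else zid
    if (is.na(id) || id < 1) stop("zone ids must be >= 1")
    bb <- do.call(rbind, f$parts)
    cols <- .cell_range(min(bb[, 1]), max(bb[, 1]), spec@originX,
                        spec@cellSize, nc)
    rows <- .cell_range(spec@originY - max(bb[, 2]),
                        spec@originY - min(bb[, 2]), 0, spec@cellSize, nr)
    for (i in rows) for (j in cols)
      if (is.na(out[i, j]) && .point_in_rings(ctr$x[j], ctr$y[i], f$parts))
        out[i, j] <- id
  }
  newGrid(spec, out, is.na(out))
}

#' Check that raster layers share one geometry
#'
#' Compares the [GridSpec-class] of every input field-by-field. The result
#' object encodes success or the set of mismatching fields; no error is
#' thrown, so callers can report all problems at once.
#'
#' @param grids list of [Grid-class] objects (or objects with a `spec`
#'   slot such as [NDVICube-class]).
#' @return list with elements `pass` (logical) and `mismatches` (character
#'   vector of differing field names), class `"stackReport"`.
#' @export
validateStack <- function(grids) {
  if (length(grids) < 1L) stop("at least one grid required")
  specs <- lapply(grids, function(g) g@spec)
  ref <- specs[[1L]]
  fields <- c("nRows", "nCols", "originX", "originY", "cellSize", "crs")
  bad <- character()
  for (s in specs[-1L]) {
    for (f in fields) {
      if (!identical(slot(ref, f), slot(s, f))) bad <- c(bad, f)
    }
  }
  bad <- sort(unique(bad))
  structure(list(pass = length(bad) == 0L, mismatches = bad),
            class = "stackReport")
}

#' @export
print.stackReport <- function(x, ...) {
  if (x$pass) cat("stack OK: all layers share one grid geometry\n")
  else cat("stack MISMATCH in field(s):", paste(x$mismatches, collapse = ", "),
           "\n")
  invisible(x)
}

#' Read well observations from CSV
#'
#' @param path CSV file with header columns `x`, `y`, `value` (map
#'   coordinates in metres; value in measurement units, e.g. groundwater
#'   depth in m or salinity in g/l).
#' @return data frame of class `wellSet` with columns `x`, `y`, `value`.
#' @seealso [fitSphericalVariogram()], [krigeSpherical()]
#' @export
readWells <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y", "value") %in% names(df)))
    stop("wells CSV must have columns x, y, value")
  wellSet(df$x, df$y, df$value)
}

#' @rdname readWells
#' @param x,y,value well coordinates (m) and measured values.
#' @export
wellSet <- function(x, y, value) {
  stopifnot(length(x) == length(y), length(x) == length(value),
            length(x) >= 1L, all(is.finite(x)), all(is.finite(y)))
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       value = as.numeric(value)),
            class = c("wellSet", "data.frame"))
}

# average duplicated locations (exact coordinate ties)
.dedupe_wells <- function(wells) {
  key <- paste(wells$x, wells$y)
  if (!anyDuplicated(key)) return(wells)
  agg <- tapply(wells$value, key, mean)
  first <- !duplicated(key)
  out <- wells[first, ]
  out$value <- as.numeric(agg[paste(out$x, out$y)])
  out
}

#' Write a Grid as CSV of cell centers (x, y, value)
#'
#' @param grid a [Grid-class].
#' @param path output CSV path.
#' @param drop_masked omit masked cells (default TRUE).
#' @return `path`, invisibly.
#' @export
writeGridCSV <- function(grid, path, drop_masked = TRUE) {
  ctr <- cellCenters(grid@spec)
  df <- expand.grid(row = seq_len(grid@spec@nRows),
                    col = seq_len(grid@spec@nCols))
  df$x <- ctr$x[df$col]; df$y <- ctr$y[df$row]
  df$value <- grid@values[cbind(df$row, df$col)]
  if (drop_masked) df <- df[!grid@mask[cbind(df$row, df$col)], ]
  write.csv(df[, c("x", "y", "value")], path, row.names = FALSE)
  invisible(path)
}
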