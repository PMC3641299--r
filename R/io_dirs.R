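# On-disk layouts: an NDVI cube as a directory of per-date GeoTIFF pairs
# plus a CSV date table, a factor stack as named GeoTIFFs plus a manifest,
# and an annual-sum stack as per-year GeoTIFFs plus a year table.

#' Write an NDVI cube as a directory of per-date GeoTIFF pairs
#'
#' Layout: `dates.csv` (columns `date`, `index_path`, `quality_path`,
#' paths relative to the directory) plus one index and one quality
#' GeoTIFF per composite.
#'
#' @param cube an [NDVICube-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCubeDir <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- format(cube@dates, "%Y%j")
  ip <- sprintf("ndvi_%s.tif", tag)
  qp <- sprintf("qual_%s.tif", tag)
  for (k in seq_along(cube@dates)) {
    writeRaster(newGrid(cube@spec, cube@values[k, , ]),
                file.path(dir, ip[k]))
    writeRaster(newGrid(cube@spec, cube@quality[k, , ]),
                file.path(dir, qp[k]), datatype = "uint8")
  }
  write.csv(data.frame(date = as.character(cube@dates), index_path = ip,
                       quality_path = qp),
            file.path(dir, "dates.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an NDVI cube directory
#'
#' @param dir directory written by [writeCubeDir()] (or following its
#'   layout).
#' @return an [NDVICube-class] with unit weights (assign weights with
#'   [screenQuality()]).
#' @export
readCubeDir <- function(dir) {
  tab <- read.csv(file.path(dir, "dates.csv"))
  stopifnot(all(c("date", "index_path", "quality_path") %in% names(tab)))
  tab <- tab[order(as.Date(tab$date)), ]
  first <- readRaster(file.path(dir, tab$index_path[1]))
  nt <- nrow(tab)
  vals <- array(NA_real_, c(nt, first@spec@nRows, first@spec@nCols))
  qual <- array(0L, dim(vals))
  for (k in seq_len(nt)) {
    g <- readRaster(file.path(dir, tab$index_path[k]))
    q <- readRaster(file.path(dir, tab$quality_path[k]))
    rep_ok <- validateStack(list(first, g, q))
    if (!rep_ok$pass)
      stop("cube layer ", tab$index_path[k], " misaligned: ",
           paste(rep_ok$mismatches, collapse = ", "))
    vals[k, , ] <- g@values
    qual[k, , ] <- q@values
  }
  ndviCube(first@spec, as.Date(tab$date), vals, qual)
}

#' Write a factor stack as named GeoTIFFs plus a manifest
#'
#' @param stack a [FactorStack-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeFactorDir <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- factorNames(stack)
  paths <- sprintf("%s.tif", nms)
  for (k in seq_along(nms)) {
    g <- newGrid(stack@spec, stack@layers[[nms[k]]])
    if (stack@kinds[[nms[k]]] == "binary")
      writeRaster(g, file.path(dir, paths[k]), datatype = "uint8",
                  nodata = 255)
    else writeRaster(g, file.path(dir, paths[k]))
  }
  write.csv(data.frame(name = nms, kind = unname(stack@kinds[nms]),
                       path = paths),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a factor stack directory
#'
#' @param dir directory written by [writeFactorDir()].
#' @return a [FactorStack-class].
#' @export
readFactorDir <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  stopifnot(all(c("name", "kind", "path") %in% names(man)))
  layers <- lapply(seq_len(nrow(man)), function(k)
    readRaster(file.path(dir, man$path[k])))
  names(layers) <- man$name
  kinds <- setNames(man$kind, man$name)
  assembleFactorStack(layers, kinds = kinds)
}

#' Write an annual-sum stack as per-year GeoTIFFs
#'
#' @param stack an [AnnualSumStack-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSumStackDir <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("sum_%d.tif", stack@years)
  for (k in seq_along(stack@years))
    writeRaster(newGrid(stack@spec, stack@values[k, , ]),
                file.path(dir, paths[k]))
  write.csv(data.frame(year = stack@years, path = paths),
            file.path(dir, "years.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an annual-sum stack directory
#'
#' @param dir directory written by [writeSumStackDir()].
#' @return an [AnnualSumStack-class].
#' @export
readSumStackDir <- function(dir) {
  tab <- read.csv(file.path(dir, "years.csv"))
  tab <- tab[order(tab$year), ]
  first <- readRaster(file.path(dir, tab$path[1]))
  vals <- array(NA_real_, c(nrow(tab), first@spec@nRows, first@spec@nCols))
  for (k in seq_len(nrow(tab)))
    vals[k, , ] <- readRaster(file.path(dir, tab$path[k]))@values
  annualSumStack(first@spec, tab$year, vals)
}

#' Read a land-use series directory
#'
#' @param dir directory with `years.csv` (columns `year`, `path`,
#'   `fallow_codes` with codes separated by `;`) and per-year class
#'   GeoTIFFs.
#' @return a [LULCSeries-class].
#' @export
readLulcDir <- function(dir) {
  tab <- read.csv(file.path(dir, "years.csv"))
  tab <- tab[order(tab$year), ]
  first <- readRaster(file.path(dir, tab$path[1]))
  vals <- array(NA_real_, c(nrow(tab), first@spec@nRows, first@spec@nCols))
  for (k in seq_len(nrow(tab)))
    vals[k, , ] <- readRaster(file.path(dir, tab$path[k]))@values
  codes <- as.numeric(strsplit(as.character(tab$fallow_codes[1]), ";")[[1]])
  lulcSeries(first@spec, tab$year, vals, fallowCodes = codes)
}
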