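# Minimal GeoTIFF I/O: uncompressed, single-plane rasters with
# ModelPixelScale / ModelTiepoint / GDAL_NODATA / GeoASCII tags.
# Reads both byte orders, multi-strip files and pixel-interleaved bands;
# writes little-endian single-strip files.

.TIFF_TYPESIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                    `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

.read_tiff_values <- function(raw, type, count, endian) {
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
    `1` = readBin(con, "integer", count, size = 1, signed = FALSE),
    `2` = rawToChar(raw[raw != as.raw(0)]),
    `3` = readBin(con, "integer", count, size = 2, signed = FALSE,
                  endian = endian),
    `4` = { # LONG is unsigned 32-bit; assemble as double from bytes
      b <- matrix(as.numeric(raw[seq_len(4L * count)]), nrow = 4)
      if (endian == "little") colSums(b * 256^(0:3)) else
        colSums(b * 256^(3:0))
    },
    `6` = readBin(con, "integer", count, size = 1, signed = TRUE),
    `8` = readBin(con, "integer", count, size = 2, signed = TRUE,
                  endian = endian),
    `9` = readBin(con, "integer", count, size = 4, endian = endian),
    `11` = readBin(con, "numeric", count, size = 4, endian = endian),
    `12` = readBin(con, "numeric", count, size = 8, endian = endian),
    stop("unsupported TIFF field type ", type)
  )
}

.read_tiff_tags <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  u16 <- function(off) {
    v <- as.integer(raw[off + 1:2])
    if (endian == "little") v[1] + 256L * v[2] else v[2] + 256L * v[1]
  }
  u32 <- function(off) {
    v <- as.numeric(raw[off + 1:4])
    if (endian == "little") sum(v * 256^(0:3)) else sum(v * 256^(3:0))
  }
  if (u16(2) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4)
  n <- u16(ifd)
  tags <- list()
  for (k in seq_len(n)) {
    e <- ifd + 2 + (k - 1) * 12
    code <- u16(e)
    type <- u16(e + 2)
    count <- u32(e + 4)
    tsize <- .TIFF_TYPESIZE[as.character(type)]
    if (is.na(tsize)) next
    nbytes <- tsize * count
    off <- if (nbytes <= 4) e + 8 else u32(e + 8)
    vals <- .read_tiff_values(raw[off + seq_len(nbytes)], type, count, endian)
    tags[[as.character(code)]] <- vals
  }
  list(tags = tags, raw = raw, endian = endian)
}

#' Read a GeoTIFF raster into a Grid
#'
#' Reads an uncompressed (Geo)TIFF. Grid geometry is taken from the
#' ModelPixelScale and ModelTiepoint tags; the declared nodata value (GDAL
#' convention) is mapped to the nodata mask. Square cells are required.
#'
#' @param path path to an existing `.tif` file.
#' @param band band to extract for pixel-interleaved multi-band files
#'   (default 1).
#' @return a [Grid-class].
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path, band = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- .read_tiff_tags(path)
  tags <- tf$tags
  need <- function(code, default = NULL) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", code, " missing in ", path)
      default
    } else v
  }
  width <- as.integer(need(256))
  height <- as.integer(need(257))
  bits <- as.integer(need(258, 32L))[1]
  if (need(259, 1) != 1) stop("compressed TIFFs are not supported: ", path)
  spp <- as.integer(need(277, 1L))
  if (band < 1 || band > spp)
    stop("requested band ", band, " but file has ", spp, " band(s)")
  sfmt <- as.integer(need(339, 1L))[1]
  offsets <- need(273)
  counts <- need(279)
  signed <- sfmt == 2L
  what <- if (sfmt == 3L) "numeric" else "integer"
  vals <- numeric(0)
  for (i in seq_along(offsets)) {
    seg <- tf$raw[offsets[i] + seq_len(counts[i])]
    con <- rawConnection(seg)
    nv <- counts[i] / (bits / 8)
    v <- readBin(con, what, n = nv, size = bits / 8,
                 signed = if (bits < 32) signed else TRUE,
                 endian = tf$endian)
    close(con)
    vals <- c(vals, as.numeric(v))
  }
  if (spp > 1L)
    vals <- vals[seq(band, length(vals), by = spp)]
  if (length(vals) != width * height)
    stop("pixel count mismatch reading ", path)
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  if (is.null(scale) || is.null(tie))
    stop("not a GeoTIFF (no geotransform tags): ", path)
  if (abs(scale[1] - scale[2]) > 1e-9 * max(abs(scale[1:2])))
    stop("non-square cells: pixel size ", scale[1], " x ", scale[2])
  originX <- tie[4] - tie[1] * scale[1]
  originY <- tie[5] + tie[2] * scale[2]
  crs <- tags[["34737"]]
  crs <- if (is.null(crs)) "unknown" else sub("\\|$", "", crs)
  spec <- gridSpec(height, width, originX, originY, scale[1], crs)

  nod <- tags[["42113"]]
  mask <- matrix(FALSE, height, width)
  if (!is.null(nod)) {
    nodval <- suppressWarnings(as.numeric(trimws(nod)))
    if (is.finite(nodval)) {
      tol <- max(1e-6 * abs(nodval), 1e-12)
      mask <- abs(m - nodval) <= tol
    }
  }
  mask <- mask | is.na(m)
  newGrid(spec, m, mask)
}

.tiff_entry <- function(code, type, count, value_or_offset) {
  # returns list(code, type, count, value bytes (4), extra raw, extra length)
  list(code = code, type = type, count = count, v = value_or_offset)
}

#' Write a Grid to a GeoTIFF file
#'
#' Writes an uncompressed little-endian single-strip GeoTIFF whose
#' geotransform reproduces the grid geometry. Masked cells are stored as the
#' declared nodata value.
#'
#' @param grid a [Grid-class].
#' @param path output path; the parent directory must exist.
#' @param datatype one of `"float64"` (default; lossless round-trip),
#'   `"float32"`, `"int16"`, `"uint8"`.
#' @param nodata nodata value recorded in the header (default -9999, or 255
#'   for `"uint8"`).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(grid, path,
                        datatype = c("float64", "float32", "int16", "uint8"),
                        nodata = NULL) {
  datatype <- match.arg(datatype)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  spec <- grid@spec
  if (is.null(nodata)) nodata <- if (datatype == "uint8") 255 else -9999
  v <- grid@values
  v[grid@mask | is.na(v)] <- nodata

  bits <- switch(datatype, float64 = 64L, float32 = 32L, int16 = 16L,
                 uint8 = 8L)
  sfmt <- switch(datatype, float64 = 3L, float32 = 3L, int16 = 2L, uint8 = 1L)
  npix <- spec@nRows * spec@nCols
  databytes <- npix * bits / 8

  crs_ascii <- paste0(spec@crs, "|")
  crs_raw <- c(charToRaw(crs_ascii), as.raw(0))
  nod_raw <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  geokeys <- c(1L, 1L, 0L, 2L,            # version, revision, minor, nkeys
               1024L, 0L, 1L, 1L,         # model type: projected
               1026L, 34737L, length(crs_raw), 0L)  # citation -> ascii tag

  entries <- list(
    list(256, 4, 1, spec@nCols),
    list(257, 4, 1, spec@nRows),
    list(258, 3, 1, bits),
    list(259, 3, 1, 1),
    list(262, 3, 1, 1),
    list(273, 4, 1, NA),   # strip offset, filled below
    list(277, 3, 1, 1),
    list(278, 4, 1, spec@nRows),
    list(279, 4, 1, databytes),
    list(284, 3, 1, 1),
    list(339, 3, 1, sfmt),
    list(33550, 12, 3, c(spec@cellSize, spec@cellSize, 0)),
    list(33922, 12, 6, c(0, 0, 0, spec@originX, spec@originY, 0)),
    list(34735, 3, length(geokeys), geokeys),
    list(34737, 2, length(crs_raw), crs_raw),
    list(42113, 2, length(nod_raw), nod_raw)
  )
  n <- length(entries)
  ifd_off <- 8
  ifd_len <- 2 + n * 12 + 4
  extra_off <- ifd_off + ifd_len
  # compute external storage for oversized values
  ext <- list(); cursor <- extra_off
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    size <- .TIFF_TYPESIZE[as.character(e[[2]])] * e[[3]]
    if (size > 4) {
      entries[[i]]$offset <- cursor
      cursor <- cursor + size
      if (cursor %% 2 == 1) cursor <- cursor + 1
    }
  }
  data_off <- cursor
  entries[[6]][[4]] <- data_off

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 2, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  for (e in entries) {
    w16(e[[1]]); w16(e[[2]]); w32(e[[3]])
    size <- .TIFF_TYPESIZE[as.character(e[[2]])] * e[[3]]
    if (size > 4) {
      w32(e$offset)
    } else {
      # inline value, left-justified in 4 bytes
      if (e[[2]] == 3) {
        vals <- c(as.integer(e[[4]]), 0L)[1:2]
        w16(vals[1]); w16(vals[2])
      } else if (e[[2]] == 2) {
        pad <- c(as.raw(e[[4]]), raw(4))[1:4]
        writeBin(pad, con)
      } else {
        w32(e[[4]])
      }
    }
  }
  w32(0)  # next IFD
  # external values
  pos <- extra_off
  for (e in entries) {
    size <- .TIFF_TYPESIZE[as.character(e[[2]])] * e[[3]]
    if (size <= 4) next
    if (e[[2]] == 12) {
      writeBin(as.numeric(e[[4]]), con, size = 8, endian = "little")
    } else if (e[[2]] == 3) {
      w16(e[[4]])
    } else if (e[[2]] == 2) {
      writeBin(as.raw(e[[4]]), con)
    }
    pos <- pos + size
    if (pos %% 2 == 1) { writeBin(raw(1), con); pos <- pos + 1 }
  }
  # pixel data, row-major from the top row
  vec <- as.vector(t(v))
  if (datatype %in% c("float64", "float32")) {
    writeBin(as.numeric(vec), con, size = bits / 8, endian = "little")
  } else {
    writeBin(as.integer(round(vec)), con, size = bits / 8, endian = "little")
  }
  invisible(path)
}
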