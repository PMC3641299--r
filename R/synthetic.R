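# Seeded synthetic study region with known ground truth: factor fields,
# logistic degradation labels, an NDVI cube with planted seasonal-sum
# declines, wells, land-use series and district zones.

#' Default true logistic coefficients for synthetic scenarios
#'
#' Headline effect sizes of the degradation model used as generating
#' truth: groundwater table depth (m) 1.46, uncultivated land 0.71,
#' terrain slope (%) 0.25, groundwater salinity (g/l) 0.23, land-use
#' no-change flag 0.14; intercept -3.55.
#'
#' @return list with `beta0` and named `beta`.
#' @export
defaultTrueBeta <- function() {
  list(beta0 = -3.55,
       beta = c(x11 = 1.46, x2 = 0.71, x10 = 0.25, x12 = 0.23, x1 = 0.14))
}

#' Synthetic scenario configuration
#'
#' All knobs of the artificial study region. Defaults emulate an 11-year
#' series of 23 yearly 16-day composites on a 120 x 120 grid of 250 m
#' cells with an April-October growing season (13 in-season composites).
#'
#' @param n_rows,n_cols grid size (default 120 x 120).
#' @param cell_size cell edge (m, default 250).
#' @param years calendar years of the series (default 2000:2010).
#' @param composites_per_year 16-day composites per year (default 23).
#' @param season_start,season_end season window month-days.
#' @param baseline bare-soil NDVI floor outside the vegetation pulse
#'   (default 0.12).
#' @param amplitude first-year amplitude of the seasonal pulse
#'   (default 0.62; peak NDVI = baseline + amplitude).
#' @param slope_degraded,slope_stable seasonal-sum trend ranges
#'   (sum-NDVI per year) for degraded and stable cells; defaults
#'   `c(-0.24, -0.08)` and `c(0, 0.04)` (stable land greens slightly, as
#'   irrigated cropland under constant management does).
#' @param noise_sd per-composite observation noise (NDVI, default 0.05).
#' @param missing_rate fraction of observations flagged unusable
#'   (default 0.05).
#' @param low_quality_rate fraction flagged marginal quality, which also
#'   receive a negative cloud-style value depression (default 0.10).
#' @param lowq_depression range of that depression (default
#'   `c(-0.2, 0)`).
#' @param blur_groundwater,blur_salinity,blur_slope,blur_fertility,blur_landuse
#'   Gaussian-blur radii (cells) of the latent fields.
#' @param range_groundwater,range_salinity,range_slope value ranges the
#'   latent fields are rescaled to: groundwater table depth 0.8-2.5 m,
#'   salinity 0.5-4 g/l, terrain slope 0-3 %.
#' @param beta0,beta true logistic intercept and named coefficients
#'   (defaults from [defaultTrueBeta()]).
#' @param wells_n number of groundwater observation wells (default 500).
#' @param wells_noise_sd well measurement noise (m, default 0.05).
#' @param n_districts number of district zones (default 10).
#' @param seed master seed; every stochastic step derives from it.
#' @return list of class `scenarioConfig`.
#' @export
scenarioConfig <- function(n_rows = 120L, n_cols = 120L, cell_size = 250,
                           years = 2000:2010, composites_per_year = 23L,
                           season_start = "04-01", season_end = "10-31",
                           baseline = 0.12, amplitude = 0.62,
                           slope_degraded = c(-0.24, -0.08),
                           slope_stable = c(0, 0.04),
                           noise_sd = 0.05, missing_rate = 0.05,
                           low_quality_rate = 0.10,
                           lowq_depression = c(-0.2, 0),
                           blur_groundwater = 8, blur_salinity = 8,
                           blur_slope = 4, blur_fertility = 6,
                           blur_landuse = 5,
                           range_groundwater = c(0.8, 2.5),
                           range_salinity = c(0.5, 4),
                           range_slope = c(0, 3),
                           beta0 = defaultTrueBeta()$beta0,
                           beta = defaultTrueBeta()$beta,
                           wells_n = 500L, wells_noise_sd = 0.05,
                           n_districts = 10L, seed = 1L) {
  stopifnot(length(years) >= 3L, composites_per_year >= 5L,
            missing_rate >= 0, missing_rate <= 1,
            low_quality_rate >= 0, low_quality_rate <= 1,
            missing_rate + low_quality_rate <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "scenarioConfig")
}

.scenario_spec <- function(cfg) {
  gridSpec(cfg$n_rows, cfg$n_cols, originX = 0,
           originY = cfg$n_rows * cfg$cell_size,
           cellSize = cfg$cell_size, crs = "synthetic-utm")
}

# Gaussian blur of white noise by exact separable band-matrix convolution
# with edge renormalization; seeded by the caller's RNG state.
.smooth_field <- function(nr, nc, radius) {
  X <- matrix(rnorm(nr * nc), nr, nc)
  if (radius <= 0) return(X)
  kern <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * radius^2))
    K / rowSums(K)
  }
  kern(nr) %*% X %*% t(kern(nc))
}

.rescale <- function(m, lo, hi) {
  r <- range(m)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - r[1]) / (r[2] - r[1]) * (hi - lo)
}

# composite start dates: evenly spaced 16-day periods from Jan 1, with
# month-days anchored to a 365-day template year so every year carries the
# same composite calendar (and hence the same 13 in-season composites)
.composite_dates <- function(years, per_year) {
  doy <- seq(1, by = 16, length.out = per_year)
  md <- format(as.Date(doy - 1, origin = "2001-01-01"), "%m-%d")
  as.Date(unlist(lapply(years, function(y) paste0(y, "-", md))))
}

#' Generate synthetic district zones and line/point infrastructure
#'
#' Districts are nearest-seed (Voronoi) regions of random interior points;
#' canals, drains and roads are random polylines crossing the region;
#' settlements and pumps are random points; the water body is a rectangle
#' near one corner.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `zones` [Grid-class], feature sets `canals`,
#'   `drains`, `roads`, and point/polygon grids used for distances.
#' @keywords internal
.make_geography <- function(cfg) {
  spec <- .scenario_spec(cfg)
  nr <- cfg$n_rows; nc <- cfg$n_cols; cs <- cfg$cell_size
  W <- nc * cs; H <- nr * cs
  ctr <- cellCenters(spec)

  sx <- runif(cfg$n_districts, 0, W)
  sy <- runif(cfg$n_districts, 0, H)
  zv <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    d2 <- outer(ctr$x, sx, function(a, b) (a - b)^2) +
      matrix(rep((ctr$y[i] - sy)^2, each = nc), nc, cfg$n_districts)
    zv[i, ] <- max.col(-d2)
  }
  zones <- newGrid(spec, zv)

  wiggly <- function(x0, y0, x1, y1, npts = 8) {
    tt <- seq(0, 1, length.out = npts)
    amp <- 0.05 * sqrt((x1 - x0)^2 + (y1 - y0)^2)
    cbind(x0 + tt * (x1 - x0) + rnorm(npts, 0, amp) * c(0, rep(1, npts - 2), 0),
          y0 + tt * (y1 - y0) + rnorm(npts, 0, amp) * c(0, rep(1, npts - 2), 0))
  }
  canals <- featureSet(lapply(seq_len(6), function(k)
    lineFeature(wiggly(0, runif(1, 0, H), W, runif(1, 0, H)))))
  drains <- featureSet(lapply(seq_len(5), function(k)
    lineFeature(wiggly(runif(1, 0, W), 0, runif(1, 0, W), H))))
  roads <- featureSet(lapply(seq_len(4), function(k)
    lineFeature(wiggly(0, runif(1, 0, H), W, runif(1, 0, H), npts = 5))))

  settlements <- featureSet(list(pointFeature(
    cbind(runif(8, 0, W), runif(8, 0, H)))))
  pumps <- featureSet(list(pointFeature(
    cbind(runif(12, 0, W), runif(12, 0, H)))))
  lake <- featureSet(list(polygonFeature(rbind(
    c(0.05 * W, 0.05 * H), c(0.25 * W, 0.05 * H),
    c(0.25 * W, 0.2 * H), c(0.05 * W, 0.2 * H), c(0.05 * W, 0.05 * H)))))

  list(zones = zones, canals = canals, drains = drains, roads = roads,
       settlements = settlements, pumps = pumps, water = lake)
}

#' Generate the synthetic land-use class series
#'
#' Three behaviours driven by smooth latent fields: persistent-fallow
#' cells (uncultivated for 7 consecutive years), short-fallow cells
#' (3 years, below the abandonment threshold), stable single-crop cells,
#' and yearly rotating cells. Class codes: 0 fallow, 1 cotton, 2 winter
#' wheat, 3 rice, 4 vegetables.
#'
#' @param cfg a [scenarioConfig()].
#' @return a [LULCSeries-class] for years 2001-2009 with `fallowCodes = 0`.
#' @keywords internal
.make_lulc <- function(cfg) {
  spec <- .scenario_spec(cfg)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  years <- 2001:2009
  ny <- length(years)
  aband <- .smooth_field(nr, nc, cfg$blur_landuse)
  stab <- .smooth_field(nr, nc, cfg$blur_landuse)
  q_ab <- quantile(aband, c(0.80, 0.65))
  persistent <- aband >= q_ab[1]                   # top 20%: 7 fallow years
  shortfallow <- aband < q_ab[1] & aband >= q_ab[2] # next 15%: 3 years
  stable <- !persistent & !shortfallow & stab >= quantile(stab, 0.25)
  crop <- matrix(1 + (round(.smooth_field(nr, nc, cfg$blur_landuse) * 10) %% 4),
                 nr, nc)
  offset <- matrix(sample.int(4, nr * nc, replace = TRUE), nr, nc)
  vals <- array(0L, c(ny, nr, nc))
  for (t in seq_len(ny)) {
    lay <- crop
    rot <- !persistent & !shortfallow & !stable
    lay[rot] <- 1 + (offset[rot] + t) %% 4
    lay[persistent & t >= 2 & t <= 8] <- 0      # 7 consecutive fallow years
    lay[shortfallow & t >= 4 & t <= 6] <- 0     # 3 fallow years
    vals[t, , ] <- lay
  }
  lulcSeries(spec, years, vals, fallowCodes = 0)
}

#' Build the synthetic factor stack
#'
#' Continuous fields are Gaussian-blurred seeded noise rescaled to
#' plausible ranges (groundwater table 0.8-2.5 m, salinity 0.5-4 g/l,
#' slope 0-3 %); distance and density layers are computed from generated
#' line/point features with the same operations the real pipeline uses;
#' bonitation classes are a quantile cut of a smooth fertility field;
#' land-use flags come from the generated class series.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `stack` ([FactorStack-class]), `geography`, `lulc`,
#'   `water_use` (per-district annual series), and `truth` (latent fields
#'   pre-noise: `gw_table`, `salinity`, `slope`, `fertility`).
#' @export
makeFactorFields <- function(cfg) {
  set.seed(cfg$seed)
  spec <- .scenario_spec(cfg)
  nr <- cfg$n_rows; nc <- cfg$n_cols

  gw <- .rescale(.smooth_field(nr, nc, cfg$blur_groundwater),
                 cfg$range_groundwater[1], cfg$range_groundwater[2])
  sal <- .rescale(.smooth_field(nr, nc, cfg$blur_salinity),
                  cfg$range_salinity[1], cfg$range_salinity[2])
  slp <- .rescale(.smooth_field(nr, nc, cfg$blur_slope),
                  cfg$range_slope[1], cfg$range_slope[2])
  fert <- .smooth_field(nr, nc, cfg$blur_fertility)
  qf <- quantile(fert, c(0.15, 0.45, 0.80))
  bonit <- matrix(4, nr, nc)
  bonit[fert <= qf[3]] <- 3
  bonit[fert <= qf[2]] <- 2
  bonit[fert <= qf[1]] <- 1

  geo <- .make_geography(cfg)
  lulc <- .make_lulc(cfg)
  flags <- lulcFlags(lulc, min_years = 6L)

  water_use <- lapply(seq_len(cfg$n_districts), function(z)
    pmax(runif(1, 80, 300) + cumsum(rnorm(length(cfg$years), 0, 15)), 10))
  names(water_use) <- seq_len(cfg$n_districts)

  pres <- function(fs) rasterizeFeatures(fs, spec, "presence")
  canal_pres <- pres(geo$canals)
  drain_pres <- pres(geo$drains)
  layers <- list(
    x1 = flags$no_change,
    x2 = flags$uncultivated,
    x7 = lineDensity(geo$canals, spec),
    x8 = lineDensity(geo$drains, spec),
    x9 = districtLayer(geo$zones, water_use),
    x10 = newGrid(spec, slp),
    x11 = newGrid(spec, gw),
    x12 = newGrid(spec, sal),
    x13 = euclideanDistance(canal_pres),
    x14 = euclideanDistance(drain_pres),
    x15 = euclideanDistance(pres(geo$pumps)),
    x16 = euclideanDistance(pres(geo$roads)),
    x17 = euclideanDistance(pres(geo$settlements)),
    x18 = euclideanDistance(pres(geo$water))
  )
  stack <- assembleFactorStack(layers, bonitation = newGrid(spec, bonit))
  list(stack = stack, geography = geo, lulc = lulc, water_use = water_use,
       truth = list(gw_table = gw, salinity = sal, slope = slp,
                    fertility = fert))
}

#' Draw degradation labels from the logistic model
#'
#' Per cell, `p = plogis(beta0 + sum_i beta_i x_i)` over the named stack
#' layers; the binary label is a Bernoulli draw.
#'
#' @param stack a [FactorStack-class].
#' @param beta0 intercept.
#' @param beta named coefficients over a subset of stack layers.
#' @param seed integer seed for the draw.
#' @return list with `labels` (binary [Grid-class]), `probability`
#'   ([Grid-class]) and `prevalence`.
#' @export
makeDegradationLabels <- function(stack, beta0 = defaultTrueBeta()$beta0,
                                  beta = defaultTrueBeta()$beta, seed = 1L) {
  miss <- setdiff(names(beta), factorNames(stack))
  if (length(miss))
    stop("beta names missing from stack: ", paste(miss, collapse = ", "))
  spec <- stack@spec
  eta <- matrix(beta0, spec@nRows, spec@nCols)
  for (nm in names(beta))
    eta <- eta + beta[[nm]] * stack@layers[[nm]]
  p <- plogis(eta)
  mask <- factorMask(stack)
  p[mask] <- NA_real_
  set.seed(seed)
  y <- matrix(NA_real_, spec@nRows, spec@nCols)
  y[!mask] <- rbinom(sum(!mask), 1, p[!mask])
  list(labels = newGrid(spec, y, mask = mask),
       probability = newGrid(spec, p, mask = mask),
       prevalence = mean(y[!mask]))
}

# seasonal pulse supported on composites 11-15 (mid June to mid August),
# zero elsewhere; the sum over the 13 in-season composites is then an
# exact linear functional preserved by the default quadratic filter.
.season_template <- function(per_year) {
  b <- numeric(per_year)
  if (per_year >= 15) b[11:15] <- c(0.6, 0.9, 1.0, 0.9, 0.6)
  else b[ceiling(per_year / 2) + (-1:1)] <- c(0.6, 1.0, 0.6)
  b
}

#' Generate the synthetic NDVI cube with planted trends
#'
#' Each cell's year-`t` series is `baseline + A_t * pulse + noise` where
#' the pulse is a fixed mid-season template and the amplitude `A_t`
#' declines linearly so that the true seasonal-sum slope equals a seeded
#' draw from the degraded range on degraded cells and the stable range
#' elsewhere. Observations are randomly flagged missing or low-quality at
#' the configured rates; low-quality observations additionally receive a
#' cloud-style negative depression.
#'
#' @param cfg a [scenarioConfig()].
#' @param degraded binary [Grid-class] of degradation labels.
#' @return list with `cube` ([NDVICube-class]) and `true_slope`
#'   ([Grid-class], seasonal-sum units per year).
#' @export
makeNdviCube <- function(cfg, degraded) {
  set.seed(cfg$seed + 1L)
  spec <- .scenario_spec(cfg)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  ny <- length(cfg$years)
  per <- cfg$composites_per_year
  dates <- .composite_dates(cfg$years, per)
  pulse <- .season_template(per)
  pulse_sum <- sum(pulse)

  deg <- degraded@values == 1 & !degraded@mask
  slope <- matrix(runif(nr * nc, cfg$slope_stable[1], cfg$slope_stable[2]),
                  nr, nc)
  slope[deg] <- runif(sum(deg), cfg$slope_degraded[1], cfg$slope_degraded[2])

  nt <- ny * per
  vals <- array(0, c(nt, nr, nc))
  for (y in seq_len(ny)) {
    A <- cfg$amplitude + slope * (y - 1) / pulse_sum
    for (c_i in seq_len(per)) {
      t <- (y - 1) * per + c_i
      vals[t, , ] <- cfg$baseline + A * pulse[c_i]
    }
  }
  if (cfg$noise_sd > 0)
    vals <- vals + array(rnorm(length(vals), 0, cfg$noise_sd), dim(vals))

  u <- array(runif(length(vals)), dim(vals))
  qual <- array(0L, dim(vals))
  qual[u < cfg$low_quality_rate] <- 1L
  qual[u >= cfg$low_quality_rate &
       u < cfg$low_quality_rate + cfg$missing_rate] <- 2L
  lowq <- qual == 1L
  if (any(lowq))
    vals[lowq] <- vals[lowq] + runif(sum(lowq), cfg$lowq_depression[1],
                                     cfg$lowq_depression[2])
  list(cube = ndviCube(spec, dates, vals, qual),
       true_slope = newGrid(spec, slope, mask = degraded@mask))
}

#' Sample observation wells from a surface
#'
#' `n` locations uniform over the unmasked extent; the value is the
#' surface value of the containing cell plus Gaussian noise.
#'
#' @param surface a [Grid-class].
#' @param n number of wells.
#' @param noise_sd measurement noise standard deviation.
#' @param seed integer seed.
#' @return a `wellSet`.
#' @export
makeWells <- function(surface, n = 500L, noise_sd = 0.05, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  spec <- surface@spec
  ok <- which(!surface@mask, arr.ind = TRUE)
  got <- 0L; xs <- ys <- vs <- numeric(0)
  while (got < n) {
    m <- n - got
    x <- runif(m, spec@originX, spec@originX + spec@nCols * spec@cellSize)
    y <- runif(m, spec@originY - spec@nRows * spec@cellSize, spec@originY)
    j <- pmin(spec@nCols, floor((x - spec@originX) / spec@cellSize) + 1)
    i <- pmin(spec@nRows, floor((spec@originY - y) / spec@cellSize) + 1)
    keep <- !surface@mask[cbind(i, j)]
    x <- x[keep]; y <- y[keep]
    v <- surface@values[cbind(i[keep], j[keep])]
    xs <- c(xs, x); ys <- c(ys, y); vs <- c(vs, v)
    got <- length(xs)
  }
  wellSet(xs, ys, vs + rnorm(length(vs), 0, noise_sd))
}

#' Write a complete synthetic scenario to disk
#'
#' Generates factor fields, degradation labels, the NDVI cube, wells,
#' land-use series and zones, and writes everything in the on-disk layout
#' the pipeline consumes (GeoTIFF layers, CSV tables, GeoJSON features, a
#' JSON manifest echoing the configuration, seed and truth file names).
#'
#' @param cfg a [scenarioConfig()].
#' @param dir output directory.
#' @param overwrite overwrite an existing directory (default FALSE).
#' @return invisibly, a list with all in-memory objects (`stack`,
#'   `labels`, `cube`, `true_slope`, `wells`, `lulc`, `zones`,
#'   `water_use`, `beta0`, `beta`, `dir`).
#' @export
makeScenario <- function(cfg = scenarioConfig(), dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("cube", "factors", "lulc", "truth"))
    dir.create(file.path(dir, d), showWarnings = FALSE)

  ff <- makeFactorFields(cfg)
  lab <- makeDegradationLabels(ff$stack, cfg$beta0, cfg$beta,
                               seed = cfg$seed + 2L)
  nd <- makeNdviCube(cfg, lab$labels)

  writeCubeDir(nd$cube, file.path(dir, "cube"))
  writeFactorDir(ff$stack, file.path(dir, "factors"))

  wells <- makeWells(newGrid(ff$stack@spec, ff$truth$gw_table),
                     n = cfg$wells_n, noise_sd = cfg$wells_noise_sd,
                     seed = cfg$seed + 3L)
  write.csv(as.data.frame(wells), file.path(dir, "wells.csv"),
            row.names = FALSE)

  lulc <- ff$lulc
  lulc_paths <- sprintf("lulc_%d.tif", lulc@years)
  for (k in seq_along(lulc@years))
    writeRaster(newGrid(lulc@spec, lulc@values[k, , ]),
                file.path(dir, "lulc", lulc_paths[k]), datatype = "int16")
  write.csv(data.frame(year = lulc@years, path = lulc_paths,
                       fallow_codes = paste(lulc@fallowCodes,
                                            collapse = ";")),
            file.path(dir, "lulc", "years.csv"), row.names = FALSE)

  writeRaster(ff$geography$zones, file.path(dir, "zones.tif"),
              datatype = "int16")
  writeGeoJSON(ff$geography$canals, file.path(dir, "canals.geojson"))
  writeGeoJSON(ff$geography$drains, file.path(dir, "drains.geojson"))

  writeRaster(nd$true_slope, file.path(dir, "truth", "true_slope.tif"))
  writeRaster(lab$labels, file.path(dir, "truth", "degraded.tif"),
              datatype = "uint8", nodata = 255)
  writeRaster(lab$probability, file.path(dir, "truth", "probability.tif"))
  writeRaster(newGrid(ff$stack@spec, ff$truth$gw_table),
              file.path(dir, "truth", "gw_surface.tif"))
  write.csv(data.frame(variable = c("(Intercept)", names(cfg$beta)),
                       beta = c(cfg$beta0, unname(cfg$beta))),
            file.path(dir, "truth", "beta.csv"), row.names = FALSE)

  cfg_echo <- cfg
  cfg_echo$beta <- as.list(cfg$beta)
  manifest <- list(
    seed = cfg$seed,
    config = cfg_echo[setdiff(names(cfg_echo), "years")],
    years = as.integer(cfg$years),
    prevalence = lab$prevalence,
    paths = list(cube = "cube", factors = "factors", wells = "wells.csv",
                 lulc = "lulc", zones = "zones.tif"),
    truth = list(true_slope = "truth/true_slope.tif",
                 degraded = "truth/degraded.tif",
                 probability = "truth/probability.tif",
                 gw_surface = "truth/gw_surface.tif",
                 beta = "truth/beta.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(stack = ff$stack, labels = lab$labels,
                 probability = lab$probability,
                 prevalence = lab$prevalence, cube = nd$cube,
                 true_slope = nd$true_slope, wells = wells, lulc = lulc,
                 zones = ff$geography$zones, water_use = ff$water_use,
                 beta0 = cfg$beta0, beta = cfg$beta, dir = dir))
}
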