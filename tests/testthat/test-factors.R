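# Distance grids, line densities, variogram/kriging, land-use flags,
# district layers, factor-stack assembly.

test_that("euclideanDistance is exact against brute force and 1-Lipschitz", {
  spec <- tiny_spec(5, 5)
  v <- matrix(0, 5, 5); v[3, 3] <- 1
  d <- euclideanDistance(newGrid(spec, v))
  expect_equal(gridValues(d)[3, 3], 0)
  expect_equal(gridValues(d)[3, 4], 250)
  expect_equal(gridValues(d)[4, 4], 250 * sqrt(2), tolerance = 1e-9)

  set.seed(71)
  spec40 <- tiny_spec(40, 40)
  tv <- matrix(as.numeric(runif(1600) < 0.02), 40, 40)
  if (sum(tv) == 0) tv[7, 9] <- 1
  dg <- euclideanDistance(newGrid(spec40, tv))
  ctr <- cellCenters(spec40)
  tg <- which(tv == 1, arr.ind = TRUE)
  for (k in 1:50) {
    i <- sample(40, 1); j <- sample(40, 1)
    brute <- min(sqrt((ctr$x[j] - ctr$x[tg[, 2]])^2 +
                      (ctr$y[i] - ctr$y[tg[, 1]])^2))
    expect_equal(gridValues(dg)[i, j], brute)
  }
  # 1-Lipschitz on the 4-neighbour graph
  dv <- gridValues(dg)
  expect_true(all(abs(diff(dv)) <= 250 + 1e-9))
  expect_true(all(abs(t(diff(t(dv)))) <= 250 + 1e-9))

  expect_error(euclideanDistance(newGrid(spec, matrix(0, 5, 5))),
               "no target")
})

test_that("lineDensity clips segments exactly and conserves total length", {
  spec <- tiny_spec(5, 5)
  # straight line through the middle of one row: 250 m per crossed cell
  ln <- featureSet(lineFeature(rbind(c(0, 625), c(1250, 625))))
  ld <- lineDensity(ln, spec)
  expect_equal(gridValues(ld)[3, ], rep(250 / 62500, 5))

  # line entirely outside the grid
  far <- featureSet(lineFeature(rbind(c(-500, -500), c(-100, -100))))
  expect_equal(sum(gridValues(lineDensity(far, spec))), 0)

  # random segments: per-cell clipped length against an independent
  # interval-intersection oracle
  set.seed(72)
  segs <- lapply(1:5, function(k) matrix(runif(4, 0, 1250), 2, 2))
  ld2 <- lineDensity(featureSet(lapply(segs, lineFeature)), spec)
  clip_len <- function(p, xmin, xmax, ymin, ymax) {
    lo <- 0; hi <- 1
    for (dim in 1:2) {
      a <- p[1, dim]; b <- p[2, dim]
      mn <- if (dim == 1) xmin else ymin
      mx <- if (dim == 1) xmax else ymax
      if (a == b) { if (a < mn || a > mx) return(0) } else {
        t1 <- (mn - a) / (b - a); t2 <- (mx - a) / (b - a)
        lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
      }
    }
    if (hi <= lo) return(0)
    (hi - lo) * sqrt(sum((p[2, ] - p[1, ])^2))
  }
  for (i in 1:5) for (j in 1:5) {
    want <- sum(vapply(segs, clip_len, 0, (j - 1) * 250, j * 250,
                       1250 - i * 250, 1250 - (i - 1) * 250))
    expect_equal(gridValues(ld2)[i, j] * 62500, want, tolerance = 1e-6)
  }
  # integral of density over the grid = total in-grid length
  total <- sum(vapply(segs, function(p) sqrt(sum((p[2, ] - p[1, ])^2)), 0))
  expect_equal(sum(gridValues(ld2)) * 62500, total, tolerance = 1e-3)
})

test_that("variogram fitting recovers a known spherical structure", {
  # constant field -> degenerate flat model
  set.seed(73)
  wc <- wellSet(runif(30, 0, 1e4), runif(30, 0, 1e4), rep(2, 30))
  mc <- fitSphericalVariogram(wc)
  expect_equal(mc@psill, 0)
  expect_true(all(attr(mc, "empirical")$gamma >= 0))

  # wells sampled from a known spherical model (range 5000, sill 1,
  # nugget 0) via Gaussian random fields with that covariance; a single
  # realization carries large variogram variance, so the check is on the
  # median recovery error over five seeded replicates
  rel_err <- vapply(74:78, function(seed) {
    set.seed(seed)
    n <- 500
    x <- runif(n, 0, 4e4); y <- runif(n, 0, 4e4)
    h <- as.matrix(dist(cbind(x, y)))
    truth <- variogramModel(0, 1, 5000)
    C <- 1 - sphericalSemivariance(truth, h)
    L <- chol(C + diag(1e-8, n))
    z <- drop(t(L) %*% rnorm(n))
    m <- fitSphericalVariogram(wellSet(x, y, z), n_lags = 15,
                               max_dist = 10000)
    expect_true(all(attr(m, "empirical")$gamma >= 0))
    abs(m@range - 5000) / 5000
  }, numeric(1))
  expect_lt(median(rel_err), 0.25)
})

test_that("ordinary kriging is exact, unbiased and matches a direct solve", {
  spec <- tiny_spec(6, 6)
  ctr <- cellCenters(spec)
  model <- variogramModel(0, 2, 1500)

  # single well -> constant surface (weights sum to 1)
  w1 <- wellSet(625, 625, 3.3)
  k1 <- krigeSpherical(w1, model, spec)
  expect_true(all(gridValues(k1) == 3.3))

  # two wells symmetric about a cell center, nugget 0 -> mean
  w2 <- wellSet(c(ctr$x[2], ctr$x[6]), c(ctr$y[4], ctr$y[4]), c(1, 5))
  k2 <- krigeSpherical(w2, model, spec)
  expect_equal(gridValues(k2)[4, 4], 3, tolerance = 1e-9)

  # <= 10 wells, full neighborhood: predictions equal an independent
  # dense solve of the kriging system at 20 random cells
  set.seed(75)
  wx <- runif(9, 0, 1500); wy <- runif(9, 0, 1500); wv <- rnorm(9, 10, 2)
  wells <- wellSet(wx, wy, wv)
  kg <- krigeSpherical(wells, model, spec, neighborhood = 9)
  gam <- function(h) {
    hr <- pmin(h / 1500, 1)
    out <- 2 * (1.5 * hr - 0.5 * hr^3)
    out[h == 0] <- 0
    out
  }
  for (k in 1:20) {
    i <- sample(6, 1); j <- sample(6, 1)
    A <- rbind(cbind(gam(as.matrix(dist(cbind(wx, wy)))), 1),
               c(rep(1, 9), 0))
    b <- c(gam(sqrt((wx - ctr$x[j])^2 + (wy - ctr$y[i])^2)), 1)
    lam <- solve(A, b)[1:9]
    expect_equal(gridValues(kg)[i, j], sum(lam * wv), tolerance = 1e-6)
  }

  # nugget-0 exactness at well cell centers + weights sum to 1
  wi <- c(2, 5); wj <- c(3, 4)
  we <- wellSet(ctr$x[wj], ctr$y[wi], c(7, 9))
  ke <- krigeSpherical(we, model, spec)
  expect_equal(gridValues(ke)[2, 3], 7, tolerance = 1e-6)
  expect_equal(gridValues(ke)[5, 4], 9, tolerance = 1e-6)
  kw <- krigeWeights(wells, model, 700, 900, neighborhood = 9)
  expect_equal(sum(kw$weights), 1, tolerance = 1e-9)

  # coincident wells are averaged before solving
  wd <- wellSet(c(625, 625, 875), c(625, 625, 875), c(2, 4, 6))
  kd <- krigeWeights(wd, model, 500, 500, neighborhood = 3)
  expect_equal(nrow(kd$wells), 2)
})

test_that("lulcFlags derives persistence and abandonment as specified", {
  spec <- tiny_spec(1, 5)
  mk <- function(...) {
    rowsl <- list(...)
    vals <- array(NA_real_, c(length(rowsl[[1]]), 1, 5))
    for (p in 1:5) vals[, 1, p] <- rowsl[[p]]
    lulcSeries(spec, 2001:2009, vals, fallowCodes = 0)
  }
  s <- mk(rep(1, 9),                    # cotton 9 straight years
          c(1, 2, 3, 4, 1, 2, 3, 4, 1), # changes every year
          c(0, 1, 0, 1, 0, 1, 0, 1, 0), # fallow 5 of 9, interleaved
          c(0, 0, 1, 0, 0, 1, 0, 0, 0), # fallow 6 of 9 non-consecutive
          c(2, 2, 2, 2, 2, 2, 0, 0, 0)) # wheat 6 years then fallow
  fl <- lulcFlags(s, min_years = 6)
  expect_equal(gridValues(fl$no_change)[1, ], c(1, 0, 0, 0, 1))
  expect_equal(gridValues(fl$uncultivated)[1, ], c(0, 0, 0, 1, 0))

  # consecutive reading differs for the non-consecutive abandonment
  flc <- lulcFlags(s, min_years = 6, uncultivated_mode = "consecutive")
  expect_equal(gridValues(flc$uncultivated)[1, 4], 0)

  # antitone in min_years: raising the threshold never creates a 1
  fl5 <- lulcFlags(s, min_years = 5)
  expect_true(all(gridValues(fl$no_change) <= gridValues(fl5$no_change)))
  expect_true(all(gridValues(fl$uncultivated) <=
                  gridValues(fl5$uncultivated)))

  # masked year propagates to both outputs
  s2 <- mk(rep(1, 9), rep(1, 9), rep(1, 9), rep(1, 9), rep(1, 9))
  s2@values[4, 1, 2] <- NA
  fl2 <- lulcFlags(s2)
  expect_true(is.na(gridValues(fl2$no_change)[1, 2]))
  expect_true(is.na(gridValues(fl2$uncultivated)[1, 2]))
})

test_that("districtLayer spreads scalar and series summaries per zone", {
  expect_equal(meanAbsDelta(c(10, 12, 9)), 2.5)

  set.seed(76)
  zn <- newGrid(tiny_spec(6, 6), matrix(sample(1:5, 36, TRUE), 6, 6))
  series <- lapply(1:5, function(z) runif(11, 50, 300))
  names(series) <- 1:5
  g <- districtLayer(zn, series)
  for (z in 1:5) {
    want <- mean(abs(diff(series[[z]])))
    sel <- gridValues(zn) == z
    expect_true(all(gridValues(g)[sel] == want))
  }
  # constant annual series -> delta 0
  g0 <- districtLayer(zn, setNames(lapply(1:5, function(z) rep(7, 11)), 1:5))
  expect_true(all(gridValues(g0) == 0))

  expect_error(districtLayer(zn, series[1:3]), "4, 5")
})

test_that("assembleFactorStack expands bonitation dummies and enforces
           layer kinds", {
  spec <- tiny_spec(4, 4)
  set.seed(77)
  bon <- newGrid(spec, matrix(sample(1:4, 16, TRUE), 4, 4))
  layers <- list(
    x1 = newGrid(spec, matrix(sample(0:1, 16, TRUE), 4, 4)),
    x2 = newGrid(spec, matrix(sample(0:1, 16, TRUE), 4, 4))
  )
  for (nm in paste0("x", 7:18))
    layers[[nm]] <- newGrid(spec, matrix(runif(16), 4, 4))
  st <- assembleFactorStack(layers, bonitation = bon)
  expect_identical(factorNames(st), paste0("x", 1:18))
  expect_identical(unname(factorKinds(st)[c("x4", "x10")]),
                   c("binary", "continuous"))
  # dummy coding: class II -> x4 = 1, others 0; dummies partition
  ii <- which(gridValues(bon) == 2)[1]
  expect_equal(st@layers$x4[ii], 1)
  expect_equal(st@layers$x3[ii] + st@layers$x5[ii] + st@layers$x6[ii], 0)
  dsum <- st@layers$x3 + st@layers$x4 + st@layers$x5 + st@layers$x6
  expect_true(all(dsum == 1))

  # a binary layer with a fractional value is rejected by name
  bad <- layers
  bv <- gridValues(bad$x1); bv[2, 2] <- 0.5
  bad$x1 <- newGrid(spec, bv)
  expect_error(assembleFactorStack(bad, bonitation = bon), "x1")
})
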