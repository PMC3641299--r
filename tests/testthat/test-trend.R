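# Per-pixel trend fitting, classification, binarization, endpoint
# sensitivity and zonal areal statistics.

stack_from_matrix <- function(Y, years = 2000:(1999 + nrow(Y))) {
  npix <- ncol(Y)
  nc <- ceiling(sqrt(npix)); nr <- ceiling(npix / nc)
  vals <- array(NA_real_, c(nrow(Y), nr, nc))
  for (p in seq_len(npix)) {
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    vals[, i, j] <- Y[, p]
  }
  annualSumStack(tiny_spec(nr, nc), years, vals)
}

test_that("fitPixelTrend matches the independent per-pixel lm fit", {
  # exact line: y = 2 + 3 t over 11 years
  st <- stack_from_matrix(cbind(2 + 3 * (0:10)))
  tr <- fitPixelTrend(st)
  expect_equal(gridValues(trendLayer(tr, "slope"))[1, 1], 3)
  expect_equal(gridValues(trendLayer(tr, "intercept"))[1, 1], 2)
  expect_equal(gridValues(trendLayer(tr, "p"))[1, 1], 0)

  # constant series: slope 0, p 1
  trc <- fitPixelTrend(stack_from_matrix(cbind(rep(7, 11))))
  expect_equal(gridValues(trendLayer(trc, "slope"))[1, 1], 0)
  expect_equal(gridValues(trendLayer(trc, "p"))[1, 1], 1)

  # 100 random series vs lm()/summary() per pixel
  set.seed(21)
  Y <- matrix(rnorm(11 * 100, 5, 2), 11, 100)
  tr2 <- fitPixelTrend(stack_from_matrix(Y))
  tt <- 0:10
  for (p in seq_len(100)) {
    i <- (p - 1) %% 10 + 1; j <- (p - 1) %/% 10 + 1
    fit <- lm(Y[, p] ~ tt)
    sm <- summary(fit)$coefficients
    expect_lt(abs(gridValues(trendLayer(tr2, "slope"))[i, j] - sm[2, 1]),
              1e-10)
    expect_lt(abs(gridValues(trendLayer(tr2, "intercept"))[i, j] - sm[1, 1]),
              1e-10)
    expect_lt(abs(gridValues(trendLayer(tr2, "t"))[i, j] - sm[2, 3]), 1e-10)
    expect_lt(abs(gridValues(trendLayer(tr2, "p"))[i, j] - sm[2, 4]), 1e-10)
  }

  # invariance to adding a constant: only the intercept shifts
  tr3 <- fitPixelTrend(stack_from_matrix(Y + 100))
  expect_equal(gridValues(trendLayer(tr3, "slope")),
               gridValues(trendLayer(tr2, "slope")))
  expect_equal(gridValues(trendLayer(tr3, "intercept")),
               gridValues(trendLayer(tr2, "intercept")) + 100)

  # a pixel masked in one year is masked in the result
  Ym <- Y; Ym[4, 7] <- NA
  tr4 <- fitPixelTrend(stack_from_matrix(Ym))
  expect_true(gridMask(trendLayer(tr4, "slope"))[7, 1])
})

test_that("classifyTrend applies the severity rules and is monotone in p", {
  mk <- function(slope, p) {
    res <- fitPixelTrend(stack_from_matrix(cbind(rnorm(11))))
    res@slope <- newGrid(tiny_spec(1, 1), slope)
    res@pValue <- newGrid(tiny_spec(1, 1), p)
    res@intercept <- res@tStat <- res@slope
    res@classMap <- newGrid(tiny_spec(1, 1), NA_real_)
    gridValues(classifyTrend(res)@classMap)[1, 1]
  }
  expect_equal(mk(-5, 0.01), 1)   # significant negative at 95 %
  expect_equal(mk(-5, 0.07), 2)   # significant at 90 % only
  expect_equal(mk(-5, 0.5), 3)    # non-significant negative
  expect_equal(mk(5, 0.001), 4)   # positive slope is always "other"
  expect_equal(mk(0, 0.5), 4)     # zero slope counts as other

  # monotone: lowering p never moves a negative-slope pixel to a less
  # severe class
  ps <- sort(runif(20))
  cls <- vapply(ps, function(p) mk(-1, p), numeric(1))
  expect_true(all(diff(cls) >= 0))
})

test_that("binarizeDegraded merges classes 1 and 2 and counts match", {
  set.seed(31)
  cl <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
  cl[3, ] <- NA
  g <- newGrid(tiny_spec(10, 10), cl)
  y <- binarizeDegraded(g)
  yv <- gridValues(y)
  expect_equal(sum(yv == 1, na.rm = TRUE),
               sum(cl %in% c(1, 2)))
  expect_equal(sum(yv == 0, na.rm = TRUE), sum(cl %in% c(3, 4)))
  expect_identical(gridMask(y), gridMask(g))
})

test_that("endpointSensitivity reports 100 % for noise-free lines and a
           tallied agreement otherwise", {
  set.seed(41)
  slopes <- runif(25, -1, 1)
  Y <- sapply(slopes, function(s) 3 + s * (0:10))
  eps <- endpointSensitivity(stack_from_matrix(Y))
  expect_equal(eps$agreement_drop_first, 100)
  expect_equal(eps$agreement_drop_last, 100)

  # noisy stack: agreement equals an independent cell-by-cell tally
  Yn <- Y + matrix(rnorm(length(Y), 0, 2), nrow(Y))
  stn <- stack_from_matrix(Yn)
  epn <- endpointSensitivity(stn)
  thr <- trendClassThresholds()
  cls <- function(sel) {
    sub <- annualSumStack(stn@spec, stn@years[sel],
                          stn@values[sel, , , drop = FALSE])
    gridValues(classifyTrend(fitPixelTrend(sub), thr)@classMap)
  }
  full <- cls(1:11)
  tally <- 100 * mean(full == cls(2:11), na.rm = TRUE)
  expect_equal(epn$agreement_drop_first, tally)
})

test_that("zonalAreaStats converts counts to hectares and percentages that
           close to the zone totals", {
  # 16 cells of a 250 m grid, all class 1, one zone -> 100 ha, 100 %
  g <- newGrid(tiny_spec(4, 4), 1)
  z <- newGrid(tiny_spec(4, 4), 1)
  tab <- zonalAreaStats(g, z)
  expect_equal(tab$high_ha[1], 100)
  expect_equal(tab$high_pct[1], 100)

  # random map and zones vs a brute-force group-by
  set.seed(51)
  cl <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  zn <- matrix(sample(1:5, 400, replace = TRUE), 20, 20)
  cl[1, 1:7] <- NA
  tab2 <- zonalAreaStats(newGrid(tiny_spec(20, 20), cl),
                         newGrid(tiny_spec(20, 20), zn))
  for (z_id in 1:5) {
    sel <- zn == z_id & !is.na(cl)
    r <- tab2[tab2$zone == as.character(z_id), ]
    expect_equal(r$high_ha, sum(cl[sel] == 1) * 6.25)
    expect_equal(r$med_ha, sum(cl[sel] == 2) * 6.25)
    expect_equal(r$low_pct, 100 * sum(cl[sel] == 3) / sum(sel))
    # percentages close to 100 per zone
    expect_equal(r$low_pct + r$med_pct + r$high_pct + r$other_pct, 100,
                 tolerance = 1e-8)
    expect_equal(r$medhigh_ha, r$med_ha + r$high_ha)
  }
  # TOTAL row sums the districts
  tot <- tab2[tab2$zone == "TOTAL", ]
  dst <- tab2[tab2$zone != "TOTAL", ]
  for (cc in c("low_ha", "med_ha", "high_ha", "other_ha", "medhigh_ha"))
    expect_equal(tot[[cc]], sum(dst[[cc]]), tolerance = 1e-8)
})

test_that("the combined-column convention reproduces an externally
           tabulated medium+high total", {
  f <- system.file("extdata", "district_negative_trend_areas.csv",
                   package = "degrisk")
  df <- read.csv(f)
  tab <- arealStatsFromAreas(df)
  tot <- tab[tab$zone == "TOTAL", ]
  expect_equal(tot$medhigh_ha, sum(df$med_ha) + sum(df$high_ha))
  expect_equal(tot$medhigh_ha, 62203.65, tolerance = 1e-9)
})

test_that("under a null stack the negative-tail type-I rates match the
           class thresholds", {
  set.seed(61)
  npix <- 3600
  Y <- matrix(rnorm(11 * npix, 10, 1), 11, npix)
  cl <- gridValues(classifyTrend(fitPixelTrend(stack_from_matrix(Y)))@classMap)
  fr_high <- mean(cl == 1)
  fr_hm <- mean(cl %in% c(1, 2))
  se_high <- sqrt(0.025 * 0.975 / npix)
  se_hm <- sqrt(0.05 * 0.95 / npix)
  expect_lt(abs(fr_high - 0.025), 3 * se_high)
  expect_lt(abs(fr_hm - 0.05), 3 * se_hm)
})
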