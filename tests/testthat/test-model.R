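# Spatial sampling, VIF screening, logistic fitting, model comparison,
# validation metrics, odds and the decile risk map.

toy_stack <- function(nr = 9, nc = 9, seed = 81, mask = NULL) {
  set.seed(seed)
  spec <- tiny_spec(nr, nc)
  layers <- list(x10 = newGrid(spec, matrix(runif(nr * nc, 0, 3), nr, nc)),
                 x11 = newGrid(spec, matrix(runif(nr * nc, 0.8, 2.5),
                                            nr, nc)))
  if (!is.null(mask))
    layers <- lapply(layers, function(g) {
      v <- gridValues(g); v[mask] <- NA; newGrid(spec, v)
    })
  assembleFactorStack(layers)
}

test_that("blockSample draws exactly one unmasked cell per occupied
           window, reproducibly", {
  stack <- toy_stack()
  y <- newGrid(tiny_spec(9, 9), matrix(rbinom(81, 1, 0.3), 9, 9))
  s1 <- blockSample(y, stack, block = 3, seed = 7)
  expect_equal(nrow(s1), 9)
  # windows are disjoint: one row per 3x3 block
  win <- paste((s1$row - 1) %/% 3, (s1$col - 1) %/% 3)
  expect_equal(anyDuplicated(win), 0)
  expect_identical(s1, blockSample(y, stack, block = 3, seed = 7))

  # fully masked grid -> empty table
  ym <- newGrid(tiny_spec(3, 3), matrix(NA_real_, 3, 3))
  sm <- toy_stack(3, 3)
  expect_equal(nrow(blockSample(ym, sm, seed = 1)), 0)

  # random mask: row count equals the number of occupied windows
  set.seed(82)
  mask <- matrix(runif(81) < 0.6, 9, 9)
  stack2 <- toy_stack(mask = mask)
  yv <- matrix(rbinom(81, 1, 0.3), 9, 9); yv[mask] <- NA
  y2 <- newGrid(tiny_spec(9, 9), yv)
  s2 <- blockSample(y2, stack2, block = 3, seed = 7)
  occupied <- 0
  for (bi in 1:3) for (bj in 1:3)
    if (any(!mask[(bi * 3 - 2):(bi * 3), (bj * 3 - 2):(bj * 3)]))
      occupied <- occupied + 1
  expect_equal(nrow(s2), occupied)
  expect_true(all(!is.na(s2$y)))
})

test_that("splitCalibration halves the sample reproducibly", {
  tab <- data.frame(row = 1:9, col = 1, y = rbinom(9, 1, .5))
  s5 <- splitCalibration(tab[1:5, ], seed = 3)
  expect_setequal(unique(s5$split), c("calibration", "validation"))
  expect_true(abs(sum(s5$split == "calibration") - 2.5) == 0.5)

  big <- data.frame(row = 1:8112, col = 1, y = 0)
  sb <- splitCalibration(big, seed = 4)
  expect_equal(sum(sb$split == "calibration"), 4056)
  expect_equal(sum(sb$split == "validation"), 4056)
  expect_identical(sb$split, splitCalibration(big, seed = 4)$split)
})

test_that("vifScreen matches auxiliary regressions and the car oracle", {
  set.seed(83)
  n <- 300
  # two orthogonal predictors
  a <- rep(c(-1, 1), n / 2); b <- rep(c(-1, 1), each = n / 2)
  t1 <- data.frame(y = rbinom(n, 1, .5), a = a, b = b)
  v1 <- vifScreen(t1, predictors = c("a", "b"))
  expect_equal(v1$vif$vif, c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(v1$removed), 0)

  # duplicated predictor removed as infinite
  t2 <- data.frame(y = rbinom(n, 1, .5), a = rnorm(n))
  t2$b <- t2$a; t2$c <- rnorm(n)
  v2 <- vifScreen(t2, predictors = c("a", "b", "c"))
  expect_true(is.infinite(v2$removed$vif[1]))
  expect_length(v2$retained, 2)

  # random correlated predictors: VIF = 1/(1-R2) from independent lm fits
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 6] <- X[, 1] * 0.8 + rnorm(n, 0, 0.6)
  t3 <- as.data.frame(X); names(t3) <- paste0("p", 1:6); t3$y <- 0
  v3 <- vifScreen(t3, threshold = 1e9, predictors = paste0("p", 1:6))
  for (j in 1:6) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(v3$vif$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  # cross-check against car::vif on a linear model
  t3$yy <- rnorm(n)
  cv <- car::vif(lm(yy ~ p1 + p2 + p3 + p4 + p5 + p6, data = t3))
  expect_equal(unname(v3$vif$vif), unname(cv), tolerance = 1e-6)
})

test_that("fitLogistic maximises the likelihood and matches an optim
           oracle", {
  set.seed(84)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, .4)
  eta <- -0.5 + 1.2 * x1 + 0.8 * x2
  df <- data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2)
  fit <- fitLogistic(df, predictors = c("x1", "x2"))

  X <- cbind(1, x1, x2)
  nll <- function(b) -sum(df$y * drop(X %*% b) - log1p(exp(drop(X %*% b))))
  grad <- function(b) -drop(t(X) %*% (df$y - plogis(drop(X %*% b))))
  op <- optim(c(0, 0, 0), nll, grad, method = "BFGS",
              control = list(reltol = 1e-14))
  expect_equal(unname(fit$coef), op$par, tolerance = 1e-6)
  expect_equal(fit$loglik, -op$value, tolerance = 1e-6)
  # covariance is symmetric PSD and SE = sqrt(diag)
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$vcov))))

  # intercept-only model reproduces the prevalence
  f0 <- degrisk:::.intercept_only_fit(df)
  expect_equal(plogis(f0$coef[[1]]), mean(df$y), tolerance = 1e-8)

  # independent outcome: no |z| should be extreme at n = 10000
  set.seed(85)
  big <- data.frame(y = rbinom(10000, 1, .5), a = rnorm(10000),
                    b = rnorm(10000), c = rnorm(10000))
  fb <- fitLogistic(big, predictors = c("a", "b", "c"))
  expect_true(all(abs(fb$z[-1]) < 4))

  expect_error(fitLogistic(data.frame(y = rep(1, 10), x = rnorm(10)),
                           predictors = "x"), "both outcome classes")
})

test_that("backwardStepwise drops noise and keeps signal", {
  set.seed(86)
  n <- 600
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("p", 1:6)
  # all-noise outcome: everything is dropped
  d0 <- data.frame(y = rbinom(n, 1, 0.5), X)
  f0 <- backwardStepwise(d0, predictors = paste0("p", 1:6))
  expect_length(f0$predictors, 0)
  expect_equal(sort(f0$dropped), sort(paste0("p", 1:6)))

  # one strong predictor among noise is retained
  kept <- 0
  for (r in 1:20) {
    Xr <- matrix(rnorm(n * 6), n, 6); colnames(Xr) <- paste0("p", 1:6)
    dr <- data.frame(y = rbinom(n, 1, plogis(2 * Xr[, 1])), Xr)
    fr <- backwardStepwise(dr, predictors = paste0("p", 1:6))
    if ("p1" %in% fr$predictors) kept <- kept + 1
  }
  expect_gte(kept, 19)

  # alpha_remove = 1 keeps the full model
  f1 <- backwardStepwise(d0, alpha_remove = 1, predictors = paste0("p", 1:6))
  expect_length(f1$predictors, 6)
})

test_that("compareAUC handles self-comparison, separable data, and agrees
           with the pROC DeLong test", {
  set.seed(87)
  n <- 300
  x <- rnorm(n); z <- rnorm(n)
  df <- data.frame(y = rbinom(n, 1, plogis(x)), x = x, z = z)
  fa <- fitLogistic(df, predictors = c("x", "z"))
  fb <- fitLogistic(df, predictors = "x")

  self <- compareAUC(fa, fa, df)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)

  cmp <- compareAUC(fa, fb, df)
  ra <- pROC::roc(df$y, predictProbability(fa, df), quiet = TRUE)
  rb <- pROC::roc(df$y, predictProbability(fb, df), quiet = TRUE)
  pr <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(cmp$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(cmp$p, pr$p.value, tolerance = 1e-8)

  # near-random vs perfect scorer on separable toy data
  sep <- data.frame(y = rep(0:1, each = 50), s = c(rnorm(50), rnorm(50)))
  fperf <- list(coef = c("(Intercept)" = 0, y2 = 10), predictors = "y2")
  class(fperf) <- "logisticFit"
  sep$y2 <- sep$y
  frand <- list(coef = c("(Intercept)" = 0, s = 0.01), predictors = "s")
  class(frand) <- "logisticFit"
  c2 <- compareAUC(fperf, frand, sep)
  expect_equal(c2$auc_a, 1)
  expect_lt(abs(c2$auc_b - 0.5), 0.2)
})

test_that("validateFit computes AUC, PCP and the likelihood-ratio
           chi-square exactly", {
  # perfect separation
  df <- data.frame(y = rep(c(0, 1), each = 100),
                   x = rep(c(-3, 3), each = 100))
  fit <- list(coef = c("(Intercept)" = 0, x = 2), predictors = "x",
              null_deviance = 277, deviance = 100)
  class(fit) <- "logisticFit"
  rep1 <- validateFit(fit, df)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$pcp, 100)

  # identical scores: AUC 0.5 under the tie convention
  fit0 <- fit; fit0$coef <- c("(Intercept)" = 0.1, x = 0)
  rep0 <- validateFit(fit0, df)
  expect_equal(rep0$auc, 0.5)
  expect_true(any(grepl("degenerate", rep0$flags)))

  # AUC equals the brute-force pairwise mean on 200 random rows
  set.seed(88)
  sc <- round(runif(200), 2)  # rounding forces ties
  y <- rbinom(200, 1, sc)
  brute <- mean(outer(sc[y == 1], sc[y == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(rankAUC(sc, y), brute)

  # PCP equals direct confusion-matrix arithmetic at the 0.5 cut
  set.seed(89)
  df2 <- data.frame(y = rbinom(150, 1, .4), x = rnorm(150))
  f2 <- fitLogistic(df2, predictors = "x")
  rep2 <- validateFit(f2, df2)
  pred <- as.numeric(predictProbability(f2, df2) > 0.5)
  expect_equal(rep2$pcp, 100 * sum(pred == df2$y) / nrow(df2))
  # chi-square = 2 * (loglik - null loglik), df = number of slopes
  expect_equal(rep2$chi_square, 2 * (f2$loglik - f2$null_loglik),
               tolerance = 1e-8)
  expect_equal(rep2$chi_df, 1)
})

test_that("oddsPercent converts coefficients to percent odds change", {
  expect_equal(oddsPercent(0), 0)
  expect_equal(oddsPercent(-log(2)), -50)
  expect_equal(round(oddsPercent(c(0.71, 0.40, 0.23))), c(103, 49, 26))
  # printed-coefficient odds match tabulated odds within rounding slack
  b <- c(1.46, 0.71, 0.40, 0.25, 0.23)
  printed <- c(329.73, 102.72, 48.59, 28.96, 25.96)
  expect_true(all(abs(oddsPercent(b) / printed - 1) < 0.02))
  rep <- fitReport(list(coef = c("(Intercept)" = -3.55, x11 = 1.46),
                        se = c(0.16, 0.65), z = c(-22.33, 9.71),
                        p = c(1e-10, 1e-10), predictors = "x11"))
  expect_equal(rep$stars, c("****", "****"))
})

test_that("riskDeciles allocates equal-count classes with the documented
           tie order", {
  set.seed(90)
  spec <- tiny_spec(10, 10)
  layers <- list(x11 = newGrid(spec, matrix(runif(100), 10, 10)))
  st <- assembleFactorStack(layers)
  fit <- list(coef = c("(Intercept)" = -1, x11 = 2), predictors = "x11")
  class(fit) <- "logisticFit"
  rm_ <- riskDeciles(fit, st)
  cls <- gridValues(rm_$classes)
  expect_equal(as.vector(table(cls)), rep(10, 10))
  top <- which(gridValues(rm_$probability) ==
               max(gridValues(rm_$probability)), arr.ind = TRUE)
  expect_equal(cls[top], 1)

  # all probabilities equal: classes follow the row-major tie order
  st0 <- assembleFactorStack(list(x11 = newGrid(spec, 1)))
  rm0 <- riskDeciles(fit, st0)
  cls0 <- gridValues(rm0$classes)
  ord <- order(row(cls0), col(cls0))
  expect_equal(cls0[ord][c(1, 10, 11, 100)], c(1, 1, 2, 10))
  expect_equal(as.vector(table(cls0)), rep(10, 10))

  # class sizes within 1 of N/10 for awkward N
  v <- matrix(runif(100), 10, 10); v[1, 1:7] <- NA
  st93 <- assembleFactorStack(list(x11 = newGrid(spec, v)))
  rm93 <- riskDeciles(fit, st93)
  sizes <- as.vector(table(gridValues(rm93$classes)))
  expect_true(all(abs(sizes - 9.3) <= 1))

  expect_error(riskDeciles(list(coef = c("(Intercept)" = 0, zz = 1),
                                predictors = "zz"), st), "zz")
})
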