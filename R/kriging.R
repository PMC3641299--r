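# Spherical variogram estimation and ordinary kriging with a moving
# neighborhood, used to interpolate groundwater table depth and salinity
# from sparse well observations.

#' Spherical semivariance
#'
#' Evaluates the model gamma(h): 0 at h = 0 (exact-interpolation limit),
#' `nugget + psill * (1.5 h/r - 0.5 (h/r)^3)` for `0 < h <= r`, and
#' `nugget + psill` beyond the range.
#'
#' @param model a [VariogramModel-class].
#' @param h distances (m), vectorised.
#' @return semivariances.
#' @export
sphericalSemivariance <- function(model, h) {
  r <- model@range
  hr <- pmin(h / r, 1)
  g <- model@nugget + model@psill * (1.5 * hr - 0.5 * hr^3)
  g[h > r] <- model@nugget + model@psill
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram and spherical model fit
#'
#' Method-of-moments semivariogram on equal-width distance bins up to
#' `max_dist`, followed by a weighted least-squares fit of the spherical
#' model with bin pair counts as weights. Duplicated well locations are
#' averaged first.
#'
#' @param wells a `wellSet` (see [wellSet()]) with at least 10 wells.
#' @param n_lags number of distance bins (default 15).
#' @param max_dist maximum pair distance considered; defaults to half the
#'   bounding-box diagonal.
#' @return a [VariogramModel-class] with attribute `"empirical"` holding
#'   the binned semivariogram (`dist`, `gamma`, `n`).
#' @export
fitSphericalVariogram <- function(wells, n_lags = 15L, max_dist = NULL) {
  wells <- .dedupe_wells(wells)
  n <- nrow(wells)
  if (n < 10L) stop("at least 10 wells required")
  if (is.null(max_dist))
    max_dist <- 0.5 * sqrt(diff(range(wells$x))^2 + diff(range(wells$y))^2)
  if (max_dist <= 0) stop("max_dist must be positive")

  dmat <- as.matrix(dist(cbind(wells$x, wells$y)))
  dv <- dmat[upper.tri(dmat)]
  gsq <- 0.5 * outer(wells$value, wells$value, `-`)^2
  gv <- gsq[upper.tri(gsq)]
  keep <- dv > 0 & dv <= max_dist
  dv <- dv[keep]; gv <- gv[keep]
  if (!length(dv)) stop("no well pairs within max_dist")

  bin <- pmin(n_lags, floor(dv / (max_dist / n_lags)) + 1L)
  emp <- data.frame(
    dist = tapply(dv, bin, mean),
    gamma = tapply(gv, bin, mean),
    n = as.integer(table(bin))
  )

  if (var(wells$value) == 0 || all(emp$gamma == 0)) {
    out <- variogramModel(0, 0, max_dist)
    attr(out, "empirical") <- emp
    return(out)
  }

  # Cressie-style weights (pair count / squared lag) favour the short
  # lags that identify the range; normalized so the objective scale does
  # not defeat the optimizer's stopping rule
  ww <- emp$n / emp$dist^2
  ww <- ww / sum(ww)
  gscale <- mean(emp$gamma)^2
  obj <- function(par) {
    m <- variogramModel(max(par[1], 0), max(par[2], 1e-10), max(par[3], 10))
    sum(ww * (sphericalSemivariance(m, emp$dist) - emp$gamma)^2) / gscale
  }
  s2 <- var(wells$value)
  start_sill <- max(s2 - min(emp$gamma) * 0.5, 1e-8)
  best <- NULL
  for (r0 in max_dist * c(0.2, 0.5, 0.9)) {
    fit <- optim(c(min(emp$gamma) * 0.5, start_sill, r0), obj,
                 method = "L-BFGS-B",
                 lower = c(0, 1e-10, max_dist * 1e-3),
                 upper = c(Inf, Inf, max_dist * 4),
                 control = list(factr = 1e4,
                                parscale = c(max(s2, 1e-4), max(s2, 1e-4),
                                             max_dist)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- variogramModel(max(best$par[1], 0), max(best$par[2], 0),
                        max(best$par[3], 10))
  attr(out, "empirical") <- emp
  out
}

# ordinary-kriging weights and prediction for one location
.ok_solve <- function(px, py, wx, wy, wv, model) {
  k <- length(wx)
  if (model@psill == 0 && model@nugget == 0) {
    # degenerate flat field: equal weights reproduce the constant
    return(list(weights = rep(1 / k, k), pred = mean(wv)))
  }
  d0 <- sqrt((wx - px)^2 + (wy - py)^2)
  dmat <- as.matrix(dist(cbind(wx, wy)))
  A <- rbind(cbind(matrix(sphericalSemivariance(model, dmat), k, k), 1),
             c(rep(1, k), 0))
  b <- c(sphericalSemivariance(model, d0), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  list(weights = sol[seq_len(k)], pred = sum(sol[seq_len(k)] * wv))
}

#' Ordinary-kriging weights at one location
#'
#' Solves the ordinary-kriging system (semivariogram form with the
#' unbiasedness constraint) for a single prediction point, using the
#' `neighborhood` nearest wells. Exposed mainly for inspection: the
#' returned weights sum to 1.
#'
#' @param wells a `wellSet`.
#' @param model a [VariogramModel-class].
#' @param x,y prediction location (m).
#' @param neighborhood number of nearest wells used (default 16).
#' @return list with `weights`, `wells` (the rows used) and `pred`.
#' @export
krigeWeights <- function(wells, model, x, y, neighborhood = 16L) {
  wells <- .dedupe_wells(wells)
  k <- min(neighborhood, nrow(wells))
  d2 <- (wells$x - x)^2 + (wells$y - y)^2
  sel <- order(d2)[seq_len(k)]
  sol <- .ok_solve(x, y, wells$x[sel], wells$y[sel], wells$value[sel], model)
  if (is.null(sol)) stop("singular kriging system")
  list(weights = sol$weights, wells = wells[sel, ], pred = sol$pred)
}

#' Ordinary kriging onto a grid
#'
#' Predicts at every cell center from the `neighborhood` nearest wells by
#' ordinary kriging under the given spherical variogram. Duplicated well
#' locations are averaged; a still-singular system raises an error naming
#' the cell.
#'
#' @param wells a `wellSet`.
#' @param model a [VariogramModel-class].
#' @param spec target [GridSpec-class].
#' @param neighborhood number of nearest wells per prediction (>= 1,
#'   default 16).
#' @return [Grid-class] of predictions.
#' @export
krigeSpherical <- function(wells, model, spec, neighborhood = 16L) {
  stopifnot(neighborhood >= 1L)
  wells <- .dedupe_wells(wells)
  if (nrow(wells) == 1L)
    return(newGrid(spec, matrix(wells$value, spec@nRows, spec@nCols)))
  k <- min(neighborhood, nrow(wells))
  ctr <- cellCenters(spec)
  out <- matrix(NA_real_, spec@nRows, spec@nCols)
  for (i in seq_len(spec@nRows)) {
    dy2 <- (wells$y - ctr$y[i])^2
    for (j in seq_len(spec@nCols)) {
      d2 <- (wells$x - ctr$x[j])^2 + dy2
      sel <- if (k < nrow(wells)) order(d2)[seq_len(k)] else seq_len(nrow(wells))
      sol <- .ok_solve(ctr$x[j], ctr$y[i], wells$x[sel], wells$y[sel],
                       wells$value[sel], model)
      if (is.null(sol))
        stop(sprintf("singular kriging system at cell (%d, %d)", i, j))
      out[i, j] <- sol$pred
    }
  }
  newGrid(spec, out)
}
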