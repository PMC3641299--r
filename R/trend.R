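# Per-pixel linear trend of the annual seasonal sum, significance
# classification, degraded-land binarization, endpoint sensitivity, and
# district areal statistics.

#' Per-pixel OLS trend over annual seasonal sums
#'
#' Ordinary least squares of the seasonal sum on the year index
#' `t = 0 .. k-1` for every pixel. The intercept is therefore the fitted
#' vegetation level at the first year of the series. The slope's t
#' statistic uses `k - 2` degrees of freedom; p values are two-sided.
#' Pixels masked in any year are masked in all outputs. A perfect line
#' yields `t = +/-Inf`, `p = 0`; a constant series yields slope 0, `p = 1`.
#'
#' @param stack an [AnnualSumStack-class] with at least 3 years.
#' @return a [TrendResult-class] (class map unset until
#'   [classifyTrend()]).
#' @export
fitPixelTrend <- function(stack) {
  k <- length(stack@years)
  if (k < 3L) stop("at least 3 years required for a trend")
  d <- dim(stack@values)
  Y <- matrix(stack@values, k, d[2L] * d[3L])
  tt <- 0:(k - 1)
  tbar <- mean(tt)
  Sxx <- sum((tt - tbar)^2)
  ok <- colSums(is.na(Y)) == 0L

  slope <- inter <- tstat <- pval <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    Yo <- Y[, ok, drop = FALSE]
    ybar <- colMeans(Yo)
    b1 <- colSums((tt - tbar) * Yo) / Sxx
    b0 <- ybar - b1 * tbar
    fitted <- outer(tt, b1) + rep(b0, each = k)
    rss <- colSums((Yo - fitted)^2)
    tolr <- 1e-12 * pmax(colSums(Yo^2), 1)
    s2 <- rss / (k - 2)
    se <- sqrt(s2 / Sxx)
    tv <- b1 / se
    pv <- 2 * pt(-abs(tv), df = k - 2)
    zero_res <- rss <= tolr
    if (any(zero_res)) {
      flat <- zero_res & abs(b1) <= sqrt(tolr / Sxx)
      line <- zero_res & !flat
      b1[flat] <- 0
      tv[flat] <- 0
      pv[flat] <- 1
      tv[line] <- sign(b1[line]) * Inf
      pv[line] <- 0
    }
    slope[ok] <- b1; inter[ok] <- b0; tstat[ok] <- tv; pval[ok] <- pv
  }
  g <- function(v) newGrid(stack@spec, matrix(v, d[2L], d[3L]))
  new("TrendResult",
    slope = g(slope), intercept = g(inter), tStat = g(tstat),
    pValue = g(pval),
    classMap = newGrid(stack@spec, matrix(NA_real_, d[2L], d[3L]))
  )
}

#' Trend classification thresholds
#'
#' Two-sided p-value ceilings for the negative-trend classes: `p_high`
#' (default 0.05, i.e. 95 % confidence) bounds the high class and
#' `p_medium` (default 0.10, 90 % confidence) the medium class.
#'
#' @param p_high,p_medium two-sided p ceilings, `0 < p_high < p_medium < 1`.
#' @return list of class `trendClassThresholds`.
#' @export
trendClassThresholds <- function(p_high = 0.05, p_medium = 0.10) {
  if (!(p_high > 0 && p_high < p_medium && p_medium < 1))
    stop("need 0 < p_high < p_medium < 1")
  structure(list(p_high = p_high, p_medium = p_medium),
            class = "trendClassThresholds")
}

#' Classify per-pixel trends into four severity classes
#'
#' Negative slopes are split by the two-sided p value of the slope:
#' class 1 "high negative" (`p <= p_high`), class 2 "medium negative"
#' (`p_high < p <= p_medium`), class 3 "low negative" (`p > p_medium`).
#' All non-negative slopes go to class 4 "other"; positive and neutral
#' trends are outside the degradation focus.
#'
#' @param result a [TrendResult-class] from [fitPixelTrend()].
#' @param thresholds a [trendClassThresholds()].
#' @return the [TrendResult-class] with its class map filled in.
#' @export
classifyTrend <- function(result, thresholds = trendClassThresholds()) {
  s <- result@slope@values
  p <- result@pValue@values
  cl <- matrix(NA_real_, nrow(s), ncol(s))
  neg <- !is.na(s) & s < 0
  cl[neg & p <= thresholds$p_high] <- 1
  cl[neg & p > thresholds$p_high & p <= thresholds$p_medium] <- 2
  cl[neg & p > thresholds$p_medium] <- 3
  cl[!is.na(s) & s >= 0] <- 4
  result@classMap <- newGrid(result@slope@spec, cl,
                             mask = result@slope@mask)
  result
}

#' Merge the significant negative classes into a binary degraded map
#'
#' Degraded land = classes 1 (high negative) and 2 (medium negative);
#' classes 3 and 4 map to 0. The nodata mask is preserved.
#'
#' @param class_map a [Grid-class] of class codes 1-4, or a classified
#'   [TrendResult-class].
#' @return binary [Grid-class] (1 = degraded).
#' @export
binarizeDegraded <- function(class_map) {
  if (is(class_map, "TrendResult")) class_map <- class_map@classMap
  cl <- class_map@values
  if (!all(cl[!is.na(cl)] %in% 1:4))
    stop("class map must contain codes 1-4")
  y <- ifelse(is.na(cl), NA_real_, as.numeric(cl %in% c(1, 2)))
  newGrid(class_map@spec, y, mask = class_map@mask)
}

#' Endpoint sensitivity of the trend classification
#'
#' Errors in the first or last image of a time series have the largest
#' leverage on a linear trend. This check recomputes the class map without
#' the first year, and separately without the last year, and reports the
#' percentage of unmasked cells classified identically to the full-series
#' map (overall agreement).
#'
#' @param stack an [AnnualSumStack-class] with at least 4 years.
#' @param thresholds a [trendClassThresholds()].
#' @return list with `agreement_drop_first` and `agreement_drop_last`
#'   (percent), plus the three class maps.
#' @export
endpointSensitivity <- function(stack, thresholds = trendClassThresholds()) {
  k <- length(stack@years)
  if (k < 4L) stop("at least 4 years required")
  cls <- function(sel) {
    sub <- annualSumStack(stack@spec, stack@years[sel],
                          stack@values[sel, , , drop = FALSE])
    classifyTrend(fitPixelTrend(sub), thresholds)@classMap
  }
  full <- cls(seq_len(k))
  nofirst <- cls(2:k)
  nolast <- cls(seq_len(k - 1))
  agree <- function(a, b) {
    okc <- !a@mask & !b@mask
    100 * mean(a@values[okc] == b@values[okc])
  }
  list(
    agreement_drop_first = agree(full, nofirst),
    agreement_drop_last = agree(full, nolast),
    class_full = full, class_drop_first = nofirst, class_drop_last = nolast
  )
}

#' Combine per-zone areal statistics
#'
#' Adds the combined medium+high column and a TOTAL row to a per-zone
#' table of class areas. This is the aggregation convention used by
#' [zonalAreaStats()]; it is exposed so externally tabulated areas can be
#' combined the same way.
#'
#' @param df data frame with a `zone` column and area columns ending in
#'   `_ha` (at least `med_ha` and `high_ha`); optional matching `_pct`
#'   columns are carried through.
#' @return the table with `medhigh_ha` (and `medhigh_pct` when the parts
#'   are present) and a final `TOTAL` row summing the `_ha` columns.
#' @export
arealStatsFromAreas <- function(df) {
  stopifnot(all(c("zone", "med_ha", "high_ha") %in% names(df)))
  df$zone <- as.character(df$zone)
  if (!"medhigh_ha" %in% names(df))
    df$medhigh_ha <- df$med_ha + df$high_ha
  ha_cols <- grep("_ha$", names(df), value = TRUE)
  total <- df[1, , drop = FALSE]
  total[1, ] <- NA
  total$zone <- "TOTAL"
  for (cc in ha_cols) total[[cc]] <- sum(df[[cc]])
  if (all(c("med_pct", "high_pct") %in% names(df)) &&
      !"medhigh_pct" %in% names(df))
    df$medhigh_pct <- df$med_pct + df$high_pct
  if ("medhigh_pct" %in% names(df) && !"medhigh_pct" %in% names(total))
    total$medhigh_pct <- NA_real_
  out <- rbind(df, total[, names(df), drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("arealStatsTable", "data.frame"))
}

#' Areal statistics of trend classes per district zone
#'
#' Per zone and class: cell count converted to hectares
#' (`cell_size^2 / 10^4`) and percent of the zone's unmasked cells. The
#' combined column merges medium and high; the TOTAL row sums the zones
#' (its percentages are of the total unmasked area).
#'
#' @param class_map classified [Grid-class] (codes 1-4) or classified
#'   [TrendResult-class].
#' @param zones [Grid-class] of integer zone ids (>= 1).
#' @return data frame of class `arealStatsTable` with columns `zone`,
#'   `low_ha`, `low_pct`, `med_ha`, `med_pct`, `high_ha`, `high_pct`,
#'   `other_ha`, `other_pct`, `medhigh_ha`, `medhigh_pct`.
#' @export
zonalAreaStats <- function(class_map, zones) {
  if (is(class_map, "TrendResult")) class_map <- class_map@classMap
  rep_ok <- validateStack(list(class_map, zones))
  if (!rep_ok$pass)
    stop("class map and zones are not aligned: ",
         paste(rep_ok$mismatches, collapse = ", "))
  ha_per_cell <- class_map@spec@cellSize^2 / 1e4
  valid <- !class_map@mask & !zones@mask
  cl <- class_map@values[valid]
  zn <- zones@values[valid]
  zids <- sort(unique(zn))
  mk_row <- function(counts, n) {
    ha <- counts * ha_per_cell
    pct <- if (n > 0) 100 * counts / n else rep(0, 4)
    c(low_ha = ha[3], low_pct = pct[3], med_ha = ha[2], med_pct = pct[2],
      high_ha = ha[1], high_pct = pct[1], other_ha = ha[4],
      other_pct = pct[4])
  }
  rows <- lapply(zids, function(z) {
    counts <- tabulate(cl[zn == z], nbins = 4)
    mk_row(counts, sum(zn == z))
  })
  df <- data.frame(zone = as.character(zids), do.call(rbind, rows))
  df$medhigh_ha <- df$med_ha + df$high_ha
  df$medhigh_pct <- df$med_pct + df$high_pct
  out <- arealStatsFromAreas(df)
  # TOTAL percentages: share of the total unmasked area
  tot <- nrow(out)
  n_all <- length(cl)
  counts_all <- tabulate(cl, nbins = 4)
  pct_all <- if (n_all > 0) 100 * counts_all / n_all else rep(0, 4)
  out$low_pct[tot] <- pct_all[3]
  out$med_pct[tot] <- pct_all[2]
  out$high_pct[tot] <- pct_all[1]
  out$other_pct[tot] <- pct_all[4]
  out$medhigh_pct[tot] <- pct_all[1] + pct_all[2]
  out
}
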