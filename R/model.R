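# Stage 2: spatially thinned sampling, multicollinearity screening,
# logistic regression of degradation on the factor stack, model comparison
# and validation, odds reporting, and the decile risk map.

#' Systematic unbalanced spatial sample
#'
#' Partitions the grid into non-overlapping `block x block` windows from
#' the top-left corner and draws exactly one unmasked cell uniformly at
#' random from every window that contains one. One observation per 750 m x
#' 750 m window (the default 3 x 3 cells at 250 m) thins the spatial
#' dependence between neighbouring cells that would otherwise bias the
#' regression's standard errors.
#'
#' @param y binary outcome [Grid-class] (from [binarizeDegraded()]).
#' @param stack aligned [FactorStack-class]; cells masked in any layer are
#'   excluded.
#' @param block window edge in cells (default 3).
#' @param seed integer seed for reproducible draws.
#' @return data frame of class `sampleTable`: `row`, `col`, `y`, one
#'   column per factor, and a `split` column (`NA` until
#'   [splitCalibration()]).
#' @export
blockSample <- function(y, stack, block = 3L, seed = 1L) {
  rep_ok <- validateStack(list(y, stack))
  if (!rep_ok$pass)
    stop("outcome and factor stack are not aligned: ",
         paste(rep_ok$mismatches, collapse = ", "))
  stopifnot(block >= 1L)
  usable <- !y@mask & !factorMask(stack)
  nr <- y@spec@nRows; nc <- y@spec@nCols
  set.seed(seed)
  rows <- integer(0); cols <- integer(0)
  for (bi in seq_len(ceiling(nr / block))) {
    ii <- ((bi - 1L) * block + 1L):min(bi * block, nr)
    for (bj in seq_len(ceiling(nc / block))) {
      jj <- ((bj - 1L) * block + 1L):min(bj * block, nc)
      cand <- which(usable[ii, jj, drop = FALSE])
      if (!length(cand)) next
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      # decode within-window index (column-major)
      pi <- (pick - 1L) %% length(ii) + 1L
      pj <- (pick - 1L) %/% length(ii) + 1L
      rows <- c(rows, ii[pi]); cols <- c(cols, jj[pj])
    }
  }
  df <- data.frame(row = rows, col = cols,
                   y = y@values[cbind(rows, cols)])
  for (nm in factorNames(stack))
    df[[nm]] <- stack@layers[[nm]][cbind(rows, cols)]
  df$split <- rep(NA_character_, nrow(df))
  structure(df, class = c("sampleTable", "data.frame"),
            predictors = factorNames(stack))
}

#' Split a sample into calibration and validation halves
#'
#' Uniform random 50/50 split (sizes differ by at most 1), reproducible
#' under the seed.
#'
#' @param table a `sampleTable` (from [blockSample()]).
#' @param seed integer seed.
#' @return the table with its `split` column set to `"calibration"` or
#'   `"validation"`.
#' @export
splitCalibration <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop("at least 2 rows required to split")
  set.seed(seed)
  idx <- sample.int(n, floor(n / 2))
  table$split <- "calibration"
  table$split[idx] <- "validation"
  table
}

.predictor_names <- function(table, predictors = NULL) {
  if (!is.null(predictors)) return(predictors)
  p <- attr(table, "predictors")
  if (!is.null(p)) return(intersect(p, names(table)))
  setdiff(names(table), c("row", "col", "y", "split"))
}

#' Iterative variance-inflation-factor screen
#'
#' VIF of predictor j is `1 / (1 - R2_j)` with `R2_j` from the ordinary
#' regression of j on all other retained predictors. While any VIF exceeds
#' the threshold, the largest is dropped and the VIFs recomputed. Exactly
#' collinear (or constant) predictors have infinite VIF and are removed
#' first.
#'
#' @param table a `sampleTable` or data frame of predictors.
#' @param threshold VIF ceiling (default 5).
#' @param predictors predictor column names (default: all factor columns).
#' @return list with `retained` (names), `vif` (final VIF table),
#'   `removed` (data frame of dropped predictors and their VIF at
#'   removal).
#' @export
vifScreen <- function(table, threshold = 5, predictors = NULL) {
  preds <- .predictor_names(table, predictors)
  if (length(preds) < 2L) stop("at least 2 predictors required")
  X <- as.matrix(table[, preds, drop = FALSE])
  if (nrow(X) <= length(preds) + 1L)
    stop("need more observations than predictors")
  vif_one <- function(j, keep) {
    xj <- X[, keep[j]]
    if (var(xj) == 0) return(Inf)
    others <- X[, keep[-j], drop = FALSE]
    fit <- lm.fit(cbind(1, others), xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  keep <- preds
  removed <- data.frame(variable = character(), vif = numeric())
  repeat {
    v <- vapply(seq_along(keep), vif_one, numeric(1), keep = keep)
    names(v) <- keep
    if (length(keep) <= 1L || all(v <= threshold)) break
    worst <- which.max(v)
    removed <- rbind(removed,
                     data.frame(variable = keep[worst], vif = v[worst]))
    keep <- keep[-worst]
  }
  list(retained = keep, vif = data.frame(variable = keep, vif = unname(v)),
       removed = removed)
}

#' Fit the logistic degradation model
#'
#' Maximum-likelihood logistic regression
#' `P(y = 1) = 1 / (1 + exp(-(b0 + sum_i b_i x_i)))`
#' fitted by iteratively reweighted least squares (convergence when the
#' relative deviance change is below 1e-8, at most 100 iterations).
#' Standard errors come from the inverse observed information; z and
#' two-sided p values per coefficient.
#'
#' @param table a `sampleTable` (typically the calibration split) or data
#'   frame with a binary `y` column.
#' @param predictors predictor columns (default: all factor columns).
#' @return object of class `logisticFit`: `coef`, `se`, `z`, `p`,
#'   `vcov`, `loglik`, `null_loglik`, `n`, `converged`, `predictors`.
#' @export
fitLogistic <- function(table, predictors = NULL) {
  preds <- .predictor_names(table, predictors)
  if (!all(table$y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(table$y)) < 2L)
    stop("both outcome classes must be present")
  df <- as.data.frame(table[, c("y", preds), drop = FALSE])
  fit <- suppressWarnings(glm(
    y ~ ., data = df, family = binomial(),
    control = list(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged)
    warning("IRLS did not converge within 100 iterations; ",
            "possible complete separation")
  sm <- summary(fit)
  cf <- sm$coefficients
  out <- list(
    coef = cf[, 1], se = cf[, 2], z = cf[, 3], p = cf[, 4],
    vcov = vcov(fit), loglik = as.numeric(logLik(fit)),
    null_loglik = as.numeric(logLik(glm(y ~ 1, data = df,
                                        family = binomial()))),
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    n = nrow(df), converged = fit$converged, predictors = preds
  )
  class(out) <- "logisticFit"
  out
}

#' @export
print.logisticFit <- function(x, ...) {
  cat(sprintf("Logistic fit: %d observations, %d predictor(s)%s\n",
              x$n, length(x$predictors),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(fitReport(x), digits = 4)
  invisible(x)
}

#' Predict degradation probabilities from a fit
#'
#' @param fit a `logisticFit`.
#' @param newdata data frame containing the fit's predictor columns.
#' @return vector of probabilities.
#' @export
predictProbability <- function(fit, newdata) {
  miss <- setdiff(fit$predictors, names(newdata))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  eta <- rep(fit$coef[["(Intercept)"]], nrow(newdata))
  for (nm in fit$predictors)
    eta <- eta + fit$coef[[nm]] * newdata[[nm]]
  plogis(eta)
}

#' Backward stepwise logistic regression
#'
#' Starts from the full model and repeatedly drops the predictor with the
#' largest Wald p value above `alpha_remove`, refitting until every
#' retained predictor has p <= `alpha_remove`.
#'
#' @inheritParams fitLogistic
#' @param alpha_remove removal threshold on the Wald p value (default
#'   0.05).
#' @return the final `logisticFit`, with the drop sequence in `$dropped`.
#' @export
backwardStepwise <- function(table, alpha_remove = 0.05, predictors = NULL) {
  preds <- .predictor_names(table, predictors)
  dropped <- character(0)
  repeat {
    fit <- fitLogistic(table, predictors = preds)
    pv <- fit$p[setdiff(names(fit$p), "(Intercept)")]
    if (!length(pv) || max(pv) <= alpha_remove) break
    worst <- names(pv)[which.max(pv)]
    dropped <- c(dropped, worst)
    preds <- setdiff(preds, worst)
    if (!length(preds)) { # intercept-only final model
      fit <- .intercept_only_fit(table)
      break
    }
  }
  fit$dropped <- dropped
  fit
}

.intercept_only_fit <- function(table) {
  df <- data.frame(y = table$y)
  fit <- glm(y ~ 1, data = df, family = binomial())
  sm <- summary(fit)$coefficients
  nm <- rownames(sm)
  out <- list(coef = setNames(sm[, 1], nm), se = setNames(sm[, 2], nm),
              z = setNames(sm[, 3], nm), p = setNames(sm[, 4], nm),
              vcov = vcov(fit), loglik = as.numeric(logLik(fit)),
              null_loglik = as.numeric(logLik(fit)),
              deviance = fit$deviance, null_deviance = fit$null.deviance,
              n = nrow(df), converged = fit$converged,
              predictors = character(0))
  class(out) <- "logisticFit"
  out
}

#' Rank-based area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counting one half (the Mann-Whitney convention).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
rankAUC <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement components: V10 per positive, V01 per negative
.delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s)
    mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s)
    mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two models' ROC areas
#'
#' Scores both fits on the same validation rows and tests equality of the
#' two correlated AUCs with the paired placement-variance (DeLong) z test
#' in the tradition of correlated-ROC comparisons. When the difference is
#' significant at `alpha` the higher-AUC model is recommended; otherwise
#' the model with fewer predictors.
#'
#' @param fit_a,fit_b `logisticFit` objects (e.g. full and stepwise).
#' @param validation a `sampleTable` subset containing both fits'
#'   predictors and `y`.
#' @param alpha significance level for the recommendation (default 0.05).
#' @return list with `auc_a`, `auc_b`, `diff`, `z`, `p`, `recommended`
#'   (`"a"` or `"b"`), and `degenerate` flag (all scores identical).
#' @export
compareAUC <- function(fit_a, fit_b, validation, alpha = 0.05) {
  if (length(unique(validation$y)) < 2L)
    stop("validation rows must contain both outcome classes")
  sa <- predictProbability(fit_a, validation)
  sb <- predictProbability(fit_b, validation)
  degenerate <- (length(unique(sa)) == 1L) || (length(unique(sb)) == 1L)
  pa <- .delong_placements(sa, validation$y)
  pb <- .delong_placements(sb, validation$y)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (abs(d) < 1e-15 || vd <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  rec <- if (!degenerate && p < alpha) {
    if (pa$auc >= pb$auc) "a" else "b"
  } else {
    if (length(fit_a$predictors) <= length(fit_b$predictors)) "a" else "b"
  }
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, z = z, p = p,
       recommended = rec, degenerate = degenerate)
}

#' Validate a fitted model on held-out rows
#'
#' Computes the rank-based AUC, the percentage of correctly predicted
#' cells at the probability threshold (PCP), and the whole-model
#' chi-square: the likelihood-ratio statistic of the fitted model against
#' the intercept-only model, with degrees of freedom equal to the number
#' of slope coefficients.
#'
#' @param fit a `logisticFit`.
#' @param validation a `sampleTable` subset disjoint from the calibration
#'   rows.
#' @param threshold probability cut for the PCP (default 0.5).
#' @return list of class `validationReport`: `auc`, `pcp`, `chi_square`,
#'   `chi_df`, `chi_p`, `threshold`, `n`, `flags`.
#' @export
validateFit <- function(fit, validation, threshold = 0.5) {
  scores <- predictProbability(fit, validation)
  flags <- character(0)
  auc <- rankAUC(scores, validation$y)
  if (is.na(auc)) flags <- c(flags, "single-class validation: AUC undefined")
  if (length(unique(scores)) == 1L)
    flags <- c(flags, "degenerate scores: all predictions identical")
  pred <- as.numeric(scores > threshold)
  pcp <- 100 * mean(pred == validation$y)
  chi <- fit$null_deviance - fit$deviance
  df <- length(fit$predictors)
  out <- list(
    auc = auc, pcp = pcp, chi_square = chi, chi_df = df,
    chi_p = pchisq(chi, df, lower.tail = FALSE),
    threshold = threshold, n = nrow(validation), flags = flags
  )
  class(out) <- "validationReport"
  out
}

#' @export
print.validationReport <- function(x, ...) {
  cat(sprintf(
    "Validation (n = %d): AUC %.3f, PCP %.1f%% at threshold %.2f\n",
    x$n, x$auc, x$pcp, x$threshold))
  cat(sprintf("  model chi-square %.2f on %d df (p = %.3g)\n",
              x$chi_square, x$chi_df, x$chi_p))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Percent change in odds per unit predictor change
#'
#' `100 * (exp(beta) - 1)`: the percent by which the odds of degradation
#' change when the predictor increases by one unit.
#'
#' @param beta coefficient(s).
#' @return percent change(s) in odds.
#' @examples
#' oddsPercent(1.46)   # ~330 %
#' oddsPercent(-log(2)) # exactly -50 %
#' @export
oddsPercent <- function(beta) 100 * expm1(beta)

#' Coefficient report with odds and significance stars
#'
#' One row per model term: coefficient, percent odds change, standard
#' error, z, p, and significance stars
#' (`*` p<0.1, `**` p<0.05, `***` p<0.01, `****` p<0.001).
#'
#' @param fit a `logisticFit`.
#' @return data frame.
#' @export
fitReport <- function(fit) {
  stars <- vapply(fit$p, function(p) {
    if (p < 0.001) "****" else if (p < 0.01) "***"
    else if (p < 0.05) "**" else if (p < 0.1) "*" else "n.s."
  }, character(1))
  data.frame(
    variable = names(fit$coef),
    coefficient = unname(fit$coef),
    odds_percent = unname(oddsPercent(fit$coef)),
    se = unname(fit$se), z = unname(fit$z), p = unname(fit$p),
    stars = unname(stars), row.names = NULL
  )
}

#' Decile risk map
#'
#' Applies the fitted model to the factor stack cell-wise to get the
#' degradation probability surface, ranks the unmasked cells by
#' probability in descending order (ties broken by row, then column), and
#' allocates sequential 10 % slices to classes 1..10 -- class 1 holds the
#' top 10 % of probabilities (highest risk).
#'
#' @param fit a `logisticFit` whose predictors are all present in the
#'   stack.
#' @param stack a [FactorStack-class].
#' @return list of class `riskMap` with `classes` (codes 1-10) and
#'   `probability` [Grid-class] layers.
#' @export
riskDeciles <- function(fit, stack) {
  miss <- setdiff(fit$predictors, factorNames(stack))
  if (length(miss))
    stop("factor stack lacks predictor layer(s): ",
         paste(miss, collapse = ", "))
  mask <- factorMask(stack)
  nr <- stack@spec@nRows; nc <- stack@spec@nCols
  eta <- matrix(fit$coef[["(Intercept)"]], nr, nc)
  for (nm in fit$predictors)
    eta <- eta + fit$coef[[nm]] * stack@layers[[nm]]
  prob <- plogis(eta)
  prob[mask] <- NA_real_
  cells <- which(!mask, arr.ind = TRUE)
  p <- prob[cells]
  ord <- order(-p, cells[, 1], cells[, 2])
  N <- length(p)
  cls_sorted <- ceiling(seq_len(N) * 10 / N)
  cls <- matrix(NA_real_, nr, nc)
  cls[cells[ord, , drop = FALSE]] <- cls_sorted
  structure(list(
    classes = newGrid(stack@spec, cls, mask = mask),
    probability = newGrid(stack@spec, prob, mask = mask)
  ), class = "riskMap")
}
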