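# Configuration-driven orchestration of the two-stage analysis:
# synth -> preprocess -> trend -> (factors) -> model -> risk -> report.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the two-stage analysis with the
#' package defaults. Any element can be overridden through `...` (nested
#' lists are merged shallowly per block).
#'
#' @param seed master seed used for sampling, splitting and (in the synth
#'   stage) scenario generation.
#' @param out output directory.
#' @param ... overrides, e.g. `sampling = list(block = 5)`.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, out = "degrisk_run", ...) {
  cfg <- list(
    seed = as.integer(seed),
    out = out,
    paths = list(cube = NULL, factors = NULL, wells = NULL, lulc = NULL,
                 zones = NULL),
    scenario = list(),
    flag_weights = as.list(defaultFlagWeights()),
    smoother = list(half_window = 4L, poly_order = 2L, envelope_iters = 2L,
                    weight_decay = 0.5),
    season = list(start = "04-01", end = "10-31"),
    thresholds = list(p_high = 0.05, p_medium = 0.10),
    kriging = list(n_lags = 15L, max_dist = NULL, neighborhood = 16L,
                   apply_to = NULL),
    sampling = list(block = 3L),
    vif = list(threshold = 5),
    stepwise = list(alpha_remove = 0.05),
    validation = list(threshold = 0.5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipelineConfig()]; unspecified keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, c(list(seed = y$seed %||% 1L,
                                 out = y$out %||% "degrisk_run"),
                            y[setdiff(names(y), c("seed", "out"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "out")]), f)
  unname(tools::md5sum(f))
}

#' Run the two-stage degradation analysis
#'
#' Executes the requested stages in dependency order
#' (`synth -> preprocess -> trend -> model -> risk -> report`, with
#' `factors` independent of `preprocess`), reading upstream artifacts
#' from disk when a stage is rerun in isolation. Every stage writes its
#' artifacts under `config$out`; `report` writes a run manifest with the
#' seed, configuration hash and per-stage wall times.
#'
#' @param config a `pipelineConfig`.
#' @param stages subset of `c("synth", "preprocess", "trend", "factors",
#'   "model", "risk", "report")`.
#' @return invisibly, a list with the run manifest and the in-memory
#'   stage results.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("synth", "preprocess", "trend", "factors",
                                   "model", "risk", "report")) {
  order_all <- c("synth", "preprocess", "trend", "factors", "model", "risk",
                 "report")
  stages <- order_all[order_all %in% stages]
  if (!length(stages)) stop("no recognised stage requested")
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ctx <- new.env(parent = emptyenv())
  timings <- list()
  artifacts <- character(0)
  note <- function(p) artifacts <<- c(artifacts, p)

  path_or <- function(key, fallback) {
    p <- config$paths[[key]]
    if (!is.null(p)) p else fallback
  }

  for (st in stages) {
    t0 <- Sys.time()
    message("[degrisk] stage: ", st)
    switch(st,
      synth = {
        scfg <- do.call(scenarioConfig,
                        c(config$scenario,
                          list(seed = config$seed)[!("seed" %in%
                                                     names(config$scenario))]))
        ctx$scenario <- makeScenario(scfg, file.path(out, "scenario"),
                                     overwrite = TRUE)
        note(file.path(out, "scenario"))
      },
      preprocess = {
        cube_dir <- path_or("cube", file.path(out, "scenario", "cube"))
        if (!file.exists(file.path(cube_dir, "dates.csv")))
          stop("no cube at ", cube_dir, "; run synth first or set paths$cube")
        cube <- readCubeDir(cube_dir)
        cube <- screenQuality(cube, unlist(config$flag_weights))
        filled <- fillGaps(cube)
        sm <- config$smoother
        smoothed <- smoothCube(filled$cube, half_window = sm$half_window,
                               poly_order = sm$poly_order,
                               envelope_iters = sm$envelope_iters,
                               weight_decay = sm$weight_decay)
        ctx$sumstack <- seasonalSum(smoothed,
                                    seasonWindow(config$season$start,
                                                 config$season$end))
        writeSumStackDir(ctx$sumstack, file.path(out, "sumstack"))
        note(file.path(out, "sumstack"))
      },
      trend = {
        if (is.null(ctx$sumstack)) {
          d <- file.path(out, "sumstack")
          if (!file.exists(file.path(d, "years.csv")))
            stop("no seasonal-sum stack found; run preprocess first")
          ctx$sumstack <- readSumStackDir(d)
        }
        thr <- trendClassThresholds(config$thresholds$p_high,
                                    config$thresholds$p_medium)
        tr <- classifyTrend(fitPixelTrend(ctx$sumstack), thr)
        ctx$trend <- tr
        ctx$degraded <- binarizeDegraded(tr)
        dir.create(file.path(out, "trend"), showWarnings = FALSE)
        writeRaster(tr@slope, file.path(out, "trend", "slope.tif"))
        writeRaster(tr@pValue, file.path(out, "trend", "pvalue.tif"))
        writeRaster(tr@classMap, file.path(out, "trend", "class.tif"),
                    datatype = "uint8", nodata = 255)
        writeRaster(ctx$degraded, file.path(out, "trend", "degraded.tif"),
                    datatype = "uint8", nodata = 255)
        eps <- endpointSensitivity(ctx$sumstack, thr)
        jsonlite::write_json(
          list(agreement_drop_first = eps$agreement_drop_first,
               agreement_drop_last = eps$agreement_drop_last),
          file.path(out, "trend", "endpoint.json"),
          auto_unbox = TRUE, digits = NA)
        zones_path <- path_or("zones", file.path(out, "scenario",
                                                 "zones.tif"))
        if (file.exists(zones_path)) {
          zones <- readRaster(zones_path)
          write.csv(zonalAreaStats(tr, zones),
                    file.path(out, "trend", "areal_stats.csv"),
                    row.names = FALSE)
        }
        note(file.path(out, "trend"))
      },
      factors = {
        fdir <- path_or("factors", file.path(out, "scenario", "factors"))
        if (!file.exists(file.path(fdir, "manifest.csv")))
          stop("no factor stack at ", fdir,
               "; run synth first or set paths$factors")
        stack <- readFactorDir(fdir)
        kr <- config$kriging
        wells_path <- path_or("wells", file.path(out, "scenario",
                                                 "wells.csv"))
        if (!is.null(kr$apply_to) && file.exists(wells_path)) {
          wells <- readWells(wells_path)
          vg <- fitSphericalVariogram(wells, n_lags = kr$n_lags,
                                      max_dist = kr$max_dist)
          kg <- krigeSpherical(wells, vg, stack@spec,
                               neighborhood = kr$neighborhood)
          stack@layers[[kr$apply_to]] <- kg@values
        }
        ctx$stack <- stack
      },
      model = {
        if (is.null(ctx$stack))
          stop("no factor stack loaded; run factors first")
        if (is.null(ctx$degraded)) {
          p <- file.path(out, "trend", "degraded.tif")
          if (!file.exists(p))
            stop("no degraded map found; run trend first")
          ctx$degraded <- readRaster(p)
        }
        samp <- blockSample(ctx$degraded, ctx$stack,
                            block = config$sampling$block,
                            seed = config$seed)
        samp <- splitCalibration(samp, seed = config$seed + 1L)
        vs <- vifScreen(samp, threshold = config$vif$threshold)
        calib <- samp[samp$split == "calibration", ]
        valid <- samp[samp$split == "validation", ]
        attr(calib, "predictors") <- attr(valid, "predictors") <- vs$retained
        full <- fitLogistic(calib, predictors = vs$retained)
        step <- backwardStepwise(calib,
                                 alpha_remove = config$stepwise$alpha_remove,
                                 predictors = vs$retained)
        cmp <- compareAUC(full, step, valid)
        chosen <- if (cmp$recommended == "a") full else step
        rep_v <- validateFit(chosen, valid,
                             threshold = config$validation$threshold)
        dir.create(file.path(out, "model"), showWarnings = FALSE)
        write.csv(samp, file.path(out, "model", "sample.csv"),
                  row.names = FALSE)
        write.csv(vs$vif, file.path(out, "model", "vif.csv"),
                  row.names = FALSE)
        write.csv(fitReport(full), file.path(out, "model", "model_full.csv"),
                  row.names = FALSE)
        write.csv(fitReport(step),
                  file.path(out, "model", "model_stepwise.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
          c(cmp[c("auc_a", "auc_b", "diff", "z", "p", "recommended")],
            list(chosen = if (cmp$recommended == "a") "full" else
                 "stepwise")),
          file.path(out, "model", "comparison.json"),
          auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(
          rep_v[c("auc", "pcp", "chi_square", "chi_df", "chi_p",
                  "threshold", "n")],
          file.path(out, "model", "validation.json"),
          auto_unbox = TRUE, digits = NA)
        ctx$sample <- samp; ctx$vif <- vs; ctx$fit_full <- full
        ctx$fit_step <- step; ctx$fit <- chosen; ctx$validation <- rep_v
        note(file.path(out, "model"))
      },
      risk = {
        if (is.null(ctx$stack))
          stop("no factor stack loaded; run factors first")
        if (is.null(ctx$fit)) {
          p <- file.path(out, "model", "model_full.csv")
          if (!file.exists(p))
            stop("no fitted model found; run model first")
          tab <- read.csv(p)
          fit <- list(coef = setNames(tab$coefficient, tab$variable),
                      predictors = setdiff(tab$variable, "(Intercept)"))
          class(fit) <- "logisticFit"
          ctx$fit <- fit
        }
        rm_ <- riskDeciles(ctx$fit, ctx$stack)
        dir.create(file.path(out, "risk"), showWarnings = FALSE)
        writeRaster(rm_$classes, file.path(out, "risk", "risk_classes.tif"),
                    datatype = "uint8", nodata = 255)
        writeRaster(rm_$probability,
                    file.path(out, "risk", "risk_probability.tif"))
        ctx$risk <- rm_
        note(file.path(out, "risk"))
      },
      report = {
        manifest <- list(
          package = "degrisk",
          version = as.character(utils::packageVersion("degrisk")),
          r_version = R.version.string,
          seed = config$seed,
          config_hash = .config_hash(config),
          stages = stages,
          wall_seconds = lapply(timings, function(x) round(x, 3)),
          artifacts = artifacts
        )
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        note(file.path(out, "manifest.json"))
      }
    )
    timings[[st]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  invisible(list(timings = timings, artifacts = artifacts,
                 context = as.list(ctx)))
}
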