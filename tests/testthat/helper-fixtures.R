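# Shared fixtures, built in code.

tiny_spec <- function(nr = 5, nc = 5, cs = 250)
  gridSpec(nr, nc, originX = 0, originY = nr * cs, cellSize = cs,
           crs = "test-utm")

random_grid <- function(nr = 10, nc = 10, seed = 1, na_frac = 0) {
  set.seed(seed)
  v <- matrix(rnorm(nr * nc), nr, nc)
  if (na_frac > 0)
    v[sample(length(v), round(na_frac * length(v)))] <- NA
  newGrid(tiny_spec(nr, nc), v)
}

# small synthetic cube: constant baseline + mid-season pulse, no trend
flat_cube <- function(nr = 3, nc = 3, years = 2000:2010, value = 0.5) {
  spec <- tiny_spec(nr, nc)
  dates <- degrisk:::.composite_dates(years, 23L)
  vals <- array(value, c(length(dates), nr, nc))
  ndviCube(spec, dates, vals)
}

# one small default scenario reused across test files (generated once)
.scen_cache <- new.env()
small_scenario <- function() {
  if (is.null(.scen_cache$sc)) {
    cfg <- scenarioConfig(n_rows = 40, n_cols = 40, seed = 42)
    ff <- makeFactorFields(cfg)
    lab <- makeDegradationLabels(ff$stack, seed = 44)
    nd <- makeNdviCube(cfg, lab$labels)
    .scen_cache$sc <- list(cfg = cfg, stack = ff$stack, truth = ff$truth,
                           geography = ff$geography, lulc = ff$lulc,
                           labels = lab$labels, prevalence = lab$prevalence,
                           probability = lab$probability,
                           cube = nd$cube, true_slope = nd$true_slope)
  }
  .scen_cache$sc
}
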