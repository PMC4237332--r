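# 1x3 chain A -> B -> C(sink): D8 code 1 = drain east.
chain_grid <- function(pop = c(0, 5, 10), runoff = c(1, 1, 1)) {
  flow_grid(
    ddir = raster_grid(matrix(c(1, 1, 0), 1, 3), semantics = "D8 code"),
    runoff = raster_grid(matrix(runoff, 1, 3)),
    landcover = raster_grid(matrix(1, 1, 3)),
    population = raster_grid(matrix(pop, 1, 3)),
    quality = c(forest = 1))
}

test_that("downstream_population matches the hand-walked chain", {
  pd <- downstream_population(chain_grid())
  expect_equal(as.vector(pd$values), c(15, 10, 0))
  incl <- downstream_population(chain_grid(), inclusive = TRUE)
  expect_equal(as.vector(incl$values), c(15, 15, 10))
  zero <- downstream_population(chain_grid(pop = c(0, 0, 0)))
  expect_true(all(zero$values == 0))
})

test_that("quality weighting multiplies runoff by the class coefficient", {
  fg <- flow_grid(
    ddir = raster_grid(matrix(c(1, 0), 1, 2)),
    runoff = raster_grid(matrix(c(10, 10), 1, 2)),
    landcover = raster_grid(matrix(c(2, 4), 1, 2)),
    population = raster_grid(matrix(0, 1, 2)),
    quality = c(forest = 1, shrub = 0.6, crop = 0.4, urban = 0))
  w <- quality_weighted_runoff(fg)
  expect_equal(as.vector(w$values), c(6, 0))

  expect_error(
    flow_grid(ddir = raster_grid(matrix(c(1, 0), 1, 2)),
              runoff = raster_grid(matrix(1, 1, 2)),
              landcover = raster_grid(matrix(c(1, 9), 1, 2)),
              population = raster_grid(matrix(0, 1, 2)),
              quality = c(forest = 1)),
    class = "psrb_quality_config_error")
})

test_that("cycles and off-grid drainage are rejected", {
  # two cells pointing at each other: E then W
  expect_error(
    flow_grid(ddir = raster_grid(matrix(c(1, 16), 1, 2)),
              runoff = raster_grid(matrix(1, 1, 2)),
              landcover = raster_grid(matrix(1, 1, 2)),
              population = raster_grid(matrix(0, 1, 2)),
              quality = c(forest = 1)),
    class = "psrb_d8_cycle_error")
  expect_error(
    flow_grid(ddir = raster_grid(matrix(c(16, 0), 1, 2)),
              runoff = raster_grid(matrix(1, 1, 2)),
              landcover = raster_grid(matrix(1, 1, 2)),
              population = raster_grid(matrix(0, 1, 2)),
              quality = c(forest = 1)),
    class = "psrb_d8_input_error")
})

test_that("downstream_population matches the path-walk oracle on random grids", {
  for (seed in 1:4) {
    cfg <- scenario_config(seed = seed, grid_shape = c(15L, 20L))
    ls <- gen_landscape(cfg)
    fg <- flow_grid(ls$grids$ddir, ls$grids$runoff, ls$grids$landcover,
                    ls$grids$population)
    pd <- downstream_population(fg)
    expect_equal(pd$values,
                 oracle_downstream_pop(ls$grids$ddir, ls$grids$population))
  }
})

test_that("runoff mass is conserved at the sinks when quality is 1", {
  cfg <- scenario_config(seed = 23L, grid_shape = c(50L, 50L))
  ls <- gen_landscape(cfg)
  fg <- flow_grid(ls$grids$ddir, ls$grids$runoff, ls$grids$landcover,
                  ls$grids$population,
                  quality = c(a = 1, b = 1, c = 1, d = 1))
  acc <- flow_accumulation(fg)
  sinks <- ls$grids$ddir$values == 0
  expect_equal(sum(acc$values[sinks]), sum(ls$grids$runoff$values),
               tolerance = 1e-9)
})

test_that("provision index normalises to [0, 1] and anchors the maximum", {
  idx <- provision_index(chain_grid())
  expect_equal(max(idx$values), 1)
  expect_equal(as.vector(idx$values), c(1, 10 / 15, 0))

  # no downstream population anywhere -> identically zero, message logged
  expect_message(z <- provision_index(chain_grid(pop = c(0, 0, 0))),
                 "identically zero")
  expect_true(all(z$values == 0))
})

test_that("index is invariant to positive rescaling of runoff", {
  cfg <- scenario_config(seed = 31L, grid_shape = c(12L, 12L))
  ls <- gen_landscape(cfg)
  fg1 <- flow_grid(ls$grids$ddir, ls$grids$runoff, ls$grids$landcover,
                   ls$grids$population)
  scaled <- ls$grids$runoff
  scaled$values <- scaled$values * 37.5
  fg2 <- flow_grid(ls$grids$ddir, scaled, ls$grids$landcover,
                   ls$grids$population)
  expect_equal(provision_index(fg1)$values, provision_index(fg2)$values)
})

test_that("unit means of the index behave like zonal means", {
  uni <- raster_grid(matrix(0.4, 3, 3))
  expect_equal(unit_mean_provision(uni, matrix(TRUE, 3, 3)), 0.4)
  two <- raster_grid(matrix(c(0.2, 0.6), 1, 2))
  expect_equal(unit_mean_provision(two, matrix(TRUE, 1, 2)), 0.4)
})
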