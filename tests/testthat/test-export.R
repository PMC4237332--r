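scenario_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "psrb-export-scn")
      write_scenario(gen_scenario(tiny_config(seed = 19L)), dir)
      cache <<- compute_indicators(dir, n_boot = 30L, seed = 4L)
    }
    cache
  }
})

test_that("record table has one row per unit x indicator, regions first", {
  res <- scenario_results()
  rec <- res$records
  expect_equal(nrow(rec), length(res$units) * 5L)
  expect_false(any(duplicated(rec[, c("unit_id", "indicator")])))
  lv <- rec$unit_level
  expect_true(all(which(lv == "region") < min(which(lv == "country"))))
  # freshwater never has a trend; rli trend carries the 0.001 scale
  expect_true(all(is.na(rec$trend_value[rec$indicator == "freshwater"])))
  expect_true(all(rec$trend_scale[rec$indicator == "rli"] == 0.001))
})

test_that("forest-only assembly yields records for just that indicator", {
  res <- scenario_results()
  only <- build_indicator_table(res$units, forest = res$forest)
  expect_equal(nrow(only), length(res$units))
  expect_true(all(only$indicator == "forest"))
  expect_error(build_indicator_table(res$units),
               class = "psrb_assembly_error")
  expect_error(build_indicator_table(res$units, forest = res$forest,
                                     kba = data.frame(
                                       unit_id = res$forest$unit_id,
                                       baseline_2010 = 1,
                                       annual_rate = 0)[c(1, 1), ]),
               class = "psrb_assembly_error")
})

test_that("CSV export preserves module outputs bit-for-bit", {
  res <- scenario_results()
  outdir <- withr::local_tempdir()
  export_products(res$records, res$units, series = res$kba$series,
                  outdir = outdir, formats = "csv")
  back <- utils::read.csv(file.path(outdir, "indicator_table.csv"),
                          stringsAsFactors = FALSE)
  expect_identical(back$baseline_value, res$records$baseline_value)
  expect_identical(back$trend_value, res$records$trend_value)
})

test_that("JSON feed round-trips losslessly and export is deterministic", {
  res <- scenario_results()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_products(res$records, res$units, series = res$kba$series,
                  outdir = d1, formats = c("csv", "geojson", "json"))
  export_products(res$records, res$units, series = res$kba$series,
                  outdir = d2, formats = c("csv", "geojson", "json"))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  feed <- read_dashboard_feed(file.path(d1, "dashboard_feed.json"))
  expect_equal(feed$records$baseline_value, res$records$baseline_value)
  expect_equal(feed$records$trend_value, res$records$trend_value)
  expect_equal(feed$series$mean_pct, res$kba$series$mean_pct)

  cho <- jsonlite::read_json(file.path(d1, "choropleth_forest.geojson"))
  expect_equal(length(cho$features), length(res$units))
})

test_that("empty record set exports a header-only CSV", {
  res <- scenario_results()
  empty <- res$records[0, , drop = FALSE]
  outdir <- withr::local_tempdir()
  export_products(empty, res$units, outdir = outdir, formats = "csv")
  lines <- readLines(file.path(outdir, "indicator_table.csv"))
  expect_equal(length(lines), 1L)
  expect_match(lines, "^unit_id,")
  expect_error(export_products(empty, res$units, outdir = outdir,
                               formats = "xlsx"),
               class = "psrb_format_error")
})

test_that("the CLI drives simulate -> compute -> export", {
  wd <- withr::local_tempdir()
  cfgfile <- file.path(wd, "cfg.yaml")
  writeLines(c("seed: 5", "n_boot: 20",
               "scenario:", "  n_units: 2", "  grid_shape: [10, 10]",
               "  n_kba: 4", "  n_pa: 6", "  survey_n: 4",
               "  n_species_per_taxon:",
               "    mammal: 5", "    bird: 5", "    amphibian: 5"),
             cfgfile)
  scn_dir <- file.path(wd, "scenario"); res_dir <- file.path(wd, "results")
  expect_equal(
    suppressMessages(psrb_main(c("simulate", "--config", cfgfile,
                                 "--out", scn_dir))), 0L)
  expect_true(file.exists(file.path(scn_dir, "cover2000.asc")))
  expect_equal(
    suppressMessages(psrb_main(c("compute", "--config", cfgfile,
                                 "--inputs", scn_dir, "--out", res_dir))),
    0L)
  expect_true(file.exists(file.path(res_dir, "dashboard_feed.json")))
  expect_equal(
    suppressMessages(psrb_main(c("export", "--results", res_dir,
                                 "--formats", "csv,geojson,png"))), 0L)
  expect_true(any(grepl("^protection_.*png$", list.files(res_dir))))
  expect_equal(suppressMessages(psrb_main(character(0))), 1L)
})
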