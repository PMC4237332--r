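# Dashboard assembly: one tidy record per analysis unit x indicator
# (baseline + trend), choropleth GeoJSON, a machine-readable JSON feed and
# trend charts. Missing values stay explicit (NA / null), never silent
# zeros; the freshwater indicator has no trend by construction (single
# time step), and the RLI trend is exported in units of 1e-3 per year with
# an explicit scale field.

INDICATOR_NAMES <- c("forest", "rli", "kba_protection", "freshwater",
                     "survey_score")

record_row <- function(unit_id, unit_level, indicator, baseline_value,
                       baseline_year, trend_value = NA_real_,
                       trend_start = NA_integer_, trend_end = NA_integer_,
                       trend_scale = 1) {
  data.frame(unit_id = unit_id, unit_level = unit_level,
             indicator = indicator, baseline_value = baseline_value,
             baseline_year = baseline_year, trend_value = trend_value,
             trend_start = trend_start, trend_end = trend_end,
             trend_scale = trend_scale, stringsAsFactors = FALSE)
}

#' Assemble indicator outputs into the dashboard record table
#'
#' Takes whichever module outputs are available and produces one row per
#' unit x indicator. RLI rows use the combined ("all") taxon and report
#' the trend in units of `1e-3`/yr (`trend_scale = 0.001`); survey rows
#' average the per-indicator monitoring scores per unit.
#'
#' @param units a [unit_set()] (defines `unit_level` per id).
#' @param forest output of [forest_indicator()], or `NULL`.
#' @param rli output of [rli_indicator()], or `NULL`.
#' @param kba `summary` element of [kba_indicator()], or `NULL`.
#' @param freshwater output of [freshwater_indicator()], or `NULL`.
#' @param survey output of [survey_scores()], or `NULL`.
#' @return data.frame of indicator records.
#' @export
build_indicator_table <- function(units, forest = NULL, rli = NULL,
                                  kba = NULL, freshwater = NULL,
                                  survey = NULL) {
  if (is.null(forest) && is.null(rli) && is.null(kba) &&
      is.null(freshwater) && is.null(survey))
    psrb_stop("no module output supplied", "assembly")
  level_of <- vapply(units, function(u) u$level, character(1))
  lv <- function(id) {
    out <- unname(level_of[id])
    out[is.na(out)] <- "country"
    out
  }
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  if (!is.null(forest))
    add(record_row(forest$unit_id, lv(forest$unit_id), "forest",
                   forest$mean_cover_2000, 2000L, forest$annual_rate,
                   2000L, 2005L))
  if (!is.null(rli)) {
    comb <- rli[rli$taxon == "all", , drop = FALSE]
    add(record_row(comb$unit_id, lv(comb$unit_id), "rli", comb$rli_last,
                   2008L, comb$annual_change / 0.001, 1980L, 2008L,
                   trend_scale = 0.001))
  }
  if (!is.null(kba))
    add(record_row(kba$unit_id, lv(kba$unit_id), "kba_protection",
                   kba$baseline_2010, 2010L, kba$annual_rate, 1980L, 2010L))
  if (!is.null(freshwater))
    add(record_row(freshwater$unit_id, lv(freshwater$unit_id), "freshwater",
                   freshwater$mean_index, 2010L))
  if (!is.null(survey)) {
    agg <- stats::aggregate(score ~ unit_id, data = survey, FUN = mean)
    add(record_row(agg$unit_id, lv(agg$unit_id), "survey_score", agg$score,
                   2012L))
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[, c("unit_id", "indicator")]))
    psrb_stop("duplicate unit x indicator rows", "assembly")
  # regions in separate rows ahead of countries, stable within level
  out <- out[order(match(out$unit_level, c("region", "country")),
                   out$unit_id, match(out$indicator, INDICATOR_NAMES)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

write_records_csv <- function(records, path) {
  df <- records
  for (col in c("baseline_value", "trend_value", "trend_scale"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

export_choropleths <- function(records, units, outdir) {
  for (ind in unique(records$indicator)) {
    sub <- records[records$indicator == ind, , drop = FALSE]
    feats <- lapply(units, function(u) {
      row <- sub[sub$unit_id == u$id, , drop = FALSE]
      list(type = "Feature",
           properties = list(
             id = u$id, name = u$name, level = u$level,
             indicator = ind,
             baseline_value = if (nrow(row) && !is.na(row$baseline_value))
               row$baseline_value else NULL,
             trend_value = if (nrow(row) && !is.na(row$trend_value))
               row$trend_value else NULL),
           geometry = geom_to_geojson(u$geometry))
    })
    write_geojson_raw(feature_collection(unname(feats)),
                      file.path(outdir, sprintf("choropleth_%s.geojson", ind)))
  }
}

plot_protection_series <- function(series, path) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(series$year, series$mean_pct, type = "l", lwd = 2,
                 ylim = c(0, 100), xlab = "Year",
                 ylab = "Mean KBA protection (%)",
                 main = sprintf("Protected-area coverage of KBAs - %s",
                                series$unit_id[1]))
  graphics::lines(series$year, series$ci_low, lty = 2)
  graphics::lines(series$year, series$ci_high, lty = 2)
}

#' Export the dashboard data products
#'
#' Writes, per requested format: `indicator_table.csv` (regions in separate
#' rows ahead of countries; full precision, no rounding),
#' `protection_series.csv`, one choropleth GeoJSON per indicator, a JSON
#' feed for a web front end (losslessly re-readable via
#' [read_dashboard_feed()]), and per-unit KBA trend charts (solid mean,
#' dashed 95% bootstrap band). File naming is deterministic.
#'
#' @param records output of [build_indicator_table()].
#' @param units a [unit_set()].
#' @param series row-bound protection series (from [kba_indicator()]`$series`),
#'   or `NULL`.
#' @param outdir output directory, created if needed.
#' @param formats subset of `c("csv", "geojson", "json", "png")`.
#' @return character vector of files written, invisibly.
#' @export
export_products <- function(records, units, series = NULL, outdir,
                            formats = c("csv", "geojson", "json")) {
  unknown <- setdiff(formats, c("csv", "geojson", "json", "png"))
  if (length(unknown))
    psrb_stop(sprintf("unknown format token(s): %s",
                      paste(unknown, collapse = ", ")), "format")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if ("csv" %in% formats) {
    write_records_csv(records, file.path(outdir, "indicator_table.csv"))
    if (!is.null(series))
      utils::write.csv(series, file.path(outdir, "protection_series.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  if ("geojson" %in% formats) export_choropleths(records, units, outdir)
  if ("json" %in% formats) {
    feed <- list(
      generated_by = "psrbdash",
      conventions = list(
        rli_trend_scale = 0.001,
        rli_combined = "pooled species multiset",
        gfcl_denominator = "annual rate is percent of 2000 forest baseline",
        freshwater = "relative index, single time step, no trend"),
      records = records,
      series = series)
    jsonlite::write_json(feed, file.path(outdir, "dashboard_feed.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  }
  if ("png" %in% formats && !is.null(series)) {
    for (uid in unique(series$unit_id))
      plot_protection_series(series[series$unit_id == uid, , drop = FALSE],
                             file.path(outdir,
                                       sprintf("protection_%s.png", uid)))
  }
  invisible(list.files(outdir, full.names = TRUE))
}

#' Read a dashboard JSON feed back into records and series
#'
#' @param path path to `dashboard_feed.json`.
#' @return list with `records`, `series`, `conventions`.
#' @export
read_dashboard_feed <- function(path) {
  feed <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- as.data.frame(feed$records, stringsAsFactors = FALSE)
  ser <- if (!is.null(feed$series))
    as.data.frame(feed$series, stringsAsFactors = FALSE) else NULL
  list(records = rec, series = ser, conventions = feed$conventions)
}

#' Run the full indicator pipeline on a scenario directory
#'
#' Reads the standard input files from `dir` (see [write_scenario()]),
#' computes the requested indicators and returns the assembled record
#' table plus per-module outputs.
#'
#' @param dir input directory.
#' @param indicators subset of
#'   `c("forest", "rli", "kba", "freshwater", "survey")`.
#' @param n_boot bootstrap replicates for the KBA series.
#' @param seed RNG seed for the bootstrap.
#' @param quality land-cover quality coefficients.
#' @return list with `records`, `units`, and the raw per-module outputs.
#' @export
compute_indicators <- function(dir,
                               indicators = c("forest", "rli", "kba",
                                              "freshwater", "survey"),
                               n_boot = 1000L, seed = 1L,
                               quality = default_quality_coefficients()) {
  inp <- read_scenario(dir)
  units <- inp$units
  region_of <- local({
    m <- vapply(units, function(u)
      if (u$level == "country") u$parent_region else NA_character_,
      character(1))
    m[!is.na(m)]
  })
  forest <- rli <- kba <- fresh <- survey <- NULL
  if ("forest" %in% indicators)
    forest <- forest_indicator(inp$grids$cover2000, inp$grids$loss, units)
  if ("rli" %in% indicators)
    rli <- rli_indicator(inp$assessments, units)
  if ("kba" %in% indicators)
    kba <- kba_indicator(units, inp$kbas, inp$pas, n_boot = n_boot,
                         seed = seed)
  if ("freshwater" %in% indicators) {
    fg <- flow_grid(inp$grids$ddir, inp$grids$runoff, inp$grids$landcover,
                    inp$grids$population, quality = quality)
    fresh <- freshwater_indicator(fg, units)
  }
  if ("survey" %in% indicators)
    survey <- survey_scores(inp$responses, region_of = region_of)
  records <- build_indicator_table(
    units, forest = forest, rli = rli,
    kba = if (is.null(kba)) NULL else kba$summary,
    freshwater = fresh, survey = survey)
  list(records = records, units = units, forest = forest, rli = rli,
       kba = kba, freshwater = fresh, survey = survey)
}
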