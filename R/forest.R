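# Pressure indicator: forest cover (2000 baseline) and gross forest cover
# loss (GFCL) 2000-2005, annualised against the 2000 baseline. GFCL is
# unidirectional: deforestation only, no credit for regrowth or plantation.

#' Mean percent forest cover over a unit
#'
#' @param cover2000 [raster_grid()] of percent forest cover per cell (2000).
#' @param mask logical unit mask from [rasterize_unit()].
#' @return mean percent cover in `[0, 100]`.
#' @export
mean_forest_cover <- function(cover2000, mask) zonal_mean(cover2000, mask)

#' Mean gross forest cover loss over a unit
#'
#' Loss is stored as percent of cell area deforested over 2000-2005 and must
#' be non-negative everywhere (unidirectional change).
#'
#' @param loss [raster_grid()] of percent-of-cell-area loss, 2000-2005.
#' @param mask logical unit mask.
#' @return mean percent-of-area loss.
#' @export
mean_gfcl <- function(loss, mask) {
  live <- loss$values[!is_nodata(loss)]
  if (length(live) && min(live) < 0)
    psrb_stop("GFCL grid contains negative loss; loss is unidirectional",
              "gfcl_negative")
  zonal_mean(loss, mask)
}

#' Annual forest loss rate from the 2000 baseline
#'
#' Converts the five-year area loss into an annual percentage of the 2000
#' forest baseline: `100 * (loss_area / cover_2000) / 5`. Both arguments are
#' in percent of land area, so their ratio is the fraction of the baseline
#' forest removed over the five years.
#'
#' @param mean_gfcl_area mean loss, percent of land area over 2000-2005.
#' @param mean_cover_2000 mean percent forest cover in 2000; must be > 0.
#' @return percent of 2000 forest baseline lost per year.
#' @export
annual_loss_rate <- function(mean_gfcl_area, mean_cover_2000) {
  if (mean_gfcl_area < 0)
    psrb_stop("loss must be non-negative", "gfcl_negative")
  if (mean_cover_2000 <= 0)
    psrb_stop("zero forest baseline: annual loss rate undefined",
              "undefined_rate")
  100 * (mean_gfcl_area / mean_cover_2000) / 5
}

#' Forest pressure indicator for a set of units
#'
#' Runs the full pressure pathway per unit. A unit with zero baseline cover
#' gets `NA` for the rate (reported missing, never zero).
#'
#' @param cover2000,loss aligned [raster_grid()]s (percent cover; percent
#'   area loss).
#' @param units a [unit_set()].
#' @return data.frame with columns `unit_id`, `mean_cover_2000`,
#'   `mean_gfcl`, `annual_rate`.
#' @export
forest_indicator <- function(cover2000, loss, units) {
  if (!same_geometry(cover2000, loss))
    psrb_stop("cover and loss grids are not aligned", "raster_input")
  rows <- lapply(units, function(u) {
    mask <- rasterize_unit(u, cover2000)
    cov <- mean_forest_cover(cover2000, mask)
    gf <- mean_gfcl(loss, mask)
    rate <- if (cov > 0) annual_loss_rate(gf, cov) else NA_real_
    data.frame(unit_id = u$id, mean_cover_2000 = cov, mean_gfcl = gf,
               annual_rate = rate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
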