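#' Rasterize an analysis unit onto a template grid
#'
#' A cell belongs to the unit iff its center lies inside the unit geometry
#' (binary center rule; partial boundary cells are not area-weighted, in
#' keeping with the coarse resolution of the source grids).
#'
#' @param unit a [spatial_unit()].
#' @param template a [raster_grid()] defining the cell layout.
#' @return logical matrix aligned with `template$values`.
#' @export
rasterize_unit <- function(unit, template) {
  cc <- cell_centers(template)
  inside <- point_in_polygon(as.vector(cc$x), as.vector(cc$y), unit$geometry)
  mask <- matrix(inside, nrow(template$values), ncol(template$values))
  if (!any(mask))
    psrb_stop(sprintf("unit '%s' covers no cell center of the template grid",
                      unit$id), "empty_mask")
  mask
}

#' Zonal mean of a raster over a mask
#'
#' Arithmetic mean over masked, non-nodata cells; nodata cells are excluded
#' from numerator and denominator alike.
#'
#' @param grid a [raster_grid()].
#' @param mask logical matrix aligned with `grid$values`.
#' @return scalar mean in the grid's units.
#' @export
zonal_mean <- function(grid, mask) {
  if (!is.logical(mask) || !identical(dim(mask), dim(grid$values)))
    psrb_stop("mask must be a logical matrix aligned with the grid",
              "zonal_input")
  vals <- grid$values[mask & !is_nodata(grid)]
  if (!length(vals))
    psrb_stop("all masked cells are nodata: zonal mean undefined",
              "undefined_mean")
  mean(vals)
}
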