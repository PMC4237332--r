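#' Rectangular raster grid
#'
#' A minimal regular, axis-aligned raster: a numeric matrix plus the
#' georeference needed for zonal work. Row 1 of `values` is the top
#' (northernmost) row, matching the ESRI ASCII grid layout. `origin` is the
#' outer corner of the lower-left cell (`xllcorner`, `yllcorner`).
#'
#' @param values numeric matrix; `nodata` marks missing cells.
#' @param cell_size edge length of a (square) cell, in map units.
#' @param origin numeric length-2, lower-left outer corner `c(x, y)`.
#' @param nodata sentinel value for missing cells.
#' @param semantics free-text tag describing the field, e.g.
#'   `"percent forest cover"` or `"D8 code"`. Grids tagged as percentages
#'   are validated to lie in `[0, 100]`.
#'
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(0:3, 2, 2), cell_size = 10)
#' dim(g$values)
#' @export
raster_grid <- function(values, cell_size = 1, origin = c(0, 0),
                        nodata = -9999, semantics = "") {
  if (!is.matrix(values) || !is.numeric(values))
    psrb_stop("`values` must be a numeric matrix", "raster_input")
  storage.mode(values) <- "double"  # .asc round-trips are double-typed
  if (nrow(values) < 1L || ncol(values) < 1L)
    psrb_stop("grid must be at least 1x1", "raster_input")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    psrb_stop("`cell_size` must be a positive scalar", "raster_input")
  if (length(origin) != 2L || !is.numeric(origin))
    psrb_stop("`origin` must be c(x, y)", "raster_input")
  live <- values[values != nodata]
  if (any(!is.finite(live)))
    psrb_stop("non-nodata cells must be finite", "raster_input")
  if (grepl("percent", semantics, ignore.case = TRUE) &&
      length(live) && (min(live) < 0 || max(live) > 100))
    psrb_stop("percent-semantics grid has values outside [0, 100]",
              "raster_input")
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), nodata = nodata,
         semantics = semantics),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid %dx%d cell=%g origin=(%g, %g) nodata=%g '%s'>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$nodata, x$semantics))
  invisible(x)
}

#' Logical matrix of nodata cells
#' @param grid a [raster_grid()].
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
is_nodata <- function(grid) grid$values == grid$nodata

#' Cell-center coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @return list with matrices `x` and `y`, aligned with `grid$values`.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  x <- matrix(grid$origin[1] + (seq_len(nc) - 0.5) * cs, nr, nc, byrow = TRUE)
  y <- matrix(grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs, nr, nc)
  list(x = x, y = y)
}

#' Check two grids share the same geometry
#' @keywords internal
#' @noRd
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by rows from
#' north to south. The nodata sentinel is honoured bit-exactly.
#'
#' @param path file path.
#' @param semantics semantics tag to attach (not stored in the format).
#' @return a [raster_grid()].
#' @export
read_asc <- function(path, semantics = "") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+\\S+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    psrb_stop(sprintf("malformed .asc header in %s", path), "asc_format")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    psrb_stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
              "asc_format")
  raster_grid(matrix(vals, nr, nc, byrow = TRUE), cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata,
              semantics = semantics)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so a write/read cycle is
#' lossless for doubles.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2]),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
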