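# Benefit indicator: relative quality-weighted freshwater provision. Each
# cell's credit is its land-cover-quality-weighted runoff times the human
# population strictly downstream of it along D8 drainage directions,
# normalised by the run-wide maximum. Values are relative: comparable only
# within one run, and only a single (baseline) time step exists.

# ESRI D8 codes: 1=E, 2=SE, 4=S, 8=SW, 16=W, 32=NW, 64=N, 128=NE, 0=sink.
D8_CODES <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
D8_DROW <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DCOL <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Default land-cover quality coefficients
#'
#' Quality of runoff originating from each land-cover class, on `[0, 1]`:
#' intact forest delivers the cleanest water, urban surfaces the least.
#' Fully user-overridable.
#'
#' @return named numeric vector (class -> coefficient).
#' @export
default_quality_coefficients <- function() {
  c(forest = 1.0, shrub = 0.7, crop = 0.4, urban = 0.1)
}

# Column-major index of each cell's receiving neighbor; NA marks a sink.
flow_targets <- function(ddir) {
  v <- ddir$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- which(!is.na(v))
  nxt <- rep(NA_integer_, nr * nc)
  code <- as.integer(v)
  bad <- !(code %in% c(0L, D8_CODES))
  if (any(bad))
    psrb_stop(sprintf("invalid D8 codes: %s",
                      paste(unique(code[bad]), collapse = ", ")),
              "d8_input")
  for (k in seq_along(D8_CODES)) {
    sel <- which(code == D8_CODES[k])
    if (!length(sel)) next
    r <- ((sel - 1L) %% nr) + 1L
    c0 <- ((sel - 1L) %/% nr) + 1L
    r2 <- r + D8_DROW[k]; c2 <- c0 + D8_DCOL[k]
    off <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
    if (any(off))
      psrb_stop("D8 cell drains off the grid edge", "d8_input")
    nxt[sel] <- (c2 - 1L) * nr + r2
  }
  nxt
}

# Steps-to-sink per cell; errors on cycles. Memoized path walking: each
# cell is resolved once, so total work is linear in the grid size.
flow_depth <- function(nxt) {
  n <- length(nxt)
  depth <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(depth[start])) next
    path <- integer(0); c0 <- start
    repeat {
      if (length(path) > n || (length(path) && c0 %in% path))
        psrb_stop("cycle detected in D8 drainage directions", "d8_cycle")
      if (!is.na(depth[c0])) break            # reached a resolved cell
      if (is.na(nxt[c0])) { depth[c0] <- 0L; break }  # reached a sink
      path <- c(path, c0)
      c0 <- nxt[c0]
    }
    d <- depth[c0]
    for (p in rev(path)) {
      d <- d + 1L
      depth[p] <- d
    }
  }
  depth
}

#' Bundle the freshwater-provision input grids
#'
#' Validates alignment of the four grids, the D8 directions (acyclic, no
#' off-grid drainage), non-negative runoff and population, and that every
#' land-cover class present has a quality coefficient.
#'
#' @param ddir [raster_grid()] of D8 codes (0 = sink).
#' @param runoff [raster_grid()] of runoff per cell (volume/area), >= 0.
#' @param landcover [raster_grid()] of land-cover classes; values are
#'   matched against `names(quality)` (numeric classes are matched against
#'   the coefficient vector positionally by class code).
#' @param population [raster_grid()] of persons per cell, >= 0.
#' @param quality named numeric vector of quality coefficients on `[0, 1]`;
#'   defaults to [default_quality_coefficients()].
#' @return object of class `flow_grid`.
#' @export
flow_grid <- function(ddir, runoff, landcover, population,
                      quality = default_quality_coefficients()) {
  for (g in list(runoff, landcover, population))
    if (!same_geometry(ddir, g))
      psrb_stop("flow grids are not mutually aligned", "raster_input")
  if (min(runoff$values) < 0 || min(population$values) < 0)
    psrb_stop("runoff and population must be non-negative", "flow_input")
  if (any(quality < 0 | quality > 1))
    psrb_stop("quality coefficients must lie in [0, 1]", "quality_input")
  classes <- sort(unique(as.vector(landcover$values)))
  codes <- seq_along(quality)
  if (!all(classes %in% codes))
    psrb_stop(sprintf(
      "land-cover classes without a quality coefficient: %s",
      paste(setdiff(classes, codes), collapse = ", ")), "quality_config")
  nxt <- flow_targets(ddir)
  flow_depth(nxt) # errors on cycles
  structure(list(ddir = ddir, runoff = runoff, landcover = landcover,
                 population = population, quality = quality, nxt = nxt),
            class = "flow_grid")
}

#' Quality-weighted runoff per cell
#'
#' `w(c) = quality(landcover(c)) * runoff(c)`.
#'
#' @param fg a [flow_grid()].
#' @return [raster_grid()] of weighted runoff.
#' @export
quality_weighted_runoff <- function(fg) {
  q <- unname(fg$quality)[as.integer(fg$landcover$values)]
  g <- fg$runoff
  g$values <- matrix(q, nrow(g$values), ncol(g$values)) * g$values
  g$semantics <- "quality-weighted runoff"
  g
}

#' Population strictly downstream of each cell
#'
#' Sums the population of every cell on the flow path below a cell,
#' excluding the cell itself (strict reading of "downstream"); set
#' `inclusive = TRUE` to count the cell's own population too.
#'
#' @param fg a [flow_grid()].
#' @param inclusive include the cell's own population.
#' @return [raster_grid()] of downstream population.
#' @export
downstream_population <- function(fg, inclusive = FALSE) {
  nxt <- fg$nxt
  depth <- flow_depth(nxt)
  pop <- as.vector(fg$population$values)
  pd <- numeric(length(pop))
  for (i in order(depth)) {
    if (is.na(nxt[i])) next  # sink: nothing downstream
    pd[i] <- pd[nxt[i]] + pop[nxt[i]]
  }
  if (inclusive) pd <- pd + pop
  g <- fg$population
  g$values <- matrix(pd, nrow(g$values), ncol(g$values))
  g$semantics <- "downstream population"
  g
}

# Runoff accumulation at each cell (own runoff + everything upstream);
# used for the mass-conservation consistency check.
flow_accumulation <- function(fg, field = quality_weighted_runoff(fg)) {
  nxt <- fg$nxt
  depth <- flow_depth(nxt)
  acc <- as.vector(field$values)
  for (i in order(depth, decreasing = TRUE)) {
    if (is.na(nxt[i])) next
    acc[nxt[i]] <- acc[nxt[i]] + acc[i]
  }
  g <- field
  g$values <- matrix(acc, nrow(g$values), ncol(g$values))
  g$semantics <- "flow accumulation"
  g
}

#' Relative freshwater provision index per cell
#'
#' `index(c) = quality-weighted runoff(c) * downstream population(c)`,
#' divided by the run-wide maximum so the field lies on `[0, 1]`. An
#' all-zero field is returned unnormalised (with a message): there is
#' nothing to scale against.
#'
#' @param fg a [flow_grid()].
#' @param inclusive passed to [downstream_population()].
#' @return [raster_grid()] of the dimensionless index.
#' @export
provision_index <- function(fg, inclusive = FALSE) {
  w <- quality_weighted_runoff(fg)
  pd <- downstream_population(fg, inclusive = inclusive)
  raw <- w$values * pd$values
  mx <- max(raw)
  if (mx == 0) {
    message("provision index is identically zero; skipping normalization")
  } else {
    raw <- raw / mx
  }
  g <- w
  g$values <- raw
  g$semantics <- "freshwater provision index"
  g
}

#' Mean provision index per unit
#'
#' @param index per-cell index grid from [provision_index()].
#' @param mask logical unit mask.
#' @return scalar mean index.
#' @export
unit_mean_provision <- function(index, mask) zonal_mean(index, mask)

#' Freshwater benefit indicator for a set of units
#'
#' @param fg a [flow_grid()].
#' @param units a [unit_set()].
#' @param inclusive passed to [downstream_population()].
#' @return data.frame with columns `unit_id`, `mean_index`.
#' @export
freshwater_indicator <- function(fg, units, inclusive = FALSE) {
  idx <- provision_index(fg, inclusive = inclusive)
  rows <- lapply(units, function(u) {
    m <- rasterize_unit(u, idx)
    data.frame(unit_id = u$id, mean_index = unit_mean_provision(idx, m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
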