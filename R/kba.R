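# Response indicator: mean percent protected-area (PA) coverage of key
# biodiversity areas (KBAs), its 1950-2010 time series, and the 1980-2010
# annual rate. Undated PAs get establishment years imputed by resampling
# known same-country dates; the imputation is bootstrapped to a percentile
# 95% band. PAs only accumulate (no degazettement), so every replicate
# series is monotone non-decreasing in year.

PROTECTION_YEARS <- 1950:2010

#' Decompose a KBA site into PA-coverage cells
#'
#' Internal workhorse shared by the single-year percent and the bootstrap
#' series: partitions the site into pieces of known area, each labelled with
#' the indices of the PAs covering it. Axis-aligned rectangles (the
#' synthetic world) are handled exactly via coordinate compression; general
#' polygons fall back to a deterministic dense point-sampling estimate.
#'
#' @param site a [kba_site()].
#' @param pas list of [protected_area()].
#' @param n_sample per-axis sample density for the general-polygon fallback.
#' @return list with `site_area`, `areas` (vector), `members` (list of PA
#'   index vectors, parallel to `areas`).
#' @keywords internal
#' @noRd
coverage_cells <- function(site, pas, n_sample = 128L) {
  rect_world <- is_axis_rect(site$geometry) &&
    all(vapply(pas, function(p) is_axis_rect(p$geometry), logical(1)))
  if (rect_world) {
    sb <- geom_bbox(site$geometry)
    rects <- Filter(Negate(is.null),
                    lapply(pas, function(p) rect_clip(geom_bbox(p$geometry), sb)))
    kept <- which(!vapply(lapply(pas, function(p)
      rect_clip(geom_bbox(p$geometry), sb)), is.null, logical(1)))
    site_area <- (sb[3] - sb[1]) * (sb[4] - sb[2])
    if (!length(rects))
      return(list(site_area = site_area, areas = numeric(0), members = list()))
    xs <- sort(unique(c(sb[c(1, 3)], unlist(lapply(rects, `[`, c(1, 3))))))
    ys <- sort(unique(c(sb[c(2, 4)], unlist(lapply(rects, `[`, c(2, 4))))))
    cx <- (xs[-1] + xs[-length(xs)]) / 2
    cy <- (ys[-1] + ys[-length(ys)]) / 2
    wx <- diff(xs); wy <- diff(ys)
    areas <- list(); members <- list()
    for (i in seq_along(cx)) for (j in seq_along(cy)) {
      m <- kept[vapply(rects, function(r)
        cx[i] > r[1] && cx[i] < r[3] && cy[j] > r[2] && cy[j] < r[4],
        logical(1))]
      if (length(m)) {
        areas[[length(areas) + 1L]] <- wx[i] * wy[j]
        members[[length(members) + 1L]] <- m
      }
    }
    return(list(site_area = site_area, areas = unlist(areas, use.names = FALSE),
                members = members))
  }
  # general polygons: regular point lattice over the site bounding box
  sb <- geom_bbox(site$geometry)
  gx <- seq(sb[1], sb[3], length.out = n_sample + 1L)
  gy <- seq(sb[2], sb[4], length.out = n_sample + 1L)
  px <- rep((gx[-1] + gx[-length(gx)]) / 2, times = n_sample)
  py <- rep((gy[-1] + gy[-length(gy)]) / 2, each = n_sample)
  in_site <- point_in_polygon(px, py, site$geometry)
  px <- px[in_site]; py <- py[in_site]
  if (!length(px))
    psrb_stop(sprintf("site %s sampled zero interior points", site$site_id),
              "site_input")
  unit_area <- polygon_area(site$geometry) / length(px)
  cover <- vapply(pas, function(p) point_in_polygon(px, py, p$geometry),
                  logical(length(px)))
  cover <- matrix(cover, nrow = length(px))
  key <- apply(cover, 1L, function(b) paste(which(b), collapse = ";"))
  keep <- nzchar(key)
  tab <- table(key[keep])
  members <- lapply(names(tab), function(k)
    as.integer(strsplit(k, ";", fixed = TRUE)[[1]]))
  list(site_area = polygon_area(site$geometry),
       areas = as.numeric(tab) * unit_area, members = members)
}

#' Percent of a KBA covered by protected areas in a given year
#'
#' Only PAs with a known establishment year at or before `year` count; the
#' union of their footprints is taken, so overlapping PAs are never double
#' counted.
#'
#' @param site a [kba_site()].
#' @param pas list of [protected_area()].
#' @param year query year.
#' @return percent of site area in `[0, 100]`.
#' @export
kba_protection_percent <- function(site, pas, year = 2010) {
  est <- vapply(pas, function(p) p$establishment_year, integer(1))
  active <- pas[!is.na(est) & est <= year]
  cells <- coverage_cells(site, active)
  100 * sum(cells$areas) / cells$site_area
}

#' Select the KBA sites belonging to an analysis unit
#'
#' Country units match on `country_id`; region units collect the sites of
#' their member countries (resolved through `units` via `parent_region`).
#'
#' @param sites list of [kba_site()].
#' @param unit a [spatial_unit()] or a country id.
#' @param units the full [unit_set()], needed to resolve region membership.
#' @return sublist of `sites`.
#' @export
sites_in_unit <- function(sites, unit, units = NULL) {
  if (inherits(unit, "spatial_unit") && unit$level == "region") {
    if (is.null(units))
      psrb_stop("resolving a region's sites requires the full unit set",
                "unit_input")
    cids <- vapply(Filter(function(u)
      u$level == "country" && !is.na(u$parent_region) &&
        u$parent_region == unit$id, units),
      function(u) u$id, character(1))
  } else {
    cids <- if (inherits(unit, "spatial_unit")) unit$id else as.character(unit)
  }
  Filter(function(s) s$country_id %in% cids, sites)
}

#' Mean KBA protection over an analysis unit
#'
#' Unweighted mean of [kba_protection_percent()] over the unit's sites.
#'
#' @param unit a [spatial_unit()] or country id.
#' @param sites list of [kba_site()].
#' @param pas list of [protected_area()].
#' @param year query year.
#' @param units full [unit_set()] (needed for region units).
#' @return percent in `[0, 100]`.
#' @export
mean_protection <- function(unit, sites, pas, year = 2010, units = NULL) {
  mine <- sites_in_unit(sites, unit, units)
  if (!length(mine))
    psrb_stop("unit contains no KBA sites: mean protection undefined",
              "no_sites")
  mean(vapply(mine, kba_protection_percent, numeric(1), pas = pas,
              year = year))
}

known_year_pools <- function(pas) {
  est <- vapply(pas, function(p) p$establishment_year, integer(1))
  ctry <- vapply(pas, function(p) p$country_id, character(1))
  known <- !is.na(est)
  if (!any(known))
    psrb_stop("no protected area has a known establishment date",
              "no_known_dates")
  # pools sorted so imputation draws do not depend on PA input order
  list(by_country = lapply(split(est[known], ctry[known]), sort),
       global = sort(est[known]))
}

#' Impute missing PA establishment dates
#'
#' Each undated PA receives a year drawn uniformly, with replacement, from
#' the known establishment years of protected areas in the same country.
#' A country with no dated PAs falls back to the global pool of known
#' years (logged via `message`). PAs are processed in `pa_id` order so the
#' result does not depend on input order.
#'
#' @param pas list of [protected_area()].
#' @param seed integer RNG seed.
#' @return list of [protected_area()] with every `establishment_year` set.
#' @export
impute_establishment_dates <- function(pas, seed = 1L) {
  pools <- known_year_pools(pas)
  ord <- order(vapply(pas, function(p) p$pa_id, character(1)))
  with_seed(seed, {
    for (i in ord) {
      if (!is.na(pas[[i]]$establishment_year)) next
      pool <- pools$by_country[[pas[[i]]$country_id]]
      if (is.null(pool) || !length(pool)) {
        message(sprintf(
          "PA %s: no dated PAs in country %s; using global date pool",
          pas[[i]]$pa_id, pas[[i]]$country_id))
        pool <- pools$global
      }
      pas[[i]]$establishment_year <- pool[sample.int(length(pool), 1L)]
    }
  })
  pas
}

# Draw an n_boot x n_pa matrix of establishment years: known years repeated,
# unknown years resampled per replicate from the same-country known pool.
impute_year_matrix <- function(pas, n_boot, seed) {
  pools <- known_year_pools(pas)
  est <- vapply(pas, function(p) p$establishment_year, integer(1))
  Y <- matrix(rep(est, each = n_boot), n_boot, length(pas))
  ord <- order(vapply(pas, function(p) p$pa_id, character(1)))
  with_seed(seed, {
    for (i in ord) {
      if (!is.na(est[i])) next
      pool <- pools$by_country[[pas[[i]]$country_id]]
      if (is.null(pool) || !length(pool)) pool <- pools$global
      Y[, i] <- pool[sample.int(length(pool), n_boot, replace = TRUE)]
    }
  })
  Y
}

# Site protection series (percent) for every replicate: n_boot x n_years.
site_series_matrix <- function(site, pas, Y, years = PROTECTION_YEARS) {
  cells <- coverage_cells(site, pas)
  n_boot <- nrow(Y); ny <- length(years)
  bump <- matrix(0, n_boot, ny + 1L)
  for (k in seq_along(cells$areas)) {
    m <- cells$members[[k]]
    cov_year <- if (length(m) == 1L) Y[, m] else do.call(pmin, lapply(m, function(j) Y[, j]))
    idx <- pmax(1L, pmin(ny, cov_year - years[1] + 1L))
    ix <- cbind(seq_len(n_boot), idx)
    bump[ix] <- bump[ix] + cells$areas[k]
  }
  S <- t(apply(bump[, seq_len(ny), drop = FALSE], 1L, cumsum))
  if (n_boot == 1L) S <- matrix(S, 1L, ny)
  100 * S / cells$site_area
}

#' Bootstrap time series of mean KBA protection for one unit
#'
#' Repeats `n_boot` times: impute missing establishment dates with a fresh
#' sub-stream, then compute the unit's mean protection for every year
#' 1950-2010. Reports the per-year mean across replicates with percentile
#' 2.5/97.5 bounds; the band width reflects only the uncertainty arising
#' from the missing dates, so it has zero width when all dates are known.
#'
#' @param unit a [spatial_unit()] or country id.
#' @param sites list of [kba_site()].
#' @param pas list of [protected_area()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed; identical seeds give identical series.
#' @param units full [unit_set()] (for region units).
#' @return data.frame of class `protection_series` with columns `unit_id`,
#'   `year`, `mean_pct`, `ci_low`, `ci_high`; the replicate matrix
#'   (`n_boot` x years) is attached as attribute `"replicates"`.
#' @export
bootstrap_protection_series <- function(unit, sites, pas, n_boot = 1000L,
                                        seed = 1L, units = NULL) {
  if (n_boot < 1L) psrb_stop("n_boot must be >= 1", "bootstrap_input")
  mine <- sites_in_unit(sites, unit, units)
  if (!length(mine))
    psrb_stop("unit contains no KBA sites: series undefined", "no_sites")
  years <- PROTECTION_YEARS
  Y <- impute_year_matrix(pas, n_boot, seed)
  acc <- matrix(0, n_boot, length(years))
  for (s in mine) acc <- acc + site_series_matrix(s, pas, Y, years)
  acc <- acc / length(mine)
  uid <- if (inherits(unit, "spatial_unit")) unit$id else as.character(unit)
  out <- data.frame(
    unit_id = uid, year = years,
    mean_pct = colMeans(acc),
    ci_low = apply(acc, 2L, stats::quantile, probs = 0.025, names = FALSE),
    ci_high = apply(acc, 2L, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "replicates") <- acc
  attr(out, "n_boot") <- n_boot
  class(out) <- c("protection_series", class(out))
  out
}

#' Annual rate of change in KBA protection, 1980-2010
#'
#' @param series a `protection_series` from
#'   [bootstrap_protection_series()] (must span 1980 and 2010).
#' @return percentage points per year.
#' @export
protection_annual_rate <- function(series) {
  if (!all(c(1980, 2010) %in% series$year))
    psrb_stop("series must cover 1980 and 2010", "series_input")
  (series$mean_pct[series$year == 2010] -
     series$mean_pct[series$year == 1980]) / 30
}

#' KBA response indicator for a set of units
#'
#' Full response pathway per unit: bootstrap series, 2010 baseline and
#' 1980-2010 annual rate. Units with no sites are reported missing (`NA`),
#' never zero.
#'
#' @param units a [unit_set()].
#' @param sites list of [kba_site()].
#' @param pas list of [protected_area()].
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `summary` (data.frame `unit_id`, `baseline_2010`,
#'   `annual_rate`) and `series` (row-bound series of all units).
#' @export
kba_indicator <- function(units, sites, pas, n_boot = 1000L, seed = 1L) {
  sums <- list(); sers <- list()
  for (u in units) {
    res <- tryCatch(
      bootstrap_protection_series(u, sites, pas, n_boot, seed, units = units),
      psrb_no_sites_error = function(e) NULL)
    if (is.null(res)) {
      sums[[length(sums) + 1L]] <- data.frame(
        unit_id = u$id, baseline_2010 = NA_real_, annual_rate = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    sums[[length(sums) + 1L]] <- data.frame(
      unit_id = u$id,
      baseline_2010 = res$mean_pct[res$year == 2010],
      annual_rate = protection_annual_rate(res), stringsAsFactors = FALSE)
    sers[[length(sers) + 1L]] <- as.data.frame(res)
  }
  list(summary = do.call(rbind, sums),
       series = if (length(sers)) do.call(rbind, sers) else NULL)
}
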