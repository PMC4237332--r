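#' Spatial analysis unit
#'
#' An analysis unit is the entity indicators are disaggregated to: a region
#' (e.g. a multi-country basin complex) or a country. Countries may carry a
#' `parent_region` id; a country belongs to at most one region.
#'
#' @param id short unique identifier.
#' @param name display name.
#' @param level `"region"` or `"country"`.
#' @param geometry ring matrix or list of ring matrices (even-odd rule).
#' @param parent_region id of the containing region, or `NA`.
#' @return object of class `spatial_unit`.
#' @export
spatial_unit <- function(id, name, level, geometry, parent_region = NA_character_) {
  level <- match.arg(level, c("region", "country"))
  structure(list(id = as.character(id), name = as.character(name),
                 level = level, geometry = as_rings(geometry),
                 parent_region = as.character(parent_region)),
            class = "spatial_unit")
}

#' @export
print.spatial_unit <- function(x, ...) {
  cat(sprintf("<spatial_unit %s '%s' (%s)%s>\n", x$id, x$name, x$level,
              if (!is.na(x$parent_region))
                paste0(" in ", x$parent_region) else ""))
  invisible(x)
}

#' Collect spatial units into a validated set
#'
#' @param ... `spatial_unit` objects, or a single list of them.
#' @return list of units (class `unit_set`), names set to unit ids.
#' @export
unit_set <- function(...) {
  units <- list(...)
  if (length(units) == 1L && !inherits(units[[1]], "spatial_unit"))
    units <- units[[1]]
  ids <- vapply(units, function(u) u$id, character(1))
  if (anyDuplicated(ids))
    psrb_stop("duplicate unit ids in unit set", "unit_input")
  names(units) <- ids
  structure(units, class = "unit_set")
}

ring_to_coords <- function(ring) {
  ring <- open_ring(ring)
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, 1:2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p)[1:2])))
  open_ring(m)
}

geom_to_geojson <- function(geom) {
  list(type = "Polygon", coordinates = lapply(as_rings(geom), ring_to_coords))
}

geojson_to_geom <- function(g) {
  if (g$type == "Polygon") {
    lapply(g$coordinates, coords_to_ring)
  } else if (g$type == "MultiPolygon") {
    unlist(lapply(g$coordinates, function(poly) lapply(poly, coords_to_ring)),
           recursive = FALSE)
  } else {
    psrb_stop(sprintf("unsupported geometry type '%s'", g$type),
              "geojson_format")
  }
}

feature_collection <- function(features) {
  list(type = "FeatureCollection", features = features)
}

write_geojson_raw <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a unit set as a GeoJSON FeatureCollection
#'
#' Properties carried per feature: `id`, `name`, `level`, `parent_region`.
#'
#' @param units a [unit_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(units, function(u) {
    list(type = "Feature",
         properties = list(id = u$id, name = u$name, level = u$level,
                           parent_region = if (is.na(u$parent_region)) NULL
                                           else u$parent_region),
         geometry = geom_to_geojson(u$geometry))
  })
  write_geojson_raw(feature_collection(unname(feats)), path)
}

#' Read a unit set from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with properties `id`, `name`,
#'   `level`, optional `parent_region`.
#' @return a [unit_set()].
#' @export
read_units_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  units <- lapply(fc$features, function(f) {
    p <- f$properties
    spatial_unit(p$id, p$name, p$level, geojson_to_geom(f$geometry),
                 parent_region = if (is.null(p$parent_region)) NA_character_
                                 else p$parent_region)
  })
  unit_set(units)
}

#' Key biodiversity area site
#'
#' @param site_id identifier.
#' @param kind `"IBA"` (important bird & biodiversity area) or `"AZE"`
#'   (alliance for zero extinction site).
#' @param country_id id of the country the site lies in.
#' @param geometry ring matrix or list of rings; must have positive area.
#' @return object of class `kba_site`.
#' @export
kba_site <- function(site_id, kind, country_id, geometry) {
  kind <- match.arg(kind, c("IBA", "AZE"))
  geometry <- as_rings(geometry)
  if (polygon_area(geometry) <= 0)
    psrb_stop(sprintf("KBA site %s has zero area", site_id), "site_input")
  structure(list(site_id = as.character(site_id), kind = kind,
                 country_id = as.character(country_id), geometry = geometry),
            class = "kba_site")
}

#' Protected area polygon
#'
#' @param pa_id identifier.
#' @param country_id country id.
#' @param geometry ring matrix or list of rings.
#' @param establishment_year integer 1950-2010, or `NA` when the
#'   establishment date is unknown (to be imputed).
#' @return object of class `protected_area`.
#' @export
protected_area <- function(pa_id, country_id, geometry,
                           establishment_year = NA_integer_) {
  if (!is.na(establishment_year) &&
      (establishment_year < 1950L || establishment_year > 2010L))
    psrb_stop("establishment_year must lie in 1950-2010 when present",
              "pa_input")
  structure(list(pa_id = as.character(pa_id),
                 country_id = as.character(country_id),
                 geometry = as_rings(geometry),
                 establishment_year = as.integer(establishment_year)),
            class = "protected_area")
}

#' Write KBA sites to GeoJSON
#' @param sites list of [kba_site()].
#' @param path output path.
#' @export
write_kbas_geojson <- function(sites, path) {
  feats <- lapply(sites, function(s)
    list(type = "Feature",
         properties = list(site_id = s$site_id, kind = s$kind,
                           country_id = s$country_id),
         geometry = geom_to_geojson(s$geometry)))
  write_geojson_raw(feature_collection(unname(feats)), path)
}

#' Read KBA sites from GeoJSON
#' @param path input path.
#' @return list of [kba_site()].
#' @export
read_kbas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    p <- f$properties
    kba_site(p$site_id, p$kind, p$country_id, geojson_to_geom(f$geometry))
  })
}

#' Write protected areas to GeoJSON
#'
#' `establishment_year` is written as a nullable property.
#'
#' @param pas list of [protected_area()].
#' @param path output path.
#' @export
write_pas_geojson <- function(pas, path) {
  feats <- lapply(pas, function(p)
    list(type = "Feature",
         properties = list(pa_id = p$pa_id, country_id = p$country_id,
                           establishment_year =
                             if (is.na(p$establishment_year)) NULL
                             else p$establishment_year),
         geometry = geom_to_geojson(p$geometry)))
  write_geojson_raw(feature_collection(unname(feats)), path)
}

#' Read protected areas from GeoJSON
#' @param path input path.
#' @return list of [protected_area()].
#' @export
read_pas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    p <- f$properties
    protected_area(p$pa_id, p$country_id, geojson_to_geom(f$geometry),
                   establishment_year =
                     if (is.null(p$establishment_year)) NA_integer_
                     else as.integer(p$establishment_year))
  })
}
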