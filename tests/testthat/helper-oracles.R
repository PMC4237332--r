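# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check: explicit loops, path walks, Monte Carlo.

# Explicit-loop RLI: accumulate weights one species at a time.
oracle_rli <- function(categories) {
  w <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 5, EX = 5)
  s <- 0
  for (cat in categories) s <- s + w[[cat]]
  1 - s / (5 * length(categories))
}

# All multisets of size 1..max_n over the 7 weighted categories, as
# non-decreasing index vectors (stars and bars by recursion).
enum_multisets <- function(max_n, n_items = 7L) {
  out <- list()
  recurse <- function(prefix, start, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (i in start:n_items) recurse(c(prefix, i), i, left - 1L)
  }
  for (n in seq_len(max_n)) recurse(integer(0), 1L, n)
  out
}

# Brute-force downstream population: follow the D8 pointer from each cell
# to the sink, summing population along the way (excluding the start).
oracle_downstream_pop <- function(ddir_grid, pop_grid) {
  v <- ddir_grid$values
  nr <- nrow(v); nc <- ncol(v)
  codes <- c(1, 2, 4, 8, 16, 32, 64, 128)
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cr <- r; ccc <- cc; total <- 0; steps <- 0
    repeat {
      code <- v[cr, ccc]
      if (code == 0) break
      k <- match(code, codes)
      cr <- cr + drow[k]; ccc <- ccc + dcol[k]
      total <- total + pop_grid$values[cr, ccc]
      steps <- steps + 1
      if (steps > nr * nc) stop("oracle: path did not reach a sink")
    }
    out[r, cc] <- total
  }
  out
}

# Monte-Carlo protection percent: uniform points in the site polygon,
# fraction falling inside any active PA.
mc_protection_percent <- function(site, pas, year = 2010, n = 1e5,
                                  seed = 99L) {
  est <- vapply(pas, function(p) p$establishment_year, integer(1))
  active <- pas[!is.na(est) & est <= year]
  bb <- geom_bbox(site$geometry)
  set.seed(seed)
  px <- runif(n, bb[1], bb[3]); py <- runif(n, bb[2], bb[4])
  keep <- point_in_polygon(px, py, site$geometry)
  px <- px[keep]; py <- py[keep]
  if (!length(active)) return(0)
  inside <- rep(FALSE, length(px))
  for (p in active) inside <- inside | point_in_polygon(px, py, p$geometry)
  100 * mean(inside)
}

# Small, fast scenario for end-to-end tests; any field overridable.
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_units = 2L, grid_shape = c(12L, 12L),
               n_species_per_taxon = c(mammal = 8L, bird = 10L,
                                       amphibian = 6L),
               n_kba = 4L, n_pa = 8L, survey_n = 6L)
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

# Deterministic "truth" protection series: restore the withheld years from
# the ground-truth sidecar, then run the (now imputation-free) series.
true_protection_series <- function(unit, sites, pas, gt_years, units = NULL) {
  for (i in seq_along(pas)) {
    j <- match(pas[[i]]$pa_id, gt_years$pa_id)
    pas[[i]]$establishment_year <- as.integer(gt_years$year[j])
  }
  bootstrap_protection_series(unit, sites, pas, n_boot = 1L, seed = 1L,
                              units = units)
}
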