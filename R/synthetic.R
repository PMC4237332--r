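# Synthetic-data generators. Every pipeline input can be generated with
# known ground truth, so each indicator is testable end to end without
# external downloads. All generators are pure functions of (seed, config):
# each artifact draws from its own sub-stream, so adding a generator never
# shifts the draws of an existing one.

#' Scenario configuration for the synthetic generators
#'
#' Defaults describe a plausible tropical study area: three countries in
#' one region, ~45% mean forest cover, 0.5%/yr loss from the 2000 baseline,
#' a vertebrate fauna dominated by birds with ~5% of species undergoing a
#' genuine Red List category change between assessments, 30% of protected
#' areas lacking establishment dates, and questionnaire response
#' probabilities giving an expected monitoring score of 0.60 (see the
#' methods vignette for the provenance of each default).
#'
#' @param seed master RNG seed.
#' @param n_units number of country units (one region spans them all).
#' @param grid_shape `c(rows, cols)` of all generated grids.
#' @param cell_size cell edge in km (18.5, the forest product resolution).
#' @param forest_cover_mean mean percent forest cover per cell.
#' @param true_annual_loss_rate percent of the 2000 forest baseline lost
#'   per year; the loss grid is constructed so this is recoverable exactly.
#' @param n_species_per_taxon named counts for mammal, bird, amphibian.
#' @param category_change_prob probability a species carries one planted
#'   genuine category change.
#' @param n_kba,n_pa counts of key biodiversity areas / protected areas.
#' @param missing_date_fraction fraction of PAs whose establishment year is
#'   withheld (truth kept in the ground-truth sidecar).
#' @param survey_n questionnaire respondents per country.
#' @param survey_probs length-4 probabilities of Monitored, Limited
#'   Monitoring, Not Monitored, Unknown; must sum to 1.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_units = 3L,
                            grid_shape = c(30L, 30L),
                            cell_size = 18.5,
                            forest_cover_mean = 45,
                            true_annual_loss_rate = 0.5,
                            n_species_per_taxon = c(mammal = 30L, bird = 45L,
                                                    amphibian = 25L),
                            category_change_prob = 0.05,
                            n_kba = 8L,
                            n_pa = 12L,
                            missing_date_fraction = 0.3,
                            survey_n = 12L,
                            survey_probs = c(0.45, 0.30, 0.15, 0.10)) {
  stopifnot(length(grid_shape) == 2L, length(survey_probs) == 4L)
  if (n_units < 1L || n_kba < 1L || n_pa < 1L || survey_n < 1L ||
      any(n_species_per_taxon < 1L))
    psrb_stop("counts must be positive", "config")
  if (true_annual_loss_rate < 0)
    psrb_stop("loss rate must be non-negative", "config")
  if (forest_cover_mean < 0 || forest_cover_mean > 100)
    psrb_stop("forest_cover_mean must lie in [0, 100]", "config")
  if (category_change_prob < 0 || category_change_prob > 1 ||
      missing_date_fraction < 0 || missing_date_fraction > 1 ||
      any(survey_probs < 0) || any(survey_probs > 1))
    psrb_stop("probabilities must lie in [0, 1]", "config")
  if (abs(sum(survey_probs) - 1) > 1e-9)
    psrb_stop("survey_probs must sum to 1", "config")
  if (true_annual_loss_rate * 5 > 100)
    psrb_stop("five-year loss exceeds the whole baseline", "config")
  if (!is.null(names(n_species_per_taxon)) &&
      !setequal(names(n_species_per_taxon), c("mammal", "bird", "amphibian")))
    psrb_stop("n_species_per_taxon must be named mammal/bird/amphibian",
              "config")
  if (is.null(names(n_species_per_taxon)))
    names(n_species_per_taxon) <- c("mammal", "bird", "amphibian")
  structure(list(
    seed = as.integer(seed), n_units = as.integer(n_units),
    grid_shape = as.integer(grid_shape), cell_size = cell_size,
    forest_cover_mean = forest_cover_mean,
    true_annual_loss_rate = true_annual_loss_rate,
    n_species_per_taxon = n_species_per_taxon,
    category_change_prob = category_change_prob,
    n_kba = as.integer(n_kba), n_pa = as.integer(n_pa),
    missing_date_fraction = missing_date_fraction,
    survey_n = as.integer(survey_n), survey_probs = survey_probs),
    class = "scenario_config")
}

country_ids <- function(cfg) sprintf("U%d", seq_len(cfg$n_units))

# Country strips snap to whole columns so no cell center sits on a border.
strip_bounds <- function(cfg) {
  nc <- cfg$grid_shape[2]
  if (nc < cfg$n_units)
    psrb_stop("grid too small to host the requested units", "config")
  per <- floor(nc / cfg$n_units)
  starts <- (seq_len(cfg$n_units) - 1L) * per
  ends <- c(starts[-1], nc)
  cbind(start_col = starts, end_col = ends)
}

scenario_units <- function(cfg) {
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]; cs <- cfg$cell_size
  sb <- strip_bounds(cfg)
  countries <- lapply(seq_len(cfg$n_units), function(i)
    spatial_unit(sprintf("U%d", i), sprintf("Country %d", i), "country",
                 rect_ring(sb[i, 1] * cs, 0, sb[i, 2] * cs, nr * cs),
                 parent_region = "R1"))
  region <- spatial_unit("R1", "Region 1", "region",
                         rect_ring(0, 0, nc * cs, nr * cs))
  unit_set(c(list(region), countries))
}

#' Generate the landscape: grids and analysis units
#'
#' The loss grid is constructed so that the area fraction lost over the
#' five-year window equals `true_annual_loss_rate * 5 * cover2000 / 100`
#' cell by cell, making the annual rate recoverable exactly. The D8 grid
#' drains every cell one Chebyshev step closer to a single edge sink, which
#' guarantees acyclicity by construction.
#'
#' @param cfg a [scenario_config()].
#' @return list with `grids` (named list of [raster_grid()]:
#'   `cover2000`, `loss`, `landcover`, `runoff`, `ddir`, `population`),
#'   `units` (a [unit_set()]) and `ground_truth`.
#' @export
gen_landscape <- function(cfg) {
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]; n <- nr * nc
  cs <- cfg$cell_size
  units <- scenario_units(cfg)

  cover <- with_seed(sub_seed(cfg$seed, 1L), {
    v <- stats::rnorm(n, cfg$forest_cover_mean, 15)
    matrix(pmin(100, pmax(0, v)), nr, nc)
  })
  loss_m <- cfg$true_annual_loss_rate * 5 * cover / 100
  landcov <- with_seed(sub_seed(cfg$seed, 2L),
    matrix(sample.int(4L, n, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), nr, nc))
  runoff <- with_seed(sub_seed(cfg$seed, 3L),
    matrix(stats::rlnorm(n, log(50), 0.5), nr, nc))
  population <- with_seed(sub_seed(cfg$seed, 4L),
    matrix(round(stats::rlnorm(n, log(200), 1)), nr, nc))

  ddir <- with_seed(sub_seed(cfg$seed, 5L), {
    edge <- which(outer(seq_len(nr), seq_len(nc), function(r, c)
      r == 1L | r == nr | c == 1L | c == nc))
    sink <- edge[sample.int(length(edge), 1L)]
    sr <- ((sink - 1L) %% nr) + 1L; sc <- ((sink - 1L) %/% nr) + 1L
    m <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) for (c0 in seq_len(nc)) {
      if (r == sr && c0 == sc) next
      dr <- sign(sr - r); dc <- sign(sc - c0)
      # candidate steps that strictly reduce Chebyshev distance to the sink
      cand <- unique(list(c(dr, dc),
                          if (dr != 0) c(dr, 0L),
                          if (dc != 0) c(0L, dc)))
      cand <- Filter(Negate(is.null), cand)
      cand <- Filter(function(s) max(abs(sr - (r + s[1])),
                                     abs(sc - (c0 + s[2]))) <
                                  max(abs(sr - r), abs(sc - c0)), cand)
      s <- cand[[sample.int(length(cand), 1L)]]
      m[r, c0] <- D8_CODES[which(D8_DROW == s[1] & D8_DCOL == s[2])]
    }
    m
  })

  grids <- list(
    cover2000 = raster_grid(cover, cs, semantics = "percent forest cover"),
    loss = raster_grid(loss_m, cs, semantics = "percent area forest loss"),
    landcover = raster_grid(landcov, cs, semantics = "land cover class"),
    runoff = raster_grid(runoff, cs, semantics = "runoff"),
    ddir = raster_grid(ddir, cs, semantics = "D8 code"),
    population = raster_grid(population, cs, semantics = "population"))
  list(grids = grids, units = units,
       ground_truth = list(
         true_annual_loss_rate = cfg$true_annual_loss_rate,
         forest_cover_mean = cfg$forest_cover_mean))
}

RL_LADDER <- c("LC", "NT", "VU", "EN", "CR", "EW", "EX")

#' Generate a species assessment table with planted genuine changes
#'
#' Each species receives a taxon group (with the fixed assessment-year
#' pairs), a last-assessment category, membership in a random nonempty set
#' of countries (plus the region), and, with probability
#' `category_change_prob`, one genuine +/-1-category change whose driver is
#' localised to a subset of the species' units. The exact RLI at both
#' assessment dates per unit and taxon is emitted as a ground-truth
#' sidecar, computed directly from the planted categories.
#'
#' @param cfg a [scenario_config()].
#' @return list with `assessments` (data.frame) and `ground_truth`
#'   (data.frame `unit_id`, `taxon`, `rli_first`, `rli_last`).
#' @export
gen_species_table <- function(cfg) {
  cids <- country_ids(cfg)
  taxa <- rep(names(cfg$n_species_per_taxon), cfg$n_species_per_taxon)
  n <- length(taxa)
  w <- rl_category_weights()

  tab <- with_seed(sub_seed(cfg$seed, 10L), {
    cat_probs <- c(LC = 0.50, NT = 0.15, VU = 0.12, EN = 0.10, CR = 0.08,
                   EW = 0.02, EX = 0.03)
    last <- sample(names(cat_probs), n, replace = TRUE, prob = cat_probs)
    members <- lapply(seq_len(n), function(i) {
      m <- cids[stats::runif(cfg$n_units) < 0.4]
      if (!length(m)) m <- sample(cids, 1L)
      m
    })
    rows <- lapply(seq_len(n), function(i) {
      from <- ""; to <- ""; drivers <- ""
      if (stats::runif(1) < cfg$category_change_prob) {
        # the drawn category is the species' FIRST state; the genuine
        # change shifts it one ladder step, deteriorating 80% of the time
        # (declines dominate real assessments), flipped at the ladder ends
        pos <- match(last[i], RL_LADDER)
        worsen <- stats::runif(1) < 0.8
        if (worsen && pos == length(RL_LADDER)) worsen <- FALSE
        if (!worsen && pos == 1L) worsen <- TRUE
        from <- last[i]
        to <- if (worsen) RL_LADDER[pos + 1L] else RL_LADDER[pos - 1L]
        last[i] <- to
        dm <- members[[i]][stats::runif(length(members[[i]])) < 0.5]
        if (!length(dm)) dm <- sample(members[[i]], 1L)
        drivers <- paste(c(dm, "R1"), collapse = ";")
      }
      data.frame(
        species_id = sprintf("sp%04d", i), taxon = taxa[i],
        last_category = last[i],
        units = paste(c(members[[i]], "R1"), collapse = ";"),
        change_from = from, change_to = to, driver_units = drivers,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  # ground truth straight from the construction
  gt <- list()
  for (uid in c("R1", cids)) {
    member <- vapply(tab$units, function(u) uid %in% split_ids(u),
                     logical(1), USE.NAMES = FALSE)
    first_cat <- ifelse(
      nzchar(tab$change_from) &
        vapply(tab$driver_units, function(d) uid %in% split_ids(d),
               logical(1), USE.NAMES = FALSE),
      tab$change_from, tab$last_category)
    for (tx in c(names(cfg$n_species_per_taxon), "all")) {
      keep <- member & (if (tx == "all") TRUE else tab$taxon == tx)
      if (!sum(keep)) next
      gt[[length(gt) + 1L]] <- data.frame(
        unit_id = uid, taxon = tx,
        rli_first = 1 - sum(w[first_cat[keep]]) / (5 * sum(keep)),
        rli_last = 1 - sum(w[tab$last_category[keep]]) / (5 * sum(keep)),
        stringsAsFactors = FALSE)
    }
  }
  list(assessments = tab, ground_truth = do.call(rbind, gt))
}

#' Generate KBA sites and protected areas with known overlap fractions
#'
#' KBAs are rectangles inside country strips. Each PA is anchored to a KBA
#' and covers a known fraction of it from the left or right edge, so the
#' true union coverage of every site (and hence every country's 2010 mean
#' protection) is computable in closed form and stored as ground truth.
#' Establishment years are drawn uniformly from 1950-2010; a
#' `missing_date_fraction` share of PAs has the year withheld (truth kept).
#'
#' @param cfg a [scenario_config()].
#' @return list with `kbas`, `pas` (public, dates withheld), and
#'   `ground_truth` (`pa_years` with every true year, `site_truth` with the
#'   true 2010 coverage percent per site, `country_truth` with the true
#'   2010 mean protection per country).
#' @export
gen_sites <- function(cfg) {
  nr <- cfg$grid_shape[1]; cs <- cfg$cell_size
  sb <- strip_bounds(cfg)
  cids <- country_ids(cfg)
  height <- nr * cs

  # KBAs are kept pairwise disjoint (one horizontal band per site within
  # its country strip) so the true union coverage stays closed-form even
  # though PAs may spill sideways beyond their anchor site.
  ci_of <- ((seq_len(cfg$n_kba) - 1L) %% cfg$n_units) + 1L
  band_of <- stats::ave(seq_len(cfg$n_kba), ci_of, FUN = seq_along)
  bands_in <- table(ci_of)
  out <- with_seed(sub_seed(cfg$seed, 20L), {
    kbas <- lapply(seq_len(cfg$n_kba), function(k) {
      ci <- ci_of[k]
      x0 <- sb[ci, 1] * cs; x1 <- sb[ci, 2] * cs
      b0 <- (band_of[k] - 1L) / bands_in[[as.character(ci)]] * height
      b1 <- band_of[k] / bands_in[[as.character(ci)]] * height
      wmax <- (x1 - x0); hmax <- b1 - b0
      wdt <- stats::runif(1, 0.3, 0.8) * wmax
      hgt <- stats::runif(1, 0.3, 0.8) * hmax
      ox <- x0 + stats::runif(1, 0, wmax - wdt)
      oy <- b0 + stats::runif(1, 0, hmax - hgt)
      kba_site(sprintf("KBA%02d", k),
               if (stats::runif(1) < 0.85) "IBA" else "AZE",
               cids[ci], rect_ring(ox, oy, ox + wdt, oy + hgt))
    })
    frac <- numeric(0); side <- character(0); anchor <- integer(0)
    pas <- lapply(seq_len(cfg$n_pa), function(p) {
      k <- ((p - 1L) %% cfg$n_kba) + 1L
      bb <- geom_bbox(kbas[[k]]$geometry)
      f <- stats::runif(1, 0.1, 0.9)
      from_left <- stats::runif(1) < 0.5
      xs <- if (from_left) c(bb[1], bb[1] + f * (bb[3] - bb[1]))
            else c(bb[3] - f * (bb[3] - bb[1]), bb[3])
      frac[p] <<- f; side[p] <<- if (from_left) "L" else "R"
      anchor[p] <<- k
      protected_area(sprintf("PA%02d", p), kbas[[k]]$country_id,
                     rect_ring(xs[1], bb[2], xs[2], bb[4]),
                     establishment_year = sample(1950:2010, 1L))
    })
    list(kbas = kbas, pas = pas, frac = frac, side = side, anchor = anchor)
  })

  true_years <- vapply(out$pas, function(p) p$establishment_year, integer(1))
  n_missing <- floor(cfg$missing_date_fraction * cfg$n_pa)
  hide <- with_seed(sub_seed(cfg$seed, 21L),
                    sample.int(cfg$n_pa, n_missing))
  pas_public <- out$pas
  for (i in hide) pas_public[[i]]$establishment_year <- NA_integer_

  # true union coverage per site: left PAs cover [0, max fL], right PAs
  # cover [1 - max fR, 1]; the union is their (possibly overlapping) sum
  site_truth <- vapply(seq_len(cfg$n_kba), function(k) {
    mine <- which(out$anchor == k)
    fl <- max(c(0, out$frac[mine][out$side[mine] == "L"]))
    fr <- max(c(0, out$frac[mine][out$side[mine] == "R"]))
    100 * min(1, fl + fr)
  }, numeric(1))
  site_country <- vapply(out$kbas, function(s) s$country_id, character(1))
  country_truth <- tapply(site_truth, site_country, mean)

  list(kbas = out$kbas, pas = pas_public,
       ground_truth = list(
         pa_years = data.frame(
           pa_id = vapply(out$pas, function(p) p$pa_id, character(1)),
           year = true_years,
           withheld = seq_len(cfg$n_pa) %in% hide,
           stringsAsFactors = FALSE),
         site_truth = data.frame(
           site_id = vapply(out$kbas, function(s) s$site_id, character(1)),
           country_id = site_country, protected_pct_2010 = site_truth,
           stringsAsFactors = FALSE),
         country_truth = data.frame(
           country_id = names(country_truth),
           mean_protection_2010 = as.numeric(country_truth),
           stringsAsFactors = FALSE)))
}

#' Generate questionnaire responses with known response probabilities
#'
#' `survey_n` respondents per country answer the monitoring-status question
#' for each of the four indicators, drawn i.i.d. from `survey_probs`, and
#' name the scales they want monitored (site/national/watershed/
#' sub-national/regional, with field-realistic inclusion probabilities).
#'
#' @param cfg a [scenario_config()].
#' @return list with `responses` (data.frame) and `ground_truth`
#'   (`survey_probs` and the implied `expected_score`).
#' @export
gen_survey <- function(cfg) {
  cids <- country_ids(cfg)
  indicators <- c("forest", "rli", "kba_protection", "freshwater")
  scale_p <- c(regional = 0.65, national = 0.76, `sub-national` = 0.68,
               watershed = 0.71, site = 0.82)
  responses <- with_seed(sub_seed(cfg$seed, 30L), {
    rows <- list()
    for (ci in cids) {
      for (r in seq_len(cfg$survey_n)) {
        rid <- sprintf("%s-r%03d", ci, r)
        sector <- sample(c("public", "civil_society", "academic"), 1L,
                         prob = c(0.39, 0.45, 0.16))
        scales <- names(scale_p)[stats::runif(length(scale_p)) < scale_p]
        for (ind in indicators) {
          rows[[length(rows) + 1L]] <- data.frame(
            respondent_id = rid, country = ci, sector = sector,
            indicator = ind,
            status = sample(SURVEY_STATUSES, 1L, prob = cfg$survey_probs),
            scales = paste(scales, collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  list(responses = responses,
       ground_truth = list(
         survey_probs = cfg$survey_probs,
         expected_score = cfg$survey_probs[1] + 0.5 * cfg$survey_probs[2]))
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running all four generators.
#'
#' @param cfg a [scenario_config()].
#' @return list with `config`, `landscape`, `species`, `sites`, `survey`.
#' @export
gen_scenario <- function(cfg = scenario_config()) {
  list(config = cfg,
       landscape = gen_landscape(cfg),
       species = gen_species_table(cfg),
       sites = gen_sites(cfg),
       survey = gen_survey(cfg))
}

#' Write a scenario to disk in the pipeline's input formats
#'
#' Writes GeoJSON (units, KBAs, PAs), `.asc` grids, CSV tables (species,
#' survey) and a `ground_truth.json` sidecar.
#'
#' @param scn output of [gen_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_units_geojson(scn$landscape$units, p("units.geojson"))
  write_kbas_geojson(scn$sites$kbas, p("kbas.geojson"))
  write_pas_geojson(scn$sites$pas, p("pas.geojson"))
  for (nm in names(scn$landscape$grids))
    write_asc(scn$landscape$grids[[nm]], p(paste0(nm, ".asc")))
  write_species_csv(scn$species$assessments, p("species.csv"))
  write_survey_csv(scn$survey$responses, p("survey.csv"))
  gt <- list(landscape = scn$landscape$ground_truth,
             species = scn$species$ground_truth,
             sites = scn$sites$ground_truth,
             survey = scn$survey$ground_truth)
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a scenario directory back into memory
#'
#' Inverse of [write_scenario()] for the pipeline inputs (the ground-truth
#' sidecar is returned as parsed JSON).
#'
#' @param dir scenario directory.
#' @return list with `units`, `kbas`, `pas`, `grids`, `assessments`,
#'   `responses`, `ground_truth`.
#' @export
read_scenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  sem <- c(cover2000 = "percent forest cover",
           loss = "percent area forest loss",
           landcover = "land cover class", runoff = "runoff",
           ddir = "D8 code", population = "population")
  grids <- lapply(names(sem), function(nm)
    read_asc(p(paste0(nm, ".asc")), semantics = sem[[nm]]))
  names(grids) <- names(sem)
  list(units = read_units_geojson(p("units.geojson")),
       kbas = read_kbas_geojson(p("kbas.geojson")),
       pas = read_pas_geojson(p("pas.geojson")),
       grids = grids,
       assessments = read_species_csv(p("species.csv")),
       responses = read_survey_csv(p("survey.csv")),
       ground_truth = if (file.exists(p("ground_truth.json")))
         jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
       else NULL)
}
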