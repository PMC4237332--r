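# State indicator: Red List Index (RLI) of species survival. Categories are
# weighted LC=0, NT=1, VU=2, EN=3, CR=4, EW=5, EX=5 and the index is
# 1 - sum(weights) / (5 N): 1 when every species is Least Concern, 0 when
# every species is Extinct or Extinct in the Wild. Data Deficient and Not
# Evaluated species carry no weight and are excluded before computation.

#' Red List category weights
#'
#' Named integer vector over the seven weighted IUCN categories. `DD` and
#' `NE` are deliberately absent: they are excluded from the index.
#'
#' @return named integer vector.
#' @export
rl_category_weights <- function() {
  c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L, EW = 5L, EX = 5L)
}

#' First/last comprehensive assessment years per taxon
#'
#' Birds 1988 and 2008, mammals 1996 and 2008, amphibians 1980 and 2004.
#'
#' @return data.frame with columns `taxon`, `first_year`, `last_year`.
#' @export
assessment_years <- function() {
  data.frame(taxon = c("mammal", "bird", "amphibian"),
             first_year = c(1996L, 1988L, 1980L),
             last_year = c(2008L, 2008L, 2004L),
             stringsAsFactors = FALSE)
}

#' Red List Index of a category multiset
#'
#' @param categories character vector of weighted category codes
#'   (`LC`, `NT`, `VU`, `EN`, `CR`, `EW`, `EX`). `DD`/`NE` must already be
#'   filtered out and trigger a validation error here.
#' @return index in `[0, 1]`.
#' @examples
#' rli(rep("LC", 10)) # 1
#' rli(c("LC", "EN")) # 0.7
#' @export
rli <- function(categories) {
  if (!length(categories))
    psrb_stop("empty species set: RLI undefined", "undefined_rli")
  w <- rl_category_weights()
  bad <- setdiff(unique(categories), names(w))
  if (length(bad))
    psrb_stop(sprintf("unweighted or unknown categories present: %s",
                      paste(bad, collapse = ", ")), "rli_category")
  1 - sum(w[categories]) / (5 * length(categories))
}

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

validate_assessments <- function(assessments) {
  need <- c("species_id", "taxon", "last_category", "units",
            "change_from", "change_to", "driver_units")
  miss <- setdiff(need, names(assessments))
  if (length(miss))
    psrb_stop(sprintf("species table lacks columns: %s",
                      paste(miss, collapse = ", ")), "species_input")
  invisible(assessments)
}

#' Filter a species table to one analysis unit
#'
#' Keeps species whose range membership includes the unit and whose last
#' category is weighted (DD and NE dropped). Membership is binary: a species
#' spanning several units counts fully in each (range proportion is not
#' considered).
#'
#' @param assessments species table (see [read_species_csv()] for columns).
#' @param unit unit id (character) or [spatial_unit()].
#' @return subset of `assessments` (possibly zero rows).
#' @export
filter_species <- function(assessments, unit) {
  validate_assessments(assessments)
  uid <- if (inherits(unit, "spatial_unit")) unit$id else as.character(unit)
  member <- vapply(assessments$units, function(u) uid %in% split_ids(u),
                   logical(1), USE.NAMES = FALSE)
  weighted <- assessments$last_category %in% names(rl_category_weights())
  assessments[member & weighted, , drop = FALSE]
}

#' Back-cast categories to the first assessment date
#'
#' A species' first-assessment category equals its last category with its
#' genuine change reversed, but only when the driving process (threat or
#' conservation action) operated within the unit in question; a change
#' driven elsewhere, or no genuine change at all, leaves the last category
#' in place at the first date.
#'
#' @param assessments species table already filtered to the unit
#'   (see [filter_species()]).
#' @param unit unit id or [spatial_unit()].
#' @return character vector of first-assessment category codes.
#' @export
backcast_first_categories <- function(assessments, unit) {
  uid <- if (inherits(unit, "spatial_unit")) unit$id else as.character(unit)
  w <- names(rl_category_weights())
  vapply(seq_len(nrow(assessments)), function(i) {
    row <- assessments[i, ]
    from <- row$change_from
    if (is.na(from) || !nzchar(from)) return(row$last_category)
    if (!uid %in% split_ids(row$driver_units)) return(row$last_category)
    if (!(from %in% w) || !(row$change_to %in% w))
      psrb_stop(sprintf(
        "species %s: genuine change involves an unweighted category",
        row$species_id), "change_integrity")
    from
  }, character(1))
}

#' Annualised RLI change
#'
#' Divides the index difference by the years between the first and last
#' comprehensive assessments: 12 for mammals, 20 for birds, 24 for
#' amphibians. The combined (`"all"`) value uses the mean time difference
#' across the three groups, 56/3 years.
#'
#' @param rli_first,rli_last index values at the two assessments.
#' @param taxon `"mammal"`, `"bird"`, `"amphibian"`, or `"all"`.
#' @return change per year; negative values mean deterioration.
#' @export
annual_rli_change <- function(rli_first, rli_last, taxon = "all") {
  yrs <- assessment_years()
  dt <- yrs$last_year - yrs$first_year
  names(dt) <- yrs$taxon
  delta <- switch(taxon, all = mean(dt), {
    if (!taxon %in% names(dt))
      psrb_stop(sprintf("unknown taxon '%s'", taxon), "taxon_input")
    dt[[taxon]]
  })
  (rli_last - rli_first) / delta
}

#' Red List Index state indicator for a set of units
#'
#' For each unit: the per-taxon RLI at first and last assessment and the
#' annualised change, plus a combined `"all"` row over the pooled species
#' multiset (see the methods vignette for why pooled rather than
#' mean-of-taxa).
#'
#' @param assessments species table.
#' @param units a [unit_set()], or character vector of unit ids.
#' @return data.frame with columns `unit_id`, `taxon`, `n_species`,
#'   `rli_first`, `rli_last`, `annual_change`. Units or taxa with no
#'   weighted species get `NA` indices.
#' @export
rli_indicator <- function(assessments, units) {
  ids <- if (inherits(units, "unit_set"))
    vapply(units, function(u) u$id, character(1)) else as.character(units)
  taxa <- c(assessment_years()$taxon, "all")
  rows <- list()
  for (uid in ids) {
    sub <- filter_species(assessments, uid)
    first_all <- if (nrow(sub)) backcast_first_categories(sub, uid)
                 else character(0)
    for (tx in taxa) {
      keep <- if (tx == "all") rep(TRUE, nrow(sub)) else sub$taxon == tx
      n <- sum(keep)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, taxon = tx, n_species = 0L,
          rli_first = NA_real_, rli_last = NA_real_,
          annual_change = NA_real_, stringsAsFactors = FALSE)
        next
      }
      r1 <- rli(first_all[keep])
      r2 <- rli(sub$last_category[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = uid, taxon = tx, n_species = n,
        rli_first = r1, rli_last = r2,
        annual_change = annual_rli_change(r1, r2, tx),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a species assessment table from CSV
#'
#' Columns: `species_id`, `taxon` (mammal/bird/amphibian), `last_category`,
#' `units` (semicolon-separated unit ids), `change_from`, `change_to`,
#' `driver_units` (semicolon list; empty when there is no genuine change).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_species_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_assessments(df)
  df
}

#' Write a species assessment table to CSV
#' @param assessments species table.
#' @param path output path.
#' @export
write_species_csv <- function(assessments, path) {
  validate_assessments(assessments)
  utils::write.csv(assessments, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
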