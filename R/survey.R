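# Monitoring-capacity score from questionnaire responses. Respondents rate
# the national monitoring status of each indicator as Monitored, Limited
# Monitoring, Not Monitored, or Unknown; the score is P1 + 0.5 * P2 with P1
# the fraction answering Monitored and P2 the fraction answering Limited
# Monitoring, scaled 0 (not monitored) to 1 (monitored).

SURVEY_STATUSES <- c("Monitored", "LimitedMonitoring", "NotMonitored",
                     "Unknown")
SURVEY_SCALES <- c("regional", "national", "sub-national", "watershed",
                   "site")

#' Monitoring-capacity score for one country x indicator cell
#'
#' @param statuses character vector of status answers (one per respondent).
#' @param include_unknown keep "Unknown" answers in the denominator
#'   (default `TRUE`: P1 and P2 are fractions of all respondents). Set
#'   `FALSE` to score only respondents who expressed a status.
#' @return list with `score`, `p1`, `p2`, `n`.
#' @examples
#' monitoring_score(c("Monitored", "Monitored", "LimitedMonitoring",
#'                    "NotMonitored"))$score # 0.625
#' @export
monitoring_score <- function(statuses, include_unknown = TRUE) {
  bad <- setdiff(unique(statuses), SURVEY_STATUSES)
  if (length(bad))
    psrb_stop(sprintf("unknown survey statuses: %s",
                      paste(bad, collapse = ", ")), "survey_input")
  if (!include_unknown) statuses <- statuses[statuses != "Unknown"]
  n <- length(statuses)
  if (!n)
    psrb_stop("no responses: monitoring score undefined", "no_responses")
  p1 <- mean(statuses == "Monitored")
  p2 <- mean(statuses == "LimitedMonitoring")
  list(score = p1 + 0.5 * p2, p1 = p1, p2 = p2, n = n)
}

validate_survey <- function(responses) {
  need <- c("respondent_id", "country", "sector", "indicator", "status",
            "scales")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    psrb_stop(sprintf("survey table lacks columns: %s",
                      paste(miss, collapse = ", ")), "survey_input")
  invisible(responses)
}

#' Monitoring-capacity scores per country (or region) and indicator
#'
#' Region-level scores pool the respondents of member countries rather than
#' averaging country scores (respondent-pooled mode); pass a
#' `region_of` mapping to add region rows.
#'
#' @param responses survey table (see [read_survey_csv()]).
#' @param include_unknown see [monitoring_score()].
#' @param region_of optional named character vector, country -> region id;
#'   when given, pooled region rows are appended.
#' @return data.frame `unit_id`, `indicator`, `score`, `p1`, `p2`, `n`.
#' @export
survey_scores <- function(responses, include_unknown = TRUE,
                          region_of = NULL) {
  validate_survey(responses)
  groups <- split(responses,
                  list(responses$country, responses$indicator), drop = TRUE)
  if (!is.null(region_of)) {
    reg <- responses
    reg$country <- unname(region_of[reg$country])
    reg <- reg[!is.na(reg$country), , drop = FALSE]
    groups <- c(groups, split(reg, list(reg$country, reg$indicator),
                              drop = TRUE))
  }
  rows <- lapply(groups, function(g) {
    s <- monitoring_score(g$status, include_unknown = include_unknown)
    data.frame(unit_id = g$country[1], indicator = g$indicator[1],
               score = s$score, p1 = s$p1, p2 = s$p2, n = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$unit_id, out$indicator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preferred monitoring scales, as percentages of respondents
#'
#' Each respondent may name several scales, so the percentages need not sum
#' to 100. Scales are counted once per distinct respondent.
#'
#' @param responses survey table; `scales` is a semicolon-separated list.
#' @return data.frame `scale`, `percent` over the five canonical scales.
#' @export
scale_preferences <- function(responses) {
  validate_survey(responses)
  per_resp <- tapply(responses$scales, responses$respondent_id,
                     function(s) unique(unlist(lapply(s, split_ids))))
  n <- length(per_resp)
  if (!n) psrb_stop("no respondents", "no_responses")
  pct <- vapply(SURVEY_SCALES, function(sc)
    100 * sum(vapply(per_resp, function(v) sc %in% v, logical(1))) / n,
    numeric(1))
  data.frame(scale = SURVEY_SCALES, percent = unname(pct),
             stringsAsFactors = FALSE)
}

#' Read a survey response table from CSV
#'
#' Columns: `respondent_id`, `country`, `sector`, `indicator`, `status`,
#' `scales` (semicolon-separated).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_survey(df)
  df
}

#' Write a survey response table to CSV
#' @param responses survey table.
#' @param path output path.
#' @export
write_survey_csv <- function(responses, path) {
  validate_survey(responses)
  utils::write.csv(responses, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
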