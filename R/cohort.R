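# Cohort assembly: join risk and attribution results by PWSID, classify
# system size from the reported population, and apply the inclusion rules
# (wholesale exclusion, >500 population floor, +/-50% population agreement)
# with a full exclusion ledger.

size_class_levels <- c("very_small", "small", "medium", "large", "very_large")

#' Classify system size from reported population
#'
#' Standard service-population classes: 500 or fewer people is very small,
#' 501-3300 small, 3301-10,000 medium, 10,001-100,000 large, more than
#' 100,000 very large.
#'
#' @param reported_population Non-negative numeric vector.
#' @return A factor with levels very_small < small < medium < large <
#'   very_large.
#' @export
classify_size <- function(reported_population) {
  if (any(reported_population < 0, na.rm = TRUE)) {
    stop("negative reported population", call. = FALSE)
  }
  cut(reported_population,
      breaks = c(-Inf, 500, 3300, 10000, 100000, Inf),
      labels = size_class_levels,
      ordered_result = TRUE)
}

#' Join risk and attribution results by PWSID
#'
#' Inner join on `pwsid`; systems present in only one source are counted
#' and listed so no record disappears silently (flow-chart accounting).
#' Duplicate PWSIDs within a source are an error.
#'
#' @param risk_results Tibble keyed by `pwsid` (e.g. [cumulative_risk()]).
#' @param attribution_results Tibble keyed by `pwsid`
#'   (e.g. [population_agreement()] output).
#' @return A list with `matched` (joined tibble), `n_risk_only`,
#'   `n_attribution_only`, `risk_only`, `attribution_only`.
#' @export
match_datasets <- function(risk_results, attribution_results) {
  for (src in list(risk = risk_results, attribution = attribution_results)) {
    dup <- src$pwsid[duplicated(src$pwsid)]
    if (length(dup) > 0) {
      stop("duplicate pwsid within a source: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }
  matched <- dplyr::inner_join(risk_results, attribution_results, by = "pwsid")
  risk_only <- setdiff(risk_results$pwsid, attribution_results$pwsid)
  attr_only <- setdiff(attribution_results$pwsid, risk_results$pwsid)
  list(matched = dplyr::arrange(matched, .data$pwsid),
       n_risk_only = length(risk_only),
       n_attribution_only = length(attr_only),
       risk_only = risk_only,
       attribution_only = attr_only)
}

#' Apply the cohort inclusion rules
#'
#' Excludes, in this fixed order: non-community systems (when a
#' `system_type` column is present), wholesale systems (reported population
#' of zero), systems serving 500 or fewer people, and systems whose
#' tract-assigned population is outside +/-50% of the reported population.
#' Every excluded system is recorded in the ledger with its first failing
#' rule, so ledger counts plus included count always equal the input count.
#'
#' @param profiles Matched system profiles carrying `pwsid`,
#'   `reported_population` and `agreement_pass` (and optionally
#'   `system_type`).
#' @return A list with `cohort` (included systems, with `size_class` and
#'   flag columns added) and `exclusions` (tibble of `pwsid`, `rule`).
#' @export
apply_inclusion <- function(profiles) {
  p <- profiles
  rule <- rep(NA_character_, nrow(p))
  if ("system_type" %in% names(p)) {
    nc <- !is.na(p$system_type) & p$system_type == "non-community"
    rule[is.na(rule) & nc] <- "non_community"
  }
  rule[is.na(rule) & p$reported_population == 0] <- "wholesale"
  rule[is.na(rule) & p$reported_population <= 500] <- "population_le_500"
  agreement_fail <- is.na(p$agreement_pass) | !p$agreement_pass
  rule[is.na(rule) & agreement_fail] <- "agreement_outside_50pct"

  p$non_wholesale <- p$reported_population > 0
  p$pop_gt_500 <- p$reported_population > 500
  p$included <- is.na(rule)
  p$size_class <- classify_size(p$reported_population)

  exclusions <- tibble::tibble(pwsid = p$pwsid[!p$included],
                               rule = rule[!p$included])
  cohort <- p[p$included, , drop = FALSE]
  if (nrow(exclusions) > 0) {
    message(nrow(exclusions), " systems excluded (",
            paste(sprintf("%s: %d", names(table(exclusions$rule)),
                          as.integer(table(exclusions$rule))), collapse = ", "),
            ")")
  }
  list(cohort = cohort, exclusions = exclusions)
}

#' Build the analysis cohort from risk and attribution tables
#'
#' Convenience wrapper: [match_datasets()] then [apply_inclusion()].
#'
#' @inheritParams match_datasets
#' @return A list with `cohort`, `exclusions`, `n_matched`, `n_risk_only`,
#'   `n_attribution_only`.
#' @export
build_cohort <- function(risk_results, attribution_results) {
  m <- match_datasets(risk_results, attribution_results)
  inc <- apply_inclusion(m$matched)
  list(cohort = inc$cohort,
       exclusions = inc$exclusions,
       n_matched = nrow(m$matched),
       n_risk_only = m$n_risk_only,
       n_attribution_only = m$n_attribution_only)
}
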