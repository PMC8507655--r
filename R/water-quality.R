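# Per-system water-quality summarisation: long-term arithmetic mean
# concentrations (non-detects as zero), the haloacetic-acid group preference
# rule, the cumulative cancer-risk hazard sum, and occurrence summaries.

# Recognised concentration units. Mass units convert freely among
# themselves (1 mg/L = 1000 ug/L = 1e6 ng/L); pCi/L is an activity unit and
# never converts to a mass unit.
unit_registry <- function() {
  structure(list(
    list(class = "mass", to_g = 1e-9),        # ng/L
    list(class = "mass", to_g = 1e-6),        # ug/L (ASCII)
    list(class = "mass", to_g = 1e-6),        # micro-sign spelling
    list(class = "mass", to_g = 1e-6),        # greek-mu spelling
    list(class = "mass", to_g = 1e-3),        # mg/L
    list(class = "activity", to_g = 1)        # pCi/L
  ), names = c("ng/L", "ug/L", "\u00b5g/L", "\u03bcg/L", "mg/L", "pCi/L"))
}

#' Convert concentrations between units
#'
#' Mass units (ng/L, ug/L, mg/L) interconvert; the activity unit pCi/L only
#' converts to itself. Mixing mass and activity units is an error, never a
#' silent pass-through.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Unit strings.
#' @return The converted values.
#' @export
convert_units <- function(value, from, to) {
  reg <- unit_registry()
  uf <- reg[[from]]
  ut <- reg[[to]]
  if (is.null(uf)) stop("unknown unit: ", from, call. = FALSE)
  if (is.null(ut)) stop("unknown unit: ", to, call. = FALSE)
  if (uf$class != ut$class) {
    stop("cannot convert ", from, " to ", to,
         ": mass and activity units are incompatible", call. = FALSE)
  }
  value * uf$to_g / ut$to_g
}

#' Construct a cancer-risk benchmark table
#'
#' Each row gives, for one contaminant (or grouped parameter such as THM4,
#' HAA5, HAA9), the concentration corresponding to a 1e-6 lifetime cancer
#' risk. The table also carries the group relationship that the nine-acid
#' haloacetic group supersedes the five-acid group when both are measured
#' for one system.
#'
#' @param contaminants A data frame with columns `id`, `benchmark`, `unit`
#'   and optionally `mcl`.
#' @param haa9_id,haa5_id Contaminant ids of the HAA9 and HAA5 grouped
#'   parameters (set to NA to disable the preference rule).
#' @return An object of class `benchmark_table` (a tibble with attributes).
#' @export
benchmark_table <- function(contaminants, haa9_id = "HAA9", haa5_id = "HAA5") {
  df <- tibble::as_tibble(contaminants)
  if (!all(c("id", "benchmark", "unit") %in% names(df))) {
    stop("benchmark table needs columns id, benchmark, unit", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate contaminant ids in benchmark table", call. = FALSE)
  }
  if (any(df$benchmark <= 0)) {
    stop("benchmarks must be > 0 (",
         paste(df$id[df$benchmark <= 0], collapse = ", "), ")", call. = FALSE)
  }
  unknown <- setdiff(unique(df$unit), names(unit_registry()))
  if (length(unknown) > 0) {
    stop("unknown benchmark units: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("benchmark_table", class(df)),
            haa9_id = haa9_id, haa5_id = haa5_id)
}

#' Read a benchmark table from YAML or JSON
#'
#' Expected layout: a `contaminants` list of `{id, benchmark, unit, mcl?}`
#' entries and an optional `group_rules: {haa9_supersedes: <id>, haa9_id: <id>}`.
#'
#' @param path Path to the config file.
#' @return A [benchmark_table()].
#' @export
read_benchmarks <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$contaminants)) {
    stop("benchmark config has no 'contaminants' section: ", path, call. = FALSE)
  }
  df <- dplyr::bind_rows(lapply(cfg$contaminants, function(ct) {
    tibble::tibble(id = ct$id, benchmark = ct$benchmark, unit = ct$unit,
                   mcl = if (is.null(ct$mcl)) NA_real_ else ct$mcl)
  }))
  haa9 <- cfg$group_rules$haa9_id %||% "HAA9"
  haa5 <- cfg$group_rules$haa9_supersedes %||% "HAA5"
  benchmark_table(df, haa9_id = haa9, haa5_id = haa5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-system long-term mean concentrations
#'
#' For each system and contaminant, computes the arithmetic mean of all
#' in-window test results with non-detects counted as zero, after
#' converting to the contaminant's benchmark unit. A contaminant with no
#' in-window records for a system is absent from the profile (testing
#' absence is not a zero concentration). Contaminants without a benchmark
#' entry keep the unit of their records.
#'
#' @param records Monitoring records (see [read_tests_csv()]).
#' @param benchmarks A [benchmark_table()].
#' @param window Length-2 Date (or coercible) vector; records outside it are
#'   ignored. Default 2014-01-01 to 2019-12-31.
#' @return A tibble with one row per system and contaminant: `pwsid`,
#'   `contaminant_id`, `c_mean` (benchmark units), `unit`, `n_tests`,
#'   `detected`.
#' @export
mean_concentrations <- function(records, benchmarks,
                                window = c("2014-01-01", "2019-12-31")) {
  validate_test_records(records)
  window <- as.Date(window)
  rec <- records[records$sample_date >= window[1] &
                   records$sample_date <= window[2], , drop = FALSE]
  if (nrow(rec) == 0) {
    return(tibble::tibble(pwsid = character(), contaminant_id = character(),
                          c_mean = numeric(), unit = character(),
                          n_tests = integer(), detected = logical()))
  }
  target_unit <- benchmarks$unit[match(rec$contaminant_id, benchmarks$id)]
  target_unit[is.na(target_unit)] <- rec$unit[is.na(target_unit)]
  # convert per unit pair (few distinct pairs, vectorised within pair)
  val <- ifelse(rec$nondetect, 0, rec$value)
  pairs <- paste(rec$unit, target_unit)
  for (p in unique(pairs)) {
    idx <- which(pairs == p)
    uf <- rec$unit[idx[1]]
    ut <- target_unit[idx[1]]
    if (uf != ut) val[idx] <- convert_units(val[idx], uf, ut)
  }
  rec$.converted <- val
  rec$.unit_out <- target_unit
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$pwsid, .data$contaminant_id),
    c_mean = mean(.data$.converted),
    unit = .data$.unit_out[1],
    n_tests = dplyr::n(),
    detected = any(.data$.converted > 0 & !.data$nondetect),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$pwsid, .data$contaminant_id)
}

#' Apply the haloacetic-acid group preference rule
#'
#' Where both the five-acid (HAA5) and nine-acid (HAA9) grouped parameters
#' are present for one system, the HAA9 value is used for risk and the HAA5
#' row is marked risk-ineligible; a system with only HAA5 keeps it. The
#' rule fired per system is recorded in the `haa_rule` column.
#'
#' @param profiles Output of [mean_concentrations()].
#' @param benchmarks A [benchmark_table()] carrying the group ids.
#' @return `profiles` with logical `risk_eligible` and character `haa_rule`
#'   columns added.
#' @export
resolve_haa <- function(profiles, benchmarks) {
  haa9 <- attr(benchmarks, "haa9_id")
  haa5 <- attr(benchmarks, "haa5_id")
  profiles$risk_eligible <- TRUE
  profiles$haa_rule <- NA_character_
  if (is.null(haa9) || is.null(haa5) || is.na(haa9) || is.na(haa5)) {
    return(profiles)
  }
  both <- intersect(profiles$pwsid[profiles$contaminant_id == haa9],
                    profiles$pwsid[profiles$contaminant_id == haa5])
  drop5 <- profiles$pwsid %in% both & profiles$contaminant_id == haa5
  profiles$risk_eligible[drop5] <- FALSE
  fired <- profiles$pwsid %in% both &
    profiles$contaminant_id %in% c(haa5, haa9)
  profiles$haa_rule[fired] <- "haa9_supersedes_haa5"
  only5 <- profiles$contaminant_id == haa5 & !(profiles$pwsid %in% both)
  profiles$haa_rule[only5] <- "haa5_only"
  profiles
}

#' Cumulative lifetime cancer risk per system
#'
#' Computes the hazard sum rho = sum(Ci / Bi) over risk-eligible
#' contaminants with a benchmark; rho is in units of 1e-6 lifetime risk and
#' `lifetime_risk = rho * 1e-6`. Contaminants in a profile that lack a
#' benchmark are skipped with a message naming them, never silently treated
#' as zero risk.
#'
#' @param profiles Output of [resolve_haa()] (or [mean_concentrations()],
#'   in which case all rows are eligible).
#' @param benchmarks A [benchmark_table()].
#' @return A tibble with `pwsid`, `rho`, `lifetime_risk`, `n_contaminants`.
#' @seealso [risk_contributions()] for the per-contaminant terms.
#' @export
cumulative_risk <- function(profiles, benchmarks) {
  contrib <- risk_contributions(profiles, benchmarks)
  out <- dplyr::summarise(
    dplyr::group_by(contrib, .data$pwsid),
    rho = sum(.data$contribution),
    n_contaminants = dplyr::n(),
    .groups = "drop"
  )
  # systems whose eligible contaminants all lacked benchmarks still appear,
  # with an empty eligible set and zero risk
  missing <- setdiff(unique(profiles$pwsid), out$pwsid)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      pwsid = missing, rho = 0, n_contaminants = 0L))
  }
  out$lifetime_risk <- out$rho * 1e-6
  dplyr::arrange(out[, c("pwsid", "rho", "lifetime_risk", "n_contaminants")],
                 .data$pwsid)
}

#' Per-contaminant hazard contributions
#'
#' One row per system and risk-eligible contaminant: `contribution = Ci/Bi`
#' after converting the mean to the benchmark unit.
#'
#' @inheritParams cumulative_risk
#' @return A tibble with `pwsid`, `contaminant_id`, `contribution`.
#' @export
risk_contributions <- function(profiles, benchmarks) {
  if (!"risk_eligible" %in% names(profiles)) profiles$risk_eligible <- TRUE
  elig <- profiles[profiles$risk_eligible, , drop = FALSE]
  m <- match(elig$contaminant_id, benchmarks$id)
  no_bench <- is.na(m)
  if (any(no_bench)) {
    skipped <- unique(elig$contaminant_id[no_bench])
    message("skipping contaminants with no benchmark: ",
            paste(skipped, collapse = ", "))
  }
  elig <- elig[!no_bench, , drop = FALSE]
  m <- m[!no_bench]
  c_bench_units <- convert_units_vec(elig$c_mean, elig$unit, benchmarks$unit[m])
  tibble::tibble(
    pwsid = elig$pwsid,
    contaminant_id = elig$contaminant_id,
    contribution = c_bench_units / benchmarks$benchmark[m]
  )
}

convert_units_vec <- function(value, from, to) {
  out <- value
  pairs <- paste(from, to)
  for (p in unique(pairs)) {
    idx <- which(pairs == p)
    if (from[idx[1]] != to[idx[1]]) {
      out[idx] <- convert_units(value[idx], from[idx[1]], to[idx[1]])
    }
  }
  out
}

#' Contaminant occurrence summary across systems
#'
#' Mirrors occurrence-table reporting: per contaminant, the number of
#' systems with data, the number with at least one detection, the total
#' population served by detecting systems, and the simple and
#' population-weighted average concentrations over systems with data.
#' Systems lacking a population figure are excluded from the weighted
#' average (and from served-population totals) with a message.
#'
#' @param profiles Output of [mean_concentrations()].
#' @param populations A data frame with `pwsid` and `population` columns.
#' @return A tibble with one row per contaminant.
#' @export
occurrence_summary <- function(profiles, populations) {
  pop <- populations$population[match(profiles$pwsid, populations$pwsid)]
  if (anyNA(pop)) {
    message("systems with no population figure excluded from weighted averages: ",
            paste(unique(profiles$pwsid[is.na(pop)]), collapse = ", "))
  }
  profiles$.pop <- pop
  dplyr::summarise(
    dplyr::group_by(profiles, .data$contaminant_id),
    unit = .data$unit[1],
    n_systems = dplyr::n(),
    n_detections = sum(.data$detected),
    population_detections = sum(.data$.pop[.data$detected], na.rm = TRUE),
    mean_simple = mean(.data$c_mean),
    mean_popweighted = {
      ok <- !is.na(.data$.pop)
      if (any(ok)) sum(.data$c_mean[ok] * .data$.pop[ok]) / sum(.data$.pop[ok])
      else NA_real_
    },
    .groups = "drop"
  )
}
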