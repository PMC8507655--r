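# Areal interpolation: tract-to-system overlap fractions and proportional
# assignment of population and demographic counts, assuming population is
# evenly distributed within each tract.

#' Tract overlap fractions for one service area
#'
#' For each tract, computes `area(tract intersect system) / area(tract)`.
#' Fractions below the sliver tolerance (a relative share of the tract
#' area) are dropped; fractions are capped at 1 against floating-point
#' overshoot. Tract polygons must be convex (true for gridded synthetic
#' tracts); service-area polygons may be concave multi-part geometries.
#'
#' @param system_geometry A geometry (vertex matrix or list of them).
#' @param tracts Tract tibble with `tract_id` and `geometry` columns.
#' @param eps Sliver tolerance as a fraction of tract area (default 1e-9).
#' @return A tibble with `tract_id` and `fraction`, one row per overlapped
#'   tract.
#' @export
overlap_fractions <- function(system_geometry, tracts, eps = 1e-9,
                              .index = NULL) {
  geom <- validate_geometry(system_geometry, "service area")
  sys_bbox <- bbox_of(geom)
  idx <- .index %||% tract_index(tracts)
  # vectorised bounding-box prefilter
  cand <- which(!(idx$bbox[, "xmax"] < sys_bbox["xmin"] |
                    idx$bbox[, "xmin"] > sys_bbox["xmax"] |
                    idx$bbox[, "ymax"] < sys_bbox["ymin"] |
                    idx$bbox[, "ymin"] > sys_bbox["ymax"]))
  ids <- character(0)
  fr <- numeric(0)
  for (i in cand) {
    a <- intersection_area_convex(geom, idx$part[[i]])
    f <- min(a / idx$area[i], 1)
    if (f >= eps) {
      ids <- c(ids, idx$tract_id[i])
      fr <- c(fr, f)
    }
  }
  tibble::tibble(tract_id = ids, fraction = fr)
}

# Validate tract geometries once and cache parts, areas and bounding boxes
# for repeated overlay against many systems.
tract_index <- function(tracts) {
  n <- nrow(tracts)
  parts <- vector("list", n)
  areas <- numeric(n)
  bbox <- matrix(0, n, 4, dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  for (i in seq_len(n)) {
    g <- validate_geometry(tracts$geometry[[i]], tracts$tract_id[i])
    if (length(g) != 1 || !is_convex_part(g[[1]])) {
      stop("tract ", tracts$tract_id[i],
           " is not a single convex polygon; convex source zones required",
           call. = FALSE)
    }
    parts[[i]] <- g[[1]]
    areas[i] <- abs(signed_area(g[[1]]))
    bbox[i, ] <- bbox_of(g)[c("xmin", "ymin", "xmax", "ymax")]
  }
  list(tract_id = tracts$tract_id, part = parts, area = areas, bbox = bbox)
}

#' Assign tract demographics to water systems by area weighting
#'
#' For every system, apportions each overlapped tract's population and
#' subgroup counts by the fraction of the tract's area inside the service
#' area, sums them, and derives subgroup percentages. In the default
#' `"counts"` mode counts are apportioned and percentages derived from the
#' summed counts (the population-conserving mode); in `"percent"` mode the
#' tract-level percentages are averaged with area-fraction weights, for
#' sensitivity analysis.
#'
#' Systems with zero assigned population are flagged `no_population` (their
#' percentages are NA) and should be excluded downstream.
#'
#' @param systems System tibble with `pwsid` and `geometry` columns.
#' @param tracts Tract tibble with `tract_id`, `population`, `sub_*` count
#'   columns and `geometry`.
#' @param subgroup_cols Names of the subgroup count columns; default every
#'   column starting with `sub_`.
#' @param mode `"counts"` (default) or `"percent"`.
#' @param eps Sliver tolerance passed to [overlap_fractions()].
#' @return A tibble with `pwsid`, `assigned_population`, one `pct_<name>`
#'   column per subgroup, `n_tracts` and `no_population`.
#' @export
attribute_demographics <- function(systems, tracts,
                                   subgroup_cols = grep("^sub_", names(tracts),
                                                        value = TRUE),
                                   mode = c("counts", "percent"),
                                   eps = 1e-9) {
  mode <- match.arg(mode)
  pct_names <- sub("^sub_", "pct_", subgroup_cols)
  n_sys <- nrow(systems)
  assigned_pop <- numeric(n_sys)
  n_tracts <- integer(n_sys)
  pct <- matrix(NA_real_, n_sys, length(subgroup_cols),
                dimnames = list(NULL, pct_names))
  no_pop <- logical(n_sys)
  idx_cache <- tract_index(tracts)

  for (i in seq_len(n_sys)) {
    ov <- overlap_fractions(systems$geometry[[i]], tracts, eps = eps,
                            .index = idx_cache)
    n_tracts[i] <- nrow(ov)
    if (nrow(ov) == 0) {
      no_pop[i] <- TRUE
      next
    }
    idx <- match(ov$tract_id, tracts$tract_id)
    pop_t <- tracts$population[idx]
    assigned_pop[i] <- sum(ov$fraction * pop_t)
    if (assigned_pop[i] <= 0) {
      no_pop[i] <- TRUE
      next
    }
    for (j in seq_along(subgroup_cols)) {
      cnt_t <- tracts[[subgroup_cols[j]]][idx]
      if (mode == "counts") {
        pct[i, j] <- 100 * sum(ov$fraction * cnt_t) / assigned_pop[i]
      } else {
        pct_t <- 100 * cnt_t / pop_t
        pct[i, j] <- sum(ov$fraction * pct_t) / sum(ov$fraction)
      }
    }
  }
  if (any(no_pop)) {
    message("systems with no assigned population (excluded downstream): ",
            paste(systems$pwsid[no_pop], collapse = ", "))
  }
  out <- tibble::tibble(pwsid = systems$pwsid,
                        assigned_population = assigned_pop)
  for (nm in pct_names) out[[nm]] <- unname(pct[, nm])
  out$n_tracts <- n_tracts
  out$no_population <- no_pop
  out
}

#' Tract-assigned vs reported population agreement
#'
#' Computes `ratio = assigned / reported` and the inclusive pass band
#' `0.5 <= ratio <= 1.5` used as a cohort inclusion filter. Systems with a
#' reported population of zero are not evaluated here (they are excluded as
#' wholesale upstream); their ratio is NA and pass is NA.
#'
#' @param attribution Output of [attribute_demographics()].
#' @param systems System tibble with `pwsid` and `reported_population`.
#' @return `attribution` with `reported_population`, `agreement_ratio` and
#'   `agreement_pass` columns added.
#' @export
population_agreement <- function(attribution, systems) {
  rep_pop <- systems$reported_population[match(attribution$pwsid, systems$pwsid)]
  ratio <- ifelse(rep_pop > 0, attribution$assigned_population / rep_pop, NA_real_)
  attribution$reported_population <- rep_pop
  attribution$agreement_ratio <- ratio
  attribution$agreement_pass <- !is.na(ratio) & ratio >= 0.5 & ratio <= 1.5
  attribution$agreement_pass[is.na(ratio)] <- NA
  attribution
}
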