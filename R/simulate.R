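# Synthetic study-region generator: a rectangular grid of square census
# tracts with Beta-distributed demographic subgroup fractions, water-system
# service areas assembled from contiguous whole and half tract cells, and
# lognormal monitoring records whose log-mean can shift with the subgroup
# fraction of the population a system serves.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe a mid-sized study region: a grid of square tracts with
#' populations in the census-tract range of 1200 to 8000 people, a
#' symmetric Beta(2, 2) subgroup fraction, and two illustrative contaminants
#' (an arsenic-like groundwater contaminant and a trihalomethane-like
#' disinfection byproduct). Benchmark values in the defaults are
#' illustrative, not regulatory values.
#'
#' @param seed Integer seed; the same seed reproduces every generated object
#'   bit for bit.
#' @param n_tracts_x,n_tracts_y Grid dimensions (number of square tracts).
#' @param tract_side Side length of each square tract in projected planar
#'   units (metres).
#' @param n_systems Number of community water systems to place on the grid.
#' @param tracts_per_system_range Integer pair: min/max number of tract cells
#'   per service area.
#' @param population_range Integer pair: uniform range for tract population.
#' @param subgroup_alpha,subgroup_beta Shape parameters of the Beta
#'   distribution for the per-tract demographic subgroup fraction.
#' @param subgroup_name Name of the demographic subgroup; tract tables carry
#'   the count as column `sub_<subgroup_name>`.
#' @param contaminants List of contaminant definitions, each a list with
#'   `id`, `benchmark` (concentration at 1e-6 lifetime cancer risk),
#'   `unit`, `meanlog` (log-scale mean concentration), `sdlog` (log-scale
#'   standard deviation) and `detection_limit` (same unit; results below it
#'   are reported as non-detects).
#' @param effect_size Log-scale shift in concentration per unit subgroup
#'   fraction of the system's served population; 0 gives the null model of
#'   no demographic-contamination association.
#' @param tests_per_system_range Integer pair: per system and contaminant,
#'   the number of monitoring records is uniform on this range.
#' @param population_noise_sd Relative Gaussian noise between the
#'   tract-derived population and the "reported" (EPA-style) population.
#' @param half_cell_prob Probability that the last cell added to a service
#'   area enters as a half cell, creating tract overlap fractions strictly
#'   between 0 and 1.
#' @param wholesale_fraction Fraction of systems stamped with a reported
#'   population of zero, emulating wholesale systems that sell finished
#'   water to other systems.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tracts_x = 12L,
                       n_tracts_y = 12L,
                       tract_side = 1000,
                       n_systems = 40L,
                       tracts_per_system_range = c(2L, 5L),
                       population_range = c(1200L, 8000L),
                       subgroup_alpha = 2,
                       subgroup_beta = 2,
                       subgroup_name = "minority",
                       contaminants = default_contaminants(),
                       effect_size = 0,
                       tests_per_system_range = c(4L, 12L),
                       population_noise_sd = 0.15,
                       half_cell_prob = 0.3,
                       wholesale_fraction = 0) {
  cfg <- list(seed = as.integer(seed),
              n_tracts_x = as.integer(n_tracts_x),
              n_tracts_y = as.integer(n_tracts_y),
              tract_side = tract_side,
              n_systems = as.integer(n_systems),
              tracts_per_system_range = as.integer(tracts_per_system_range),
              population_range = as.integer(population_range),
              subgroup_alpha = subgroup_alpha,
              subgroup_beta = subgroup_beta,
              subgroup_name = subgroup_name,
              contaminants = contaminants,
              effect_size = effect_size,
              tests_per_system_range = as.integer(tests_per_system_range),
              population_noise_sd = population_noise_sd,
              half_cell_prob = half_cell_prob,
              wholesale_fraction = wholesale_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default illustrative contaminant set
#'
#' Two contaminants spanning the two common occurrence profiles: a
#' groundwater inorganic (arsenic-like, low benchmark) and a disinfection
#' byproduct group (THM4-like, higher concentrations). Benchmarks are
#' illustrative placeholders; real analyses supply their own table.
#'
#' @return A list of contaminant definition lists.
#' @export
default_contaminants <- function() {
  list(
    list(id = "ARSENIC", benchmark = 0.004, unit = "ug/L",
         meanlog = log(1.0), sdlog = 0.6, detection_limit = 0.5),
    list(id = "THM4", benchmark = 0.15, unit = "ug/L",
         meanlog = log(30), sdlog = 0.7, detection_limit = 1.0)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot_config <- function(ok, msg) {
    if (!ok) stop("invalid simulation config: ", msg, call. = FALSE)
  }
  stopifnot_config(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed required")
  stopifnot_config(cfg$n_tracts_x >= 1 && cfg$n_tracts_y >= 1,
                   "grid dimensions must be positive")
  stopifnot_config(cfg$tract_side > 0, "tract_side must be positive")
  stopifnot_config(cfg$n_systems >= 1, "n_systems must be positive")
  for (rng in list(cfg$tracts_per_system_range, cfg$population_range,
                   cfg$tests_per_system_range)) {
    stopifnot_config(length(rng) == 2 && rng[1] >= 1 && rng[2] >= rng[1],
                     "ranges must be non-empty positive integer pairs")
  }
  stopifnot_config(cfg$subgroup_alpha > 0 && cfg$subgroup_beta > 0,
                   "Beta shape parameters must be positive")
  stopifnot_config(cfg$population_noise_sd >= 0,
                   "population_noise_sd must be non-negative")
  stopifnot_config(cfg$half_cell_prob >= 0 && cfg$half_cell_prob <= 1,
                   "half_cell_prob must be in [0, 1]")
  stopifnot_config(cfg$wholesale_fraction >= 0 && cfg$wholesale_fraction < 1,
                   "wholesale_fraction must be in [0, 1)")
  stopifnot_config(length(cfg$contaminants) >= 1, "need >= 1 contaminant")
  for (ct in cfg$contaminants) {
    stopifnot_config(all(c("id", "benchmark", "unit", "meanlog", "sdlog",
                           "detection_limit") %in% names(ct)),
                     "each contaminant needs id, benchmark, unit, meanlog, sdlog, detection_limit")
    stopifnot_config(ct$benchmark > 0, paste0("benchmark must be > 0 (", ct$id, ")"))
    stopifnot_config(ct$sdlog >= 0, paste0("sdlog must be >= 0 (", ct$id, ")"))
    stopifnot_config(ct$detection_limit >= 0,
                     paste0("detection_limit must be >= 0 (", ct$id, ")"))
  }
  invisible(cfg)
}

#' Generate the synthetic census-tract grid
#'
#' Tiles a rectangle with `n_tracts_x * n_tracts_y` non-overlapping square
#' tracts. Each tract draws its population uniformly from
#' `population_range` and its subgroup count as
#' `round(population * Beta(subgroup_alpha, subgroup_beta))`.
#'
#' @param config A [sim_config()].
#' @return A tibble with `tract_id`, `population`, one `sub_<name>` count
#'   column and a `geometry` list-column of square polygons.
#' @export
generate_tracts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nx <- config$n_tracts_x
  ny <- config$n_tracts_y
  s <- config$tract_side
  n <- nx * ny
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  geoms <- lapply(seq_len(n), function(i) {
    list(rect_part((ix[i] - 1) * s, (iy[i] - 1) * s, ix[i] * s, iy[i] * s))
  })
  pop <- sample(config$population_range[1]:config$population_range[2], n,
                replace = TRUE)
  frac <- stats::rbeta(n, config$subgroup_alpha, config$subgroup_beta)
  out <- tibble::tibble(
    tract_id = sprintf("T%04d", seq_len(n)),
    population = pop
  )
  out[[paste0("sub_", config$subgroup_name)]] <- round(pop * frac)
  out$geometry <- geoms
  out
}

# Cell neighbours (4-connectivity) on the nx x ny grid; cells indexed 1..nx*ny
# column-major by x then y (matching generate_tracts ordering).
grid_neighbours <- function(cell, nx, ny) {
  x <- (cell - 1) %% nx + 1
  y <- (cell - 1) %/% nx + 1
  nb <- c(if (x > 1) cell - 1, if (x < nx) cell + 1,
          if (y > 1) cell - nx, if (y < ny) cell + nx)
  nb
}

half_cell_rect <- function(ix, iy, s, side) {
  x0 <- (ix - 1) * s
  y0 <- (iy - 1) * s
  switch(side,
         left   = rect_part(x0, y0, x0 + s / 2, y0 + s),
         right  = rect_part(x0 + s / 2, y0, x0 + s, y0 + s),
         bottom = rect_part(x0, y0, x0 + s, y0 + s / 2),
         top    = rect_part(x0, y0 + s / 2, x0 + s, y0 + s))
}

#' Generate synthetic water-system service areas
#'
#' Places `n_systems` service areas on the tract grid. Each service area is
#' a contiguous block of free tract cells grown from a random anchor; with
#' probability `half_cell_prob` the last cell enters as a half cell, so
#' tract overlap fractions strictly between 0 and 1 occur. Cells are never
#' shared between systems. The reported population is the tract-derived
#' covered population perturbed by relative Gaussian noise and floored at
#' zero; a `wholesale_fraction` of systems is stamped with a reported
#' population of zero.
#'
#' @param config A [sim_config()].
#' @param tracts Output of [generate_tracts()].
#' @return A tibble with `pwsid`, `reported_population`, `true_population`
#'   (tract-derived, for diagnostics) and a `geometry` list-column.
#' @export
generate_systems <- function(config, tracts) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  nx <- config$n_tracts_x
  ny <- config$n_tracts_y
  s <- config$tract_side
  n_cells <- nx * ny
  free <- rep(TRUE, n_cells)
  rng <- config$tracts_per_system_range

  systems <- vector("list", config$n_systems)
  for (i in seq_len(config$n_systems)) {
    candidates <- which(free)
    if (length(candidates) == 0) {
      stop("grid cannot host ", config$n_systems,
           " systems without sharing cells; increase the grid or lower n_systems",
           call. = FALSE)
    }
    target <- sample(rng[1]:rng[2], 1)
    anchor <- candidates[sample.int(length(candidates), 1)]
    block <- anchor
    free[anchor] <- FALSE
    while (length(block) < target) {
      frontier <- unique(unlist(lapply(block, grid_neighbours, nx = nx, ny = ny)))
      frontier <- frontier[free[frontier]]
      if (length(frontier) == 0) break
      nxt <- frontier[sample.int(length(frontier), 1)]
      block <- c(block, nxt)
      free[nxt] <- FALSE
    }
    half <- length(block) > 1 && stats::runif(1) < config$half_cell_prob
    systems[[i]] <- list(cells = block, half_last = half,
                         half_side = sample(c("left", "right", "bottom", "top"), 1))
  }

  pops <- tracts$population
  geoms <- vector("list", config$n_systems)
  true_pop <- numeric(config$n_systems)
  for (i in seq_len(config$n_systems)) {
    sys <- systems[[i]]
    cells <- sys$cells
    frac <- rep(1, length(cells))
    parts <- vector("list", length(cells))
    for (j in seq_along(cells)) {
      cx <- (cells[j] - 1) %% nx + 1
      cy <- (cells[j] - 1) %/% nx + 1
      if (sys$half_last && j == length(cells)) {
        parts[[j]] <- half_cell_rect(cx, cy, s, sys$half_side)
        frac[j] <- 0.5
      } else {
        parts[[j]] <- rect_part((cx - 1) * s, (cy - 1) * s, cx * s, cy * s)
      }
    }
    geoms[[i]] <- parts
    true_pop[i] <- sum(frac * pops[cells])
  }

  noise <- stats::rnorm(config$n_systems, 0, config$population_noise_sd)
  reported <- pmax(0, round(true_pop * (1 + noise)))
  if (config$wholesale_fraction > 0) {
    n_wholesale <- round(config$wholesale_fraction * config$n_systems)
    if (n_wholesale > 0) {
      idx <- sample.int(config$n_systems, n_wholesale)
      reported[idx] <- 0
    }
  }

  tibble::tibble(
    pwsid = sprintf("SY%07d", seq_len(config$n_systems)),
    reported_population = as.integer(reported),
    true_population = true_pop,
    geometry = geoms
  )
}

#' Generate synthetic monitoring records
#'
#' For each system and contaminant, draws a uniform number of test records
#' with concentrations from a lognormal whose log-mean is
#' `meanlog + effect_size * f`, where `f` is the system's demographic
#' subgroup fraction computed by exact areal attribution of tract counts.
#' Concentrations below the detection limit are emitted as non-detects
#' (empty value, flag set). Sample dates are uniform over 2014-01-01 to
#' 2019-12-31.
#'
#' @param config A [sim_config()].
#' @param systems Output of [generate_systems()].
#' @param tracts Output of [generate_tracts()].
#' @return A tibble of monitoring records with columns `pwsid`,
#'   `contaminant_id`, `sample_date`, `value` (NA when non-detect), `unit`,
#'   `nondetect`.
#' @export
generate_tests <- function(config, systems, tracts) {
  validate_sim_config(config)
  attribution <- attribute_demographics(systems, tracts)
  pct_col <- paste0("pct_", config$subgroup_name)
  f <- attribution[[pct_col]][match(systems$pwsid, attribution$pwsid)] / 100
  f[is.na(f)] <- 0

  set.seed(config$seed + 2L)
  day0 <- as.Date("2014-01-01")
  day1 <- as.Date("2019-12-31")
  n_days <- as.integer(day1 - day0) + 1L
  rng <- config$tests_per_system_range

  rows <- list()
  for (i in seq_len(nrow(systems))) {
    for (ct in config$contaminants) {
      k <- sample(rng[1]:rng[2], 1)
      conc <- stats::rlnorm(k, meanlog = ct$meanlog + config$effect_size * f[i],
                            sdlog = ct$sdlog)
      nd <- conc < ct$detection_limit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pwsid = systems$pwsid[i],
        contaminant_id = ct$id,
        sample_date = day0 + (sample.int(n_days, k, replace = TRUE) - 1L),
        value = ifelse(nd, NA_real_, conc),
        unit = ct$unit,
        nondetect = nd
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full generator and write its outputs to disk
#'
#' Writes `tracts.geojson`, `systems.geojson` and `tests.csv` in the schema
#' the downstream stages read.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with the three generated tables.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tracts <- generate_tracts(config)
  systems <- generate_systems(config, tracts)
  tests <- generate_tests(config, systems, tracts)
  write_geojson(tracts, file.path(out_dir, "tracts.geojson"))
  write_geojson(dplyr::select(systems, -"true_population"),
                file.path(out_dir, "systems.geojson"))
  write_tests_csv(tests, file.path(out_dir, "tests.csv"))
  invisible(list(tracts = tracts, systems = systems, tests = tests))
}
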