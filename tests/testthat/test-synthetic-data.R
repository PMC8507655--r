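test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_tracts_x = 6, n_tracts_y = 6, n_systems = 8)
  t1 <- generate_tracts(cfg); t2 <- generate_tracts(cfg)
  expect_identical(t1, t2)
  s1 <- generate_systems(cfg, t1); s2 <- generate_systems(cfg, t2)
  expect_identical(s1, s2)
  r1 <- generate_tests(cfg, s1, t1); r2 <- generate_tests(cfg, s2, t2)
  expect_identical(r1, r2)
})

test_that("tracts tile the study rectangle with no pairwise overlap", {
  cfg <- sim_config(seed = 3, n_tracts_x = 3, n_tracts_y = 3, tract_side = 1,
                    n_systems = 2, tracts_per_system_range = c(1, 2))
  tracts <- generate_tracts(cfg)
  expect_equal(nrow(tracts), 9)
  areas <- vapply(tracts$geometry, polygon_area, numeric(1))
  expect_equal(sum(areas), 9)
  expect_false(anyDuplicated(tracts$tract_id) > 0)
  for (i in 1:8) for (j in (i + 1):9) {
    inter <- cwsdisparity:::intersection_area_convex(
      tracts$geometry[[i]], tracts$geometry[[j]][[1]])
    expect_equal(inter, 0)
  }
})

test_that("symmetric Beta parameters give mean subgroup fraction near one half", {
  cfg <- sim_config(seed = 5, n_tracts_x = 40, n_tracts_y = 40, n_systems = 1,
                    subgroup_alpha = 2, subgroup_beta = 2)
  tracts <- generate_tracts(cfg)
  frac <- tracts$sub_minority / tracts$population
  expect_equal(mean(frac), 0.5, tolerance = 0.02)
  expect_true(all(tracts$sub_minority >= 0 &
                    tracts$sub_minority <= tracts$population))
})

test_that("noise-free whole-cell systems report exactly the tract-derived population", {
  cfg <- sim_config(seed = 9, n_tracts_x = 8, n_tracts_y = 8, n_systems = 10,
                    population_noise_sd = 0, half_cell_prob = 0)
  tracts <- generate_tracts(cfg)
  systems <- generate_systems(cfg, tracts)
  expect_equal(as.numeric(systems$reported_population), systems$true_population)
  # whole-cell geometry implies every overlap fraction is 1
  ov <- overlap_fractions(systems$geometry[[1]], tracts)
  expect_true(all(abs(ov$fraction - 1) < 1e-12))
})

test_that("a one-tract system overlaps that tract with fraction one", {
  cfg <- sim_config(seed = 2, n_tracts_x = 4, n_tracts_y = 4, n_systems = 3,
                    tracts_per_system_range = c(1, 1), half_cell_prob = 0)
  tracts <- generate_tracts(cfg)
  systems <- generate_systems(cfg, tracts)
  for (i in seq_len(nrow(systems))) {
    ov <- overlap_fractions(systems$geometry[[i]], tracts)
    expect_equal(nrow(ov), 1)
    expect_equal(ov$fraction, 1)
  }
})

test_that("an over-packed grid raises rather than duplicating blocks", {
  cfg <- sim_config(seed = 1, n_tracts_x = 2, n_tracts_y = 2, n_systems = 5,
                    tracts_per_system_range = c(1, 1))
  tracts <- generate_tracts(cfg)
  expect_error(generate_systems(cfg, tracts), "cannot host")
})

test_that("PWSIDs are unique and formatted", {
  cfg <- sim_config(seed = 4, n_tracts_x = 8, n_tracts_y = 8, n_systems = 12)
  systems <- generate_systems(cfg, generate_tracts(cfg))
  expect_true(all(grepl("^SY[0-9]{7}$", systems$pwsid)))
  expect_equal(anyDuplicated(systems$pwsid), 0L)
})

test_that("detection limit zero yields no non-detects and sigma=0 collapses to exp(meanlog)", {
  ct <- list(list(id = "X", benchmark = 1, unit = "ug/L",
                  meanlog = log(2), sdlog = 0, detection_limit = 0))
  cfg <- sim_config(seed = 6, n_tracts_x = 5, n_tracts_y = 5, n_systems = 6,
                    contaminants = ct, effect_size = 0)
  tracts <- generate_tracts(cfg)
  systems <- generate_systems(cfg, tracts)
  tests <- generate_tests(cfg, systems, tracts)
  expect_false(any(tests$nondetect))
  expect_true(all(abs(tests$value - 2) < 1e-12))
  expect_true(all(tests$sample_date >= as.Date("2014-01-01") &
                    tests$sample_date <= as.Date("2019-12-31")))
})

test_that("with no injected effect the subgroup-concentration association is null", {
  ct <- list(list(id = "X", benchmark = 1, unit = "ug/L",
                  meanlog = 0, sdlog = 0.5, detection_limit = 0))
  cfg <- sim_config(seed = 8, n_tracts_x = 33, n_tracts_y = 33, n_systems = 500,
                    tracts_per_system_range = c(1, 2), contaminants = ct,
                    effect_size = 0, tests_per_system_range = c(3, 6))
  tracts <- generate_tracts(cfg)
  systems <- generate_systems(cfg, tracts)
  tests <- generate_tests(cfg, systems, tracts)
  att <- attribute_demographics(systems, tracts)
  mean_by_sys <- tapply(ifelse(tests$nondetect, 0, tests$value), tests$pwsid, mean)
  f <- att$pct_minority[match(names(mean_by_sys), att$pwsid)]
  rho <- suppressWarnings(cor(mean_by_sys, f, method = "spearman"))
  expect_lt(abs(rho), 0.1)
})

test_that("a positive effect size induces a positive rank association", {
  ct <- list(list(id = "X", benchmark = 1, unit = "ug/L",
                  meanlog = 0, sdlog = 0.3, detection_limit = 0))
  cfg <- sim_config(seed = 8, n_tracts_x = 20, n_tracts_y = 20, n_systems = 120,
                    tracts_per_system_range = c(1, 2), contaminants = ct,
                    effect_size = 2, tests_per_system_range = c(4, 8))
  tracts <- generate_tracts(cfg)
  systems <- generate_systems(cfg, tracts)
  tests <- generate_tests(cfg, systems, tracts)
  att <- attribute_demographics(systems, tracts)
  mean_by_sys <- tapply(tests$value, tests$pwsid, mean)
  f <- att$pct_minority[match(names(mean_by_sys), att$pwsid)]
  rho <- suppressWarnings(cor(mean_by_sys, f, method = "spearman"))
  expect_gt(rho, 0.3)
})

test_that("simulated outputs round-trip through GeoJSON and CSV", {
  cfg <- sim_config(seed = 13, n_tracts_x = 5, n_tracts_y = 5, n_systems = 5)
  out <- withr::local_tempdir()
  sim <- simulate_study(cfg, out)
  tracts2 <- read_tracts_geojson(file.path(out, "tracts.geojson"))
  systems2 <- read_systems_geojson(file.path(out, "systems.geojson"))
  tests2 <- read_tests_csv(file.path(out, "tests.csv"))
  expect_equal(tracts2$tract_id, sim$tracts$tract_id)
  expect_equal(tracts2$population, sim$tracts$population)
  expect_equal(systems2$reported_population, sim$systems$reported_population)
  expect_equal(nrow(tests2), nrow(sim$tests))
  expect_equal(tests2$value, sim$tests$value)
  expect_equal(tests2$nondetect, sim$tests$nondetect)
  # geometry survives the round trip (same areas)
  a1 <- vapply(sim$tracts$geometry, polygon_area, numeric(1))
  a2 <- vapply(tracts2$geometry, polygon_area, numeric(1))
  expect_equal(a1, a2)
})
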