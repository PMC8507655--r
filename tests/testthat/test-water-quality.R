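bm <- simple_benchmarks()

test_that("arithmetic means count non-detects as zero and respect the window", {
  rec <- make_test_records("A", "ARSENIC", c(1.0, NA, 2.0))
  prof <- mean_concentrations(rec, bm)
  expect_equal(prof$c_mean, 1.0)
  expect_equal(prof$n_tests, 3L)
  expect_true(prof$detected)

  # all non-detect: mean zero, not detected, still a profile row
  rec_nd <- make_test_records("A", "ARSENIC", c(NA_real_, NA_real_))
  prof_nd <- mean_concentrations(rec_nd, bm)
  expect_equal(prof_nd$c_mean, 0)
  expect_false(prof_nd$detected)

  # out-of-window records vanish; no records -> contaminant absent
  rec_out <- make_test_records("A", "ARSENIC", 5,
                               dates = as.Date("2013-01-01"))
  expect_equal(nrow(mean_concentrations(rec_out, bm)), 0)
})

test_that("units convert to the benchmark unit before averaging", {
  rec <- make_test_records("A", "ARSENIC", 500, unit = "ng/L")
  prof <- mean_concentrations(rec, bm)
  expect_equal(prof$c_mean, 0.5)   # benchmark table is in ug/L
  expect_equal(prof$unit, "ug/L")

  expect_equal(convert_units(1, "mg/L", "ug/L"), 1000)
  expect_equal(convert_units(1, "mg/L", "ng/L"), 1e6)
  expect_error(convert_units(1, "pCi/L", "ug/L"), "incompatible")
  expect_error(convert_units(1, "ppm", "ug/L"), "unknown unit")
})

test_that("record validation rejects malformed inputs", {
  bad_xor <- make_test_records("A", "X", c(1, 2))
  bad_xor$nondetect[1] <- TRUE
  expect_error(cwsdisparity:::validate_test_records(bad_xor), "XOR")
  neg <- make_test_records("A", "X", c(-1))
  expect_error(cwsdisparity:::validate_test_records(neg), "negative")
})

test_that("HAA9 supersedes HAA5 only when both are present", {
  rec <- dplyr::bind_rows(
    make_test_records("A", "HAA5", 8),
    make_test_records("A", "HAA9", 20),
    make_test_records("B", "HAA5", 8)
  )
  prof <- resolve_haa(mean_concentrations(rec, bm), bm)
  a5 <- prof[prof$pwsid == "A" & prof$contaminant_id == "HAA5", ]
  a9 <- prof[prof$pwsid == "A" & prof$contaminant_id == "HAA9", ]
  b5 <- prof[prof$pwsid == "B" & prof$contaminant_id == "HAA5", ]
  expect_false(a5$risk_eligible)
  expect_true(a9$risk_eligible)
  expect_true(b5$risk_eligible)
  expect_equal(a5$haa_rule, "haa9_supersedes_haa5")
  expect_equal(b5$haa_rule, "haa5_only")

  # a profile with neither group is unchanged
  prof2 <- resolve_haa(mean_concentrations(
    make_test_records("C", "ARSENIC", 1), bm), bm)
  expect_true(all(prof2$risk_eligible))
})

test_that("no risk result ever carries both HAA5 and HAA9 contributions", {
  set.seed(1)
  for (rep in 1:10) {
    ids <- sample(c("HAA5", "HAA9", "ARSENIC"), sample(1:3, 1))
    rec <- dplyr::bind_rows(lapply(ids, function(id) {
      make_test_records("S", id, runif(2, 1, 10))
    }))
    prof <- resolve_haa(mean_concentrations(rec, bm), bm)
    contrib <- risk_contributions(prof, bm)
    expect_false(all(c("HAA5", "HAA9") %in% contrib$contaminant_id))
  }
})

test_that("cumulative risk is the hazard sum of mean over benchmark", {
  prof <- tibble::tibble(
    pwsid = c("A", "A"),
    contaminant_id = c("a", "b"),
    c_mean = c(2, 5),
    unit = "ug/L",
    n_tests = 1L,
    detected = TRUE
  )
  bm2 <- benchmark_table(data.frame(id = c("a", "b"), benchmark = c(1, 10),
                                    unit = "ug/L"),
                         haa9_id = NA, haa5_id = NA)
  risk <- cumulative_risk(prof, bm2)
  expect_equal(risk$rho, 2.5)
  expect_equal(risk$lifetime_risk, 2.5e-6)
  expect_equal(risk$n_contaminants, 2L)

  # a unit concentration at the benchmark is exactly one-in-a-million risk
  prof1 <- prof[1, ]; prof1$c_mean <- 1
  expect_equal(cumulative_risk(prof1, bm2)$rho, 1)

  # contaminants without benchmarks are skipped with a message, not zeroed
  prof_extra <- dplyr::bind_rows(prof, tibble::tibble(
    pwsid = "A", contaminant_id = "mystery", c_mean = 100, unit = "ug/L",
    n_tests = 1L, detected = TRUE))
  expect_message(risk2 <- cumulative_risk(prof_extra, bm2), "mystery")
  expect_equal(risk2$rho, 2.5)
})

test_that("an empty eligible set gives zero risk", {
  prof <- tibble::tibble(pwsid = "A", contaminant_id = "a", c_mean = 3,
                         unit = "ug/L", n_tests = 1L, detected = TRUE,
                         risk_eligible = FALSE, haa_rule = NA_character_)
  bm2 <- benchmark_table(data.frame(id = "a", benchmark = 1, unit = "ug/L"),
                         haa9_id = NA, haa5_id = NA)
  risk <- cumulative_risk(prof, bm2)
  expect_equal(risk$rho, 0)
  expect_equal(risk$lifetime_risk, 0)
})

test_that("rho is linear in concentrations, monotone in contaminant set, unit-invariant", {
  set.seed(7)
  bmr <- benchmark_table(data.frame(id = letters[1:5],
                                    benchmark = runif(5, 0.01, 10),
                                    unit = "ug/L"),
                         haa9_id = NA, haa5_id = NA)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    ids <- letters[1:k]
    cm <- runif(k, 0, 20)
    prof <- tibble::tibble(pwsid = "S", contaminant_id = ids, c_mean = cm,
                           unit = "ug/L", n_tests = 1L, detected = TRUE)
    rho1 <- cumulative_risk(prof, bmr)$rho
    # linearity: scaling all concentrations scales rho
    prof_scaled <- prof; prof_scaled$c_mean <- prof_scaled$c_mean * 3.7
    expect_equal(cumulative_risk(prof_scaled, bmr)$rho, rho1 * 3.7)
    # monotonicity: dropping a contaminant never increases rho
    prof_drop <- prof[-1, ]
    expect_lte(cumulative_risk(prof_drop, bmr)$rho, rho1 + 1e-12)
    # unit invariance: same concentrations expressed in ng/L
    prof_ng <- prof
    prof_ng$c_mean <- prof_ng$c_mean * 1000
    prof_ng$unit <- "ng/L"
    expect_equal(cumulative_risk(prof_ng, bmr)$rho, rho1)
  }
})

test_that("occurrence summary weights by population and counts detections", {
  prof <- dplyr::bind_rows(
    mean_concentrations(make_test_records("A", "ARSENIC", c(10, 10)), bm),
    mean_concentrations(make_test_records("B", "ARSENIC", c(20, 20)), bm),
    mean_concentrations(make_test_records("C", "ARSENIC", c(NA_real_, NA_real_)), bm)
  )
  pops <- data.frame(pwsid = c("A", "B", "C"), population = c(100, 300, 50))
  s <- occurrence_summary(prof, pops)
  expect_equal(s$n_systems, 3L)          # all systems with data
  expect_equal(s$n_detections, 2L)       # the all-ND system is not a detection
  expect_equal(s$population_detections, 400)
  expect_equal(s$mean_simple, mean(c(10, 20, 0)))
  expect_equal(s$mean_popweighted, (10 * 100 + 20 * 300 + 0 * 50) / 450)

  # equal populations collapse weighted onto simple average
  pops_eq <- data.frame(pwsid = c("A", "B", "C"), population = 100)
  s_eq <- occurrence_summary(prof, pops_eq)
  expect_equal(s_eq$mean_popweighted, s_eq$mean_simple)

  # missing population excluded from the weighted average with a message
  pops_na <- data.frame(pwsid = c("A", "B"), population = c(100, 300))
  expect_message(s_na <- occurrence_summary(prof, pops_na), "C")
  expect_equal(s_na$mean_popweighted, (10 * 100 + 20 * 300) / 400)
})

test_that("benchmark configs read from YAML round-trip the table", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "contaminants:",
    "  - {id: ARSENIC, benchmark: 0.004, unit: ug/L, mcl: 10}",
    "  - {id: HAA5, benchmark: 0.1, unit: ug/L}",
    "  - {id: HAA9, benchmark: 0.06, unit: ug/L}",
    "group_rules:",
    "  haa9_supersedes: HAA5",
    "  haa9_id: HAA9"
  ), path)
  b <- read_benchmarks(path)
  expect_s3_class(b, "benchmark_table")
  expect_equal(nrow(b), 3)
  expect_equal(attr(b, "haa5_id"), "HAA5")
  expect_equal(b$benchmark[b$id == "ARSENIC"], 0.004)
  expect_error(benchmark_table(data.frame(id = "x", benchmark = 0, unit = "ug/L")),
               "must be > 0")
})
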