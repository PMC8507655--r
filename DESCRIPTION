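Package: cwsdisparity
Title: Community Water System Cancer-Risk Disparity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for community-level drinking-water disparity
    screening. Computes per-water-system cumulative lifetime cancer risk from
    multi-contaminant monitoring records (hazard-sum of long-term mean
    concentrations over per-contaminant cancer-risk benchmarks, with
    non-detects substituted as zero), apportions census-tract population and
    demographic counts to water-system service areas by planar areal
    interpolation, applies cohort inclusion rules (wholesale exclusion,
    population floor, tract-vs-reported population agreement) and size
    classification, and tests for monotone trend of risk across demographic
    terciles with a tie-corrected Jonckheere-Terpstra test (asymptotic, exact,
    or permutation p-values). Includes a seeded synthetic-data generator for
    tract grids, service areas, and monitoring records with a tunable
    demographic-contamination association, and a deterministic end-to-end
    pipeline runner with a machine-readable run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
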