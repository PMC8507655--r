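# Monte-Carlo calibration of the tercile trend test under the generator's
# system-level sampling model.

#' Rejection rate of the tercile trend test under the simulation model
#'
#' Draws `n_reps` cohorts from the generator's system-level model — a
#' Beta(`subgroup_alpha`, `subgroup_beta`) demographic subgroup fraction
#' per system, and a per-system mean risk computed from a uniform number of
#' lognormal test results whose log-mean is `meanlog + effect_size * f` —
#' then splits each cohort into subgroup terciles and runs the asymptotic
#' Jonckheere-Terpstra test. With `effect_size = 0` the risk draw is
#' independent of the subgroup fraction, so the rejection rate estimates
#' the test's type-I error at `alpha`; with a positive effect it estimates
#' power.
#'
#' @param n_reps Number of simulated cohorts.
#' @param n_systems Systems per cohort.
#' @param effect_size Log-scale shift per unit subgroup fraction.
#' @param alpha Nominal level (default 0.05).
#' @param alternative Sidedness of the test (default `"increasing"`).
#' @param subgroup_alpha,subgroup_beta Beta shape parameters of the
#'   subgroup fraction.
#' @param meanlog,sdlog Lognormal parameters of single test results.
#' @param tests_per_system_range Uniform range for tests per system.
#' @param seed Seed for the whole run.
#' @return A list with `rejection_rate`, `alpha`, `p_values` and the
#'   simulation settings.
#' @export
trend_test_calibration <- function(n_reps, n_systems,
                                   effect_size = 0,
                                   alpha = 0.05,
                                   alternative = "increasing",
                                   subgroup_alpha = 2, subgroup_beta = 2,
                                   meanlog = 0, sdlog = 0.5,
                                   tests_per_system_range = c(4L, 12L),
                                   seed = 1L) {
  set.seed(seed)
  ids <- sprintf("SY%07d", seq_len(n_systems))
  rng <- tests_per_system_range
  p_values <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    f <- stats::rbeta(n_systems, subgroup_alpha, subgroup_beta)
    k <- sample(rng[1]:rng[2], n_systems, replace = TRUE)
    risk <- vapply(seq_len(n_systems), function(i) {
      mean(stats::rlnorm(k[i], meanlog + effect_size * f[i], sdlog))
    }, numeric(1))
    labels <- tercile_split(100 * f, ids)
    jt <- jonckheere_terpstra(risk, labels, alternative = alternative,
                              method = "asymptotic")
    p_values[r] <- jt$p.value
  }
  list(rejection_rate = mean(p_values < alpha),
       alpha = alpha,
       p_values = p_values,
       n_reps = n_reps,
       n_systems = n_systems,
       effect_size = effect_size,
       alternative = alternative)
}
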