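# Tercile disparity analysis: order systems by a demographic percentage,
# split into equal-count terciles, summarise risk per tercile, and test for
# a monotone trend with a tie-corrected Jonckheere-Terpstra test.

#' Split systems into demographic terciles
#'
#' Systems are sorted ascending by percentage with ties broken by id
#' (stable, deterministic), then cut into three contiguous groups whose
#' sizes differ by at most one; when n is not divisible by 3 the extra
#' system(s) go to the lowest tercile(s) first.
#'
#' @param values Numeric vector (demographic percentage per system).
#' @param ids Character vector of system ids, used as the tie-break key.
#' @return A factor of labels T1 < T2 < T3 aligned with the input order.
#' @export
tercile_split <- function(values, ids) {
  n <- length(values)
  if (n < 3) stop("need at least 3 systems to form terciles", call. = FALSE)
  if (length(ids) != n) stop("values and ids lengths differ", call. = FALSE)
  ord <- order(values, ids)
  base <- n %/% 3
  rem <- n %% 3
  sizes <- base + c(rem >= 1, rem >= 2, FALSE)
  lab_sorted <- rep(c("T1", "T2", "T3"), times = sizes)
  labels <- character(n)
  labels[ord] <- lab_sorted
  factor(labels, levels = c("T1", "T2", "T3"), ordered = TRUE)
}

#' Per-tercile summary of systems
#'
#' For each tercile: number of systems, the min/max demographic percentage
#' (the tercile boundaries), total reported population, and the median
#' lifetime cancer risk (midpoint-of-order-statistics median).
#'
#' @param labels Tercile factor from [tercile_split()].
#' @param profiles Tibble aligned with `labels`, carrying
#'   `reported_population`, `lifetime_risk` and the percentage column.
#' @param pct_col Name of the percentage column summarised as boundaries.
#' @return A tibble with one row per tercile.
#' @export
tercile_summary <- function(labels, profiles, pct_col) {
  df <- profiles
  df$.tercile <- labels
  dplyr::summarise(
    dplyr::group_by(df, tercile = .data$.tercile),
    n = dplyr::n(),
    pct_min = min(.data[[pct_col]]),
    pct_max = max(.data[[pct_col]]),
    total_population = sum(.data$reported_population),
    median_risk = stats::median(.data$lifetime_risk),
    .groups = "drop"
  )
}

# J statistic: sum over ordered group pairs (k < l) of the Mann-Whitney
# count #(x < y) + 0.5 #(x = y), computed via midranks.
jt_statistic <- function(x, group_sizes) {
  k <- length(group_sizes)
  ends <- cumsum(group_sizes)
  starts <- ends - group_sizes + 1
  J <- 0
  for (a in seq_len(k - 1)) {
    xa <- x[starts[a]:ends[a]]
    for (b in (a + 1):k) {
      xb <- x[starts[b]:ends[b]]
      r <- rank(c(xa, xb))
      nb <- length(xb)
      J <- J + sum(r[(length(xa) + 1):(length(xa) + nb)]) - nb * (nb + 1) / 2
    }
  }
  J
}

jt_null_moments <- function(x, group_sizes) {
  n <- length(x)
  nk <- group_sizes
  mu0 <- (n^2 - sum(nk^2)) / 4
  t_sizes <- as.numeric(table(x))
  A <- n * (n - 1) * (2 * n + 5) -
    sum(nk * (nk - 1) * (2 * nk + 5)) -
    sum(t_sizes * (t_sizes - 1) * (2 * t_sizes + 5))
  B <- sum(nk * (nk - 1) * (nk - 2)) * sum(t_sizes * (t_sizes - 1) * (t_sizes - 2))
  C <- sum(nk * (nk - 1)) * sum(t_sizes * (t_sizes - 1))
  var0 <- A / 72
  if (n > 2) var0 <- var0 + B / (36 * n * (n - 1) * (n - 2))
  var0 <- var0 + C / (8 * n * (n - 1))
  list(mu0 = mu0, var0 = var0)
}

# All distinct assignments of n pooled observations to ordered groups of
# the given sizes, as a list of index permutations. Used by the exact
# method; sizes are capped upstream.
enumerate_assignments <- function(n, group_sizes) {
  recurse <- function(remaining, sizes) {
    if (length(sizes) == 0) return(list(integer(0)))
    if (length(sizes) == 1) return(list(remaining))
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- setdiff(remaining, p)
      for (tail in recurse(rest, sizes[-1])) {
        out[[length(out) + 1L]] <- c(p, tail)
      }
    }
    out
  }
  recurse(seq_len(n), group_sizes)
}

#' Jonckheere-Terpstra test for ordered alternatives
#'
#' Tests whether location shifts monotonically across ordered groups, using
#' the statistic J = sum over group pairs k < l of
#' #(x in G_k < y in G_l) + 0.5 #(ties). The null mean is
#' (n^2 - sum n_k^2)/4 and the null variance uses the tie-corrected
#' Hollander-Wolfe form, which reduces to
#' (n^2 (2n+3) - sum n_k^2 (2 n_k + 3))/72 without ties.
#'
#' P-values: `"asymptotic"` uses the normal approximation for
#' z = (J - mu0)/sqrt(var0); `"exact"` enumerates every equally likely
#' assignment of the pooled observations to the groups (total n <= 10);
#' `"permutation"` is a seeded Monte-Carlo version of the same null;
#' `"auto"` picks exact for n <= 10, asymptotic otherwise. When all
#' observations are identical (null variance zero) the test returns z = 0
#' and p = 1.
#'
#' @param x Numeric observations.
#' @param g Group membership, coercible to a factor whose level order is
#'   the hypothesised ordering (increasing group index = hypothesised
#'   larger location under `"increasing"`).
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param method `"auto"`, `"asymptotic"`, `"exact"` or `"permutation"`.
#' @param nperm Number of Monte-Carlo permutations (permutation method).
#' @param seed Seed for the permutation method.
#' @return An object of class `jt_test`: a list with `J`, `mu0`, `var0`,
#'   `z`, `p.value`, `alternative`, `method`, `n` (per-group sizes).
#' @export
#' @examples
#' jonckheere_terpstra(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2),
#'                     alternative = "increasing", method = "exact")
jonckheere_terpstra <- function(x, g,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                method = c("auto", "asymptotic", "exact",
                                           "permutation"),
                                nperm = 1e5, seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  g <- as.factor(g)  # keeps declared-but-empty levels so they error below
  if (length(x) != length(g)) stop("x and g lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(g)) stop("missing values not allowed", call. = FALSE)
  sizes <- as.integer(table(g))
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes == 0)) {
    stop("every group must have at least one observation", call. = FALSE)
  }
  ord <- order(g)
  xs <- x[ord]
  n <- length(xs)

  J <- jt_statistic(xs, sizes)
  mom <- jt_null_moments(xs, sizes)
  mu0 <- mom$mu0
  var0 <- mom$var0

  if (var0 <= 0) {
    res <- list(J = J, mu0 = mu0, var0 = 0, z = 0, p.value = 1,
                alternative = alternative, method = "degenerate",
                n = sizes)
    class(res) <- "jt_test"
    return(res)
  }

  z <- (J - mu0) / sqrt(var0)
  if (method == "auto") method <- if (n <= 10) "exact" else "asymptotic"

  if (method == "asymptotic") {
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(p, 1)
  } else if (method == "exact") {
    if (n > 10) {
      stop("exact enumeration limited to n <= 10; use permutation", call. = FALSE)
    }
    assigns <- enumerate_assignments(n, sizes)
    Jnull <- vapply(assigns, function(idx) jt_statistic(xs[idx], sizes),
                    numeric(1))
    tol <- 1e-9
    p <- switch(alternative,
                increasing = mean(Jnull >= J - tol),
                decreasing = mean(Jnull <= J + tol),
                two.sided = mean(abs(Jnull - mu0) >= abs(J - mu0) - tol))
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed_up <- 0L
    exceed_dn <- 0L
    exceed_two <- 0L
    tol <- 1e-9
    for (b in seq_len(nperm)) {
      Jb <- jt_statistic(sample(xs), sizes)
      if (Jb >= J - tol) exceed_up <- exceed_up + 1L
      if (Jb <= J + tol) exceed_dn <- exceed_dn + 1L
      if (abs(Jb - mu0) >= abs(J - mu0) - tol) exceed_two <- exceed_two + 1L
    }
    p <- switch(alternative,
                increasing = (1 + exceed_up) / (nperm + 1),
                decreasing = (1 + exceed_dn) / (nperm + 1),
                two.sided = (1 + exceed_two) / (nperm + 1))
  }

  res <- list(J = J, mu0 = mu0, var0 = var0, z = z, p.value = p,
              alternative = alternative, method = method, n = sizes)
  class(res) <- "jt_test"
  res
}

#' @export
print.jt_test <- function(x, ...) {
  cat("Jonckheere-Terpstra test\n")
  cat(sprintf("  groups: %s (n = %d)\n", paste(x$n, collapse = "/"), sum(x$n)))
  cat(sprintf("  J = %.4g, mu0 = %.4g, var0 = %.4g, z = %.4f\n",
              x$J, x$mu0, x$var0, x$z))
  cat(sprintf("  p = %.4g (%s, %s)\n", x$p.value, x$alternative, x$method))
  invisible(x)
}

#' Tercile trend analysis of cumulative risk against demographics
#'
#' For each demographic subgroup (and, when stratified, within each system
#' size class present in the cohort), arrays systems into terciles of the
#' subgroup percentage, summarises the median lifetime risk and total
#' population per tercile, and runs the Jonckheere-Terpstra trend test on
#' lifetime risk across terciles. Strata with fewer than `min_n` systems
#' report their terciles skipped with a reason instead of a test.
#'
#' @param cohort Included system profiles with `pwsid`,
#'   `reported_population`, `lifetime_risk`, `size_class` and `pct_*`
#'   columns.
#' @param subgroups Names of the percentage columns to analyse; default
#'   every `pct_*` column.
#' @param by_size If TRUE, also analyse within each size class.
#' @param alternative,method,nperm,seed Passed to [jonckheere_terpstra()].
#' @param min_n Minimum stratum size for running the trend test (default 6).
#' @return A list of class `disparity_report` with `terciles` (one row per
#'   tercile per stratum) and `tests` (one row per stratum) tibbles.
#' @export
run_disparity <- function(cohort,
                          subgroups = grep("^pct_", names(cohort), value = TRUE),
                          by_size = FALSE,
                          alternative = "two.sided",
                          method = "auto",
                          nperm = 1e5,
                          seed = NULL,
                          min_n = 6) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  strata <- list(list(size_class = "all", data = cohort))
  if (by_size) {
    for (sc in size_class_levels) {
      sub <- cohort[!is.na(cohort$size_class) & cohort$size_class == sc, ,
                    drop = FALSE]
      if (nrow(sub) > 0) {
        strata[[length(strata) + 1L]] <- list(size_class = sc, data = sub)
      }
    }
  }

  terciles <- list()
  tests <- list()
  for (sg in subgroups) {
    for (st in strata) {
      d <- st$data
      key <- tibble::tibble(subgroup = sg, size_class = st$size_class)
      if (nrow(d) < 3) {
        tests[[length(tests) + 1L]] <- dplyr::mutate(
          key, n = nrow(d), J = NA_real_, z = NA_real_, p.value = NA_real_,
          method = NA_character_, alternative = NA_character_,
          reason = "insufficient n")
        next
      }
      labels <- tercile_split(d[[sg]], d$pwsid)
      ts <- tercile_summary(labels, d, sg)
      terciles[[length(terciles) + 1L]] <- dplyr::bind_cols(
        key[rep(1, nrow(ts)), ], ts)
      if (nrow(d) < min_n) {
        tests[[length(tests) + 1L]] <- dplyr::mutate(
          key, n = nrow(d), J = NA_real_, z = NA_real_, p.value = NA_real_,
          method = NA_character_, alternative = NA_character_,
          reason = "insufficient n")
        next
      }
      jt <- jonckheere_terpstra(d$lifetime_risk, labels,
                                alternative = alternative, method = method,
                                nperm = nperm, seed = seed)
      tests[[length(tests) + 1L]] <- dplyr::mutate(
        key, n = nrow(d), J = jt$J, z = jt$z, p.value = jt$p.value,
        method = jt$method, alternative = jt$alternative,
        reason = NA_character_)
    }
  }
  out <- list(terciles = dplyr::bind_rows(terciles),
              tests = dplyr::bind_rows(tests))
  class(out) <- "disparity_report"
  out
}

#' @export
print.disparity_report <- function(x, ...) {
  cat("Disparity report:", nrow(x$tests), "trend test(s)\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}
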