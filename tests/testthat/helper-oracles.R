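# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: areas come from point sampling, J from a naive
# double loop, exact p-values from a from-first-principles enumeration.

# --- geometry -------------------------------------------------------------

# Even-odd ray-casting point-in-polygon (single part, no holes).
point_in_part <- function(px, py, part) {
  n <- nrow(part)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- part[i, 1]; yi <- part[i, 2]
    xj <- part[j, 1]; yj <- part[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_in_geom <- function(px, py, geom) {
  if (is.matrix(geom)) geom <- list(geom)
  for (part in geom) if (point_in_part(px, py, part)) return(TRUE)
  FALSE
}

# Monte-Carlo-free raster estimate of area(A intersect B) over a shared
# bounding box with an m x m grid of cell-centre sample points.
raster_intersection_area <- function(geom_a, geom_b, m = 200) {
  ba <- cwsdisparity:::bbox_of(geom_a)
  bb <- cwsdisparity:::bbox_of(geom_b)
  xmin <- max(ba["xmin"], bb["xmin"]); xmax <- min(ba["xmax"], bb["xmax"])
  ymin <- max(ba["ymin"], bb["ymin"]); ymax <- min(ba["ymax"], bb["ymax"])
  if (xmin >= xmax || ymin >= ymax) return(0)
  xs <- seq(xmin, xmax, length.out = m + 1)
  xs <- (xs[-1] + xs[-length(xs)]) / 2
  ys <- seq(ymin, ymax, length.out = m + 1)
  ys <- (ys[-1] + ys[-length(ys)]) / 2
  hits <- 0L
  for (px in xs) for (py in ys) {
    if (point_in_geom(px, py, geom_a) && point_in_geom(px, py, geom_b)) {
      hits <- hits + 1L
    }
  }
  hits / (m * m) * (xmax - xmin) * (ymax - ymin)
}

# --- Jonckheere-Terpstra --------------------------------------------------

# Naive O(n^2) J: count pairs across ordered groups directly.
naive_jt_J <- function(x, g) {
  g <- as.integer(factor(g))
  levels_ord <- sort(unique(g))
  J <- 0
  for (a in seq_along(levels_ord)) {
    for (b in seq_along(levels_ord)) {
      if (b <= a) next
      xa <- x[g == levels_ord[a]]
      xb <- x[g == levels_ord[b]]
      J <- J + sum(outer(xa, xb, "<")) + 0.5 * sum(outer(xa, xb, "=="))
    }
  }
  J
}

# Exact null distribution of J by enumerating every distinct assignment of
# the pooled observations to groups of the given sizes (first-principles
# recursion over index subsets, naive J counting).
brute_jt_null <- function(x, sizes) {
  n <- length(x)
  glab <- rep(seq_along(sizes), times = sizes)
  out <- numeric(0)
  recurse <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1) return(list(remaining))
    subsets <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    res <- list()
    for (s in subsets) {
      for (tail in recurse(setdiff(remaining, s), sizes_left[-1])) {
        res[[length(res) + 1L]] <- c(s, tail)
      }
    }
    res
  }
  for (idx in recurse(seq_len(n), sizes)) {
    out <- c(out, naive_jt_J(x[idx], glab))
  }
  out
}

brute_jt_exact_p <- function(x, g, alternative = "increasing") {
  g <- factor(g)
  sizes <- as.integer(table(g))
  ord <- order(g)
  xs <- x[ord]
  Jobs <- naive_jt_J(xs, rep(seq_along(sizes), times = sizes))
  null <- brute_jt_null(xs, sizes)
  mu0 <- mean(null)
  tol <- 1e-9
  switch(alternative,
         increasing = mean(null >= Jobs - tol),
         decreasing = mean(null <= Jobs + tol),
         two.sided = mean(abs(null - mu0) >= abs(Jobs - mu0) - tol))
}

# --- fixtures -------------------------------------------------------------

square_part <- function(x0 = 0, y0 = 0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

# A tiny tract table: k unit squares in a row with given populations and
# subgroup counts.
make_tract_row <- function(pops, subs, side = 1) {
  k <- length(pops)
  tibble::tibble(
    tract_id = sprintf("T%02d", seq_len(k)),
    population = pops,
    sub_minority = subs,
    geometry = lapply(seq_len(k), function(i) list(square_part((i - 1) * side, 0, side)))
  )
}

make_test_records <- function(pwsid, contaminant, values, unit = "ug/L",
                              dates = NULL) {
  n <- length(values)
  if (is.null(dates)) dates <- as.Date("2015-06-01") + seq_len(n)
  tibble::tibble(
    pwsid = pwsid,
    contaminant_id = contaminant,
    sample_date = dates,
    value = values,
    unit = unit,
    nondetect = is.na(values)
  )
}

simple_benchmarks <- function() {
  benchmark_table(data.frame(
    id = c("ARSENIC", "THM4", "HAA5", "HAA9"),
    benchmark = c(0.004, 0.15, 0.1, 0.06),
    unit = "ug/L"
  ))
}
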