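# Planar polygon primitives used by the areal-interpolation step.
#
# A polygon "part" is an n x 2 numeric matrix of vertices (not closed: the
# first vertex is not repeated at the end). A geometry is a list of one or
# more parts (a MultiPolygon whose parts may share edges but not interior
# area). Holes are not supported. All coordinates must be in one planar
# equal-area coordinate system; areas are in squared coordinate units.

#' Area of a polygon part or geometry
#'
#' Computes the planar (shoelace) area. For a geometry with several parts the
#' part areas are summed, which is exact when parts do not overlap in
#' interior area.
#'
#' @param geom An n x 2 vertex matrix, or a list of such matrices.
#' @return Non-negative area in squared coordinate units.
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
polygon_area <- function(geom) {
  if (is.matrix(geom)) {
    return(abs(signed_area(geom)))
  }
  sum(vapply(geom, function(p) abs(signed_area(p)), numeric(1)))
}

signed_area <- function(part) {
  x <- part[, 1]
  y <- part[, 2]
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Ensure counter-clockwise vertex order.
orient_ccw <- function(part) {
  if (signed_area(part) < 0) part[rev(seq_len(nrow(part))), , drop = FALSE] else part
}

is_convex_part <- function(part) {
  n <- nrow(part)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  nxt2 <- c(3:n, 1, 2)
  ex1 <- part[nxt, 1] - part[, 1]
  ey1 <- part[nxt, 2] - part[, 2]
  ex2 <- part[nxt2, 1] - part[nxt, 1]
  ey2 <- part[nxt2, 2] - part[nxt, 2]
  cr <- ex1 * ey2 - ey1 * ex2
  scale <- max(abs(cr), 1)
  all(cr >= -1e-12 * scale) || all(cr <= 1e-12 * scale)
}

validate_part <- function(part, label = "polygon") {
  if (!is.matrix(part) || ncol(part) != 2 || nrow(part) < 3 ||
      !is.numeric(part) || any(!is.finite(part))) {
    stop("invalid geometry for ", label,
         ": need a finite numeric n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (abs(signed_area(part)) == 0) {
    stop("invalid geometry for ", label, ": degenerate (zero-area) polygon",
         call. = FALSE)
  }
  invisible(part)
}

validate_geometry <- function(geom, label = "feature") {
  if (is.matrix(geom)) geom <- list(geom)
  if (!is.list(geom) || length(geom) == 0) {
    stop("invalid geometry for ", label, ": empty geometry", call. = FALSE)
  }
  for (part in geom) validate_part(part, label)
  invisible(geom)
}

# Sutherland-Hodgman: clip an arbitrary simple subject polygon against a
# CONVEX clip polygon. Returns the clipped vertex matrix (possibly with
# degenerate zero-area bridges for concave subjects, which is harmless for
# area computation), or NULL when the intersection is empty.
clip_to_convex <- function(subject, clip) {
  clip <- orient_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    # signed distance proxy: positive means inside (left of edge a->b)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    tol <- 1e-12 * max(abs(side), 1)
    inside <- side >= -tol
    if (all(inside)) next
    if (!any(inside)) return(NULL)
    n <- nrow(out)
    nxt <- c(2:n, 1)
    res_x <- numeric(0)
    res_y <- numeric(0)
    for (j in seq_len(n)) {
      k <- nxt[j]
      if (inside[j]) {
        res_x <- c(res_x, out[j, 1])
        res_y <- c(res_y, out[j, 2])
      }
      if (xor(inside[j], inside[k])) {
        # intersection of segment j->k with the infinite clip edge
        denom <- side[j] - side[k]
        t <- side[j] / denom
        res_x <- c(res_x, out[j, 1] + t * (out[k, 1] - out[j, 1]))
        res_y <- c(res_y, out[j, 2] + t * (out[k, 2] - out[j, 2]))
      }
    }
    out <- cbind(res_x, res_y)
  }
  if (is.null(out) || nrow(out) < 3) NULL else unname(out)
}

# Area of intersection between a geometry (list of simple parts, concave OK)
# and a single convex polygon part.
intersection_area_convex <- function(geom, clip_part) {
  if (is.matrix(geom)) geom <- list(geom)
  total <- 0
  for (part in geom) {
    clipped <- clip_to_convex(part, clip_part)
    if (!is.null(clipped)) total <- total + abs(signed_area(clipped))
  }
  total
}

bbox_of <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  xs <- unlist(lapply(geom, function(p) range(p[, 1])))
  ys <- unlist(lapply(geom, function(p) range(p[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bboxes_disjoint <- function(b1, b2) {
  b1["xmax"] < b2["xmin"] || b2["xmax"] < b1["xmin"] ||
    b1["ymax"] < b2["ymin"] || b2["ymax"] < b1["ymin"]
}

# Axis-aligned rectangle as a polygon part (CCW).
rect_part <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
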