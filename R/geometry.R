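#' Spherocylinder cell geometry
#'
#' A rod-shaped bacterial cell is modelled as a spherocylinder: a cylinder of
#' radius `radius` capped by two hemispheres, with pole-to-pole length
#' `length_total` (caps included). The cell lies in the focal plane with its
#' long axis at `axis_angle` degrees to the x-axis; the axis is at z = 0.
#' All lengths are in nanometres.
#'
#' @param length_total Pole-to-pole length in nm (must be >= 2 * radius).
#' @param radius Cell radius in nm (> 0).
#' @param center Numeric length-2, (x, y) of the cell centre in nm.
#' @param axis_angle In-plane angle of the long axis, degrees.
#' @param caps `"hemispherical"` for a true spherocylinder, `"none"` for an
#'   infinite open cylinder (periodic in nothing; molecules simply never meet
#'   a cap). The open cylinder is used for idealised membrane-diffusion
#'   studies.
#' @return An object of class `spherocylinder`.
#' @export
spherocylinder <- function(length_total, radius, center = c(0, 0),
                           axis_angle = 0, caps = c("hemispherical", "none")) {
  caps <- match.arg(caps)
  stopifnot(is.numeric(length_total), is.numeric(radius),
            length(center) == 2, is.numeric(axis_angle))
  if (radius <= 0) stop("radius must be > 0")
  if (caps == "hemispherical" && length_total < 2 * radius)
    stop("length_total must be >= 2 * radius")
  structure(list(
    length_total = length_total,
    radius = radius,
    center = as.numeric(center),
    axis_angle = axis_angle,
    caps = caps
  ), class = "spherocylinder")
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf(
    "spherocylinder: length %.0f nm, radius %.0f nm, centre (%.0f, %.0f), axis %.1f deg%s\n",
    x$length_total, x$radius, x$center[1], x$center[2], x$axis_angle,
    if (x$caps == "none") " (open cylinder)" else ""))
  invisible(x)
}

# half-length of the cylindrical section
sc_half_cyl <- function(cell) {
  if (cell$caps == "none") Inf else cell$length_total / 2 - cell$radius
}

# distance from points (n x 3, cell-local frame: axis along x, centre at 0)
# to the axis segment
sc_axis_dist_local <- function(cell, p) {
  hc <- sc_half_cyl(cell)
  ax <- pmin(pmax(p[, 1], -hc), hc)
  sqrt((p[, 1] - ax)^2 + p[, 2]^2 + p[, 3]^2)
}

#' Test whether 3D points lie inside a spherocylinder (cell-local frame)
#'
#' @param cell A [spherocylinder()].
#' @param p Numeric matrix n x 3 of positions in the cell-local frame
#'   (long axis along x, centre at the origin), nm.
#' @param tol Tolerance in nm.
#' @return Logical vector.
#' @export
sc_contains <- function(cell, p, tol = 0) {
  sc_axis_dist_local(cell, p) <= cell$radius + tol
}

# nearest point on the surface (cell-local frame); also used as the
# re-projection step of the membrane diffusion integrator
sc_project_surface <- function(cell, p) {
  hc <- sc_half_cyl(cell)
  ax <- pmin(pmax(p[, 1], -hc), hc)
  v <- cbind(p[, 1] - ax, p[, 2], p[, 3])
  d <- sqrt(rowSums(v^2))
  # points exactly on the axis have no unique projection; nudge radially
  deg <- d < 1e-12
  if (any(deg)) {
    v[deg, ] <- matrix(c(0, 0, 1), sum(deg), 3, byrow = TRUE)
    d[deg] <- 1
  }
  cbind(ax, 0, 0) + v * (cell$radius / d)
}

# reflect points that escaped the wall back inside (mirror across the tangent
# plane at the nearest surface point); iterated because a large step can
# re-exit near the caps
sc_reflect_inside <- function(cell, p) {
  for (it in 1:8) {
    d <- sc_axis_dist_local(cell, p)
    out <- d > cell$radius
    if (!any(out)) break
    s <- sc_project_surface(cell, p[out, , drop = FALSE])
    p[out, ] <- 2 * s - p[out, , drop = FALSE]
  }
  # numerical safety: clamp any stragglers onto the surface
  d <- sc_axis_dist_local(cell, p)
  out <- d > cell$radius
  if (any(out)) {
    p[out, ] <- sc_project_surface(cell, p[out, , drop = FALSE])
  }
  p
}

#' Sample points uniformly in the spherocylinder volume (cell-local frame)
#'
#' @inheritParams sc_contains
#' @param n Number of points.
#' @return n x 3 matrix, nm.
#' @export
sc_sample_volume <- function(cell, n) {
  hc <- sc_half_cyl(cell)
  if (!is.finite(hc)) stop("cannot volume-sample an infinite cylinder")
  R <- cell$radius
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 2.2)
    cand <- cbind(stats::runif(m, -hc - R, hc + R),
                  stats::runif(m, -R, R),
                  stats::runif(m, -R, R))
    cand <- cand[sc_contains(cell, cand), , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample points uniformly on the spherocylinder surface (cell-local frame)
#'
#' Area-weighted between the cylindrical wall and the two hemispherical caps.
#' For an open cylinder (`caps = "none"`) sampling is restricted to axial
#' positions within `length_total`/2 of the centre.
#'
#' @inheritParams sc_sample_volume
#' @return n x 3 matrix, nm.
#' @export
sc_sample_surface <- function(cell, n) {
  R <- cell$radius
  hc <- sc_half_cyl(cell)
  if (cell$caps == "none") {
    x <- stats::runif(n, -cell$length_total / 2, cell$length_total / 2)
    phi <- stats::runif(n, 0, 2 * pi)
    return(cbind(x, R * cos(phi), R * sin(phi)))
  }
  a_cyl <- 2 * pi * R * (2 * hc)
  a_cap <- 4 * pi * R^2           # two hemispheres = one sphere
  on_cyl <- stats::runif(n) < a_cyl / (a_cyl + a_cap)
  p <- matrix(0, n, 3)
  ncyl <- sum(on_cyl)
  if (ncyl) {
    x <- stats::runif(ncyl, -hc, hc)
    phi <- stats::runif(ncyl, 0, 2 * pi)
    p[on_cyl, ] <- cbind(x, R * cos(phi), R * sin(phi))
  }
  ncap <- n - ncyl
  if (ncap) {
    # uniform on the unit sphere, then shift each hemisphere onto its cap
    u <- matrix(stats::rnorm(3 * ncap), ncap, 3)
    u <- u / sqrt(rowSums(u^2))
    shift <- ifelse(u[, 1] >= 0, hc, -hc)
    p[!on_cyl, ] <- cbind(u[, 1] * R + shift, u[, 2] * R, u[, 3] * R)
  }
  p
}

#' Map cell-local coordinates to world focal-plane coordinates
#'
#' Rotates by the cell's axis angle, translates to its centre and drops z
#' (orthographic projection onto the focal plane).
#'
#' @inheritParams sc_contains
#' @return n x 2 matrix of (x, y) in nm.
#' @export
sc_local_to_world <- function(cell, p) {
  th <- cell$axis_angle * pi / 180
  x <- cos(th) * p[, 1] - sin(th) * p[, 2] + cell$center[1]
  y <- sin(th) * p[, 1] + cos(th) * p[, 2] + cell$center[2]
  cbind(x, y)
}

# minimal distance between the axis segments of two cells (world frame),
# used to reject overlapping cells
sc_axis_segment <- function(cell) {
  hc <- sc_half_cyl(cell)
  if (!is.finite(hc)) hc <- cell$length_total / 2 - cell$radius
  th <- cell$axis_angle * pi / 180
  u <- c(cos(th), sin(th))
  list(a = cell$center - hc * u, b = cell$center + hc * u)
}

segment_distance_2d <- function(p1, p2, q1, q2) {
  # minimum distance between segments [p1,p2] and [q1,q2]
  pts <- function(a, b, p) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    a + t * ab
  }
  d <- function(p, q) sqrt(sum((p - q)^2))
  min(d(p1, pts(q1, q2, p1)), d(p2, pts(q1, q2, p2)),
      d(q1, pts(p1, p2, q1)), d(q2, pts(p1, p2, q2)))
}

sc_overlaps <- function(c1, c2) {
  s1 <- sc_axis_segment(c1); s2 <- sc_axis_segment(c2)
  segment_distance_2d(s1$a, s1$b, s2$a, s2$b) < (c1$radius + c2$radius)
}
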