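#' Local density from the Voronoi tessellation
#'
#' Assigns each point the inverse area of its Voronoi polygon. Points whose
#' polygon is unbounded (points on or near the convex hull of the set) get
#' density 0, as their area is undefined.
#'
#' @param points Two-column matrix or data.frame of (x, y) positions, nm.
#' @return Numeric vector of densities in 1/nm^2 with attribute
#'   `delaunay_edges` (two-column index matrix of Voronoi-adjacent point
#'   pairs), for reuse by [segment_cells()].
#' @export
compute_local_densities <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points")
  # degenerate collinear input: the tessellation has no bounded polygons
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-12) {
    warning("degenerate (collinear) input: all densities set to 0")
    out <- rep(0, n)
    attr(out, "delaunay_edges") <- matrix(integer(), 0, 2)
    return(out)
  }
  span <- apply(pts, 2, range)
  pad <- 0.2 * max(span[2, ] - span[1, ]) + 1
  rw <- c(span[1, 1] - pad, span[2, 1] + pad,
          span[1, 2] - pad, span[2, 2] + pad)
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = rw, suppressMsge = TRUE)
  area <- dd$summary$dir.area
  dens <- ifelse(area > 0, 1 / area, 0)
  # polygons clipped by the enclosing window are unbounded in the plane:
  # flag every point whose tile has a boundary vertex or boundary segment
  gs <- dd$dirsgs
  on_bnd <- unique(c(gs$ind1[gs$bp1 | gs$bp2], gs$ind2[gs$bp1 | gs$bp2]))
  # tiles can also be cut by the window corner without a dirsgs flag; the
  # padded window makes that geometrically impossible for interior points
  dens[on_bnd] <- 0
  attr(dens, "delaunay_edges") <-
    cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  dens
}

#' Segment localization point clouds into candidate cells
#'
#' Thresholds Voronoi densities at `alpha_density` times the mean bounded
#' density and takes connected components of Voronoi-adjacent retained
#' points. Components are aligned by their covariance eigenvectors and
#' checked against `min_points` and `max_dim_nm` (merged multi-cell blobs
#' exceed the box and are rejected with a reason, as are undersized
#' components).
#'
#' @param points Two-column matrix/data.frame of (x, y) in nm, or a
#'   localization table with `x_nm`, `y_nm`.
#' @param alpha_density Density threshold as a multiple of the mean bounded
#'   density (default 2).
#' @param min_points Minimum localizations per accepted cell (default 300).
#' @param max_dim_nm Aligned bounding box limits (length, width), nm;
#'   default `c(4000, 1500)`.
#' @return List of `cell_cluster` objects (accepted or not); possibly empty.
#' @export
segment_cells <- function(points, alpha_density = 2, min_points = 300,
                          max_dim_nm = c(4000, 1500)) {
  pts <- as_points(points)
  if (nrow(pts) < 4) return(list())
  dens <- compute_local_densities(pts)
  edges <- attr(dens, "delaunay_edges")
  bounded <- dens > 0
  if (!any(bounded)) return(list())
  # field-average density: bounded points over the area they tessellate
  # (in-cell points have tiny polygons, so a plain mean of per-point
  # densities would sit at the in-cell level and shred the clusters)
  thr <- alpha_density * sum(bounded) / sum(1 / dens[bounded])
  core <- which(dens >= thr)
  if (!length(core)) return(list())
  sel <- edges[, 1] %in% core & edges[, 2] %in% core
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges[sel, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(core),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  comp_of <- rep(NA_integer_, nrow(pts))
  comp_of[as.integer(igraph::V(g)$name)] <- comp$membership
  # border attachment: a cell's rim has genuinely lower local density (thin
  # projected chord); points below the core threshold but above a floor are
  # attached to the component of the majority of their core neighbours
  floor_thr <- 0.25 * thr
  border <- which(is.na(comp_of) & dens >= floor_thr)
  if (length(border) && nrow(edges)) {
    cand <- rbind(cbind(p = edges[, 1], comp = comp_of[edges[, 2]]),
                  cbind(p = edges[, 2], comp = comp_of[edges[, 1]]))
    cand <- cand[cand[, 1] %in% border & !is.na(cand[, 2]), , drop = FALSE]
    if (nrow(cand)) {
      pick <- vapply(split(cand[, 2], cand[, 1]), function(v)
        as.integer(names(which.max(table(v)))), integer(1))
      comp_of[as.integer(names(pick))] <- pick
    }
  }
  out <- list()
  for (ci in seq_len(comp$no)) {
    idx <- which(comp_of == ci)
    cl <- new_cell_cluster(idx, pts[idx, , drop = FALSE])
    if (length(idx) < min_points) {
      cl$accepted <- FALSE
      cl$reason <- sprintf("too few points (%d < %d)", length(idx), min_points)
    } else {
      al <- align_cell(cl)
      bb <- apply(al$aligned, 2, function(v) diff(range(v)))
      if (bb[1] > max_dim_nm[1]) {
        cl <- al; cl$accepted <- FALSE
        cl$reason <- sprintf("exceeds max length (%.0f > %.0f nm)",
                             bb[1], max_dim_nm[1])
      } else if (bb[2] > max_dim_nm[2]) {
        cl <- al; cl$accepted <- FALSE
        cl$reason <- sprintf("exceeds max width (%.0f > %.0f nm)",
                             bb[2], max_dim_nm[2])
      } else {
        cl <- al
      }
    }
    out[[length(out) + 1L]] <- cl
  }
  # stable ordering: by size, largest first
  out[order(vapply(out, function(cl) -length(cl$indices), numeric(1)))]
}

as_points <- function(points) {
  if (is.data.frame(points) && all(c("x_nm", "y_nm") %in% names(points)))
    cbind(points$x_nm, points$y_nm)
  else as.matrix(points)[, 1:2, drop = FALSE]
}

new_cell_cluster <- function(indices, pts) {
  structure(list(
    indices = indices,
    points = pts,
    centroid = colMeans(pts),
    rotation_angle = 0,
    aligned = NULL,
    eigenvalues = NULL,
    accepted = TRUE,
    reason = NA_character_
  ), class = "cell_cluster")
}

#' @export
print.cell_cluster <- function(x, ...) {
  cat(sprintf("cell cluster: %d points, centroid (%.0f, %.0f) nm, rotation %.1f deg, %s\n",
              length(x$indices), x$centroid[1], x$centroid[2],
              x$rotation_angle,
              if (x$accepted) "accepted" else paste("rejected:", x$reason)))
  invisible(x)
}

#' Align a cell cluster to the x-axis
#'
#' Rotates the cluster's coordinates about its centroid so that the leading
#' eigenvector of the coordinate covariance lies along +x (rotation chosen
#' in (-90, 90] degrees; cells have no intrinsic left/right). The applied
#' rotation accumulates in `rotation_angle`; applying `align_cell` to an
#' already-aligned cluster is the identity, so alignment is idempotent.
#' Near-isotropic clusters (eigenvalue ratio < 1.05) are left unrotated with
#' a warning.
#'
#' @param cluster A `cell_cluster`.
#' @return The cluster with `aligned` coordinates (centroid at the origin),
#'   `eigenvalues`, and updated `rotation_angle`.
#' @export
align_cell <- function(cluster) {
  stopifnot(inherits(cluster, "cell_cluster"))
  pts <- if (is.null(cluster$aligned)) {
    sweep(cluster$points, 2, cluster$centroid)
  } else cluster$aligned
  eg <- eigen(stats::cov(pts), symmetric = TRUE)
  cluster$eigenvalues <- eg$values
  if (eg$values[1] / max(eg$values[2], 1e-300) < 1.05) {
    warning("near-isotropic cluster: alignment angle set to 0")
    cluster$aligned <- pts
    return(cluster)
  }
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi      # axis direction, degrees
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  rot <- -ang * pi / 180
  Rm <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
  cluster$aligned <- pts %*% t(Rm)
  colnames(cluster$aligned) <- NULL
  cluster$rotation_angle <- cluster$rotation_angle - ang
  cluster
}

#' Pole fraction implied by cell geometry
#'
#' The hemispherical pole of a rod-shaped cell spans one radius of the total
#' length, so the geometric pole fraction is `radius / length`. For average
#' cell dimensions of 2.02 um length and 0.32 um radius this gives 0.16,
#' motivating the default 20% pole regions.
#'
#' @param length Cell pole-to-pole length (any unit).
#' @param radius Cell radius (same unit).
#' @return `radius / length`.
#' @export
pole_fraction_from_geometry <- function(length, radius) {
  if (length <= 0 || radius <= 0) stop("length and radius must be > 0")
  radius / length
}

#' Assign pole and middle region labels in an aligned cell
#'
#' The cell length is taken as the span of aligned x-coordinates; the
#' leftmost and rightmost `pole_fraction` of the length are labelled
#' `pole_left` / `pole_right` and the remainder `middle`.
#'
#' @param cluster An aligned `cell_cluster`.
#' @param pole_fraction Fraction of the length per pole, in (0, 0.5);
#'   default 0.2.
#' @return List with `labels` (factor per member point, levels `pole_left`,
#'   `middle`, `pole_right`), `pole_fraction`, and the x break points.
#' @export
assign_regions <- function(cluster, pole_fraction = 0.2) {
  stopifnot(inherits(cluster, "cell_cluster"))
  if (is.null(cluster$aligned)) stop("cluster must be aligned first")
  if (pole_fraction <= 0 || pole_fraction >= 0.5)
    stop("pole_fraction must lie in (0, 0.5)")
  x <- cluster$aligned[, 1]
  len <- max(x) - min(x)
  if (len <= 0) stop("degenerate cluster: zero length")
  lo <- min(x) + pole_fraction * len
  hi <- max(x) - pole_fraction * len
  lab <- ifelse(x < lo, "pole_left", ifelse(x > hi, "pole_right", "middle"))
  list(labels = factor(lab, levels = c("pole_left", "middle", "pole_right")),
       pole_fraction = pole_fraction, breaks = c(lo, hi),
       length = len)
}
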