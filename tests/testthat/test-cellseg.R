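test_that("Voronoi densities are exact on a lattice and zero on the hull", {
  g <- as.matrix(expand.grid(x = seq(0, 1000, by = 100),
                             y = seq(0, 1000, by = 100)))
  d <- compute_local_densities(g)
  interior <- g[, 1] > 0 & g[, 1] < 1000 & g[, 2] > 0 & g[, 2] < 1000
  expect_equal(d[interior], rep(1e-4, sum(interior)), tolerance = 1e-9)
  expect_true(all(d[!interior] == 0))
})

test_that("interior densities average to n over area on a uniform cloud", {
  set.seed(12)
  n <- 4000
  pts <- cbind(runif(n, 0, 10000), runif(n, 0, 10000))
  d <- compute_local_densities(pts)
  # aggregate density of the tessellated interior: points per unit area
  d_mean <- sum(d > 0) / sum(1 / d[d > 0])
  expect_lt(abs(d_mean / (n / 1e8) - 1), 0.1)
})

test_that("degenerate point sets are handled explicitly", {
  expect_error(compute_local_densities(cbind(1:3, 1:3)), "at least 4")
  expect_warning(d <- compute_local_densities(cbind(1:10, 2 * (1:10))),
                 "collinear")
  expect_true(all(d == 0))
})

test_that("two separated cells are segmented with near-perfect membership", {
  set.seed(9)
  p1 <- cell_cloud(5000, 5000, 30, 5000)
  p2 <- cell_cloud(11000, 9000, -50, 5000)
  bg <- cbind(runif(800, 0, 16000), runif(800, 0, 16000))
  pts <- rbind(p1, p2, bg)
  truth <- rep(c(1, 2, 0), c(5000, 5000, 800))
  cls <- segment_cells(pts)
  acc <- Filter(function(x) x$accepted, cls)
  expect_length(acc, 2)
  for (cl in acc) {
    tt <- truth[cl$indices]
    lab <- as.integer(names(which.max(table(tt))))
    expect_gte(mean(tt == lab), 0.99)                 # purity
    expect_gte(sum(tt == lab) / 5000, 0.99)           # recall
    expect_false(is.null(cl$aligned))
  }
  # recovered orientations match the planted cells (sign convention:
  # rotation_angle is the rotation applied, minus the axis angle)
  angles <- sort(vapply(acc, function(cl) cl$rotation_angle, numeric(1)))
  expect_lt(abs(angles[1] - (-30)), 2)
  expect_lt(abs(angles[2] - 50), 2)
})

test_that("uniform background alone yields no accepted cell", {
  set.seed(14)
  pts <- cbind(runif(3000, 0, 10000), runif(3000, 0, 10000))
  expect_length(Filter(function(x) x$accepted, segment_cells(pts)), 0)
})

test_that("two cells 200 nm apart merge and are rejected for length", {
  set.seed(15)
  q1 <- cell_cloud(4000, 12000, 0, 2500)
  q2 <- cell_cloud(4000 + 2220, 12000, 0, 2500)
  bg <- cbind(runif(500, 0, 16000), runif(500, 0, 16000))
  cls <- segment_cells(rbind(q1, q2, bg))
  big <- cls[[which.max(vapply(cls, function(x) length(x$indices), numeric(1)))]]
  expect_gt(length(big$indices), 4000)
  expect_false(big$accepted)
  expect_match(big$reason, "exceeds max length")
})

test_that("segmentation is invariant under global rotation and translation", {
  set.seed(16)
  p <- rbind(cell_cloud(3000, 3000, 10, 1500),
             cell_cloud(7000, 6000, 70, 1500),
             cbind(runif(300, 0, 9000), runif(300, 0, 9000)))
  a <- 37 * pi / 180
  Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  q <- p %*% t(Rm) + matrix(c(1234, -987), nrow(p), 2, byrow = TRUE)
  memb <- function(cls) lapply(Filter(function(x) x$accepted, cls),
                               function(x) sort(x$indices))
  m1 <- memb(segment_cells(p, min_points = 200))
  m2 <- memb(segment_cells(q, min_points = 200))
  expect_length(m1, 2)
  expect_length(m2, 2)
  # membership invariant up to ties on the rim (Jaccard >= 0.995 per cell)
  for (a in m1) {
    jac <- vapply(m2, function(b)
      length(intersect(a, b)) / length(union(a, b)), numeric(1))
    expect_gte(max(jac), 0.995)
  }
})

test_that("alignment puts the long axis on x and is idempotent", {
  # points on a line at 45 degrees
  t <- seq(-1000, 1000, length.out = 200)
  cl <- smdmap:::new_cell_cluster(seq_along(t), cbind(t, t) / sqrt(2))
  al <- align_cell(cl)
  expect_equal(al$rotation_angle, -45, tolerance = 0.5)
  expect_lt(var(al$aligned[, 2]), 1e-12)
  # an aligned cell is a fixed point of align_cell
  al2 <- align_cell(al)
  expect_equal(al2$rotation_angle, al$rotation_angle, tolerance = 0.5)
  expect_lt(max(abs(al2$aligned - al$aligned)), 1e-9)
  # exactly isotropic cluster (regular polygon): refuse to rotate
  ph <- seq(0, 2 * pi, length.out = 13)[-13]
  iso <- smdmap:::new_cell_cluster(1:12, cbind(100 * cos(ph), 100 * sin(ph)))
  expect_warning(ali <- align_cell(iso), "isotropic")
  expect_equal(ali$rotation_angle, 0)
  # simulated cell at a known angle
  set.seed(19)
  cl30 <- smdmap:::new_cell_cluster(1:4000, cell_cloud(0, 0, 30, 4000))
  expect_equal(align_cell(cl30)$rotation_angle, -30, tolerance = 2)
  expect_true(diff(align_cell(cl30)$eigenvalues) <= 0)
})

test_that("pole fraction from geometry reproduces the printed rationale", {
  # 0.32 um radius over 2.02 um length
  expect_equal(round(pole_fraction_from_geometry(2.02, 0.32), 2), 0.16)
  expect_equal(pole_fraction_from_geometry(2020, 320), 320 / 2020)
  expect_error(pole_fraction_from_geometry(0, 1))
})

test_that("region labels partition the cell 20/60/20 along x", {
  x <- seq(0.5, 99.5, by = 1) * 10           # 100 evenly spaced points
  cl <- smdmap:::new_cell_cluster(seq_along(x), cbind(x, 0))
  cl$aligned <- cbind(x - mean(x), 0)
  rg <- assign_regions(cl, pole_fraction = 0.2)
  expect_equal(as.vector(table(rg$labels)), c(20, 60, 20))
  # uniform random x converges to the same fractions
  set.seed(20)
  xr <- runif(20000, 0, 2000)
  clr <- smdmap:::new_cell_cluster(seq_along(xr), cbind(xr, 0))
  clr$aligned <- cbind(xr - mean(xr), rnorm(20000, sd = 50))
  fr <- table(assign_regions(clr)$labels) / 20000
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_lt(abs(fr[["pole_left"]] - 0.2), 3 * se)
  expect_lt(abs(fr[["middle"]] - 0.6), 3 * sqrt(0.6 * 0.4 / 20000))
  # degenerate and invalid inputs
  cl0 <- smdmap:::new_cell_cluster(1:10, cbind(rep(1, 10), 1:10))
  cl0$aligned <- cbind(rep(0, 10), 1:10)
  expect_error(assign_regions(cl0), "degenerate")
  expect_error(assign_regions(cl, pole_fraction = 0.6), "pole_fraction")
})
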