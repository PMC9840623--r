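# Shared fixtures and independent oracles for the test suite.

# Rayleigh step lengths for free 2D diffusion: per-coordinate variance
# 2 D dt (D in um^2/s, dt in ms, lengths in nm).
rayleigh_steps <- function(n, D, dt) {
  s <- sqrt(2 * D * 1e3 * dt)
  sqrt(rnorm(n, sd = s)^2 + rnorm(n, sd = s)^2)
}

# Independent implementation of the truncated mixture-of-Rayleighs density
# with linear background, written directly from the model definition. Kept
# separate from the package's displacement_pdf on purpose: it is the oracle
# the fitting path is checked against.
oracle_pdf <- function(r, D, f, b, r_max, dt) {
  fourDdt <- 4 * D * 1e3 * dt
  num <- b * r
  for (i in seq_along(D))
    num <- num + f[i] * 2 * r / fourDdt[i] * exp(-r^2 / fourDdt[i])
  den <- 1 - sum(f * exp(-r_max^2 / fourDdt)) + b / 2 * r_max^2
  num / den
}

# rejection sampler from oracle_pdf on [0, r_max]
oracle_draw <- function(n, D, f = 1, b = 0, r_max = 600, dt = 1.5) {
  grid <- seq(1e-3, r_max, length.out = 4096)
  M <- max(oracle_pdf(grid, D, f, b, r_max, dt)) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, r_max)
    u <- runif(2 * n, 0, M)
    out <- c(out, x[u < oracle_pdf(x, D, f, b, r_max, dt)])
  }
  out[seq_len(n)]
}

# localization table skeleton from bare coordinates
loc_table <- function(frame, x, y) {
  data.table::data.table(
    frame = as.integer(frame), x_nm = as.numeric(x), y_nm = as.numeric(y),
    amplitude = 200, background = 10, sigma_x_nm = 130, sigma_y_nm = 130,
    pair_id = NA_character_)
}

# world-frame points of a simulated cell's localization cloud
cell_cloud <- function(cx, cy, angle, n, length_nm = 2020, radius_nm = 320) {
  cell <- spherocylinder(length_nm, radius_nm, c(cx, cy), angle)
  sc_local_to_world(cell, sc_sample_volume(cell, n))
}

# synthetic displacement set with a known local diffusion field:
# start points uniform in [0, lx] x [0, ly], step lengths Rayleigh at
# D_of(x, y), random direction, truncated at r_max
field_displacements <- function(n, lx, ly, D_of, dt = 1.5, r_max = 600) {
  x0 <- runif(n, 0, lx); y0 <- runif(n, 0, ly)
  r <- rayleigh_steps(n, 1, dt) * sqrt(D_of(x0, y0))
  ok <- r <= r_max
  th <- runif(n, 0, 2 * pi)
  displacement_set(
    data.table::data.table(
      x0 = x0[ok], y0 = y0[ok],
      x1 = x0[ok] + r[ok] * cos(th[ok]), y1 = y0[ok] + r[ok] * sin(th[ok]),
      r = r[ok], pair = seq_len(sum(ok))),
    dt = dt, r_max = r_max)
}
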