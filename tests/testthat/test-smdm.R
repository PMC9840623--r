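test_that("displacement densities integrate to 1 and vanish at r = 0", {
  cases <- list(
    list(D = 1, f = 1, b = 1e-7, dt = 1.5),
    list(D = 5, f = 1, b = 0, dt = 1.5),
    list(D = c(2, 0.12), f = c(0.6, 0.4), b = 2e-7, dt = 10),
    list(D = c(7, 1, 0.05), f = c(0.5, 0.3, 0.2), b = 5e-8, dt = 1.5))
  for (cs in cases) {
    I <- integrate(function(r)
      displacement_pdf(r, cs$D, cs$dt, f = cs$f, b = cs$b, r_max = 600),
      0, 600, rel.tol = 1e-10, abs.tol = 1e-12)
    expect_lt(abs(I$value - 1), 1e-8)
    expect_equal(displacement_pdf(0, cs$D, cs$dt, f = cs$f, b = 0,
                                  r_max = 600), 0)
  }
  # untruncated background-free case
  I <- integrate(function(r) displacement_pdf(r, 1, 10, r_max = Inf),
                 0, Inf, rel.tol = 1e-10)
  expect_lt(abs(I$value - 1), 1e-8)
  expect_error(displacement_pdf(700, 1, 1.5, r_max = 600), "r must lie")
  expect_error(displacement_pdf(-1, 1, 1.5, r_max = 600), "r must lie")
})

test_that("the pdf matches an independently coded density and merges equal components", {
  r <- seq(1, 599, length.out = 97)
  got <- displacement_pdf(r, c(2, 0.12), 10, f = c(0.6, 0.4), b = 2e-7,
                          r_max = 600)
  expect_equal(got, oracle_pdf(r, c(2, 0.12), c(0.6, 0.4), 2e-7, 600, 10),
               tolerance = 1e-12)
  two <- displacement_pdf(r, c(1, 1), 1.5, f = c(0.5, 0.5), r_max = 600)
  one <- displacement_pdf(r, 1, 1.5, r_max = 600)
  expect_equal(two, one, tolerance = 1e-12)
})

test_that("closed-form diffusion reproduces the r_max sanity bound", {
  expect_equal(closed_form_diffusion(rep(600, 5), dt = 1.5), 60)
  expect_equal(closed_form_diffusion(rep(600, 5), dt = 10), 9)
  expect_equal(closed_form_diffusion(0, dt = 1.5), 0)
  expect_error(closed_form_diffusion(numeric(), dt = 1.5), "empty")
})

test_that("displacement extraction follows the parity and cutoff rules", {
  # one peak in each frame of the pair, 100 nm apart
  ds <- extract_displacements(loc_table(c(1, 2), c(0, 100), c(0, 0)),
                              dt = 1.5)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$r, 100)
  # second-frame peak beyond r_max
  ds2 <- extract_displacements(loc_table(c(1, 2), c(0, 700), c(0, 0)),
                               dt = 1.5)
  expect_equal(nrow(ds2), 0)
  # all-candidates policy: two admissible second-frame peaks, two records
  ds3 <- extract_displacements(loc_table(c(1, 2, 2), c(0, 100, 400), c(0, 0, 0)),
                               dt = 1.5)
  expect_equal(sort(ds3$r), c(100, 400))
  # nearest-only alternative keeps the mutual nearest match
  ds4 <- extract_displacements(loc_table(c(1, 2, 2), c(0, 100, 400), c(0, 0, 0)),
                               dt = 1.5, pairing = "nearest")
  expect_equal(ds4$r, 100)
  # frames 2 and 3 belong to different pairs: no record
  ds5 <- extract_displacements(loc_table(c(2, 3), c(0, 50), c(0, 0)),
                               dt = 1.5)
  expect_equal(nrow(ds5), 0)
  expect_equal(nrow(extract_displacements(loc_table(integer(), numeric(),
                                                    numeric()), dt = 1.5)), 0)
})

test_that("degenerate MLE equals the closed form exactly", {
  # all displacements equal: D = r^2 / (4 dt), here 200 nm at 10 ms -> 1.0
  ft <- fit_displacement_mle(rep(200, 60), n_components = 1, dt = 10,
                             r_max = Inf, fix_b = 0)
  expect_equal(ft$components$D, 1.0, tolerance = 1e-5)
  expect_error(fit_displacement_mle(rep(200, 10), 1, dt = 10, r_max = Inf,
                                    fix_b = 0), "refusing")
})

test_that("single-component MLE agrees with the moment oracle when truncation is negligible", {
  set.seed(101)
  r <- rayleigh_steps(1e4, D = 0.5, dt = 1.5)  # rms ~ 55 nm << 600
  ft <- fit_displacement_mle(r, 1, dt = 1.5, r_max = 600, fix_b = 0)
  expect_lt(abs(ft$components$D / closed_form_diffusion(r, dt = 1.5) - 1),
            0.01)
})

test_that("MLE recovers one- and two-component parameters from model draws", {
  set.seed(202)
  r1 <- oracle_draw(1e4, D = 5, b = 0, r_max = 600, dt = 1.5)
  f1 <- fit_displacement_mle(r1, 1, dt = 1.5, r_max = 600)
  expect_lt(abs(f1$components$D / 5 - 1), 0.05)
  expect_true(f1$converged)

  r2 <- oracle_draw(1e4, D = c(2, 0.12), f = c(0.6, 0.4), b = 0,
                    r_max = 600, dt = 10)
  f2 <- fit_displacement_mle(r2, 2, dt = 10, r_max = 600, fix_b = 0)
  expect_lt(abs(f2$components$f[1] - 0.6), 0.05)
  expect_lt(abs(f2$components$D[1] / 2 - 1), 0.15)
  expect_lt(abs(f2$components$D[2] / 0.12 - 1), 0.15)
  # fractions sum to 1, components sorted by descending D
  expect_equal(sum(f2$components$f), 1)
  expect_true(!is.unsorted(rev(f2$components$D)))
})

test_that("adding a component never lowers the maximized log-likelihood", {
  set.seed(303)
  r <- oracle_draw(4e3, D = c(2, 0.12), f = c(0.6, 0.4), b = 0,
                   r_max = 600, dt = 10)
  l1 <- fit_displacement_mle(r, 1, dt = 10, r_max = 600, fix_b = 0)$loglik
  l2 <- fit_displacement_mle(r, 2, dt = 10, r_max = 600, fix_b = 0)$loglik
  expect_gte(l2, l1 - 1e-6)
})

test_that("the background term absorbs uniform false pairings", {
  set.seed(404)
  n <- 8000
  r_true <- rayleigh_steps(n, D = 2, dt = 10)
  r_true <- r_true[r_true <= 600]
  D_free <- c(); D_fix <- c()
  for (frac in c(0.05, 0.1, 0.2)) {
    fake <- 600 * sqrt(runif(round(frac * length(r_true))))
    r <- c(r_true, fake)
    D_free <- c(D_free,
                fit_displacement_mle(r, 1, dt = 10, r_max = 600)$components$D)
    D_fix <- c(D_fix,
               fit_displacement_mle(r, 1, dt = 10, r_max = 600,
                                    fix_b = 0)$components$D)
  }
  # with b free the estimate stays near truth even at 20% contamination
  expect_lt(max(abs(D_free / 2 - 1)), 0.10)
  # with b fixed to zero the inflation grows monotonically with the load
  expect_true(all(diff(D_fix) > 0))
  expect_gt(D_fix[3], D_free[3])
})

test_that("diffusivity maps recover a homogeneous field and mask sparse pixels", {
  set.seed(505)
  ds <- field_displacements(6e4, lx = 2000, ly = 600,
                            D_of = function(x, y) rep(5, length(x)))
  map <- build_diffusion_map(ds, grid_nm = 50, min_count = 30, b = 0)
  expect_true(any(map$valid))
  err <- abs(map$D[map$valid] / 5 - 1)
  expect_gte(mean(err < 0.25), 0.9)
  # count-weighted pixel mean agrees with the whole-set fit
  whole <- fit_displacement_mle(ds, 1, fix_b = 0)$components$D
  wmean <- sum(map$D[map$valid] * map$count[map$valid]) /
    sum(map$count[map$valid])
  expect_lt(abs(wmean / whole - 1), 0.15)
  # pixels below min_count are masked but counted
  expect_true(all(map$count[!map$valid & map$count > 0] < 30))
})

test_that("diffusivity maps resolve a two-zone cell in the right direction", {
  set.seed(606)
  ds <- field_displacements(6e4, lx = 2000, ly = 600,
                            D_of = function(x, y) ifelse(x < 1000, 5, 0.5))
  map <- build_diffusion_map(ds, grid_nm = 50, min_count = 30, b = 0)
  nx <- ncol(map$D)
  left <- map$D[, seq_len(floor(nx / 2))]
  right <- map$D[, (floor(nx / 2) + 1):nx]
  expect_gte(median(left, na.rm = TRUE) / median(right, na.rm = TRUE), 5)
})
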