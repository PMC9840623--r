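render_single <- function(A = 200, B = 10, x = 480, y = 430,
                          sigma = 130, fov = 900, noise = FALSE) {
  photons <- A * 2 * pi * sigma * sigma / 100^2
  tab <- loc_table(1, x, y)
  stk <- render_frames(tab, psf_sigma_nm = sigma, photons_per_spot = photons,
                       fov_nm = c(fov, fov), offset = B, shot_noise = noise)
  stk[, , 1]
}

test_that("noiseless spot fits recover all parameters within 1%", {
  roi <- render_single()
  ft <- fit_gaussian_spot(roi)
  expect_true(ft$accepted)
  expect_lt(abs(ft$A / 200 - 1), 0.01)
  expect_lt(abs(ft$B / 10 - 1), 0.01)
  expect_lt(abs(ft$x0 / 480 - 1), 0.01)
  expect_lt(abs(ft$y0 / 430 - 1), 0.01)
  expect_lt(abs(ft$sigma_x / 130 - 1), 0.01)
  expect_lt(abs(ft$sigma_y / 130 - 1), 0.01)
})

test_that("spot centres stay unbiased and sub-pixel under shot noise", {
  set.seed(31)
  ex <- ey <- numeric(50)
  for (i in 1:50) {
    roi <- render_single(noise = TRUE)
    ft <- fit_gaussian_spot(roi)
    ex[i] <- ft$x0 - 480
    ey[i] <- ft$y0 - 430
  }
  expect_lt(sd(ex), 100)          # well below one 100 nm pixel
  expect_lt(sd(ey), 100)
  expect_lt(abs(mean(ex)), 5)     # nm
  expect_lt(abs(mean(ey)), 5)
})

test_that("degenerate rois are rejected with a reason code", {
  flat <- matrix(10, 9, 9)
  ft <- fit_gaussian_spot(flat)
  expect_false(ft$accepted)
  expect_equal(ft$reason, "no signal")
  expect_error(fit_gaussian_spot(matrix(0, 5, 5)), "7 x 7")
})

test_that("fit residual at the optimum does not exceed the initializer residual", {
  set.seed(77)
  roi <- render_single(noise = TRUE)
  init <- list(B = 12, A = 150, x0 = 420, y0 = 470,
               sigma_x = 110, sigma_y = 160)
  ft <- fit_gaussian_spot(roi, init = init)
  # residual sum of squares of the initializer, same pixel-integrated model
  model_rss <- function(p) {
    nx <- ncol(roi); ny <- nrow(roi)
    gx <- (pnorm(((1:nx) * 100 - p$x0) / p$sigma_x) -
             pnorm(((0:(nx - 1)) * 100 - p$x0) / p$sigma_x)) *
      p$sigma_x * sqrt(2 * pi) / 100
    gy <- (pnorm(((1:ny) * 100 - p$y0) / p$sigma_y) -
             pnorm(((0:(ny - 1)) * 100 - p$y0) / p$sigma_y)) *
      p$sigma_y * sqrt(2 * pi) / 100
    sum((roi - (p$B + p$A * outer(gy, gx)))^2)
  }
  expect_lte(ft$rss, model_rss(init))
})

test_that("a rendered emitter grid is recovered exactly by the localizer", {
  set.seed(55)
  nside <- 6                         # 36 well-separated emitters
  cc <- as.matrix(expand.grid(x = seq(1500, 9000, length.out = nside),
                              y = seq(1500, 9000, length.out = nside)))
  cc <- cc + matrix(runif(2 * nrow(cc), -40, 40), ncol = 2)
  tab <- loc_table(1, cc[, 1], cc[, 2])
  stk <- render_frames(tab, psf_sigma_nm = 130, photons_per_spot = 3000,
                       fov_nm = c(10500, 10500), offset = 100)
  loc <- localize_stack(stk)
  expect_equal(nrow(loc), nrow(cc))
  d <- sqrt(outer(cc[, 1], loc$x_nm, "-")^2 + outer(cc[, 2], loc$y_nm, "-")^2)
  expect_lt(max(apply(d, 1, min)), 1)
  # pure-offset frames produce nothing
  empty <- render_frames(loc_table(integer(), numeric(), numeric()),
                         fov_nm = c(3000, 3000), offset = 100, n_frames = 2)
  expect_equal(nrow(localize_stack(empty)), 0)
})

test_that("unresolvable emitter pairs are never accepted as a merged spot", {
  tab <- loc_table(c(1, 1), c(2000, 2150), c(2000, 2000))  # 150 nm apart
  stk <- render_frames(tab, psf_sigma_nm = 130, photons_per_spot = 3000,
                       fov_nm = c(4000, 4000), offset = 100)
  loc <- localize_stack(stk)
  if (nrow(loc) == 1) {
    # a single accepted row must be a genuine resolved emitter, not the
    # inflated-width midpoint blob
    expect_lt(abs(loc$x_nm - 2075), 40)
    fail("merged midpoint localization was accepted")
  }
  expect_true(nrow(loc) %in% c(0L, 2L))
})

test_that("localization is equivariant under integer pixel shifts", {
  tab <- loc_table(1, 1540, 1230)
  stk <- render_frames(tab, psf_sigma_nm = 130, photons_per_spot = 3000,
                       fov_nm = c(3000, 3000), offset = 100)
  sh <- array(100, dim = dim(stk))
  sh[(1 + 3):30, (1 + 2):30, 1] <- stk[1:27, 1:28, 1]  # shift by (+2, +3) px
  l0 <- localize_stack(stk)
  l1 <- localize_stack(sh)
  expect_equal(l1$x_nm - l0$x_nm, 200, tolerance = 1e-6)
  expect_equal(l1$y_nm - l0$y_nm, 300, tolerance = 1e-6)
})

drift_fixture <- function(n, n_frames, slope_x, slope_y, seed) {
  set.seed(seed)
  base <- rbind(cell_cloud(3000, 3000, 20, n / 2),
                cell_cloud(6000, 5000, -40, n / 2))
  fr <- sample.int(n_frames, n, replace = TRUE)
  tab <- loc_table(fr, base[, 1] + slope_x * fr + rnorm(n, sd = 20),
                   base[, 2] + slope_y * fr + rnorm(n, sd = 20))
  list(tab = tab, base = base, fr = fr)
}

test_that("injected linear drift is recovered and removed", {
  fx <- drift_fixture(10000, 10000, 2, -0.4, seed = 21)
  dc <- estimate_and_apply_drift(fx$tab)
  sl <- coef(lm(dx_nm ~ frame, dc$drift))[[2]]
  expect_lt(abs(sl / 2 - 1), 0.10)
  expect_equal(dc$drift$dx_nm[1], 0)    # reference segment pinned at zero
  # corrected coordinates match the pre-drift truth (up to the reference
  # offset) with residual RMS below the localization error
  ex <- dc$table$x_nm - (fx$tab$x_nm - 2 * fx$fr)
  ey <- dc$table$y_nm - (fx$tab$y_nm + 0.4 * fx$fr)
  expect_lt(sqrt(mean((ex - mean(ex))^2)), 20)
  expect_lt(sqrt(mean((ey - mean(ey))^2)), 20)
})

test_that("drift-free tables are left essentially untouched", {
  fx <- drift_fixture(50000, 10000, 0, 0, seed = 33)
  dc <- estimate_and_apply_drift(fx$tab)
  expect_lt(max(abs(c(dc$drift$dx_nm, dc$drift$dy_nm))), 5)
})

test_that("degenerate drift inputs degrade to identity with a warning", {
  fx <- drift_fixture(500, 1500, 1, 0, seed = 3)
  expect_warning(dc <- estimate_and_apply_drift(fx$tab), "single segment")
  expect_equal(dc$table$x_nm, fx$tab$x_nm)
  expect_equal(nrow(dc$drift), 1)
  # enough segments but one of them starved
  fx2 <- drift_fixture(120, 10000, 1, 0, seed = 4)
  expect_warning(dc2 <- estimate_and_apply_drift(fx2$tab), "too few")
  expect_equal(dc2$table$y_nm, fx2$tab$y_nm)
})
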